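# Shared fixtures: one modest training problem reused across test files.
# A 300-subject cohort keeps the float training + INQ pipeline to a few
# seconds while still giving a discriminative network (ideal C ~ 0.70).
fix_data <- generate_whas_like(generator_params(n = 300, seed = 5))
fix_net <- train(NULL, fix_data, train_config(epochs = 300, seed = 3))
fix_qnet <- inq_train(fix_net, fix_data,
                      inq_plan(epochs_per_step = 40, seed = 7),
                      train_config(seed = 3))
fix_assign <- assign_pairs(fix_qnet, base_level = "L6", algorithm = "ml_set")

# Device config with a given drift-amplitude multiplier (mu_inf only;
# p_drift and sigma untouched) -- used for drift-stress studies.
drift_amplitude_config <- function(k) {
  cfg <- device_config()
  for (alg in c("ml_set", "ml_hybrid")) {
    for (l in paste0("L", 1:9)) {
      cfg$algorithms[[alg]]$levels[[l]]$mu_inf <-
        cfg$algorithms[[alg]]$levels[[l]]$mu_inf * k
    }
  }
  cfg
}

# Degenerate (effectively noise- and drift-free) device model.
degenerate_config <- function(sigma = 1e-9) {
  cfg <- scale_device_config(device_config(), drift_mult = 0)
  for (alg in c("ml_set", "ml_hybrid")) {
    for (l in paste0("L", 1:9)) {
      cfg$algorithms[[alg]]$levels[[l]]$sigma0 <- sigma
    }
  }
  cfg
}

# Gaussian-only config (no drift) with one common sigma for all levels.
gaussian_config <- function(sigma) {
  cfg <- scale_device_config(device_config(), drift_mult = 0)
  for (alg in c("ml_set", "ml_hybrid")) {
    for (l in paste0("L", 1:9)) {
      cfg$algorithms[[alg]]$levels[[l]]$sigma0 <- sigma
    }
  }
  cfg
}
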