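#' Peripheral circuit specification
#'
#' Power and latency of the digital periphery around the crossbars, with
#' defaults taken from published 14 nm DSP/ADC and 130 nm DAC designs:
#' DSP 18.35 uW / 20 ns, ADC 41.3 uW / 20 ns, DAC 100 uW / 500 ns. The
#' DSP clock period equals the DSP latency (20 ns). Component counts
#' default to the four-crossbar floor plan: 54 DACs (6 first-layer + 48
#' second-layer, each set working in parallel), 4 ADCs (one per crossbar)
#' and 2 DSPs, and are overridable.
#'
#' @param dsp_power,adc_power,dac_power Watts.
#' @param dsp_latency,adc_latency,dac_latency Seconds.
#' @param dsp_clock DSP clock period, seconds (default = `dsp_latency`).
#' @param n_dac,n_adc,n_dsp Component counts for the power budget.
#' @return A `peripheral_spec`.
#' @export
peripheral_spec <- function(dsp_power = 18.35e-6, dsp_latency = 20e-9,
                            adc_power = 41.3e-6, adc_latency = 20e-9,
                            dac_power = 100e-6, dac_latency = 500e-9,
                            dsp_clock = dsp_latency,
                            n_dac = 54L, n_adc = 4L, n_dsp = 2L) {
  vals <- c(dsp_power, dsp_latency, adc_power, adc_latency,
            dac_power, dac_latency, dsp_clock)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop_memsurv("peripheral powers/latencies must be non-negative numbers",
                 "memsurv_parameter_error")
  }
  structure(list(dsp_power = dsp_power, dsp_latency = dsp_latency,
                 adc_power = adc_power, adc_latency = adc_latency,
                 dac_power = dac_power, dac_latency = dac_latency,
                 dsp_clock = dsp_clock,
                 n_dac = as.integer(n_dac), n_adc = as.integer(n_adc),
                 n_dsp = as.integer(n_dsp)),
            class = "peripheral_spec")
}

#' Latency of one crossbar layer
#'
#' Timing model of a layer's inference chain: the DACs convert all inputs
#' in parallel (one DAC latency), the two polarity ADCs run in parallel,
#' each converting its `n_outputs` bitline values sequentially, and the
#' pipelined DSP adds a single tail stage. With the default periphery and
#' 48 outputs: 500 ns + 48 x 20 ns + 20 ns = 1.48 us.
#'
#' @param spec A [peripheral_spec()].
#' @param n_outputs Number of bitline outputs converted per polarity.
#' @return Seconds.
#' @export
layer_latency <- function(spec = peripheral_spec(), n_outputs) {
  if (!is_count(n_outputs)) {
    stop_memsurv("n_outputs must be a positive integer",
                 "memsurv_parameter_error")
  }
  spec$dac_latency + n_outputs * spec$adc_latency + spec$dsp_latency
}

#' Total inference latency
#'
#' Sum of the crossbar layer latencies plus the final digital linear
#' combination of the output neuron. The combination occupies
#' `final_clocks` DSP clock periods, but because the DSP accumulates the
#' 48 products as the ADC values stream in, only the last clock extends
#' the critical path (`pipelined = TRUE`, the default); setting
#' `pipelined = FALSE` serializes the full `final_clocks` after the last
#' layer instead. With the default two 48-output layers:
#' 1.48 us + 1.48 us + 20 ns = 2.98 us.
#'
#' @param spec A [peripheral_spec()].
#' @param layer_outputs Integer vector of per-layer output counts
#'   (default `c(48, 48)`).
#' @param final_clocks DSP clock cycles occupied by the output
#'   combination (default 10; 0 drops the stage entirely).
#' @param pipelined Whether the final combination overlaps the ADC
#'   stream (default TRUE).
#' @return Seconds.
#' @export
inference_latency <- function(spec = peripheral_spec(),
                              layer_outputs = c(48L, 48L),
                              final_clocks = 10L,
                              pipelined = TRUE) {
  exposed <- if (pipelined) min(final_clocks, 1L) else final_clocks
  sum(vapply(layer_outputs, function(k) layer_latency(spec, k), 0)) +
    exposed * spec$dsp_clock
}

#' Throughput from latency
#'
#' @param tau_i Inference latency, seconds (> 0).
#' @param integer_display Floor the result to whole inferences per second
#'   (default TRUE, matching how accelerator throughput is reported).
#' @return Inferences per second.
#' @export
throughput <- function(tau_i, integer_display = TRUE) {
  if (!is_scalar_num(tau_i) || tau_i <= 0) {
    stop_memsurv("latency must be > 0", "memsurv_parameter_error")
  }
  tr <- 1 / tau_i
  if (integer_display) floor(tr) else tr
}

#' Energy per inference and efficiency
#'
#' `E_inf = P_inf * tau_i` (joules) and `gamma = Tr / P_inf`
#' (inferences per joule).
#'
#' @param p_inf Power per inference, watts (> 0).
#' @param tau_i Inference latency, seconds (> 0).
#' @param tr Throughput, 1/s (> 0).
#' @return Joules / inferences-per-joule.
#' @export
energy_per_inference <- function(p_inf, tau_i) {
  if (!is_scalar_num(p_inf) || p_inf <= 0 || !is_scalar_num(tau_i) || tau_i <= 0) {
    stop_memsurv("power and latency must be > 0", "memsurv_parameter_error")
  }
  p_inf * tau_i
}

#' @rdname energy_per_inference
#' @export
efficiency <- function(tr, p_inf) {
  if (!is_scalar_num(tr) || tr <= 0 || !is_scalar_num(p_inf) || p_inf <= 0) {
    stop_memsurv("throughput and power must be > 0", "memsurv_parameter_error")
  }
  tr / p_inf
}

#' Total inference power
#'
#' MVM read power plus the periphery budget:
#' `P_inf = P_mvm + n_dac P_dac + n_adc P_adc + n_dsp P_dsp`.
#'
#' @param mvm_power_w Crossbar MVM power, watts.
#' @param spec A [peripheral_spec()].
#' @return Watts.
#' @export
inference_power <- function(mvm_power_w, spec = peripheral_spec()) {
  if (!is_scalar_num(mvm_power_w) || mvm_power_w < 0) {
    stop_memsurv("MVM power must be non-negative", "memsurv_parameter_error")
  }
  mvm_power_w + spec$n_dac * spec$dac_power + spec$n_adc * spec$adc_power +
    spec$n_dsp * spec$dsp_power
}

#' Giga-operations metrics
#'
#' Counts the multiply-accumulate operations of one inference over the
#' mapped layers (6x48 and 48x48) and the 48-wide digital tail, under one
#' of two conventions: `"mac2_differential_once"` counts each differential
#' synapse once (2 ops per MAC: multiply + accumulate), giving
#' (288 + 2304 + 48) x 2 = 5280 ops; `"mac2_per_polarity"` counts the
#' analog MACs once per polarity crossbar, giving
#' (288 + 2304) x 2 x 2 + 48 x 2 = 10464 ops.
#'
#' @param tau_i Inference latency, seconds.
#' @param p_inf Inference power, watts.
#' @param convention Op-counting convention (see above).
#' @param layer_sizes Synapse counts of the mapped layers
#'   (default `c(288, 2304)`).
#' @param tail_size Digital tail synapse count (default 48).
#' @return List with `ops_per_inference`, `gops` (GOP/s) and `gopj`
#'   (GOP/J).
#' @export
gop_metrics <- function(tau_i, p_inf,
                        convention = c("mac2_differential_once",
                                       "mac2_per_polarity"),
                        layer_sizes = c(288L, 2304L), tail_size = 48L) {
  convention <- match.arg(convention)
  ops <- switch(convention,
                mac2_differential_once = (sum(layer_sizes) + tail_size) * 2,
                mac2_per_polarity = sum(layer_sizes) * 2 * 2 + tail_size * 2)
  gops <- ops / tau_i * 1e-9
  list(ops_per_inference = ops, gops = gops, gopj = gops / p_inf,
       convention = convention)
}

#' Assemble mutually consistent figures of merit
#'
#' @param mvm_power_w MVM power, watts.
#' @param spec A [peripheral_spec()].
#' @param layer_outputs,final_clocks Passed to [inference_latency()].
#' @param convention Passed to [gop_metrics()].
#' @return A `figures_of_merit` list: `tau_i` (s), `throughput` (1/s,
#'   exact), `throughput_display` (floored), `p_inf` (W), `e_inf` (J),
#'   `efficiency` (inf/J), `gops`, `gopj`. The identities
#'   `Tr * tau_i = 1`, `E_inf = P_inf * tau_i` and
#'   `gamma = Tr / P_inf` hold exactly.
#' @export
figures_of_merit <- function(mvm_power_w, spec = peripheral_spec(),
                             layer_outputs = c(48L, 48L), final_clocks = 10L,
                             convention = "mac2_differential_once") {
  tau <- inference_latency(spec, layer_outputs, final_clocks)
  tr <- throughput(tau, integer_display = FALSE)
  p <- inference_power(mvm_power_w, spec)
  gop <- gop_metrics(tau, p, convention)
  structure(list(
    tau_i = tau,
    throughput = tr,
    throughput_display = floor(tr),
    p_inf = p,
    e_inf = energy_per_inference(p, tau),
    efficiency = efficiency(tr, p),
    gops = gop$gops,
    gopj = gop$gopj,
    convention = gop$convention
  ), class = "figures_of_merit")
}

#' Break-even inference count of a programming-energy overhead
#'
#' ML-Hybrid doubles the programming cost of L2-L5 cells but saves energy
#' on every inference; this returns the number of inferences after which
#' the extra programming energy is amortized:
#' `ceiling(extra_energy / per_inference_saving)`.
#'
#' @param extra_programming_energy Joules (>= 0).
#' @param per_inference_saving Joules (> 0).
#' @return Integer inference count.
#' @export
amortization_breakeven <- function(extra_programming_energy,
                                   per_inference_saving) {
  if (!is_scalar_num(per_inference_saving) || per_inference_saving <= 0) {
    stop_memsurv("no break-even: per-inference saving must be > 0",
                 "memsurv_no_breakeven_error")
  }
  if (!is_scalar_num(extra_programming_energy) || extra_programming_energy < 0) {
    stop_memsurv("programming overhead must be >= 0",
                 "memsurv_parameter_error")
  }
  ceiling(extra_programming_energy / per_inference_saving)
}
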