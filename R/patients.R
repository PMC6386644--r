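# Synthetic patients: stand-ins for a patient's PC-MRI + cuff-pressure
# dataset, with known ground-truth Windkessel parameters for recovery
# tests. Draw ranges follow the cohort tables (inflow 3.7-6.3 L/min,
# systolic 94-131 / diastolic 49-66 mmHg, branch areas within the measured
# ranges) with the flow split centered on the pre-operative mean split
# (BCT 12%, LCCA 4%, LSA 4.8%, DAo 79%).

#' Generate a synthetic patient with known ground truth
#'
#' Draws an inflow waveform, outlet areas, target mean-flow split (summing
#' exactly to the inflow mean), cuff pressure targets, and ground-truth
#' three-element Windkessel parameters per outlet. Resistance totals follow
#' `R_total,i = MAP / Q_mean,i` with MAP = (sys + 2 dia)/3; the proximal
#' fraction is drawn log-uniformly on (0.05, 0.2) and the total compliance
#' log-uniformly on (0.8, 2.5) mL/mmHg, distributed across outlets in
#' proportion to branch conductance. All draws are governed by `seed`;
#' regeneration with the same seed is bit-identical.
#'
#' @param seed integer seed.
#' @return Object of class `synthetic_patient`: list with `inflow`,
#'   `outlets` (per-outlet name, `area_cm2`, `target_mean_flow_lpm`, `wk`),
#'   `target_sys`, `target_dia`, `seed`.
#' @export
gen_synthetic_patient <- function(seed = 1) {
  draws <- with_seed(seed, {
    list(mean_lpm = stats::runif(1, 3.7, 6.3),
         peak_factor = stats::runif(1, 3.2, 4.2),
         period = stats::runif(1, 0.8, 1.0),
         wave_seed = sample.int(.Machine$integer.max - 1L, 1),
         split_jitter = stats::runif(4, -0.3, 0.3),
         areas = c(BCT = stats::runif(1, 0.95, 6.09),
                   LCCA = stats::runif(1, 0.39, 1.44),
                   LSA = stats::runif(1, 0.75, 2.90),
                   DAo = stats::runif(1, 3.0, 6.0)),
         sys = stats::runif(1, 94, 131),
         dia = stats::runif(1, 49, 66),
         prox_frac = exp(stats::runif(4, log(0.05), log(0.2))),
         c_total = exp(stats::runif(1, log(0.8), log(2.5))))
  })

  inflow <- gen_inflow_waveform(draws$mean_lpm,
                                draws$peak_factor * draws$mean_lpm,
                                draws$period, 256, seed = draws$wave_seed)
  base_split <- c(BCT = 0.1197, LCCA = 0.0405, LSA = 0.0483, DAo = 0.7915)
  split <- base_split * exp(draws$split_jitter)
  split <- split / sum(split)
  target_lpm <- draws$mean_lpm * split

  map <- (draws$sys + 2 * draws$dia) / 3
  qbar_mls <- m3s_to_mls(lpm_to_m3s(target_lpm))
  r_total <- map / qbar_mls
  g <- 1 / r_total
  c_i <- draws$c_total * g / sum(g)

  outlets <- lapply(seq_along(target_lpm), function(i) {
    list(name = names(target_lpm)[i],
         area_cm2 = unname(draws$areas[i]),
         target_mean_flow_lpm = unname(target_lpm[i]),
         wk = wk3_params(unname(draws$prox_frac[i] * r_total[i]),
                         unname(c_i[i]),
                         unname((1 - draws$prox_frac[i]) * r_total[i])))
  })
  names(outlets) <- names(target_lpm)

  structure(list(inflow = inflow, outlets = outlets,
                 target_sys = draws$sys, target_dia = draws$dia,
                 seed = as.integer(seed)),
            class = "synthetic_patient")
}

#' @export
print.synthetic_patient <- function(x, ...) {
  cat(sprintf(
    "<synthetic_patient> seed %d; inflow %.2f L/min, targets %.0f/%.0f mmHg\n",
    x$seed, mean_flow(x$inflow), x$target_sys, x$target_dia))
  for (o in x$outlets) {
    cat(sprintf("  %-4s area %.2f cm^2, target flow %.2f L/min, R_total %.3g\n",
                o$name, o$area_cm2, o$target_mean_flow_lpm,
                o$wk$r_prox + o$wk$r_dist))
  }
  invisible(x)
}

#' Build a pre-TEVAR arch model from a synthetic patient
#'
#' @param patient a [gen_synthetic_patient()] result.
#' @return A pre-TEVAR [arch_model()] with the patient's ground-truth
#'   Windkessel parameters.
#' @export
as_arch_model <- function(patient) {
  stopifnot(inherits(patient, "synthetic_patient"))
  outs <- lapply(patient$outlets, function(o) {
    outlet_branch(o$name, o$area_cm2, o$wk)
  })
  arch_model(patient$inflow, outs, topology = "pre_tevar")
}
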