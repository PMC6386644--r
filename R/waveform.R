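# Pulsatile flow waveforms: one closed cardiac cycle of volumetric flow.

#' Construct a flow waveform
#'
#' A `flow_waveform` holds one cardiac cycle of volumetric flow sampled on a
#' closed grid: `times[1] == 0`, `times[length(times)] == period`, and the
#' first and last flow samples agree (periodicity). Flows are stored in SI
#' (m^3/s); the clinical I/O unit is L/min.
#'
#' @param times_s strictly increasing sample times in seconds, spanning one
#'   period from 0 to `period`.
#' @param flows_m3s volumetric flow at each sample, m^3/s.
#' @return An object of class `flow_waveform` with fields `times`, `flows`,
#'   `period`.
#' @export
flow_waveform <- function(times_s, flows_m3s) {
  times_s <- as.numeric(times_s)
  flows_m3s <- as.numeric(flows_m3s)
  if (length(times_s) < 2L || length(times_s) != length(flows_m3s)) {
    stop("times and flows must have equal length >= 2", call. = FALSE)
  }
  if (any(!is.finite(times_s)) || any(!is.finite(flows_m3s))) {
    stop("non-finite samples in waveform", call. = FALSE)
  }
  if (any(diff(times_s) <= 0)) {
    stop("invalid waveform: times must be strictly increasing", call. = FALSE)
  }
  if (abs(times_s[1]) > 1e-12) {
    stop("invalid waveform: times must start at 0", call. = FALSE)
  }
  period <- times_s[length(times_s)]
  if (period <= 0) stop("invalid waveform: period must be positive", call. = FALSE)
  scale <- max(abs(flows_m3s), 1e-300)
  if (abs(flows_m3s[1] - flows_m3s[length(flows_m3s)]) > 1e-9 * scale) {
    stop("invalid waveform: endpoint flow must equal start flow (periodicity)",
         call. = FALSE)
  }
  structure(list(times = times_s, flows = flows_m3s, period = period),
            class = "flow_waveform")
}

#' @export
print.flow_waveform <- function(x, ...) {
  cat(sprintf(
    "<flow_waveform> %d samples over %.4g s; mean %.3f L/min, peak %.3f L/min\n",
    length(x$times), x$period, mean_flow(x), peak_flow(x)))
  invisible(x)
}

#' Cycle-mean and peak flow of a waveform
#'
#' `mean_flow()` is the trapezoidal average over the cycle; `peak_flow()` the
#' cycle maximum. Both are reported in L/min, the unit of the source tables.
#'
#' @param w a [flow_waveform()].
#' @return Flow in L/min.
#' @export
mean_flow <- function(w) {
  stopifnot(inherits(w, "flow_waveform"))
  m3s_to_lpm(trapz(w$times, w$flows) / w$period)
}

#' @rdname mean_flow
#' @export
peak_flow <- function(w) {
  stopifnot(inherits(w, "flow_waveform"))
  m3s_to_lpm(max(w$flows))
}

#' Generate a PC-MRI-like pulsatile inflow waveform
#'
#' Synthesises one cardiac cycle with a single dominant systolic peak: a
#' half-sine systolic bump occupying the first 35% of the cycle plus four
#' low-amplitude Fourier harmonics (seeded), affinely rescaled so that the
#' trapezoidal cycle mean and the cycle maximum match the requested values
#' exactly. With `peak_flow == mean_flow` the waveform is constant.
#'
#' @param mean_flow_lpm requested cycle-mean flow, L/min (> 0).
#' @param peak_flow_lpm requested peak flow, L/min (>= mean).
#' @param period_s cycle duration, seconds (default 1).
#' @param n_samples number of intervals per cycle (>= 32); the closed grid
#'   has `n_samples + 1` points.
#' @param seed integer seed controlling the harmonic perturbation.
#' @return A [flow_waveform()].
#' @examples
#' w <- gen_inflow_waveform(5, 20, 1, 256, seed = 1)
#' mean_flow(w) # 5
#' @export
gen_inflow_waveform <- function(mean_flow_lpm, peak_flow_lpm, period_s = 1,
                                n_samples = 256, seed = 1) {
  if (!is.finite(mean_flow_lpm) || mean_flow_lpm <= 0) {
    stop("invalid waveform: mean flow must be positive", call. = FALSE)
  }
  if (!is.finite(peak_flow_lpm) || peak_flow_lpm < mean_flow_lpm) {
    stop("invalid waveform: peak flow must be >= mean flow", call. = FALSE)
  }
  if (period_s <= 0) stop("invalid waveform: period must be positive", call. = FALSE)
  if (n_samples < 32) stop("invalid waveform: n_samples must be >= 32", call. = FALSE)

  t <- seq(0, period_s, length.out = n_samples + 1)
  if (peak_flow_lpm == mean_flow_lpm) {
    q <- rep(lpm_to_m3s(mean_flow_lpm), n_samples + 1)
    return(flow_waveform(t, q))
  }

  x <- t / period_s
  sys_frac <- 0.35
  s <- ifelse(x < sys_frac, sin(pi * x / sys_frac), 0)
  h <- with_seed(seed, list(amp = stats::runif(4, 0, 0.05),
                            phase = stats::runif(4, 0, 2 * pi)))
  for (k in 1:4) s <- s + h$amp[k] * sin(2 * pi * k * x + h$phase[k])
  s[n_samples + 1] <- s[1] # close the cycle exactly

  s_mean <- trapz(t, s) / period_s
  s_max <- max(s)
  b <- (peak_flow_lpm - mean_flow_lpm) / (s_max - s_mean)
  a <- mean_flow_lpm - b * s_mean
  flow_waveform(t, lpm_to_m3s(a + b * s))
}
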