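# Three-element Windkessel (RCR) outlet circuit: proximal resistance R_prox
# in series with a parallel compliance C / distal resistance R_dist pair,
# representing the distal vascular bed. Governing ODE for the distal
# (capacitor) pressure P_d, with Q the imposed branch flow:
#
#   C dP_d/dt = Q(t) - P_d / R_dist,      P(t) = P_d(t) + R_prox Q(t)
#
# Units follow clinical convention: pressures mmHg, flows mL/s, resistances
# mmHg.s/mL, compliance mL/mmHg.

#' Three-element Windkessel parameters
#'
#' @param r_prox proximal (characteristic) resistance, mmHg.s/mL.
#' @param c compliance, mL/mmHg.
#' @param r_dist distal resistance, mmHg.s/mL.
#' @return Object of class `wk3_params`.
#' @export
wk3_params <- function(r_prox, c, r_dist) {
  vals <- c(r_prox = r_prox, c = c, r_dist = r_dist)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("parameter error: Windkessel parameters must be positive and finite",
         call. = FALSE)
  }
  structure(list(r_prox = r_prox, c = c, r_dist = r_dist), class = "wk3_params")
}

#' @export
print.wk3_params <- function(x, ...) {
  cat(sprintf(
    "<wk3_params> R_prox %.4g, C %.4g, R_dist %.4g (R_total %.4g mmHg.s/mL, tau %.3g s)\n",
    x$r_prox, x$c, x$r_dist, x$r_prox + x$r_dist, x$c * x$r_dist))
  invisible(x)
}

#' Pressure trace over one or more cardiac cycles
#'
#' @param times_s sample times, s, strictly increasing.
#' @param pressures_mmhg pressures, mmHg.
#' @param cycle_starts indices of the first sample of each cycle.
#' @param period_s cycle duration, s.
#' @return Object of class `pressure_trace`.
#' @export
pressure_trace <- function(times_s, pressures_mmhg, cycle_starts, period_s) {
  if (any(diff(times_s) <= 0)) {
    stop("trace error: times must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(pressures_mmhg))) {
    stop("trace error: non-finite pressures", call. = FALSE)
  }
  structure(list(times = as.numeric(times_s),
                 pressures = as.numeric(pressures_mmhg),
                 cycle_starts = as.integer(cycle_starts),
                 period = period_s),
            class = "pressure_trace")
}

#' @export
print.pressure_trace <- function(x, ...) {
  lc <- tryCatch(suppressWarnings(last_cycle(x)), error = function(e) x)
  cat(sprintf(
    "<pressure_trace> %d cycles of %.4g s; last cycle %0.1f/%0.1f (mean %0.1f) mmHg\n",
    length(x$cycle_starts), x$period, max(lc$pressures), min(lc$pressures),
    trapz(lc$times, lc$pressures) / (max(lc$times) - min(lc$times))))
  invisible(x)
}

# Number of cycles in a trace
n_cycles_of <- function(trace) length(trace$cycle_starts)

# Indices of samples belonging to cycle k (closed interval, shares its end
# sample with the next cycle's start).
cycle_indices <- function(trace, k) {
  starts <- trace$cycle_starts
  from <- starts[k]
  to <- if (k < length(starts)) starts[k + 1] else length(trace$times)
  from:to
}

cycle_mean_pressure <- function(trace, k) {
  i <- cycle_indices(trace, k)
  trapz(trace$times[i], trace$pressures[i]) /
    (trace$times[i[length(i)]] - trace$times[i[1]])
}

#' Simulate a three-element Windkessel against an imposed flow
#'
#' Integrates the RCR circuit ODE with the trapezoidal (Crank–Nicolson)
#' rule — second-order accurate and A-stable — at a fixed step of
#' `period / steps_per_cycle`. The default initial state is the exact
#' periodic fixed point of the discretised map (available in closed form for
#' this linear one-step scheme), so every simulated cycle is already the
#' converged periodic solution; `init = "mean"` instead starts from the
#' warm-start value `P_d(0) = R_dist * mean inflow` and converges over the
#' simulated cycles. Six cycles are simulated by default and downstream
#' analyses use the last one.
#'
#' @param params a [wk3_params()].
#' @param inflow a [flow_waveform()] (branch flow imposed on the circuit).
#' @param n_cycles number of cardiac cycles to simulate (>= 1).
#' @param steps_per_cycle time steps per cycle (>= 100).
#' @param init `"periodic"` (default) or `"mean"` initial distal pressure.
#' @return A [pressure_trace()] of the outlet pressure `P = P_d + R_prox Q`
#'   over all simulated cycles.
#' @export
simulate_wk3 <- function(params, inflow, n_cycles = 6, steps_per_cycle = 1000,
                         init = c("periodic", "mean")) {
  stopifnot(inherits(params, "wk3_params"), inherits(inflow, "flow_waveform"))
  init <- match.arg(init)
  if (n_cycles < 1) stop("parameter error: n_cycles must be >= 1", call. = FALSE)
  if (steps_per_cycle < 100) {
    stop("parameter error: steps_per_cycle must be >= 100", call. = FALSE)
  }
  period <- inflow$period
  n <- as.integer(steps_per_cycle)
  tq <- seq(0, period, length.out = n + 1)
  q <- stats::approx(inflow$times, m3s_to_mls(inflow$flows), xout = tq)$y
  qbar <- trapz(tq, q) / period

  h <- period / n
  a <- h / (2 * params$c)
  A <- (1 - a / params$r_dist) / (1 + a / params$r_dist)
  # forcing for each step within one cycle
  B1 <- a * (q[-(n + 1)] + q[-1]) / (1 + a / params$r_dist)

  pd0 <- if (init == "mean") {
    params$r_dist * qbar
  } else {
    # exact periodic fixed point of the affine cycle map pd -> A^n pd + K
    K <- as.numeric(stats::filter(B1, A, method = "recursive"))[n]
    K / (1 - A^n)
  }

  B <- rep(B1, n_cycles)
  B[1] <- B[1] + A * pd0
  pd <- c(pd0, as.numeric(stats::filter(B, A, method = "recursive")))
  qq <- c(q[1], rep(q[-1], n_cycles))
  p <- pd + params$r_prox * qq
  times <- seq(0, n_cycles * period, length.out = n_cycles * n + 1)
  pressure_trace(times, p, cycle_starts = (seq_len(n_cycles) - 1L) * n + 1L,
                 period_s = period)
}

#' Extract the final cardiac cycle of a pressure trace
#'
#' Returns the last cycle with times rebased to `[0, period]`. A convergence
#' warning (not an error) is raised when the mean pressures of the last two
#' cycles differ by 0.1% relative or more, mirroring the requirement that
#' results be taken from a converged final cycle.
#'
#' @param trace a [pressure_trace()] with at least two complete cycles.
#' @return A single-cycle [pressure_trace()].
#' @export
last_cycle <- function(trace) {
  stopifnot(inherits(trace, "pressure_trace"))
  nc <- n_cycles_of(trace)
  if (nc < 2) {
    stop("insufficient cycles: need >= 2 to extract a converged last cycle",
         call. = FALSE)
  }
  m_prev <- cycle_mean_pressure(trace, nc - 1)
  m_last <- cycle_mean_pressure(trace, nc)
  drift <- abs(m_last - m_prev) / abs(m_prev)
  if (drift >= 1e-3) {
    warning(sprintf("pressure not converged: last-two-cycle mean drift %.3g%%",
                    100 * drift), call. = FALSE)
  }
  i <- cycle_indices(trace, nc)
  pressure_trace(trace$times[i] - trace$times[i[1]], trace$pressures[i],
                 cycle_starts = 1L, period_s = trace$period)
}

# Relative drift between the means of the last two cycles.
cycle_drift <- function(trace) {
  nc <- n_cycles_of(trace)
  stopifnot(nc >= 2)
  m_prev <- cycle_mean_pressure(trace, nc - 1)
  m_last <- cycle_mean_pressure(trace, nc)
  abs(m_last - m_prev) / abs(m_prev)
}

#' Calibrate a three-element Windkessel to cuff pressures and measured flow
#'
#' Finds RCR parameters reproducing a patient's brachial-cuff systolic and
#' diastolic pressures under a measured flow waveform. The total resistance
#' is initialised from the cuff mean-pressure estimate
#' `MAP = (sys + 2 dia) / 3` as `R_total = MAP / Q_mean` and split as
#' `R_prox = prox_fraction * R_total` (characteristic-impedance heuristic);
#' the compliance is found by a monotone root search on pulse pressure
#' (pulse pressure decreases monotonically with C). Because the simulated
#' trace's own systolic/diastolic/mean relationship need not satisfy the
#' one-third cuff rule exactly, an outer update then shifts `R_total` (and
#' hence the mean pressure) until the achieved systolic and diastolic both
#' land on target; on return `R_total` equals achieved mean pressure over
#' mean flow.
#'
#' @param inflow a [flow_waveform()] of the branch flow.
#' @param target_sys,target_dia target systolic/diastolic pressures, mmHg
#'   (`target_sys > target_dia > 0`).
#' @param prox_fraction fraction of total resistance assigned to `R_prox`
#'   (default 0.09; must lie in (0, 0.5)).
#' @param tol_mmhg convergence tolerance on the achieved systolic and
#'   diastolic pressures, mmHg.
#' @param c_bracket compliance search bracket, mL/mmHg.
#' @param n_cycles,steps_per_cycle passed to [simulate_wk3()].
#' @return A [wk3_params()] whose re-simulation reproduces the targets
#'   within `tol_mmhg`, with attributes `achieved` (sys, dia) and `c_search`.
#' @export
calibrate_wk3 <- function(inflow, target_sys, target_dia, prox_fraction = 0.09,
                          tol_mmhg = 0.25, c_bracket = c(1e-3, 10),
                          n_cycles = 6, steps_per_cycle = 1000) {
  stopifnot(inherits(inflow, "flow_waveform"))
  if (!(target_sys > target_dia && target_dia > 0)) {
    stop("parameter error: require target_sys > target_dia > 0", call. = FALSE)
  }
  if (!(prox_fraction > 0 && prox_fraction < 0.5)) {
    stop("parameter error: prox_fraction must lie in (0, 0.5)", call. = FALSE)
  }
  qbar <- m3s_to_mls(lpm_to_m3s(mean_flow(inflow)))
  map <- (target_sys + 2 * target_dia) / 3
  pp_target <- target_sys - target_dia

  sysdia <- function(rt, cc) {
    p <- wk3_params(prox_fraction * rt, cc, (1 - prox_fraction) * rt)
    lc <- last_cycle(simulate_wk3(p, inflow, n_cycles, steps_per_cycle))
    c(sys = max(lc$pressures), dia = min(lc$pressures))
  }

  rt <- map / qbar
  achieved <- c(sys = NA_real_, dia = NA_real_)
  cc <- NA_real_
  for (outer in 1:20) {
    g <- function(x) {
      sd <- sysdia(rt, x)
      (sd[["sys"]] - sd[["dia"]]) - pp_target
    }
    glo <- g(c_bracket[1]); ghi <- g(c_bracket[2])
    if (is.na(glo) || is.na(ghi) || glo * ghi > 0) {
      sd0 <- sysdia(rt, sqrt(prod(c_bracket)))
      stop(sprintf(paste0(
        "calibration failure: pulse-pressure targets unreachable with this ",
        "waveform (achieved sys %.1f, dia %.1f mmHg)"),
        sd0[["sys"]], sd0[["dia"]]), call. = FALSE)
    }
    cc <- stats::uniroot(g, c_bracket, tol = 1e-9)$root
    achieved <- sysdia(rt, cc)
    err_s <- achieved[["sys"]] - target_sys
    err_d <- achieved[["dia"]] - target_dia
    if (max(abs(err_s), abs(err_d)) <= tol_mmhg) break
    rt <- rt - ((err_s + err_d) / 2) / qbar # shift mean pressure onto target
  }
  out <- wk3_params(prox_fraction * rt, cc, (1 - prox_fraction) * rt)
  attr(out, "achieved") <- achieved
  attr(out, "c_search") <- c(compliance = cc, outer_iterations = outer)
  out
}
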