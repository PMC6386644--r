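# 0D aortic-arch network: the ascending-aortic inflow feeds a single common
# pressure node from which each branch (BCT, LCCA, LSA, descending aorta)
# drains through its own three-element Windkessel circuit. At every instant
# the node pressure satisfies the algebraic conservation constraint
#
#   sum_i (P - P_d,i) / R_prox,i = Q_in(t)
#
# and each distal pressure advances by its Windkessel ODE. Zone-2 TEVAR is a
# topology transform: the LSA outlet is removed from the arch and its distal
# bed re-attached behind the LCCA origin through a carotid-to-subclavian
# bypass resistance.

PRE_OUTLETS <- c("BCT", "LCCA", "LSA", "DAo")
POST_OUTLETS <- c("BCT", "LCCA", "DAo")

#' Define an arch outlet branch
#'
#' @param name outlet name: one of `"BCT"`, `"LCCA"`, `"LSA"`, `"DAo"`.
#' @param area_cm2 branch cross-sectional area just distal to its origin,
#'   cm^2 (> 0); used for velocity estimation.
#' @param wk a [wk3_params()] for the branch's distal bed.
#' @return Object of class `outlet_branch`.
#' @export
outlet_branch <- function(name, area_cm2, wk) {
  name <- match.arg(name, PRE_OUTLETS)
  if (!is.finite(area_cm2) || area_cm2 <= 0) {
    stop("model error: outlet area must be positive", call. = FALSE)
  }
  stopifnot(inherits(wk, "wk3_params"))
  structure(list(name = name, area = area_cm2, wk = wk),
            class = "outlet_branch")
}

#' Assemble a 0D aortic-arch model
#'
#' A pre-TEVAR model has outlets BCT, LCCA, LSA and DAo; a post-TEVAR model
#' (built with [apply_tevar()]) has BCT, LCCA and DAo, with the old LSA bed
#' reachable through the bypass. Names must be unique and complete for the
#' topology.
#'
#' @param inflow a [flow_waveform()] imposed at the ascending aorta.
#' @param outlets list of [outlet_branch()] objects.
#' @param topology `"pre_tevar"` or `"post_tevar"`.
#' @param bypass_resistance carotid-subclavian bypass resistance, mmHg.s/mL
#'   (post-TEVAR only, >= 0).
#' @return Object of class `arch_model`.
#' @export
arch_model <- function(inflow, outlets, topology = c("pre_tevar", "post_tevar"),
                       bypass_resistance = 0) {
  topology <- match.arg(topology)
  stopifnot(inherits(inflow, "flow_waveform"))
  if (!length(outlets)) stop("model error: empty outlet set", call. = FALSE)
  if (!all(vapply(outlets, inherits, TRUE, "outlet_branch"))) {
    stop("model error: outlets must be outlet_branch objects", call. = FALSE)
  }
  names(outlets) <- vapply(outlets, `[[`, "", "name")
  expect <- if (topology == "pre_tevar") PRE_OUTLETS else POST_OUTLETS
  if (!setequal(names(outlets), expect) || anyDuplicated(names(outlets))) {
    stop(sprintf("model error: %s topology requires outlets {%s}", topology,
                 paste(expect, collapse = ", ")), call. = FALSE)
  }
  if (!is.finite(bypass_resistance) || bypass_resistance < 0) {
    stop("model error: bypass_resistance must be >= 0", call. = FALSE)
  }
  structure(list(inflow = inflow, outlets = outlets[expect],
                 topology = topology, bypass_resistance = bypass_resistance,
                 lsa_bed = NULL, lsa_area = NULL),
            class = "arch_model")
}

#' @export
print.arch_model <- function(x, ...) {
  cat(sprintf("<arch_model> %s; inflow %.2f L/min; outlets: %s%s\n",
              x$topology, mean_flow(x$inflow),
              paste(names(x$outlets), collapse = ", "),
              if (x$topology == "post_tevar")
                sprintf("; bypass %.3g mmHg.s/mL", x$bypass_resistance)
              else ""))
  invisible(x)
}

#' Apply the zone-2 TEVAR topology transform
#'
#' Removes the LSA from the arch (its origin is covered by the stent graft)
#' and re-attaches its distal bed in parallel with the LCCA bed through the
#' carotid-to-subclavian bypass resistance. Electrically the bypass path
#' runs from the arch node through `bypass_resistance` in series with the
#' old LSA branch, and the flow it carries is counted as LCCA flow (it
#' enters through the LCCA origin). With zero bypass resistance the combined
#' LCCA branch conductance therefore equals the sum of the old LCCA and LSA
#' branch conductances.
#'
#' @param model a pre-TEVAR [arch_model()].
#' @param bypass_resistance bypass resistance, mmHg.s/mL (>= 0).
#' @param inflow optional post-operative inflow waveform; the post-operative
#'   ascending-aortic flow is an input, not a model prediction. Defaults to
#'   the pre-operative inflow.
#' @return A post-TEVAR [arch_model()].
#' @export
apply_tevar <- function(model, bypass_resistance = 0, inflow = NULL) {
  stopifnot(inherits(model, "arch_model"))
  if (model$topology != "pre_tevar") {
    stop("topology error: apply_tevar requires a pre-TEVAR model", call. = FALSE)
  }
  post <- arch_model(if (is.null(inflow)) model$inflow else inflow,
                     model$outlets[POST_OUTLETS],
                     topology = "post_tevar",
                     bypass_resistance = bypass_resistance)
  post$lsa_bed <- model$outlets$LSA$wk
  post$lsa_area <- model$outlets$LSA$area
  post
}

# Internal compartments actually simulated: for a post-TEVAR model the LSA
# bed persists as a hidden branch whose proximal resistance includes the
# bypass; its flow is reported under LCCA.
network_compartments <- function(model) {
  comps <- lapply(model$outlets, function(o) {
    list(name = o$name, report = o$name, r_prox = o$wk$r_prox,
         c = o$wk$c, r_dist = o$wk$r_dist)
  })
  if (model$topology == "post_tevar" && !is.null(model$lsa_bed)) {
    wk <- model$lsa_bed
    comps <- c(comps, list(bypass_LSA = list(
      name = "bypass_LSA", report = "LCCA",
      r_prox = wk$r_prox + model$bypass_resistance,
      c = wk$c, r_dist = wk$r_dist)))
  }
  comps
}

#' Simulate the 0D arch network
#'
#' Advances all distal-bed pressures with the trapezoidal rule applied to
#' the coupled (linear, constant-coefficient) system, with the node pressure
#' eliminated algebraically, so flow conservation holds to machine precision
#' at every step. The default initial state is the exact periodic fixed
#' point of the discretised cycle map; `init = "mean"` warm-starts each bed
#' at `R_dist,i * Q_mean,i`.
#'
#' @param model an [arch_model()].
#' @param n_cycles number of cardiac cycles (>= 2).
#' @param steps_per_cycle time steps per cycle (>= 100).
#' @param init `"periodic"` (default) or `"mean"`.
#' @return Object of class `network_result` with fields `node_pressure` (a
#'   [pressure_trace()] over all cycles), `flows` (last-cycle per-outlet
#'   [flow_waveform()]s, bypass flow folded into LCCA), `mean_flows` and
#'   `peak_flows` (L/min, last cycle), and `conservation` (max relative
#'   flow-sum residual over all steps).
#' @export
simulate_network <- function(model, n_cycles = 6, steps_per_cycle = 1000,
                             init = c("periodic", "mean")) {
  stopifnot(inherits(model, "arch_model"))
  init <- match.arg(init)
  if (n_cycles < 2) stop("parameter error: n_cycles must be >= 2", call. = FALSE)
  if (steps_per_cycle < 100) {
    stop("parameter error: steps_per_cycle must be >= 100", call. = FALSE)
  }
  comps <- network_compartments(model)
  m <- length(comps)
  rp <- vapply(comps, `[[`, 0, "r_prox")
  rd <- vapply(comps, `[[`, 0, "r_dist")
  cc <- vapply(comps, `[[`, 0, "c")
  G <- sum(1 / rp)

  period <- model$inflow$period
  n <- as.integer(steps_per_cycle)
  tq <- seq(0, period, length.out = n + 1)
  qin <- stats::approx(model$inflow$times, m3s_to_mls(model$inflow$flows),
                       xout = tq)$y
  h <- period / n

  # dPd/dt = M Pd + b(t):
  #   M_ij = [ 1/(G rp_i rp_j) - d_ij (1/rp_i + 1/rd_i) ] / c_i
  #   b_i  = Qin(t) / (G rp_i c_i)
  M <- outer(1 / rp, 1 / rp) / G
  diag(M) <- diag(M) - (1 / rp + 1 / rd)
  M <- M / cc
  bcoef <- 1 / (G * rp * cc)

  I_m <- diag(m)
  Aimp <- I_m - (h / 2) * M
  Bexp <- I_m + (h / 2) * M
  S <- solve(Aimp, Bexp)
  Ainv <- solve(Aimp)

  # per-step forcing within one cycle: (h/2) Ainv bcoef (qin_k + qin_{k+1})
  qsum <- qin[-(n + 1)] + qin[-1]
  Fstep <- (h / 2) * (Ainv %*% matrix(bcoef, ncol = 1)) %*% qsum # m x n

  step_through <- function(pd0) {
    pd <- matrix(0, m, n + 1)
    pd[, 1] <- pd0
    for (k in seq_len(n)) pd[, k + 1] <- S %*% pd[, k] + Fstep[, k]
    pd
  }

  qbar <- trapz(tq, qin) / period
  if (init == "mean") {
    # warm start: split mean flow by branch conductance
    g_branch <- 1 / (rp + rd)
    q0 <- qbar * g_branch / sum(g_branch)
    pd0 <- rd * q0
  } else {
    K <- step_through(rep(0, m))[, n + 1]
    Sn <- I_m
    Spow <- S
    k <- n
    while (k > 0) { # S^n by binary exponentiation
      if (k %% 2 == 1) Sn <- Sn %*% Spow
      Spow <- Spow %*% Spow
      k <- k %/% 2
    }
    pd0 <- solve(I_m - Sn, K)
  }

  # simulate all cycles, retaining the full node-pressure history and the
  # last cycle's per-branch flows
  times <- seq(0, n_cycles * period, length.out = n_cycles * n + 1)
  node_p <- numeric(n_cycles * n + 1)
  pd <- pd0
  node_of <- function(pd, q) (q + sum(pd / rp)) / G
  node_p[1] <- node_of(pd, qin[1])
  last_pd <- NULL
  idx <- 1L
  for (cyc in seq_len(n_cycles)) {
    pdmat <- step_through(pd)
    pd <- pdmat[, n + 1]
    node_p[idx + seq_len(n)] <- (qin[-1] + colSums(pdmat[, -1, drop = FALSE] / rp)) / G
    idx <- idx + n
    if (cyc == n_cycles) last_pd <- pdmat
  }

  # last-cycle branch flows from the algebraic node relation
  node_last <- (qin + colSums(last_pd / rp)) / G
  qbranch <- (matrix(node_last, m, n + 1, byrow = TRUE) - last_pd) / rp
  resid <- abs(colSums(qbranch) - qin) / pmax(abs(qin), 1e-12)

  report <- vapply(comps, `[[`, "", "report")
  flows <- list()
  for (nm in unique(report)) {
    qi <- colSums(qbranch[report == nm, , drop = FALSE])
    qi[n + 1] <- qi[1] # periodic by construction of the fixed point; enforce closure
    flows[[nm]] <- flow_waveform(tq, mls_to_m3s(qi))
  }
  flows <- flows[intersect(c("BCT", "LCCA", "LSA", "DAo"), names(flows))]

  structure(list(
    node_pressure = pressure_trace(times, node_p,
                                   cycle_starts = (seq_len(n_cycles) - 1L) * n + 1L,
                                   period_s = period),
    flows = flows,
    mean_flows = vapply(flows, mean_flow, 0),
    peak_flows = vapply(flows, peak_flow, 0),
    conservation = max(resid),
    topology = model$topology), class = "network_result")
}

#' @export
print.network_result <- function(x, ...) {
  cat(sprintf("<network_result> %s; mean flows (L/min): %s\n", x$topology,
              paste(sprintf("%s %.2f", names(x$mean_flows), x$mean_flows),
                    collapse = ", ")))
  invisible(x)
}

#' Estimate maximum branch velocity from peak flow and lumen area
#'
#' `v_max = profile_factor * peak_flow / area`, reported in cm/s. The
#' profile factor maps the cross-section average velocity to the centerline
#' maximum (2 for a parabolic Poiseuille profile, 1 for plug flow).
#'
#' @param peak_flow_lpm peak branch flow, L/min.
#' @param area_cm2 lumen area just distal to the branch origin, cm^2 (> 0).
#' @param profile_factor velocity-profile shape factor (>= 1, default 2).
#' @return Maximum velocity, cm/s.
#' @examples
#' max_velocity(1.2, 1.0, 2) # 40 cm/s
#' @export
max_velocity <- function(peak_flow_lpm, area_cm2, profile_factor = 2) {
  if (!is.finite(area_cm2) || area_cm2 <= 0) {
    stop("parameter error: area must be positive", call. = FALSE)
  }
  if (profile_factor < 1) {
    stop("parameter error: profile_factor must be >= 1", call. = FALSE)
  }
  # L/min -> cm^3/s: 1000/60
  profile_factor * (peak_flow_lpm * 1000 / 60) / area_cm2
}
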