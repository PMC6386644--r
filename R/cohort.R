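# Four-patient clinical fixture tables (zone-2 TEVAR cohort) and the
# Results-section arithmetic computed from them: column means with ranges,
# percent changes, mass-conservation residuals, and the Pearson correlation
# test. Means are computed in exact decimal arithmetic with half-away-from-
# zero rounding; binary floating point would misround column means such as
# 16.38/4 = 4.095 and 179.4/4 = 44.85.

#' Embedded cohort tables
#'
#' The five clinical tables of the four-patient zone-2 TEVAR cohort:
#' patient/graft characteristics, pre/post branch flows (L/min), branch
#' surface areas (cm^2), maximum branch velocities (cm/s), and ascending
#' aortic pressures (mmHg). Values are the printed table cells.
#'
#' @return Named list of data frames `table1` .. `table5`.
#' @export
cohort_tables <- function() {
  list(
    table1 = data.frame(
      patient = 1:4,
      age = c(48L, 65L, 74L, 81L),
      sex = c("M", "M", "M", "M"),
      disease = c("TAA", "PAU", "TAA", "TAA"),
      graft_mm = c("28-24-150",
                   "42-42-100",
                   "44-44-200/46-46-200/46-46-150",
                   "42-42-200/46-46-200/46-46-150"),
      stringsAsFactors = FALSE),
    table2 = data.frame( # flows, L/min
      patient = 1:4,
      pre_AAo = c(6.31, 5.98, 4.74, 3.69),
      pre_BCT = c(0.54, 0.67, 0.54, 0.75),
      pre_LCCA = c(0.19, 0.12, 0.12, 0.41),
      pre_LSA = c(0.33, 0.17, 0.24, 0.28),
      pre_DAo = c(5.26, 5.01, 3.85, 2.26),
      post_AAo = c(6.64, 4.61, 4.53, 2.62),
      post_BCT = c(1.21, 0.57, 0.72, 0.30),
      post_LCCA = c(1.08, 0.24, 0.76, 0.37),
      post_DAo = c(4.35, 3.81, 3.05, 1.95)),
    table3 = data.frame( # branch surface areas, cm^2
      patient = 1:4,
      pre_BCT = c(0.95, 2.22, 3.40, 6.09),
      pre_LCCA = c(0.39, 0.67, 1.27, 1.44),
      pre_LSA = c(0.75, 0.82, 1.95, 2.90),
      post_BCT = c(1.05, 2.10, 3.53, 6.06),
      post_LCCA = c(0.57, 0.76, 1.30, 1.46)),
    table4 = data.frame( # maximum branch velocities, cm/s
      patient = 1:4,
      pre_BCT = c(104.4, 36.6, 35.9, 14.1),
      pre_LCCA = c(89.3, 27.0, 33.8, 29.3),
      pre_LSA = c(105.3, 25.8, 45.9, 13.3),
      post_BCT = c(106.7, 33.7, 28.3, 8.9),
      post_LCCA = c(134.9, 40.8, 71.4, 43.2)),
    table5 = data.frame( # ascending aortic pressures, mmHg
      patient = 1:4,
      pre_sys = c(131, 110, 117, 94),
      pre_dia = c(58, 49, 61, 62),
      pre_mean = c(82, 80, 89, 77),
      post_sys = c(127, 108, 114, 106),
      post_dia = c(66, 56, 65, 55),
      post_mean = c(87, 80, 88, 77))
  )
}

# Printed mean rows (as published), used for printed-vs-recomputed flags.
printed_means <- function() {
  list(
    table2 = c(pre_AAo = 5.18, pre_BCT = 0.62, pre_LCCA = 0.21,
               pre_LSA = 0.25, pre_DAo = 4.10, post_AAo = 4.60,
               post_BCT = 0.70, post_LCCA = 0.61, post_DAo = 3.29),
    table3 = c(pre_BCT = 3.16, pre_LCCA = 0.94, pre_LSA = 1.61,
               post_BCT = 3.19, post_LCCA = 1.02),
    table4 = c(pre_BCT = 47.8, pre_LCCA = 44.9, pre_LSA = 47.6,
               post_BCT = 44.5, post_LCCA = 72.6),
    table5 = c(pre_sys = 113, pre_dia = 58, pre_mean = 82,
               post_sys = 114, post_dia = 61, post_mean = 83)
  )
}

#' Cohort patient records
#'
#' One record per patient assembling that patient's rows across all tables:
#' graft dimensions, pre/post branch flows, branch areas, maximum velocities
#' and pressures.
#'
#' @return List of four `patient_record` objects.
#' @export
cohort_fixture <- function() {
  tb <- cohort_tables()
  lapply(1:4, function(i) {
    structure(list(
      patient = i,
      age = tb$table1$age[i],
      sex = tb$table1$sex[i],
      disease = tb$table1$disease[i],
      graft_components_mm = strsplit(tb$table1$graft_mm[i], "/")[[1]],
      flows_lpm = as.list(tb$table2[i, -1]),
      areas_cm2 = as.list(tb$table3[i, -1]),
      velocities_cms = as.list(tb$table4[i, -1]),
      pressures_mmhg = as.list(tb$table5[i, -1])),
      class = "patient_record")
  })
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf("<patient_record> patient %d (%s, %d y, %s); graft %s\n",
              x$patient, x$sex, x$age, x$disease,
              paste(x$graft_components_mm, collapse = " / ")))
  invisible(x)
}

# ---- exact decimal arithmetic -------------------------------------------

# Convert decimal-printed numbers to integers at 10^-d, checking exactness.
as_scaled_int <- function(values, d) {
  ints <- round(values * 10^d)
  if (any(abs(ints - values * 10^d) > 1e-6)) {
    stop(sprintf("values are not exact %d-decimal numbers", d), call. = FALSE)
  }
  ints
}

# How many decimals the printed values carry (0, 1 or 2).
infer_decimals <- function(values) {
  for (d in 0:4) {
    if (all(abs(round(values * 10^d) - values * 10^d) < 1e-6)) return(d)
  }
  stop("values carry more than 4 decimals", call. = FALSE)
}

# round(p / q) with q > 0, half away from zero, exact integer arithmetic
round_half_away <- function(p, q) {
  s <- sign(p)
  s * ((2 * abs(p) + q) %/% (2 * q))
}

#' Column mean in exact decimal arithmetic
#'
#' Arithmetic mean of decimally printed values, rounded half away from zero
#' to `decimals` places — the convention that reproduces the published mean
#' rows (e.g. 16.38/4 = 4.095 -> 4.10, where double arithmetic would give
#' 4.09).
#'
#' @param values numeric vector of printed decimal values (nonempty).
#' @param decimals number of decimal places in the result.
#' @return The rounded mean.
#' @examples
#' column_mean(c(0.19, 0.12, 0.12, 0.41), 2) # 0.21
#' @export
column_mean <- function(values, decimals = 2) {
  if (!length(values)) stop("empty value list", call. = FALSE)
  d <- infer_decimals(values)
  ints <- as_scaled_int(values, d)
  # mean * 10^decimals = sum(ints) * 10^decimals / (n * 10^d)
  round_half_away(sum(ints) * 10^decimals, length(values) * 10^d) / 10^decimals
}

#' Percent change between printed means
#'
#' `round(100 * (post - pre) / pre)` to the nearest integer, half away from
#' zero, in exact decimal arithmetic.
#'
#' @param pre_mean,post_mean printed means (pre nonzero).
#' @return Integer percent change.
#' @examples
#' percent_change(44.9, 72.6) # 62
#' @export
percent_change <- function(pre_mean, post_mean) {
  if (pre_mean == 0) stop("zero baseline for percent change", call. = FALSE)
  d <- max(infer_decimals(pre_mean), infer_decimals(post_mean))
  a <- as_scaled_int(pre_mean, d)
  b <- as_scaled_int(post_mean, d)
  round_half_away(100 * (b - a) * sign(a), abs(a))
}

#' Mass-conservation residual of a patient-phase row
#'
#' The inlet flow must equal the sum of the branch flows:
#' `|AAo - (BCT + LCCA [+ LSA] + DAo)|`, in L/min, exact to the printed
#' decimals. Post-TEVAR rows have no LSA column (covered origin).
#'
#' @param record a `patient_record` from [cohort_fixture()].
#' @param phase `"pre"` or `"post"`.
#' @return Residual in L/min.
#' @examples
#' conservation_residual(cohort_fixture()[[2]], "pre") # 0.01
#' @export
conservation_residual <- function(record, phase = c("pre", "post")) {
  phase <- match.arg(phase)
  fl <- record$flows_lpm
  cols <- if (phase == "pre") c("pre_BCT", "pre_LCCA", "pre_LSA", "pre_DAo")
          else c("post_BCT", "post_LCCA", "post_DAo")
  inlet <- fl[[paste0(phase, "_AAo")]]
  if (is.null(inlet) || any(!cols %in% names(fl))) {
    stop("missing flow field for phase ", phase, call. = FALSE)
  }
  branches <- unlist(fl[cols])
  ints <- as_scaled_int(c(inlet, branches), 2)
  unname(abs(ints[1] - sum(ints[-1])) / 100)
}

#' Pearson correlation with a two-sided t-test p-value
#'
#' Standard Pearson r with the p-value from
#' `t = r sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom
#' (two-sided). Perfect correlations return p = 0.
#'
#' @param x,y numeric vectors, length >= 3, nonzero variance.
#' @return Object of class `correlation_result`: list with `r`, `p`, `n`,
#'   `t`.
#' @export
pearson_with_p <- function(x, y) {
  n <- length(x)
  if (n < 3 || length(y) != n) {
    stop("need n >= 3 paired observations", call. = FALSE)
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("degenerate variance: constant input", call. = FALSE)
  }
  r <- stats::cor(x, y)
  if (abs(r) >= 1) {
    t <- Inf * sign(r)
    p <- 0
  } else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(t), df = n - 2)
  }
  structure(list(r = r, p = p, n = n, t = t), class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> r = %.3f (n = %d), t = %.3f, p = %.4f\n",
              x$r, x$n, x$t, x$p))
  invisible(x)
}

# Output decimals per table (flows/areas 2, velocities 1, pressures 0).
table_decimals <- c(table2 = 2, table3 = 2, table4 = 1, table5 = 0)

#' Cohort summary report
#'
#' Recomputes the Results-section arithmetic from the fixture tables: column
#' means (exact decimal, half away from zero) with ranges, percent changes
#' pre vs post, mass-conservation residuals, and printed-vs-recomputed
#' flags. Percent changes are computed from the printed (rounded) column
#' means by default, matching the published workflow; set
#' `percent_from = "unrounded"` to use the exact column means instead.
#'
#' @param records list of `patient_record`s (default [cohort_fixture()]).
#' @param percent_from `"printed"` or `"unrounded"`.
#' @return Object of class `cohort_summary`: list of data frames `means`
#'   (with `printed` and `agrees` columns), `percent_changes`,
#'   `conservation`.
#' @export
cohort_report <- function(records = cohort_fixture(),
                          percent_from = c("printed", "unrounded")) {
  percent_from <- match.arg(percent_from)
  stopifnot(length(records) == 4L)
  tb <- cohort_tables()
  pm <- printed_means()

  means <- do.call(rbind, lapply(names(pm), function(tn) {
    cols <- names(pm[[tn]])
    dec <- table_decimals[[tn]]
    data.frame(
      table = tn,
      column = cols,
      mean = vapply(cols, function(cl) column_mean(tb[[tn]][[cl]], dec), 0),
      min = vapply(cols, function(cl) min(tb[[tn]][[cl]]), 0),
      max = vapply(cols, function(cl) max(tb[[tn]][[cl]]), 0),
      printed = unname(pm[[tn]]),
      row.names = NULL)
  }))
  means$agrees <- means$mean == means$printed

  pick <- function(tn, col) {
    if (percent_from == "printed") pm[[tn]][[col]]
    else column_mean(tb[[tn]][[col]], table_decimals[[tn]])
  }
  pc_spec <- list(
    c("AAo flow", "table2", "pre_AAo", "post_AAo"),
    c("BCT flow", "table2", "pre_BCT", "post_BCT"),
    c("LCCA flow", "table2", "pre_LCCA", "post_LCCA"),
    c("DAo flow", "table2", "pre_DAo", "post_DAo"),
    c("BCT area", "table3", "pre_BCT", "post_BCT"),
    c("LCCA area", "table3", "pre_LCCA", "post_LCCA"),
    c("BCT velocity", "table4", "pre_BCT", "post_BCT"),
    c("LCCA velocity", "table4", "pre_LCCA", "post_LCCA"))
  percent_changes <- do.call(rbind, lapply(pc_spec, function(s) {
    pre <- pick(s[2], s[3]); post <- pick(s[2], s[4])
    data.frame(quantity = s[1], pre = pre, post = post,
               change_pct = percent_change(pre, post), row.names = NULL)
  }))

  conservation <- do.call(rbind, lapply(records, function(r) {
    data.frame(patient = r$patient, phase = c("pre", "post"),
               residual_lpm = c(conservation_residual(r, "pre"),
                                conservation_residual(r, "post")),
               row.names = NULL)
  }))

  structure(list(means = means, percent_changes = percent_changes,
                 conservation = conservation,
                 percent_from = percent_from),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary>\n\nColumn means (with ranges):\n")
  print(x$means, row.names = FALSE)
  ndis <- sum(!x$means$agrees)
  if (ndis) {
    cat(sprintf("\n%d printed mean(s) disagree with exact recomputation:\n", ndis))
    print(x$means[!x$means$agrees, ], row.names = FALSE)
  }
  cat(sprintf("\nPercent changes (from %s means):\n", x$percent_from))
  print(x$percent_changes, row.names = FALSE)
  cat("\nConservation residuals (L/min):\n")
  print(x$conservation, row.names = FALSE)
  invisible(x)
}
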