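# Unit conversions. All internal state is SI (m, s, Pa, m^3/s); clinical
# units (L/min, mmHg, cm/s, cm^2, mL) appear only at I/O boundaries and in
# the Windkessel parameterisation, which follows clinical convention
# (mmHg.s/mL, mL/mmHg) as is standard for RCR outlet circuits.

#' Unit conversion helpers
#'
#' Convert between the clinical units used at input/output boundaries and
#' the SI units used internally. The conversion factors are
#' 1 L/min = 1/60000 m^3/s and 1 mmHg = 133.322 Pa.
#'
#' @param x numeric vector to convert.
#' @return Converted numeric vector.
#' @name units
NULL

MMHG_PA <- 133.322

#' @rdname units
#' @export
lpm_to_m3s <- function(x) x / 60000

#' @rdname units
#' @export
m3s_to_lpm <- function(x) x * 60000

#' @rdname units
#' @export
mmhg_to_pa <- function(x) x * MMHG_PA

#' @rdname units
#' @export
pa_to_mmhg <- function(x) x / MMHG_PA

#' @rdname units
#' @export
m3s_to_mls <- function(x) x * 1e6

#' @rdname units
#' @export
mls_to_m3s <- function(x) x / 1e6

# Evaluate `code` under a fixed RNG seed without touching the caller's
# global random state (the package keeps no global RNG dependence).
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Trapezoidal integral of y over x (supports non-uniform spacing).
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}
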