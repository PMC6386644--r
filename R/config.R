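# Pipeline configuration: a strict, schema-validated YAML block tree.
# Every under-specified constant of the pipeline (resistance split, search
# bracket, profile factor, rounding mode, ...) lives here so a run is fully
# auditable from its config plus seed.

#' Default pipeline configuration
#'
#' @return Named list with blocks `units`, `windkessel`, `network`, `force`,
#'   `stats`, plus `schema` (version) and `seed`.
#' @export
default_pipeline_config <- function() {
  list(
    schema = 1L,
    seed = 1L,
    units = list(flow = "L/min", pressure = "mmHg",
                 velocity = "cm/s", area = "cm2"),
    windkessel = list(prox_fraction = 0.09,
                      c_bracket = c(0.001, 10),
                      tol_mmhg = 0.25,
                      steps_per_cycle = 1000L,
                      n_cycles = 6L),
    network = list(topology = "pre_tevar",
                   bypass_resistance = 0,
                   profile_factor = 2,
                   outlets = list()),
    force = list(peak = "pressure", frame = list(cranial = "z",
                                                 ventral = "x", left = "y")),
    stats = list(rounding = "half_away_from_zero", percent_from = "printed")
  )
}

# Allowed keys per block; unknown keys are rejected.
config_schema <- function() {
  list(schema = NULL, seed = NULL,
       units = list(flow = NULL, pressure = NULL, velocity = NULL, area = NULL),
       windkessel = list(prox_fraction = NULL, c_bracket = NULL,
                         tol_mmhg = NULL, steps_per_cycle = NULL,
                         n_cycles = NULL),
       network = list(topology = NULL, bypass_resistance = NULL,
                      profile_factor = NULL, outlets = NA), # outlets free-form
       force = list(peak = NULL, frame = list(cranial = NULL, ventral = NULL,
                                              left = NULL)),
       stats = list(rounding = NULL, percent_from = NULL))
}

check_keys <- function(cfg, schema, path = "") {
  unknown <- setdiff(names(cfg), names(schema))
  if (length(unknown)) {
    stop(sprintf("config error: unknown key%s %s%s",
                 if (length(unknown) > 1) "s" else "",
                 path, paste(unknown, collapse = ", ")), call. = FALSE)
  }
  for (k in names(cfg)) {
    if (is.list(schema[[k]]) && is.list(cfg[[k]])) {
      check_keys(cfg[[k]], schema[[k]], paste0(path, k, "."))
    }
  }
  invisible(cfg)
}

#' Validate a pipeline configuration
#'
#' Rejects unknown keys anywhere in the block tree and checks the value
#' ranges of the numeric knobs.
#'
#' @param cfg configuration list.
#' @return `cfg`, invisibly; errors on violation.
#' @export
validate_pipeline_config <- function(cfg) {
  check_keys(cfg, config_schema())
  if (!identical(as.integer(cfg$schema), 1L)) {
    stop("config error: unsupported schema version", call. = FALSE)
  }
  wk <- cfg$windkessel
  if (!is.null(wk)) {
    if (!is.null(wk$prox_fraction) &&
        !(wk$prox_fraction > 0 && wk$prox_fraction < 0.5)) {
      stop("config error: windkessel.prox_fraction must lie in (0, 0.5)",
           call. = FALSE)
    }
    if (!is.null(wk$steps_per_cycle) && wk$steps_per_cycle < 100) {
      stop("config error: windkessel.steps_per_cycle must be >= 100",
           call. = FALSE)
    }
  }
  nw <- cfg$network
  if (!is.null(nw)) {
    if (!is.null(nw$topology) &&
        !nw$topology %in% c("pre_tevar", "post_tevar")) {
      stop("config error: network.topology must be pre_tevar or post_tevar",
           call. = FALSE)
    }
    if (!is.null(nw$bypass_resistance) && nw$bypass_resistance < 0) {
      stop("config error: network.bypass_resistance must be >= 0",
           call. = FALSE)
    }
  }
  invisible(cfg)
}

#' Read or write a pipeline configuration (YAML)
#'
#' Configurations round-trip identically through write-then-read and are
#' validated on both paths.
#'
#' @param path YAML file path.
#' @param cfg configuration list.
#' @return `read_pipeline_config()` returns the validated list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_pipeline_config(cfg)
  cfg
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(cfg, path) {
  validate_pipeline_config(cfg)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Hash of a configuration
#'
#' MD5 of the canonical YAML serialisation; embedded in output-file headers
#' so every artifact is traceable to its configuration.
#'
#' @param cfg configuration list.
#' @return Hex digest string.
#' @export
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(cfg, tmp)
  unname(tools::md5sum(tmp))
}
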