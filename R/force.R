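# Hemodynamic displacement force: the net load exerted by the blood on the
# stent graft at the systolic peak, obtained by integrating the pressure and
# wall shear-stress tractions over the graft's wetted (lateral) surface:
#
#   DF = sum_faces [ p_f n_f A_f + tau_f A_f ]        (Newtons)
#
# with n_f the unit normal pointing outward from the lumen (the force is the
# load ON the graft) and A_f the face area. Anatomical frame: +z cranial,
# +x ventral (anterior), +y patient-left; "dorsocranial" therefore means
# negative x and positive z.

#' Integrate pressure and shear tractions into a displacement force
#'
#' Piecewise-constant quadrature over the triangulation: each face
#' contributes its pressure times outward-normal area vector plus its shear
#' traction times area. Accuracy is controlled by mesh refinement
#' (second-order in element size).
#'
#' @param mesh a [tri_surface()] carrying `face_pressure` (Pa) and
#'   `face_shear` (Pa, vector) on every face.
#' @return Object of class `force_vector` with fields `components` (N, in
#'   the anatomical frame), `magnitude` (N), `pressure_part` and
#'   `shear_part` (N).
#' @export
integrate_force <- function(mesh) {
  stopifnot(inherits(mesh, "tri_surface"))
  if (is.null(mesh$face_pressure) || is.null(mesh$face_shear)) {
    stop("field error: mesh must carry pressure and shear fields", call. = FALSE)
  }
  validate_tri_surface(mesh)
  a <- face_areas(mesh)
  nrm <- face_normals(mesh)
  pressure_part <- colSums(nrm * (mesh$face_pressure * a))
  shear_part <- colSums(mesh$face_shear * a)
  force_vector(pressure_part, shear_part)
}

#' Construct a force vector from its pressure and shear parts
#'
#' @param pressure_part,shear_part numeric length-3 vectors, N.
#' @return Object of class `force_vector`.
#' @export
force_vector <- function(pressure_part, shear_part = c(0, 0, 0)) {
  stopifnot(length(pressure_part) == 3L, length(shear_part) == 3L)
  components <- as.numeric(pressure_part) + as.numeric(shear_part)
  structure(list(components = components,
                 magnitude = sqrt(sum(components^2)),
                 pressure_part = as.numeric(pressure_part),
                 shear_part = as.numeric(shear_part)),
            class = "force_vector")
}

#' @export
print.force_vector <- function(x, ...) {
  dir <- tryCatch(classify_direction(x)$label, error = function(e) "undefined")
  cat(sprintf("<force_vector> |DF| %.4g N = (%.4g, %.4g, %.4g) N, %s\n",
              x$magnitude, x$components[1], x$components[2], x$components[3],
              dir))
  cat(sprintf("  pressure part %.4g N, shear part %.4g N\n",
              sqrt(sum(x$pressure_part^2)), sqrt(sum(x$shear_part^2))))
  invisible(x)
}

#' Time of the systolic peak within the last cycle
#'
#' Returns the time of maximum pressure within the final cycle of the
#' trace; ties are broken by the earliest occurrence. Times are reported on
#' the trace's own clock.
#'
#' @param trace a [pressure_trace()] covering at least one full cycle.
#' @return Time of the systolic peak, seconds.
#' @export
systolic_peak_time <- function(trace) {
  stopifnot(inherits(trace, "pressure_trace"))
  if (!length(trace$pressures)) stop("trace error: empty trace", call. = FALSE)
  nc <- n_cycles_of(trace)
  i <- cycle_indices(trace, nc)
  trace$times[i][which.max(trace$pressures[i])]
}

#' Classify the anatomical direction of a force vector
#'
#' Uses the sign quadrant of the (x, z) components in the anatomical frame
#' (+z cranial, +x ventral): dorsocranial (x < 0, z > 0), ventrocranial
#' (x > 0, z > 0), dorsocaudal (x < 0, z < 0), ventrocaudal (x > 0, z < 0).
#' When the (x, z) projection lies within 5 degrees of either separating
#' plane the classification is flagged as a boundary case.
#'
#' @param f a [force_vector()] with positive magnitude.
#' @return List with `label`, `boundary` (logical), and `angle_deg` (angle
#'   of the (x, z) projection measured from +z toward -x).
#' @export
classify_direction <- function(f) {
  stopifnot(inherits(f, "force_vector"))
  if (f$magnitude <= 0) {
    stop("undefined direction: zero force vector", call. = FALSE)
  }
  x <- f$components[1]; z <- f$components[3]
  if (x == 0 && z == 0) {
    stop("undefined direction: force lies entirely along the y axis",
         call. = FALSE)
  }
  label <- if (z >= 0) {
    if (x < 0) "dorsocranial" else "ventrocranial"
  } else {
    if (x < 0) "dorsocaudal" else "ventrocaudal"
  }
  # angle of (x, z) from the +z axis, positive toward dorsal (-x)
  ang <- atan2(-x, z) * 180 / pi
  r <- sqrt(x^2 + z^2)
  boundary <- min(abs(x), abs(z)) / r < sin(5 * pi / 180)
  list(label = label, boundary = boundary, angle_deg = ang)
}

#' Total surface area of a graft mesh
#'
#' Sum of triangle areas, reported in cm^2 (the unit of the clinical
#' tables). An empty mesh returns 0 with a warning.
#'
#' @param mesh a [tri_surface()].
#' @return Surface area, cm^2.
#' @export
graft_surface_area <- function(mesh) {
  stopifnot(inherits(mesh, "tri_surface"))
  if (nrow(mesh$faces) == 0L) {
    warning("empty mesh: surface area is 0", call. = FALSE)
    return(0)
  }
  sum(face_areas(mesh)) * 1e4
}

#' Structured displacement-force report
#'
#' Bundles the force integration, direction classification and surface area
#' into one list, suitable for JSON export.
#'
#' @param mesh a [tri_surface()] with fields.
#' @return List with `components_N`, `magnitude_N`, `pressure_part_N`,
#'   `shear_part_N`, `direction`, `boundary_case`, `surface_area_cm2`.
#' @export
force_report <- function(mesh) {
  f <- integrate_force(mesh)
  dir <- tryCatch(classify_direction(f),
                  error = function(e) list(label = "undefined",
                                           boundary = NA, angle_deg = NA_real_))
  list(components_N = f$components,
       magnitude_N = f$magnitude,
       pressure_part_N = f$pressure_part,
       shear_part_N = f$shear_part,
       direction = dir$label,
       boundary_case = dir$boundary,
       surface_area_cm2 = graft_surface_area(mesh))
}
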