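# Triangulated surfaces carrying per-face pressure and shear-traction
# fields: the discrete counterpart of the stent-graft wetted surface over
# which the displacement force is integrated.

#' Construct a triangulated surface with optional per-face fields
#'
#' @param vertices numeric matrix, n x 3, coordinates in meters.
#' @param faces integer matrix, m x 3, vertex indices (1-based), consistently
#'   oriented so that face normals point outward from the lumen.
#' @param face_pressure optional numeric vector, Pa per face.
#' @param face_shear optional numeric m x 3 matrix, shear traction vector in
#'   Pa per face (tangent to the wall).
#' @param closed logical; declared topology. For closed surfaces validity
#'   additionally requires every edge shared by exactly two faces and a
#'   positive signed volume (outward orientation).
#' @return Object of class `tri_surface`.
#' @export
tri_surface <- function(vertices, faces, face_pressure = NULL,
                        face_shear = NULL, closed = FALSE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be n x 3", call. = FALSE)
  if (ncol(faces) != 3L) stop("faces must be m x 3", call. = FALSE)
  m <- structure(list(vertices = vertices, faces = faces,
                      face_pressure = face_pressure, face_shear = face_shear,
                      closed = isTRUE(closed)),
                 class = "tri_surface")
  validate_tri_surface(m)
  m
}

#' Validate a triangulated surface
#'
#' Checks index validity, strictly positive face areas, consistent
#' orientation (each directed edge used at most once), field lengths, and —
#' for closed surfaces — watertightness and positive signed volume.
#'
#' @param mesh a [tri_surface()].
#' @return `mesh`, invisibly; errors on violation.
#' @export
validate_tri_surface <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  if (nrow(f) == 0L) return(invisible(mesh))
  if (min(f) < 1L || max(f) > nrow(v)) {
    stop("mesh error: face indices out of range", call. = FALSE)
  }
  if (any(f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3])) {
    stop("mesh error: degenerate face (repeated vertex)", call. = FALSE)
  }
  a <- face_areas(mesh)
  if (any(a <= 0 | !is.finite(a))) {
    stop("mesh error: face with zero or invalid area", call. = FALSE)
  }
  # Orientation consistency: in a consistently oriented manifold each
  # directed edge appears at most once, and the opposite edge in a neighbor.
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(e[, 1], e[, 2])
  if (anyDuplicated(key)) {
    stop("mesh error: inconsistent face orientation (repeated directed edge)",
         call. = FALSE)
  }
  if (isTRUE(mesh$closed)) {
    undirected <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    if (!all(table(undirected) == 2L)) {
      stop("mesh error: closed surface is not watertight", call. = FALSE)
    }
    if (signed_volume(mesh) <= 0) {
      stop("mesh error: closed surface has inward orientation (signed volume <= 0)",
           call. = FALSE)
    }
  }
  np <- length(mesh$face_pressure)
  if (np > 0L && np != nrow(f)) {
    stop("field error: face_pressure length != number of faces", call. = FALSE)
  }
  if (!is.null(mesh$face_shear) && nrow(mesh$face_shear) != nrow(f)) {
    stop("field error: face_shear rows != number of faces", call. = FALSE)
  }
  invisible(mesh)
}

#' @export
print.tri_surface <- function(x, ...) {
  cat(sprintf("<tri_surface> %d vertices, %d faces, %s; area %.4g cm^2%s\n",
              nrow(x$vertices), nrow(x$faces),
              if (isTRUE(x$closed)) "closed" else "open",
              graft_surface_area(x),
              if (!is.null(x$face_pressure)) "; fields attached" else ""))
  invisible(x)
}

# cross products of the two edge vectors of every face (rows)
face_edge_cross <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
        e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
        e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
}

#' Per-face geometry of a triangulated surface
#'
#' `face_areas()` returns triangle areas (m^2), `face_normals()` unit outward
#' normals (m x 3), `face_centers()` centroids, and `signed_volume()` the
#' signed enclosed volume (m^3, positive for outward-oriented closed
#' surfaces).
#'
#' @param mesh a [tri_surface()].
#' @name mesh_geometry
NULL

#' @rdname mesh_geometry
#' @export
face_areas <- function(mesh) {
  cr <- face_edge_cross(mesh)
  sqrt(rowSums(cr^2)) / 2
}

#' @rdname mesh_geometry
#' @export
face_normals <- function(mesh) {
  cr <- face_edge_cross(mesh)
  cr / sqrt(rowSums(cr^2))
}

#' @rdname mesh_geometry
#' @export
face_centers <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] +
     v[f[, 3], , drop = FALSE]) / 3
}

#' @rdname mesh_geometry
#' @export
signed_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) +
      a[, 2] * (b[, 3] * cc[, 1] - b[, 1] * cc[, 3]) +
      a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
}

#' Generate an idealized stent-graft tube surface
#'
#' Builds the lateral surface (no end caps — the wetted graft surface) of a
#' straight cylinder or a circular-arc bend, as a consistently
#' outward-oriented triangulation.
#'
#' The straight tube has its axis along +z starting at the origin. The bend
#' is a torus segment in the x–z plane: the centerline runs from
#' `(bend_radius, 0, 0)` at angle 0 (tangent +z) sweeping toward the z axis.
#'
#' @param radius tube radius, m (> 0).
#' @param length_or_angle tube length in m (`kind = "straight"`) or bend
#'   angle in degrees (`kind = "bend"`).
#' @param kind `"straight"` or `"bend"`.
#' @param n_circumferential,n_axial grid resolution (each >= 8).
#' @param bend_radius centerline radius of the bend, m (required for bends;
#'   must exceed `radius`).
#' @return An open [tri_surface()] with tube metadata attached (used by
#'   [assign_poiseuille_fields()]).
#' @examples
#' m <- gen_tube_mesh(0.01, 0.1, "straight", 64, 64)
#' graft_surface_area(m) # ~ 2*pi*r*L in cm^2
#' @export
gen_tube_mesh <- function(radius, length_or_angle, kind = c("straight", "bend"),
                          n_circumferential = 32, n_axial = 32,
                          bend_radius = NULL) {
  kind <- match.arg(kind)
  if (!is.finite(radius) || radius <= 0) {
    stop("mesh error: radius must be positive", call. = FALSE)
  }
  if (n_circumferential < 8 || n_axial < 8) {
    stop("mesh error: resolution must be at least 8 x 8", call. = FALSE)
  }
  nc <- as.integer(n_circumferential); na <- as.integer(n_axial)
  theta <- 2 * pi * (seq_len(nc) - 1) / nc

  if (kind == "straight") {
    L <- length_or_angle
    if (!is.finite(L) || L <= 0) stop("mesh error: length must be positive", call. = FALSE)
    z <- seq(0, L, length.out = na + 1)
    verts <- cbind(radius * rep(cos(theta), na + 1),
                   radius * rep(sin(theta), na + 1),
                   rep(z, each = nc))
    axis <- c(0, 0, 1); origin <- c(0, 0, 0)
  } else {
    if (is.null(bend_radius)) stop("mesh error: bend requires bend_radius", call. = FALSE)
    if (bend_radius <= radius) {
      stop("mesh error: bend_radius must exceed tube radius", call. = FALSE)
    }
    ang <- length_or_angle * pi / 180
    if (!is.finite(ang) || ang <= 0) stop("mesh error: angle must be positive", call. = FALSE)
    phi <- seq(0, ang, length.out = na + 1)
    # ring j at sweep angle phi_j: center Rb*er, er = (cos phi, 0, sin phi)
    verts <- matrix(0, nc * (na + 1), 3)
    for (j in seq_len(na + 1)) {
      er <- c(cos(phi[j]), 0, sin(phi[j]))
      rows <- (j - 1) * nc + seq_len(nc)
      rad <- bend_radius + radius * cos(theta)
      verts[rows, 1] <- rad * er[1]
      verts[rows, 2] <- radius * sin(theta)
      verts[rows, 3] <- rad * er[3]
    }
    axis <- NULL; origin <- NULL; L <- NULL
  }

  # quad (i, j) -> two triangles, oriented so normals point radially outward
  i <- rep(seq_len(nc), na)
  j <- rep(seq_len(na), each = nc)
  ip <- ifelse(i == nc, 1L, i + 1L)
  v00 <- (j - 1L) * nc + i
  v10 <- (j - 1L) * nc + ip
  v01 <- j * nc + i
  v11 <- j * nc + ip
  faces <- rbind(cbind(v00, v10, v11), cbind(v00, v11, v01))

  m <- tri_surface(verts, faces, closed = FALSE)
  attr(m, "tube") <- list(kind = kind, radius = radius, length = L,
                          axis = axis, origin = origin,
                          bend_radius = if (kind == "bend") bend_radius,
                          angle_deg = if (kind == "bend") length_or_angle)
  m
}

#' Generate a closed icosphere
#'
#' Recursively subdivided icosahedron projected to the sphere; watertight and
#' outward-oriented. Used as an analytic oracle geometry (known area and
#' volume; the net pressure force on any closed surface vanishes).
#'
#' @param radius sphere radius, m (> 0).
#' @param refinement number of 4-to-1 subdivision passes (0 gives the raw
#'   icosahedron, 20 faces; level k gives `20 * 4^k`).
#' @return A closed [tri_surface()].
#' @export
gen_closed_sphere <- function(radius = 1, refinement = 3) {
  if (!is.finite(radius) || radius <= 0) {
    stop("mesh error: radius must be positive", call. = FALSE)
  }
  refinement <- as.integer(refinement)
  if (refinement < 0 || refinement > 7) {
    stop("mesh error: refinement must be between 0 and 7", call. = FALSE)
  }
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
    c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (lev in seq_len(refinement)) {
    nf <- nrow(f)
    edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    # midpoint index cache
    e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
    keys <- edge_key(e[, 1], e[, 2])
    uk <- unique(keys)
    mid_of <- match(keys, uk)
    pairs <- e[match(uk, keys), , drop = FALSE]
    mids <- (v[pairs[, 1], , drop = FALSE] + v[pairs[, 2], , drop = FALSE]) / 2
    mids <- mids / sqrt(rowSums(mids^2))
    base <- nrow(v)
    v <- rbind(v, mids)
    m12 <- base + mid_of[seq_len(nf)]
    m23 <- base + mid_of[nf + seq_len(nf)]
    m31 <- base + mid_of[2 * nf + seq_len(nf)]
    f <- rbind(cbind(f[, 1], m12, m31),
               cbind(f[, 2], m23, m12),
               cbind(f[, 3], m31, m23),
               cbind(m12, m23, m31))
  }
  tri_surface(radius * v, f, closed = TRUE)
}

#' Attach a uniform pressure field
#'
#' Sets `face_pressure` to `p` on every face and `face_shear` to zero.
#' Negative gauge pressures are accepted.
#'
#' @param mesh a [tri_surface()].
#' @param p pressure, Pa (finite).
#' @return `mesh` with fields attached.
#' @export
assign_uniform_pressure <- function(mesh, p) {
  stopifnot(inherits(mesh, "tri_surface"))
  if (!is.finite(p)) stop("field error: pressure must be finite", call. = FALSE)
  mesh$face_pressure <- rep(as.numeric(p), nrow(mesh$faces))
  mesh$face_shear <- matrix(0, nrow(mesh$faces), 3)
  mesh
}

#' Attach analytic Poiseuille pressure and wall-shear fields
#'
#' For a straight tube of radius r and length L carrying steady flow Q of a
#' fluid with viscosity mu, the wall shear stress is
#' `tau_w = 4 mu Q / (pi r^3)` (directed along the flow axis, tangent to the
#' wall) and the pressure falls linearly along the axis with total drop
#' `dP = 8 mu L Q / (pi r^4)`. Serves as the analytic oracle for the
#' displacement-force integrator.
#'
#' @param mesh a straight tube from [gen_tube_mesh()].
#' @param Q volumetric flow, m^3/s.
#' @param mu dynamic viscosity, Pa.s.
#' @param inlet_pressure pressure at the inlet plane (z = 0), Pa.
#' @return `mesh` with `face_pressure` and `face_shear` attached.
#' @export
assign_poiseuille_fields <- function(mesh, Q, mu, inlet_pressure = 0) {
  stopifnot(inherits(mesh, "tri_surface"))
  tube <- attr(mesh, "tube")
  if (is.null(tube) || !identical(tube$kind, "straight")) {
    stop("field error: Poiseuille fields require a straight tube mesh",
         call. = FALSE)
  }
  r <- tube$radius; L <- tube$length
  tau_w <- 4 * mu * Q / (pi * r^3)
  dP <- 8 * mu * L * Q / (pi * r^4)
  s <- face_centers(mesh) %*% tube$axis # axial coordinate of each face
  mesh$face_pressure <- as.numeric(inlet_pressure - dP * s / L)
  mesh$face_shear <- matrix(rep(tube$axis, each = nrow(mesh$faces)),
                            ncol = 3) * tau_w
  mesh
}
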