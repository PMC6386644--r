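# File formats: flow-waveform CSV, STL (ASCII and binary) with a sidecar
# per-face field CSV. STL carries no attributes, so pressure/shear travel in
# a CSV whose row order equals the STL facet order.

#' Read and write flow-waveform CSV files
#'
#' The on-disk format is one cardiac cycle with header
#' `time_s,flow_L_per_min` and at least 32 rows; flows are converted to SI
#' at this boundary. `write_waveform_csv()` writes comment lines (`#`) ahead
#' of the header when `comments` are supplied.
#'
#' @param path file path.
#' @param w a [flow_waveform()].
#' @param comments optional character vector written as `#`-prefixed header
#'   comments (e.g. a config hash).
#' @return `read_waveform_csv()` returns a [flow_waveform()];
#'   `write_waveform_csv()` returns `path` invisibly.
#' @export
read_waveform_csv <- function(path) {
  lines <- readLines(path)
  body <- grep("^\\s*#", lines, invert = TRUE)
  if (length(body) < 2L) stop("format error: empty waveform file", call. = FALSE)
  hdr <- trimws(strsplit(lines[body[1]], ",")[[1]])
  if (!identical(hdr, c("time_s", "flow_L_per_min"))) {
    stop(sprintf("format error: line %d: expected header 'time_s,flow_L_per_min'",
                 body[1]), call. = FALSE)
  }
  d <- utils::read.csv(text = lines[body], header = TRUE)
  if (nrow(d) < 32L) {
    stop("format error: waveform must have at least 32 rows", call. = FALSE)
  }
  bad <- which(diff(d$time_s) <= 0)
  if (length(bad)) {
    stop(sprintf("format error: line %d: time_s not strictly increasing",
                 body[1] + bad[1] + 1L), call. = FALSE)
  }
  flow_waveform(d$time_s, lpm_to_m3s(d$flow_L_per_min))
}

#' @rdname read_waveform_csv
#' @export
write_waveform_csv <- function(w, path, comments = NULL) {
  stopifnot(inherits(w, "flow_waveform"))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  writeLines("time_s,flow_L_per_min", con)
  writeLines(sprintf("%.12g,%.12g", w$times, m3s_to_lpm(w$flows)), con)
  invisible(path)
}

#' Read and write STL surface files
#'
#' Both the ASCII and little-endian binary STL dialects are supported;
#' `write_stl()` chooses by `binary`. STL stores each facet's vertices
#' independently; on read, vertices are merged by exact coordinate equality
#' (safe because STL stores 32-bit floats) so that orientation and
#' watertightness checks remain possible. Facet order is preserved.
#'
#' @param path file path.
#' @param mesh a [tri_surface()].
#' @param binary write binary STL (default) or ASCII.
#' @param closed declared topology of the surface being read.
#' @return `read_stl()` returns a [tri_surface()] without fields.
#' @export
read_stl <- function(path, closed = FALSE) {
  head_bytes <- readBin(path, "raw", n = 512)
  is_ascii <- length(head_bytes) > 0 && all(head_bytes < as.raw(128))
  if (is_ascii) {
    txt <- rawToChar(head_bytes[head_bytes != as.raw(0)])
    is_ascii <- grepl("^\\s*solid", txt) && grepl("facet", txt)
  }
  tri <- if (is_ascii) read_stl_ascii(path) else read_stl_binary(path)
  # merge duplicated vertices (exact match on float32-quantised coordinates)
  key <- paste(tri[, 1], tri[, 2], tri[, 3])
  uk <- !duplicated(key)
  idx <- match(key, key[uk])
  verts <- tri[uk, , drop = FALSE]
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  tri_surface(verts, faces, closed = closed)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path)
  vl <- grep("^\\s*vertex", lines, value = TRUE)
  if (!length(vl)) stop("format error: no vertices in ASCII STL", call. = FALSE)
  nums <- strsplit(trimws(sub("^\\s*vertex\\s+", "", vl)), "\\s+")
  tri <- matrix(as.numeric(unlist(nums)), ncol = 3, byrow = TRUE)
  if (nrow(tri) %% 3 != 0) stop("format error: vertex count not multiple of 3",
                                call. = FALSE)
  tri
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80)
  nf <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  if (nf <= 0) stop("format error: binary STL with no facets", call. = FALSE)
  rec <- readBin(con, "raw", n = nf * 50)
  if (length(rec) < nf * 50) stop("format error: truncated binary STL", call. = FALSE)
  rec <- matrix(rec, nrow = 50)
  floats <- matrix(readBin(as.vector(rec[1:48, ]), "numeric", n = 12L * nf,
                           size = 4, endian = "little"),
                   nrow = 12)
  tri <- matrix(as.vector(floats[4:12, ]), ncol = 3, byrow = TRUE)
  tri
}

#' @rdname read_stl
#' @export
write_stl <- function(mesh, path, binary = TRUE) {
  stopifnot(inherits(mesh, "tri_surface"))
  v <- mesh$vertices; f <- mesh$faces
  n <- face_normals(mesh)
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(c(charToRaw(sprintf("%-79s", "archflow binary STL")), as.raw(0)), con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(c(n[i, ], v[f[i, 1], ], v[f[i, 2], ], v[f[i, 3], ]),
               con, size = 4, endian = "little")
      writeBin(as.raw(c(0, 0)), con)
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid archflow", con)
    for (i in seq_len(nrow(f))) {
      writeLines(c(
        sprintf("  facet normal %.9g %.9g %.9g", n[i, 1], n[i, 2], n[i, 3]),
        "    outer loop",
        sprintf("      vertex %.9g %.9g %.9g",
                v[f[i, c(1, 2, 3)], 1], v[f[i, c(1, 2, 3)], 2],
                v[f[i, c(1, 2, 3)], 3]),
        "    endloop",
        "  endfacet"), con)
    }
    writeLines("endsolid archflow", con)
  }
  invisible(path)
}

#' Read or write a mesh together with its per-face fields
#'
#' The sidecar CSV has header
#' `face_index,pressure_Pa,shear_x_Pa,shear_y_Pa,shear_z_Pa` with one row per
#' STL facet, in facet order.
#'
#' @param stl_path STL file path.
#' @param field_csv_path sidecar field CSV path.
#' @param mesh a [tri_surface()] with fields attached.
#' @param binary passed to [write_stl()].
#' @param closed declared topology for [read_stl()].
#' @param comments optional `#` comment lines for the field CSV.
#' @return `read_mesh_with_fields()` returns a [tri_surface()] with fields.
#' @export
read_mesh_with_fields <- function(stl_path, field_csv_path, closed = FALSE) {
  mesh <- read_stl(stl_path, closed = closed)
  lines <- readLines(field_csv_path)
  body <- grep("^\\s*#", lines, invert = TRUE)
  d <- utils::read.csv(text = lines[body], header = TRUE)
  need <- c("face_index", "pressure_Pa", "shear_x_Pa", "shear_y_Pa", "shear_z_Pa")
  if (!identical(names(d), need)) {
    stop("format error: field CSV header must be ",
         paste(need, collapse = ","), call. = FALSE)
  }
  if (nrow(d) != nrow(mesh$faces)) {
    stop(sprintf("alignment error: field CSV has %d rows but STL has %d facets",
                 nrow(d), nrow(mesh$faces)), call. = FALSE)
  }
  mesh$face_pressure <- d$pressure_Pa
  mesh$face_shear <- as.matrix(d[, c("shear_x_Pa", "shear_y_Pa", "shear_z_Pa")])
  dimnames(mesh$face_shear) <- NULL
  mesh
}

#' @rdname read_mesh_with_fields
#' @export
write_mesh_with_fields <- function(mesh, stl_path, field_csv_path,
                                   binary = TRUE, comments = NULL) {
  stopifnot(inherits(mesh, "tri_surface"))
  if (is.null(mesh$face_pressure) || is.null(mesh$face_shear)) {
    stop("field error: mesh has no fields to write", call. = FALSE)
  }
  write_stl(mesh, stl_path, binary = binary)
  con <- file(field_csv_path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  writeLines("face_index,pressure_Pa,shear_x_Pa,shear_y_Pa,shear_z_Pa", con)
  writeLines(sprintf("%d,%.12g,%.12g,%.12g,%.12g",
                     seq_len(nrow(mesh$faces)), mesh$face_pressure,
                     mesh$face_shear[, 1], mesh$face_shear[, 2],
                     mesh$face_shear[, 3]), con)
  invisible(stl_path)
}
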