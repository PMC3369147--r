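## Mesh and curve file IO.  ASCII PLY/OBJ and ASCII+binary STL are written
## natively; readers accept ASCII PLY/OBJ/STL.  Rim curves and landmark sets
## travel as JSON.

#' Write a surface mesh to PLY, STL or OBJ
#'
#' @param mesh a `surface_mesh`.
#' @param path output file; format from extension (.ply, .stl, .obj).
#' @param binary write binary STL instead of ASCII (STL only).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, binary = FALSE) {
  ext <- tolower(tools::file_ext(path))
  v <- mesh$vertices
  f <- mesh$faces
  if (ext == "ply") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(v)),
                 "property float x", "property float y", "property float z",
                 sprintf("element face %d", nrow(f)),
                 "property list uchar int vertex_indices", "end_header"), con)
    writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  } else if (ext == "stl") {
    fn <- face_normals(mesh)
    if (binary) {
      con <- file(path, "wb")
      on.exit(close(con))
      writeBin(raw(80), con)
      writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
      for (i in seq_len(nrow(f))) {
        writeBin(as.numeric(c(fn[i, ], v[f[i, 1], ], v[f[i, 2], ], v[f[i, 3], ])),
                 con, size = 4, endian = "little")
        writeBin(as.integer(0), con, size = 2, endian = "little")
      }
    } else {
      con <- file(path, "w")
      on.exit(close(con))
      writeLines("solid mesh", con)
      for (i in seq_len(nrow(f))) {
        writeLines(sprintf("facet normal %.9g %.9g %.9g",
                           fn[i, 1], fn[i, 2], fn[i, 3]), con)
        writeLines("  outer loop", con)
        for (k in 1:3) {
          p <- v[f[i, k], ]
          writeLines(sprintf("    vertex %.9g %.9g %.9g", p[1], p[2], p[3]), con)
        }
        writeLines(c("  endloop", "endfacet"), con)
      }
      writeLines("endsolid mesh", con)
    }
  } else if (ext == "obj") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]), con)
  } else stop("unsupported mesh format: ", ext)
  invisible(path)
}

#' Read a surface mesh from PLY, STL or OBJ (ASCII)
#'
#' @param path input file.
#' @return a `surface_mesh`.
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "ply") read_ply_ascii(path)
  else if (ext == "obj") read_obj(path)
  else if (ext == "stl") read_stl_ascii(path)
  else stop("unsupported mesh format: ", ext)
}

read_ply_ascii <- function(path) {
  lines <- readLines(path)
  if (!grepl("ascii", lines[2])) stop("only ASCII PLY is supported")
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", lines, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", lines, value = TRUE)))
  hdr_end <- which(lines == "end_header")
  vl <- lines[(hdr_end + 1):(hdr_end + nv)]
  fl <- lines[(hdr_end + nv + 1):(hdr_end + nv + nf)]
  v <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(x) as.numeric(x[1:3])))
  f <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(x) as.integer(x[2:4]) + 1L))
  surface_mesh(v, f, clean = FALSE)
}

read_obj <- function(path) {
  lines <- readLines(path)
  vl <- grep("^v ", lines, value = TRUE)
  fl <- grep("^f ", lines, value = TRUE)
  v <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(x) as.numeric(x[2:4])))
  f <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(x)
    as.integer(sub("/.*", "", x[2:4]))))
  surface_mesh(v, f, clean = FALSE)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path)
  vl <- grep("^\\s*vertex", lines, value = TRUE)
  pts <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                               function(x) as.numeric(x[2:4])))
  ## merge duplicate vertices
  key <- apply(round(pts, 9), 1, paste, collapse = ",")
  uk <- !duplicated(key)
  idx <- match(key, key[uk])
  v <- pts[uk, , drop = FALSE]
  f <- matrix(idx, ncol = 3, byrow = TRUE)
  surface_mesh(v, f, clean = FALSE)
}

#' Write / read a rim curve as a JSON array of [x, y, z] points (mm)
#' @param rim a `rim_curve` or an n x 3 matrix of points.
#' @param path file path.
#' @return `path` invisibly (write); an n x 3 matrix (read).
#' @export
write_rim_json <- function(rim, path) {
  pts <- if (inherits(rim, "rim_curve")) rim$points else as.matrix(rim)
  jsonlite::write_json(unname(apply(pts, 1, as.numeric, simplify = FALSE)),
                       path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_rim_json
#' @export
read_rim_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  pts <- if (is.list(x)) do.call(rbind, x) else x
  matrix(as.numeric(pts), ncol = 3)
}
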