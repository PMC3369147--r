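## Triangle surface meshes: a light S3 container plus the geometric
## primitives the coverage pipeline needs (areas, normals, plane cuts,
## planar cross-sections).  Vertices are in mm in the anatomical frame
## (+x lateral, +y anterior, +z superior for a right hip).

#' Construct a triangle surface mesh
#'
#' @param vertices numeric matrix (n x 3), mm.
#' @param faces integer matrix (m x 3) of 1-based vertex indices with
#'   consistent (outward, counter-clockwise) winding.
#' @param clean drop unreferenced vertices and zero-area faces.
#' @return object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, clean = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3)
  if (nrow(faces) > 0 && (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  m <- structure(list(vertices = vertices, faces = faces),
                 class = "surface_mesh")
  if (clean) m <- clean_mesh(m)
  m
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d faces, area %.1f mm^2\n",
              nrow(x$vertices), nrow(x$faces), sum(face_areas(x))))
  invisible(x)
}

## drop zero-area faces and unreferenced vertices
clean_mesh <- function(mesh, area_tol = 1e-12) {
  a <- face_areas(mesh)
  keep <- a > area_tol
  faces <- mesh$faces[keep, , drop = FALSE]
  used <- sort(unique(as.vector(faces)))
  remap <- integer(nrow(mesh$vertices))
  remap[used] <- seq_along(used)
  structure(list(vertices = mesh$vertices[used, , drop = FALSE],
                 faces = matrix(remap[faces], ncol = 3)),
            class = "surface_mesh")
}

face_corners <- function(mesh) {
  list(a = mesh$vertices[mesh$faces[, 1], , drop = FALSE],
       b = mesh$vertices[mesh$faces[, 2], , drop = FALSE],
       c = mesh$vertices[mesh$faces[, 3], , drop = FALSE])
}

#' Triangulated sphere mesh
#'
#' Latitude-longitude triangulation of a sphere (closed, outward winding);
#' used as an idealised femoral head in validation work.
#'
#' @param radius sphere radius, mm.
#' @param n_target approximate vertex count.
#' @param center sphere center.
#' @return a `surface_mesh`.
#' @export
sphere_mesh <- function(radius = 25, n_target = 10000, center = c(0, 0, 0)) {
  k <- max(4L, as.integer(round(sqrt(n_target / 2))))
  kk <- 2L * k
  th <- pi * seq_len(kk - 1) / kk
  rings <- lapply(th, function(t)
    cbind(radius * sin(t) * cos(2 * pi * (0:(kk - 1)) / kk),
          radius * sin(t) * sin(2 * pi * (0:(kk - 1)) / kk),
          radius * cos(t)))
  verts <- sweep(rbind(c(0, 0, radius), do.call(rbind, rings),
                       c(0, 0, -radius)), 2, center, "+")
  ridx <- function(j) 1L + (j - 1L) * kk + seq_len(kk)
  fcs <- list(cbind(1L, ridx(1)[c(2:kk, 1)], ridx(1)))
  for (j in seq_len(length(th) - 1)) {
    a <- ridx(j); b <- ridx(j + 1)
    an <- a[c(2:kk, 1)]; bn <- b[c(2:kk, 1)]
    fcs[[j + 1]] <- rbind(cbind(a, bn, b), cbind(a, an, bn))
  }
  fcs[[length(th) + 1]] <- cbind(nrow(verts), ridx(length(th)),
                                 ridx(length(th))[c(2:kk, 1)])
  m <- surface_mesh(verts, do.call(rbind, fcs), clean = FALSE)
  if (mesh_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m
}

#' Per-face areas of a mesh (mm^2)
#' @param mesh a `surface_mesh`.
#' @return numeric vector, one area per face.
#' @export
face_areas <- function(mesh) {
  fc <- face_corners(mesh)
  0.5 * rownorms(cross3(fc$b - fc$a, fc$c - fc$a))
}

face_centroids <- function(mesh) {
  fc <- face_corners(mesh)
  (fc$a + fc$b + fc$c) / 3
}

face_normals <- function(mesh) {
  fc <- face_corners(mesh)
  normalize_rows(cross3(fc$b - fc$a, fc$c - fc$a))
}

## area-weighted vertex normals
vertex_normals <- function(mesh) {
  fn <- face_normals(mesh)
  a <- face_areas(mesh)
  nv <- nrow(mesh$vertices)
  n <- matrix(0, nv, 3)
  for (k in 1:3) {
    idx <- mesh$faces[, k]
    acc <- rowsum(fn * a, idx)
    rows <- as.integer(rownames(acc))
    n[rows, ] <- n[rows, ] + acc
  }
  normalize_rows(n)
}

mean_edge_length <- function(mesh) {
  fc <- face_corners(mesh)
  mean(c(rownorms(fc$b - fc$a), rownorms(fc$c - fc$b), rownorms(fc$a - fc$c)))
}

## edge-manifold check: every edge shared by at most 2 faces
is_edge_manifold <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) <= 2)
}

is_watertight <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2)
}

## ---- plane cutting ----------------------------------------------------------

## Split every face by the plane; faces straddling it are subdivided so that
## each output face lies wholly on one side.  Returns the mesh with an
## attribute "side" (+1/-1) per face.  Exact area conservation by
## construction.  `tol` snaps near-zero signed distances onto the plane.
split_mesh_by_plane <- function(mesh, plane, tol = 1e-9) {
  v <- mesh$vertices
  d <- plane_signed_distance(plane, v)
  d[abs(d) < tol] <- 0
  f <- mesh$faces
  dv <- matrix(d[f], ncol = 3)
  straddle <- (pmax(dv[, 1], dv[, 2], dv[, 3]) > 0) &
    (pmin(dv[, 1], dv[, 2], dv[, 3]) < 0)

  new_vs <- list(v)
  n_v <- nrow(v)
  out_faces <- list(f[!straddle, , drop = FALSE])
  out_side <- list(ifelse(rowSums(dv[!straddle, , drop = FALSE]) >= 0, 1L, -1L))

  if (any(straddle)) {
    sf <- f[straddle, , drop = FALSE]
    add_f <- vector("list", nrow(sf)); add_s <- vector("list", nrow(sf))
    extra <- matrix(0, 0, 3)
    for (i in seq_len(nrow(sf))) {
      tri <- sf[i, ]
      dd <- d[tri]
      ## rotate so the lone-signed vertex is first
      pos <- dd > 0; neg <- dd < 0
      lone <- if (sum(pos) == 1) which(pos) else if (sum(neg) == 1) which(neg) else NA
      if (is.na(lone)) { # one vertex exactly on plane, others opposite signs
        onp <- which(dd == 0)
        tri <- rotate_to_first(sf[i, ], onp)  # rotation preserves winding
        dd <- d[tri]
        p <- v[tri[2], ] + (v[tri[3], ] - v[tri[2], ]) * (0 - dd[2]) / (dd[3] - dd[2])
        extra <- rbind(extra, p)
        ip <- n_v + nrow(extra)
        add_f[[i]] <- rbind(c(tri[1], tri[2], ip), c(tri[1], ip, tri[3]))
        add_s[[i]] <- c(if (dd[2] > 0) 1L else -1L, if (dd[3] > 0) 1L else -1L)
      } else {
        tri <- rotate_to_first(tri, lone)
        dd <- d[tri]
        t12 <- (0 - dd[1]) / (dd[2] - dd[1])
        t13 <- (0 - dd[1]) / (dd[3] - dd[1])
        p12 <- v[tri[1], ] + (v[tri[2], ] - v[tri[1], ]) * t12
        p13 <- v[tri[1], ] + (v[tri[3], ] - v[tri[1], ]) * t13
        extra <- rbind(extra, p12, p13)
        i12 <- n_v + nrow(extra) - 1L
        i13 <- n_v + nrow(extra)
        s1 <- if (dd[1] > 0) 1L else -1L
        add_f[[i]] <- rbind(c(tri[1], i12, i13),
                            c(tri[2], tri[3], i13),
                            c(tri[2], i13, i12))
        add_s[[i]] <- c(s1, -s1, -s1)
      }
    }
    new_vs <- c(new_vs, list(extra))
    out_faces <- c(out_faces, list(do.call(rbind, add_f)))
    out_side <- c(out_side, list(unlist(add_s)))
  }

  vv <- do.call(rbind, new_vs)
  ff <- do.call(rbind, out_faces)
  side <- unlist(out_side)
  m <- structure(list(vertices = vv, faces = ff), class = "surface_mesh")
  attr(m, "side") <- side
  m
}

rotate_to_first <- function(tri, k) {
  if (k == 1) tri else if (k == 2) tri[c(2, 3, 1)] else tri[c(3, 1, 2)]
}

## keep faces on the positive (or negative) side of a plane, splitting
## straddling triangles at the plane
cut_mesh_by_plane <- function(mesh, plane, keep = c("positive", "negative")) {
  keep <- match.arg(keep)
  s <- split_mesh_by_plane(mesh, plane)
  side <- attr(s, "side")
  want <- if (keep == "positive") side > 0 else side < 0
  surface_mesh(s$vertices, s$faces[want, , drop = FALSE], clean = TRUE)
}

## ---- planar cross-sections --------------------------------------------------

## Area and centroid of the planar region cut by `plane` through a closed,
## consistently wound mesh, via Green's theorem on the (unordered) oriented
## intersection segments.  Orientation comes from the face winding, so no
## contour assembly is needed.
cross_section <- function(mesh, plane) {
  v <- mesh$vertices
  d <- plane_signed_distance(plane, v)
  f <- mesh$faces
  dv <- matrix(d[f], ncol = 3)
  hit <- (pmax(dv[, 1], dv[, 2], dv[, 3]) > 0) &
    (pmin(dv[, 1], dv[, 2], dv[, 3]) < 0)
  if (!any(hit)) return(list(area = 0, centroid = NULL))
  n <- plane$normal
  ## in-plane orthonormal basis
  u1 <- unitv(pick_perp(n))
  u2 <- cross3(n, u1)
  ff <- f[hit, , drop = FALSE]
  m <- nrow(ff)
  A1 <- v[ff[, 1], , drop = FALSE]
  B1 <- v[ff[, 2], , drop = FALSE]
  C1 <- v[ff[, 3], , drop = FALSE]
  dA <- d[ff[, 1]]; dB <- d[ff[, 2]]; dC <- d[ff[, 3]]
  edge_hit <- function(da, db, Pa, Pb) {
    cr <- (da > 0) != (db > 0)
    t <- ifelse(cr, da / (da - db), NA_real_)
    list(cr = cr, P = Pa + t * (Pb - Pa))
  }
  e1 <- edge_hit(dA, dB, A1, B1)
  e2 <- edge_hit(dB, dC, B1, C1)
  e3 <- edge_hit(dC, dA, C1, A1)
  ## each hit face has exactly two crossing edges (parity)
  P1 <- matrix(NA_real_, m, 3); P2 <- matrix(NA_real_, m, 3)
  P1[e1$cr, ] <- e1$P[e1$cr, ]
  P2[e3$cr, ] <- e3$P[e3$cr, ]
  only23 <- !e1$cr
  P1[only23, ] <- e2$P[only23, ]
  both12 <- e1$cr & e2$cr
  P2[both12, ] <- e2$P[both12, ]
  ok <- rowSums(is.na(P1)) == 0 & rowSums(is.na(P2)) == 0
  if (!any(ok)) return(list(area = 0, centroid = NULL))
  P1 <- P1[ok, , drop = FALSE]; P2 <- P2[ok, , drop = FALSE]
  ## orient each segment so (segment, n) matches the face winding:
  ## intersection direction = n_face x n_plane
  fn <- cross3(B1[ok, , drop = FALSE] - A1[ok, , drop = FALSE],
               C1[ok, , drop = FALSE] - A1[ok, , drop = FALSE])
  dir <- cross3(fn, matrix(n, sum(ok), 3, byrow = TRUE))
  flip <- rowSums((P2 - P1) * dir) < 0
  tmp <- P1[flip, , drop = FALSE]
  P1[flip, ] <- P2[flip, , drop = FALSE]
  P2[flip, ] <- tmp
  x1 <- as.numeric(sweep(P1, 2, plane$point) %*% u1)
  y1 <- as.numeric(sweep(P1, 2, plane$point) %*% u2)
  x2 <- as.numeric(sweep(P2, 2, plane$point) %*% u1)
  y2 <- as.numeric(sweep(P2, 2, plane$point) %*% u2)
  crossz <- x1 * y2 - x2 * y1
  A <- sum(crossz) / 2
  if (abs(A) < 1e-12) return(list(area = 0, centroid = NULL))
  Cx <- sum((x1 + x2) * crossz) / 6
  Cy <- sum((y1 + y2) * crossz) / 6
  perim <- sum(sqrt((x2 - x1)^2 + (y2 - y1)^2))
  vec_sum <- c(sum(x2 - x1), sum(y2 - y1))
  closed <- perim > 0 && vnorm(vec_sum) < 1e-6 * perim
  cx <- Cx / A; cy <- Cy / A
  list(area = abs(A),
       centroid = plane$point + cx * u1 + cy * u2,
       closed = closed)
}

## any vector not parallel to n
pick_perp <- function(n) {
  ax <- which.min(abs(n))
  e <- c(0, 0, 0); e[ax] <- 1
  cross3(n, e)
}

## ---- neighbor search --------------------------------------------------------

## Fixed-radius neighbors via a uniform grid hash; returns list of integer
## vectors (excluding self).
radius_neighbors <- function(pts, radius) {
  n <- nrow(pts)
  cell <- pmax(radius, 1e-9)
  key <- floor(sweep(pts, 2, apply(pts, 2, min)) / cell)
  kstr <- paste(key[, 1], key[, 2], key[, 3])
  buckets <- split(seq_len(n), kstr)
  offsets <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  out <- vector("list", n)
  r2 <- radius^2
  for (i in seq_len(n)) {
    cand <- integer(0)
    for (o in seq_len(27)) {
      k <- paste(key[i, 1] + offsets[o, 1], key[i, 2] + offsets[o, 2],
                 key[i, 3] + offsets[o, 3])
      b <- buckets[[k]]
      if (!is.null(b)) cand <- c(cand, b)
    }
    d2 <- rowSums((pts[cand, , drop = FALSE] -
                     matrix(pts[i, ], length(cand), 3, byrow = TRUE))^2)
    out[[i]] <- cand[d2 <= r2 & cand != i]
  }
  out
}
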