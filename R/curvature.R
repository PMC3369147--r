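## Per-vertex principal curvature estimation by local quadric fitting in the
## vertex tangent frame.  Sign convention: convex surfaces (outward normals)
## have positive curvature, so a sphere of radius R gives k1 = k2 = 1/R and
## the saddle-shaped head-neck junction gives k2 < 0.

#' Estimate principal curvatures of a surface mesh
#'
#' For each vertex a quadric height field
#' \eqn{z = ax^2 + bxy + cy^2 + dx + ey} is fitted over the neighbours
#' within `neighborhood_radius` in the local tangent frame, and the
#' principal curvatures are the eigenvalues of the shape operator built
#' from the fitted fundamental forms.  Vertices with fewer than six
#' neighbours are flagged and their curvatures interpolated from
#' neighbouring vertices.
#'
#' @param mesh a `surface_mesh`.
#' @param neighborhood_radius fitting radius in mm; default 2.5 times the
#'   mean edge length, and at least 2 times the mean edge length.
#' @return object of class `curvature_field`: list with `k1`, `k2`
#'   (numeric per vertex, `k1 >= k2`, 1/mm), `dir1`, `dir2` (n x 3 principal
#'   directions) and `flagged` (logical: insufficient neighbourhood).
#' @export
estimate_curvature <- function(mesh, neighborhood_radius = NULL) {
  stopifnot(inherits(mesh, "surface_mesh"))
  mel <- mean_edge_length(mesh)
  if (is.null(neighborhood_radius)) neighborhood_radius <- 2.5 * mel
  if (neighborhood_radius < 2 * mel)
    stop("neighborhood_radius must be at least 2x the mean edge length")
  v <- mesh$vertices
  nv <- nrow(v)
  vn <- vertex_normals(mesh)
  nb <- radius_neighbors(v, neighborhood_radius)

  k1 <- rep(NA_real_, nv); k2 <- rep(NA_real_, nv)
  dir1 <- matrix(NA_real_, nv, 3); dir2 <- matrix(NA_real_, nv, 3)
  flagged <- lengths(nb) < 6

  for (i in which(!flagged)) {
    nrm <- vn[i, ]
    t1 <- unitv(pick_perp(nrm))
    t2 <- cross3(nrm, t1)
    dp <- v[nb[[i]], , drop = FALSE] -
      matrix(v[i, ], length(nb[[i]]), 3, byrow = TRUE)
    x <- dp %*% t1; y <- dp %*% t2; z <- dp %*% nrm
    X <- cbind(x^2, x * y, y^2, x, y)
    cf <- tryCatch(qr.solve(crossprod(X), crossprod(X, z)),
                   error = function(e) NULL)
    if (is.null(cf)) { flagged[i] <- TRUE; next }
    a <- cf[1]; b <- cf[2]; cc <- cf[3]; d <- cf[4]; e <- cf[5]
    ## fundamental forms of z(x, y); outward-normal z makes convex bending
    ## negative, flip so convex is positive
    w <- sqrt(1 + d^2 + e^2)
    E <- 1 + d^2; Fq <- d * e; G <- 1 + e^2
    L <- 2 * a / w; M <- b / w; N <- 2 * cc / w
    den <- E * G - Fq^2
    S <- matrix(c(G * L - Fq * M, G * M - Fq * N,
                  E * M - Fq * L, E * N - Fq * M), 2, 2, byrow = TRUE) / den
    ev <- eigen((S + t(S)) / 2, symmetric = TRUE)
    ks <- -ev$values            # flip: convex positive
    ord <- order(ks, decreasing = TRUE)
    k1[i] <- ks[ord[1]]; k2[i] <- ks[ord[2]]
    d1 <- ev$vectors[, ord[1]]; d2v <- ev$vectors[, ord[2]]
    dir1[i, ] <- d1[1] * as.numeric(t1) + d1[2] * as.numeric(t2)
    dir2[i, ] <- d2v[1] * as.numeric(t1) + d2v[2] * as.numeric(t2)
  }

  ## interpolate flagged vertices from their (valid) neighbours
  if (any(flagged)) {
    for (i in which(flagged)) {
      cand <- nb[[i]]
      cand <- cand[!flagged[cand]]
      if (length(cand) > 0) {
        k1[i] <- mean(k1[cand]); k2[i] <- mean(k2[cand])
        dir1[i, ] <- dir1[cand[1], ]; dir2[i, ] <- dir2[cand[1], ]
      }
    }
  }
  structure(list(k1 = k1, k2 = k2, dir1 = dir1, dir2 = dir2,
                 flagged = flagged,
                 neighborhood_radius = neighborhood_radius),
            class = "curvature_field")
}

#' @export
print.curvature_field <- function(x, ...) {
  cat(sprintf(paste0("<curvature_field> %d vertices, median k1 %.4f, ",
                     "median k2 %.4f 1/mm (radius %.2f mm)\n"),
              length(x$k1), median(x$k1, na.rm = TRUE),
              median(x$k2, na.rm = TRUE), x$neighborhood_radius))
  invisible(x)
}
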