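#' Brute-force stationary Fokker-Planck solution on a grid (1-D/2-D)
#'
#' Independent low-dimensional oracle for the mixture fit: discretizes the
#' stationary Fokker-Planck operator with a flux-conservative Chang-Cooper
#' scheme (drift-diffusion fluxes with exponential upwind weights, which keep
#' the discrete density nonnegative) on a regular cell-centered grid with
#' zero-flux (reflecting) boundaries, and solves for the null vector of the
#' resulting sparse generator.  Probability is conserved exactly on the
#' truncated domain.  This code path shares no derivative machinery with
#' [stationary_residual()].
#'
#' @param fpe an [fpe_model()] or [fpe_custom()] with `d <= 2`.
#' @param box `2 x d` matrix: `box[1, ]` lower and `box[2, ]` upper bounds
#'   (default `[0, 10]` per gene).
#' @param n_grid cells per dimension (scalar or per-dimension).
#' @param neg_tol most negative admissible density value, relative to the
#'   maximum, before the grid is declared too coarse.
#' @return An object of class `grid_solution`: list with `grid` (cell-center
#'   coordinates per dimension), `density` (vector / matrix, normalized so
#'   that `sum(density) * prod(h) = 1`), `h` (cell widths), `box`.
#' @export
grid_stationary <- function(fpe, box = NULL, n_grid = 201, neg_tol = 1e-8) {
  d <- fpe$d
  if (d > 2) stop_("grid solutions are supported only for d <= 2")
  if (is.null(box)) box <- rbind(rep(0, d), rep(10, d))
  box <- as.matrix(box)
  K <- rep(as.integer(n_grid), length.out = d)
  h <- (box[2, ] - box[1, ]) / K
  centers <- lapply(seq_len(d), function(j)
    box[1, j] + (seq_len(K[j]) - 0.5) * h[j])
  ntot <- prod(K)
  idx_of <- function(k1, k2) if (d == 1) k1 else k1 + (k2 - 1L) * K[1]

  # Chang-Cooper weight: delta(w) = 1/w - 1/(e^w - 1), delta(0) = 1/2.
  cc_delta <- function(w) {
    out <- ifelse(abs(w) < 1e-8, 0.5 - w / 12,
                  1 / w - 1 / expm1(pmin(w, 700)))
    ifelse(w >= 700, 1 / w, out)
  }

  ii <- jj <- xx <- list()
  push <- function(i, j, x) {
    k <- length(ii) + 1L
    ii[[k]] <<- i; jj[[k]] <<- j; xx[[k]] <<- x
  }

  # Assemble fluxes for each dimension.
  for (dim_j in seq_len(d)) {
    K_j <- K[dim_j]; h_j <- h[dim_j]
    other <- if (d == 2) centers[[3 - dim_j]] else numeric(0)
    n_other <- max(1L, length(other))
    # face positions along dim_j (interior faces only)
    faces <- box[1, dim_j] + seq_len(K_j - 1) * h_j
    for (f in seq_len(K_j - 1)) {
      # points: the face in dim_j crossed with all cells in the other dim
      pts <- matrix(NA_real_, n_other, d)
      pts[, dim_j] <- faces[f]
      if (d == 2) pts[, 3 - dim_j] <- other
      a <- drift_field(fpe, pts)
      if (is.null(dim(a))) a <- matrix(a, n_other)
      # D = Gamma/2 at the face and its derivative along dim_j
      eps <- h_j / 2
      pp <- pm <- pts
      pp[, dim_j] <- pts[, dim_j] + eps
      pm[, dim_j] <- pmax(pts[, dim_j] - eps, box[1, dim_j])
      Gf <- diffusion_field(fpe, pts)
      Gp <- diffusion_field(fpe, pp)
      Gm <- diffusion_field(fpe, pm)
      if (is.null(dim(Gf))) {
        Gf <- matrix(Gf, n_other); Gp <- matrix(Gp, n_other)
        Gm <- matrix(Gm, n_other)
      }
      Dface <- Gf[, dim_j] / 2
      Dprime <- (Gp[, dim_j] - Gm[, dim_j]) / 2 / (pp[, dim_j] - pm[, dim_j])
      atil <- a[, dim_j] - Dprime
      Dh <- pmax(Dface, 1e-300) / h_j
      w <- atil / Dh
      del <- cc_delta(w)
      # flux F = atil [ (1-delta) P_L + delta P_R ] - Dh (P_R - P_L);
      # delta -> 0 (1) for strong right- (left-) ward advection, so the
      # advective weight sits upwind and the generator stays an M-matrix.
      cL <- atil * (1 - del) + Dh # coefficient of P_left in F
      cR <- atil * del - Dh       # coefficient of P_right in F
      for (o in seq_len(n_other)) {
        if (d == 1) { left <- idx_of(f); right <- idx_of(f + 1L) }
        else if (dim_j == 1) { left <- idx_of(f, o); right <- idx_of(f + 1L, o) }
        else { left <- idx_of(o, f); right <- idx_of(o, f + 1L) }
        # dP_left/dt -= F/h ; dP_right/dt += F/h
        push(left, left, -cL[o] / h_j); push(left, right, -cR[o] / h_j)
        push(right, left, cL[o] / h_j); push(right, right, cR[o] / h_j)
      }
    }
  }
  M <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(ntot, ntot))
  # Null vector: replace one balance equation by the normalization sum = 1.
  M[1, ] <- 1
  rhs <- c(1, rep(0, ntot - 1))
  dens <- as.numeric(Matrix::solve(M, rhs))
  if (min(dens) < -neg_tol * max(dens))
    stop_(paste0("grid too coarse: discretized density has negative values; ",
                 "refine 'n_grid'"))
  dens <- pmax(dens, 0)
  dens <- dens / (sum(dens) * prod(h))
  structure(list(grid = centers,
                 density = if (d == 1) dens else matrix(dens, K[1], K[2]),
                 h = h, box = box, genes = fpe$genes),
            class = "grid_solution")
}

#' @export
print.grid_solution <- function(x, ...) {
  cat(sprintf("Grid stationary density: %s cells on [%s] x [%s]\n",
              paste(vapply(x$grid, length, integer(1)), collapse = " x "),
              paste(signif(x$box[, 1], 3), collapse = ", "),
              if (ncol(x$box) > 1) paste(signif(x$box[, 2], 3), collapse = ", ")
              else ""))
  invisible(x)
}

#' Evaluate a grid solution by interpolation
#'
#' Linear interpolation of the grid density at arbitrary points (clamped to
#' the grid hull).
#'
#' @param gs a [grid_stationary()] result.
#' @param p point vector or matrix of row-points.
#' @return Density values.
#' @export
grid_density_at <- function(gs, p) {
  d <- length(gs$grid)
  P <- if (is.null(dim(p))) matrix(as.numeric(p), ncol = d, byrow = TRUE)
       else as.matrix(p)
  clamp <- function(x, g) pmin(pmax(x, g[1]), g[length(g)])
  if (d == 1) {
    stats::approx(gs$grid[[1]], gs$density,
                  clamp(P[, 1], gs$grid[[1]]), rule = 2)$y
  } else {
    g1 <- gs$grid[[1]]; g2 <- gs$grid[[2]]
    x <- clamp(P[, 1], g1); y <- clamp(P[, 2], g2)
    i <- pmin(pmax(findInterval(x, g1), 1), length(g1) - 1)
    j <- pmin(pmax(findInterval(y, g2), 1), length(g2) - 1)
    tx <- (x - g1[i]) / (g1[i + 1] - g1[i])
    ty <- (y - g2[j]) / (g2[j + 1] - g2[j])
    Z <- gs$density
    (1 - tx) * (1 - ty) * Z[cbind(i, j)] + tx * (1 - ty) * Z[cbind(i + 1, j)] +
      (1 - tx) * ty * Z[cbind(i, j + 1)] + tx * ty * Z[cbind(i + 1, j + 1)]
  }
}

#' Smoothly interpolated 1-D density with derivatives
#'
#' Wraps a 1-D [grid_stationary()] solution as a differentiable density
#' (natural spline of the log density), so that [stationary_residual()] can
#' be evaluated on the oracle solution itself.
#'
#' @param gs a 1-D [grid_stationary()] result.
#' @param floor densities below `floor * max(density)` are floored before
#'   taking logs.
#' @return An object of class `interpolated_density`.
#' @export
interpolated_density <- function(gs, floor = 1e-12) {
  stopifnot(inherits(gs, "grid_solution"), length(gs$grid) == 1)
  x <- gs$grid[[1]]
  lf <- log(pmax(gs$density, floor * max(gs$density)))
  sf <- stats::splinefun(x, lf, method = "natural")
  structure(list(logf = sf, genes = gs$genes, weights = 1),
            class = "interpolated_density")
}

#' Write a grid solution to CSV
#'
#' Columns: the coordinates of each cell center, then `density`.
#'
#' @param gs a [grid_stationary()] result.
#' @param path output file.
#' @export
write_grid_csv <- function(gs, path) {
  d <- length(gs$grid)
  df <- if (d == 1) data.frame(gs$grid[[1]], density = as.numeric(gs$density))
        else data.frame(expand.grid(gs$grid[[1]], gs$grid[[2]]),
                        density = as.numeric(gs$density))
  names(df)[seq_len(d)] <- gs$genes[seq_len(d)]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
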