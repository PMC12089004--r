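#' Collocation configuration
#'
#' Settings for the Monte Carlo weighted-residual (collocation) estimate of
#' the stationary Fokker-Planck residual norm: the number of collocation
#' points, the rectangular domain `[0, p_max]^d`, and the sampling scheme
#' (uniform over the box, the default and unbiased choice, or importance
#' sampling from a proxy mixture).
#'
#' @param n_points number of collocation points (default `1e6`).
#' @param p_max per-gene upper bound of the domain box (scalar or vector;
#'   default 10, comfortably above all attractor concentrations since the
#'   drift is strongly negative beyond `(1 + alpha0)/delta`).
#' @param sampling `"uniform"` or `"proxy"`.
#' @param seed optional integer seed.
#' @return An object of class `collocation_config`.
#' @export
collocation_config <- function(n_points = 1e6, p_max = 10,
                               sampling = c("uniform", "proxy"),
                               seed = NULL) {
  check_scalar(n_points, "n_points", 1)
  if (any(p_max <= 0)) stop_("'p_max' must be positive")
  structure(list(n_points = as.integer(n_points), p_max = p_max,
                 sampling = match.arg(sampling), seed = seed),
            class = "collocation_config")
}

# Draw collocation points inside (0, p_max)^d.  For proxy sampling, points
# are drawn from `proxy` and rejected outside the box; the returned matrix
# carries the per-point proposal density as attribute "q".
draw_collocation_points <- function(colloc, d, proxy = NULL) {
  upper <- expand_per_gene(colloc$p_max, d, "p_max")
  m <- colloc$n_points
  if (colloc$sampling == "uniform" || is.null(proxy)) {
    P <- matrix(stats::runif(m * d), m, d)
    P <- sweep(P, 2, upper, `*`)
    attr(P, "q") <- rep(1 / prod(upper), m)
  } else {
    P <- matrix(NA_real_, m, d)
    got <- 0L
    for (it in 1:100) {
      X <- mixture_sample(proxy, m)
      ok <- rowSums(X <= 0 | X >= rep(upper, each = m)) == 0
      take <- min(m - got, sum(ok))
      if (take > 0) P[got + seq_len(take), ] <- X[which(ok)[seq_len(take)], ]
      got <- got + take
      if (got == m) break
    }
    if (got < m) stop_("proxy importance sampling kept rejecting the box")
    attr(P, "q") <- mixture_pdf(proxy, P)
  }
  attr(P, "volume") <- prod(upper)
  P
}

# Field coefficients of the stationary FPE residual operator at the
# row-points of P:
#   R(p) = sum_j [ c0_j Q + c1_j dQ/dp_j + c2_j d2Q/dp_j2 ]
# with c0 = -da_j/dp_j + (1/2) d2Gamma_j/dp_j2,
#      c1 = -a_j + dGamma_j/dp_j,  c2 = Gamma_j / 2,
# for drift a and diagonal diffusion Gamma.  Field derivatives are central
# finite differences (coordinate-wise, step scaled to the point).
residual_coefficients <- function(fpe, P, h = 1e-4) {
  m <- nrow(P)
  d <- ncol(P)
  a0 <- drift_field(fpe, P)
  g0 <- diffusion_field(fpe, P)
  if (is.null(dim(a0))) { a0 <- matrix(a0, m); g0 <- matrix(g0, m) }
  da <- dg <- d2g <- matrix(NA_real_, m, d)
  nonneg <- !inherits(fpe, "fpe_custom")
  for (j in seq_len(d)) {
    hj <- h * pmax(1, abs(P[, j]))
    if (nonneg) hj <- pmin(hj, P[, j])  # keep p - h inside the domain
    Pp <- Pm <- P
    Pp[, j] <- P[, j] + hj
    Pm[, j] <- P[, j] - hj
    ap <- drift_field(fpe, Pp); am <- drift_field(fpe, Pm)
    gp <- diffusion_field(fpe, Pp); gm <- diffusion_field(fpe, Pm)
    if (is.null(dim(ap))) {
      ap <- matrix(ap, m); am <- matrix(am, m)
      gp <- matrix(gp, m); gm <- matrix(gm, m)
    }
    da[, j] <- (ap[, j] - am[, j]) / (2 * hj)
    dg[, j] <- (gp[, j] - gm[, j]) / (2 * hj)
    d2g[, j] <- (gp[, j] - 2 * g0[, j] + gm[, j]) / hj^2
  }
  list(c0 = -da + d2g / 2, c1 = -a0 + dg, c2 = g0 / 2)
}

# R(p) at the row-points of P given precomputed field coefficients.
residual_values <- function(fpe, mix, P, coefs = NULL, h = 1e-4) {
  if (is.null(coefs)) coefs <- residual_coefficients(fpe, P, h)
  dd <- mixture_derivative_data(mix, P)
  R <- numeric(nrow(P))
  for (i in seq_along(dd$weights)) {
    u <- dd$u[[i]]
    Tm <- coefs$c0 + coefs$c1 * u + coefs$c2 * (u^2 - dd$w[[i]])
    R <- R + dd$weights[i] * exp(dd$logc[, i]) * rowSums(Tm)
  }
  R
}

#' Stationary Fokker-Planck residual of a trial density
#'
#' Evaluates, at one or more interior points, the residual
#' \deqn{R(p) = -\sum_j \partial_{p_j}[(B_j - \delta_j p_j)\hat P]
#'   + \tfrac12 \sum_j \partial^2_{p_j}[\Gamma_j \hat P]}
#' of the stationary Fokker-Planck equation for the mixture density
#' `hat P` (diffusion is diagonal).  The mixture's first and second
#' derivatives are analytic; the drift/diffusion fields are differentiated
#' by central finite differences.  `R` is identically 0 for an exact
#' stationary solution, and is linear in the density.
#'
#' @param fpe an [fpe_model()] or [fpe_custom()].
#' @param mix a [gamma_mixture()] or [gaussian_mixture()].
#' @param p strictly interior point vector or matrix of row-points (gamma
#'   densities have singular derivatives on the boundary).
#' @return Numeric vector of residual values, one per point.
#' @export
stationary_residual <- function(fpe, mix, p) {
  d <- fpe$d
  P <- if (is.null(dim(p))) matrix(as.numeric(p), ncol = d, byrow = TRUE)
       else as.matrix(p)
  if (ncol(P) != d) stop_("point dimension does not match the model")
  if (inherits(mix, "gamma_mixture") && any(P <= 0))
    stop_("points must lie strictly inside the positive orthant")
  residual_values(fpe, mix, P)
}

#' Monte Carlo collocation norm of the stationary residual
#'
#' Estimates the integral of `|R(p)|` over the domain box by Monte Carlo
#' quadrature: the mean of `|R|` at the collocation points times the box
#' volume (uniform sampling), or the importance-weighted mean under proxy
#' sampling.  The return value carries the per-point mean absolute residual
#' as attribute `"mean_abs"` (the convergence figure reported by the fit)
#' and the number of points as `"n_points"`.
#'
#' @param fpe an [fpe_model()] or [fpe_custom()].
#' @param mix a mixture trial density.
#' @param colloc a [collocation_config()].
#' @param proxy optional proxy mixture for importance sampling.
#' @return The scalar norm estimate (with attributes).
#' @export
collocation_residual_norm <- function(fpe, mix, colloc = collocation_config(),
                                      proxy = NULL) {
  stopifnot(inherits(colloc, "collocation_config"))
  with_seed(colloc$seed, {
    P <- draw_collocation_points(colloc, fpe$d, proxy)
    R <- residual_values(fpe, mix, P)
    q <- attr(P, "q")
    norm <- mean(abs(R) / q)  # E_q[|R|/q] = integral of |R| over the box
    structure(norm, mean_abs = mean(abs(R)), n_points = nrow(P))
  })
}
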