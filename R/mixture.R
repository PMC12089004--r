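#' Gamma mixture ansatz for the stationary density
#'
#' Trial stationary density of the Fokker-Planck equation: a weighted sum of
#' `n` components, each a product of independent gamma densities, one factor
#' per gene,
#' \deqn{\hat P(p) = \sum_i A_i \prod_j
#'   \frac{\beta_{ij}^{\alpha_{ij}}}{\Gamma(\alpha_{ij})}
#'   p_j^{\alpha_{ij}-1} e^{-\beta_{ij} p_j}.}
#' `n` is the number of stationary states (attractors) of the system.
#' Component weights are kept on the probability simplex, so the mixture is a
#' normalized density; weights supplied to the constructor are rescaled to
#' sum to 1.
#'
#' @param weights nonnegative component weights (rescaled to sum to 1).
#' @param shapes `n x d` matrix of gamma shapes `alpha_ij > 0` (a vector is
#'   taken as a single component).
#' @param rates `n x d` matrix of gamma rates `beta_ij > 0`.
#' @param genes optional gene names (length `d`).
#' @return An object of class `gamma_mixture`.
#' @seealso [mixture_pdf()], [mixture_sample()], [mixture_modes()],
#'   [landscape()], [at_table2_mixture()]
#' @export
gamma_mixture <- function(weights, shapes, rates, genes = NULL) {
  shapes <- as_param_matrix(shapes)
  rates <- as_param_matrix(rates)
  new_mixture("gamma_mixture", weights, shapes, rates, genes,
              check = function(m) {
                if (any(m$shapes <= 0) || any(m$rates <= 0))
                  stop_("gamma shapes and rates must be strictly positive")
              })
}

#' Diagonal Gaussian mixture (stage-2 proxy distribution)
#'
#' Same interface as [gamma_mixture()] but with product-of-normals
#' components (diagonal covariance).  Used as the proxy distribution in the
#' global and gradient-refinement stages of the fit, because its quadrature
#' points are tightly concentrated and residual evaluations fluctuate less
#' than under heavy-tailed gamma components.
#'
#' @param weights nonnegative component weights (rescaled to sum to 1).
#' @param means `n x d` matrix of component means.
#' @param variances `n x d` matrix of per-gene variances (> 0).
#' @param genes optional gene names.
#' @return An object of class `gaussian_mixture`.
#' @export
gaussian_mixture <- function(weights, means, variances, genes = NULL) {
  means <- as_param_matrix(means)
  variances <- as_param_matrix(variances)
  new_mixture("gaussian_mixture", weights, means, variances, genes,
              fields = c("means", "variances"),
              check = function(m) {
                if (any(m$variances <= 0))
                  stop_("variances must be strictly positive")
              })
}

as_param_matrix <- function(x) {
  if (is.null(dim(x))) matrix(as.numeric(x), nrow = 1) else as.matrix(x)
}

new_mixture <- function(class, weights, m1, m2, genes,
                        fields = c("shapes", "rates"), check) {
  weights <- as.numeric(weights)
  if (any(weights < 0) || sum(weights) <= 0 || any(!is.finite(weights)))
    stop_("weights must be nonnegative with positive sum")
  if (!all(dim(m1) == dim(m2)))
    stop_("parameter matrices must have identical dimensions")
  if (nrow(m1) != length(weights))
    stop_("number of weights must match the number of components")
  if (any(!is.finite(m1)) || any(!is.finite(m2)))
    stop_("mixture parameters must be finite")
  if (is.null(genes)) genes <- paste0("g", seq_len(ncol(m1)))
  if (length(genes) != ncol(m1))
    stop_("'genes' length must match the number of columns")
  obj <- structure(list(weights = weights / sum(weights), genes = genes),
                   class = class)
  obj[[fields[1]]] <- m1
  obj[[fields[2]]] <- m2
  check(obj)
  obj
}

#' @export
print.gamma_mixture <- function(x, ...) {
  cat(sprintf("Gamma mixture: %d components x %d genes\n",
              length(x$weights), ncol(x$shapes)))
  cat("  weights:", paste(signif(x$weights, 3), collapse = " "), "\n")
  cat("  modes:\n")
  print(round(mixture_modes(x), 3))
  invisible(x)
}

#' @export
print.gaussian_mixture <- function(x, ...) {
  cat(sprintf("Gaussian mixture: %d components x %d genes\n",
              length(x$weights), ncol(x$means)))
  cat("  weights:", paste(signif(x$weights, 3), collapse = " "), "\n")
  invisible(x)
}

mixture_dim <- function(mix) {
  if (inherits(mix, "gamma_mixture")) ncol(mix$shapes)
  else if (inherits(mix, "gaussian_mixture")) ncol(mix$means)
  else 1L  # interpolated 1-D density
}

# m x n matrix of per-component log densities at the row-points of P.
component_logpdf <- function(mix, P) {
  n <- length(mix$weights)
  d <- mixture_dim(mix)
  out <- matrix(NA_real_, nrow(P), n)
  for (i in seq_len(n)) {
    out[, i] <- if (inherits(mix, "gamma_mixture"))
      rowSums(stats::dgamma(P, matrix(mix$shapes[i, ], nrow(P), d, byrow = TRUE),
                            matrix(mix$rates[i, ], nrow(P), d, byrow = TRUE),
                            log = TRUE))
    else
      rowSums(stats::dnorm(P, matrix(mix$means[i, ], nrow(P), d, byrow = TRUE),
                           matrix(sqrt(mix$variances[i, ]), nrow(P), d,
                                  byrow = TRUE), log = TRUE))
  }
  out
}

#' Mixture density and log-density
#'
#' Evaluates the (normalized) mixture density at one or more points.  For a
#' gamma mixture the domain is the nonnegative orthant; negative coordinates
#' raise an error.  Where the density is exactly 0, `log = TRUE` returns
#' `-Inf`.
#'
#' @param mix a [gamma_mixture()] or [gaussian_mixture()].
#' @param p point vector, or matrix with one point per row.
#' @param log return the log density?
#' @return Numeric vector of densities (one per point).
#' @export
mixture_pdf <- function(mix, p, log = FALSE) {
  d <- mixture_dim(mix)
  P <- if (is.null(dim(p))) matrix(as.numeric(p), ncol = d, byrow = TRUE)
       else as.matrix(p)
  if (ncol(P) != d) stop_("point dimension does not match the mixture")
  if (inherits(mix, "gamma_mixture") && any(P < 0))
    stop_("gamma mixture density is defined on the nonnegative orthant")
  lc <- component_logpdf(mix, P)
  lw <- matrix(base::log(mix$weights), nrow(P), length(mix$weights),
               byrow = TRUE)
  M <- apply(lc + lw, 1, max)
  lp <- ifelse(is.finite(M),
               M + base::log(rowSums(exp(lc + lw - M))), M)
  if (log) lp else exp(lp)
}

#' Draw samples from a mixture
#'
#' Ancestral sampling: a component is drawn by weight, then each coordinate
#' independently from its gamma (or normal) factor.
#'
#' @param mix a mixture object.
#' @param m number of samples.
#' @param seed optional integer seed (private RNG stream).
#' @return `m x d` matrix with gene-named columns.
#' @export
mixture_sample <- function(mix, m, seed = NULL) {
  stopifnot(m >= 1)
  d <- mixture_dim(mix)
  n <- length(mix$weights)
  with_seed(seed, {
    comp <- sample.int(n, m, replace = TRUE, prob = mix$weights)
    out <- matrix(NA_real_, m, d)
    for (i in seq_len(n)) {
      idx <- which(comp == i)
      if (!length(idx)) next
      out[idx, ] <- if (inherits(mix, "gamma_mixture"))
        matrix(stats::rgamma(length(idx) * d,
                             rep(mix$shapes[i, ], each = length(idx)),
                             rep(mix$rates[i, ], each = length(idx))),
               length(idx), d)
      else
        matrix(stats::rnorm(length(idx) * d,
                            rep(mix$means[i, ], each = length(idx)),
                            rep(sqrt(mix$variances[i, ]), each = length(idx))),
               length(idx), d)
    }
    colnames(out) <- mix$genes
    out
  })
}

#' Component modes
#'
#' For a gamma component the per-gene mode is `(alpha - 1) / beta` when
#' `alpha > 1` and 0 otherwise (the density is maximal, or unbounded, at the
#' origin); these are the attractor locations of the fitted landscape.  For a
#' Gaussian mixture the modes are the means.
#'
#' @param mix a mixture object.
#' @return `n x d` matrix of modes, columns named by gene.
#' @export
mixture_modes <- function(mix) {
  out <- if (inherits(mix, "gamma_mixture"))
    pmax(mix$shapes - 1, 0) / mix$rates
  else mix$means
  colnames(out) <- mix$genes
  out
}

#' Mean concentration of the active genes in each component
#'
#' For each mixture component (attractor), the arithmetic mean of the mode
#' entries exceeding `active_threshold` -- i.e. the typical concentration of
#' the proteins whose genes are switched on in that attractor.  Components
#' with no active gene report 0.
#'
#' @param x a mixture object, or a precomputed `n x d` matrix of modes.
#' @param active_threshold modes above this count as active (default 0).
#' @return Numeric vector, one summary per component.
#' @export
active_gene_summary <- function(x, active_threshold = 0) {
  modes <- if (is.matrix(x)) x else mixture_modes(x)
  apply(modes, 1, function(m) {
    act <- m[m > active_threshold]
    if (length(act)) mean(act) else 0
  })
}

#' Epigenetic landscape (quasi-potential)
#'
#' The landscape value `U(p) = -log P(p)` of a mixture density: minima of `U`
#' coincide with the density's local maxima, the attractors.  Points of zero
#' density map to `+Inf`.
#'
#' @param mix a mixture object.
#' @param p point vector or matrix of row-points.
#' @return Numeric vector of landscape values (dimensionless).
#' @export
landscape <- function(mix, p) -mixture_pdf(mix, p, log = TRUE)

#' Geometry of the fitted landscape
#'
#' Pairwise Manhattan (L1) distances between component modes, together with
#' the landscape depth `U` at each mode.  Inter-mode distances order the
#' likely transitions between cell states; relative depths order the time
#' spent in each state.
#'
#' @param mix a mixture object.
#' @return List with `modes` (n x d), `depths` (U at each mode) and
#'   `distances` (symmetric n x n Manhattan distance matrix, zero diagonal).
#' @export
landscape_summary <- function(mix) {
  modes <- mixture_modes(mix)
  dists <- as.matrix(stats::dist(modes, method = "manhattan"))
  dimnames(dists) <- NULL
  list(modes = modes, depths = landscape(mix, modes), distances = dists)
}

#' Read / write mixtures as JSON
#'
#' Format: `{"weights": [...], "shapes": [[...]], "rates": [[...]],
#' "gene_names": [...]}` (fields `means`/`variances` for a Gaussian mixture).
#'
#' @param path file path.
#' @return `read_mixture_json` returns a mixture object.
#' @export
read_mixture_json <- function(path) {
  if (!file.exists(path)) stop_(sprintf("mixture file not found: %s", path))
  obj <- jsonlite::fromJSON(path)
  genes <- obj$gene_names
  if (!is.null(obj$shapes))
    gamma_mixture(obj$weights, obj$shapes, obj$rates, genes)
  else if (!is.null(obj$means))
    gaussian_mixture(obj$weights, obj$means, obj$variances, genes)
  else stop_("mixture JSON must have 'shapes'/'rates' or 'means'/'variances'")
}

#' @rdname read_mixture_json
#' @param mix a mixture object.
#' @export
write_mixture_json <- function(mix, path) {
  obj <- if (inherits(mix, "gamma_mixture"))
    list(weights = mix$weights, shapes = mix$shapes, rates = mix$rates,
         gene_names = mix$genes)
  else
    list(weights = mix$weights, means = mix$means,
         variances = mix$variances, gene_names = mix$genes)
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' The packaged A. thaliana stationary-density fit
#'
#' The published 4-component, 12-gene gamma mixture approximating the
#' stationary density of the A. thaliana flower-morphogenesis model; each
#' component sits at one of the four developmental attractors.  Component
#' weights were not reported with the fit, so the fixture assumes uniform
#' weights 1/4.
#'
#' @return A [gamma_mixture()].
#' @export
at_table2_mixture <- function() {
  read_mixture_json(system.file("extdata", "at_table2_mixture.json",
                                package = "grnlandscape", mustWork = TRUE))
}

# Pointwise density derivatives used by the residual operator.
# Returns, for each component i: logP[, i] and, per coordinate j,
#   dP/dp_j   = P * u_ij(p)
#   d2P/dp_j2 = P * (u_ij^2 - w_ij(p))
# with u = (alpha-1)/p - beta, w = (alpha-1)/p^2   (gamma), or
#      u = -(p-mu)/s2,         w = 1/s2            (gaussian).
mixture_derivative_data <- function(mix, P) {
  if (inherits(mix, "interpolated_density")) {
    x <- P[, 1]
    lg1 <- mix$logf(x, deriv = 1)
    return(list(logc = matrix(mix$logf(x), ncol = 1),
                u = list(matrix(lg1, ncol = 1)),
                w = list(matrix(-mix$logf(x, deriv = 2), ncol = 1)),
                weights = 1))
  }
  n <- length(mix$weights)
  d <- mixture_dim(mix)
  m <- nrow(P)
  logc <- component_logpdf(mix, P)
  u <- w <- vector("list", n)
  for (i in seq_len(n)) {
    if (inherits(mix, "gamma_mixture")) {
      am1 <- matrix(mix$shapes[i, ] - 1, m, d, byrow = TRUE)
      be <- matrix(mix$rates[i, ], m, d, byrow = TRUE)
      u[[i]] <- am1 / P - be
      w[[i]] <- am1 / P^2
    } else {
      mu <- matrix(mix$means[i, ], m, d, byrow = TRUE)
      s2 <- matrix(mix$variances[i, ], m, d, byrow = TRUE)
      u[[i]] <- -(P - mu) / s2
      w[[i]] <- 1 / s2
    }
  }
  list(logc = logc, u = u, w = w, weights = mix$weights)
}
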