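#' Correlation (coexpression) matrix container
#'
#' A symmetric, unit-diagonal matrix of pairwise Pearson correlations with
#' gene labels; entries lie in `[-1, 1]`.
#'
#' @param values square numeric matrix.
#' @param labels gene labels (default taken from `dimnames`).
#' @param tol tolerance for the symmetry / diagonal / range checks.
#' @return An object of class `correlation_matrix`.
#' @export
correlation_matrix <- function(values, labels = NULL, tol = 1e-8) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop_("correlation matrix must be square")
  if (is.null(labels)) labels <- rownames(values)
  if (is.null(labels)) labels <- paste0("g", seq_len(nrow(values)))
  if (length(labels) != nrow(values)) stop_("label length mismatch")
  if (anyDuplicated(labels)) stop_("duplicate gene labels")
  if (max(abs(values - t(values))) > tol) stop_("matrix is not symmetric")
  if (max(abs(diag(values) - 1)) > tol) stop_("diagonal must be 1")
  if (max(abs(values)) > 1 + tol) stop_("entries must lie in [-1, 1]")
  values <- (values + t(values)) / 2
  diag(values) <- 1
  values[values > 1] <- 1; values[values < -1] <- -1
  dimnames(values) <- list(labels, labels)
  structure(list(labels = labels, values = values),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("Coexpression matrix: %d genes\n", length(x$labels)))
  print(round(x$values, 3))
  invisible(x)
}

#' @export
as.matrix.correlation_matrix <- function(x, ...) x$values

#' Pairwise Pearson correlations of expression samples
#'
#' Computes `rho = sigma_xy / (sigma_x sigma_y)` for each gene pair from an
#' `m x t` sample matrix (rows = observations).  A constant column has no
#' defined correlation; such entries are set to 0 with a warning (matching
#' the convention of zeroing missing coexpression data).
#'
#' @param samples numeric matrix, `m >= 3` rows, one column per gene.
#' @param labels gene labels (default: column names).
#' @return A [correlation_matrix()].
#' @export
pearson_matrix <- function(samples, labels = colnames(samples)) {
  samples <- as.matrix(samples)
  if (nrow(samples) < 3) stop_("need at least 3 observations")
  if (is.null(labels)) labels <- paste0("g", seq_len(ncol(samples)))
  V <- suppressWarnings(stats::cor(samples))
  if (anyNA(V)) {
    warning("constant column(s): undefined correlations set to 0",
            call. = FALSE)
    V[is.na(V)] <- 0
  }
  diag(V) <- 1
  correlation_matrix(V, labels)
}

as_corr_values <- function(M) {
  if (inherits(M, "correlation_matrix")) M$values else as.matrix(M)
}

#' Euclidean (Frobenius) distance between two coexpression matrices
#'
#' `d(M, N) = sqrt(sum_s (m_s - n_s)^2)` over all `t^2` entries (diagonal
#' included; it cancels for two true correlation matrices).  This is the
#' statistic compared against the random-matrix null distributions.
#'
#' @param M,N [correlation_matrix()] objects with matching labels.
#' @return Nonnegative scalar distance.
#' @export
matrix_distance <- function(M, N) {
  vM <- as_corr_values(M); vN <- as_corr_values(N)
  lM <- rownames(vM); lN <- rownames(vN)
  if (!is.null(lM) && !is.null(lN) && !identical(lM, lN)) {
    if (setequal(lM, lN)) {
      vN <- vN[lM, lM]  # same genes, different order
    } else {
      stop_(sprintf("gene labels do not match; unmatched: %s",
                    paste(union(setdiff(lM, lN), setdiff(lN, lM)),
                          collapse = ", ")))
    }
  }
  if (!all(dim(vM) == dim(vN))) stop_("matrix dimensions differ")
  sqrt(sum((vM - vN)^2))
}

#' Random correlation matrices
#'
#' Draws the sample correlation matrix of `m_eff` independent standard-normal
#' `t`-vectors: by construction symmetric, unit-diagonal and positive
#' semidefinite ("the same characteristics of a correlation matrix").
#' `m_eff` tunes the spread of the null: large `m_eff` concentrates the
#' matrix near the identity (off-diagonal entries ~ `1/sqrt(m_eff)`).
#'
#' @param t number of genes (>= 2).
#' @param m_eff number of underlying samples (>= t + 1).
#' @param seed optional seed.
#' @param labels optional labels.
#' @return A [correlation_matrix()].
#' @export
random_correlation_matrix <- function(t, m_eff = 100, seed = NULL,
                                      labels = NULL) {
  stopifnot(t >= 2, m_eff >= t + 1)
  with_seed(seed,
    pearson_matrix(matrix(stats::rnorm(m_eff * t), m_eff, t), labels))
}

#' Null distributions of coexpression-matrix distances
#'
#' Samples the two reference distributions the model-data distance is judged
#' against: (1) distances between two independent random correlation
#' matrices, and (2) distances between the experimental matrix `M_e` and
#' random correlation matrices.
#'
#' @param M_e the experimental [correlation_matrix()].
#' @param n_draws number of sampled distances per distribution (>= 100).
#' @param m_eff spread parameter of [random_correlation_matrix()].
#' @param seed optional seed.
#' @return List with elements `random_vs_random` and
#'   `experimental_vs_random`, each of class `null_distance_distribution`
#'   (fields `kind`, `samples`, `seed`).
#' @export
null_distance_distributions <- function(M_e, n_draws = 1000, m_eff = 100,
                                        seed = NULL) {
  if (n_draws < 100) stop_("'n_draws' must be at least 100")
  t <- length(as_corr_labels(M_e))
  with_seed(seed, {
    rr <- vapply(seq_len(n_draws), function(k)
      matrix_distance(random_correlation_matrix(t, m_eff),
                      random_correlation_matrix(t, m_eff)), numeric(1))
    er <- vapply(seq_len(n_draws), function(k)
      matrix_distance(M_e, random_correlation_matrix(
        t, m_eff, labels = as_corr_labels(M_e))), numeric(1))
    list(random_vs_random = structure(
           list(kind = "random-vs-random", samples = rr, seed = seed),
           class = "null_distance_distribution"),
         experimental_vs_random = structure(
           list(kind = "experimental-vs-random", samples = er, seed = seed),
           class = "null_distance_distribution"))
  })
}

as_corr_labels <- function(M)
  if (inherits(M, "correlation_matrix")) M$labels else rownames(as.matrix(M))

#' @export
print.null_distance_distribution <- function(x, ...) {
  cat(sprintf("%s distance null: %d draws, mean %.3f, sd %.3f\n",
              x$kind, length(x$samples), mean(x$samples),
              stats::sd(x$samples)))
  invisible(x)
}

#' Validate a model coexpression matrix against experiment
#'
#' Computes the distance `D = d(M_e, M_m)` between the experimental and
#' model-implied coexpression matrices and locates it within the two
#' random-matrix null distributions.  Percentiles use the `(r + 1)/(n + 1)`
#' convention.  Verdict policy: `D` below the `q`-quantile of the
#' experimental-vs-random null is `"discriminated from random"` (the model
#' is closer to the data than random matrices are); `D` not exceeding the
#' `(1 - q)`-quantile is `"cannot be discarded"`; otherwise `"discard"`.
#'
#' @param M_m model-implied [correlation_matrix()] (e.g. from
#'   [pearson_matrix()] of [mixture_sample()] draws).
#' @param M_e experimental [correlation_matrix()].
#' @param n_draws,m_eff,seed passed to [null_distance_distributions()].
#' @param q tail probability of the verdict thresholds (default 0.05).
#' @return An object of class `grn_validation`: list with `D`, `percentile`
#'   (within each null), `verdict`, `thresholds`, `nulls`, `q`.
#' @export
validate_model <- function(M_m, M_e, n_draws = 1000, m_eff = 100,
                           seed = NULL, q = 0.05) {
  D <- matrix_distance(M_e, M_m)
  nulls <- null_distance_distributions(M_e, n_draws, m_eff, seed)
  pct <- vapply(nulls, function(nd)
    (sum(nd$samples <= D) + 1) / (length(nd$samples) + 1), numeric(1))
  er <- nulls$experimental_vs_random$samples
  lo <- stats::quantile(er, q, names = FALSE)
  hi <- stats::quantile(er, 1 - q, names = FALSE)
  verdict <- if (D <= lo) "discriminated from random"
             else if (D <= hi) "cannot be discarded"
             else "discard"
  structure(list(D = D, percentile = pct, verdict = verdict,
                 thresholds = c(lower = lo, upper = hi), q = q,
                 nulls = nulls),
            class = "grn_validation")
}

#' @export
print.grn_validation <- function(x, ...) {
  cat("Model-vs-experiment coexpression comparison\n")
  cat(sprintf("  distance D = %.4f\n", x$D))
  cat(sprintf("  percentile in random-vs-random null:       %.3f\n",
              x$percentile[["random_vs_random"]]))
  cat(sprintf("  percentile in experimental-vs-random null: %.3f\n",
              x$percentile[["experimental_vs_random"]]))
  cat(sprintf("  verdict (q = %.2f): %s\n", x$q, x$verdict))
  invisible(x)
}

#' Read / write a coexpression matrix as CSV
#'
#' Format: first row and first column hold gene labels; empty cells are
#' missing data and are set to 0.  On read, asymmetry beyond `1e-6` is
#' warned about and resolved by averaging `(M + t(M))/2`; the diagonal is
#' forced to 1.  `gene_order` optionally reorders the matrix to a caller's
#' gene list.
#'
#' @param path CSV file path.
#' @param gene_order optional character vector of labels.
#' @return A [correlation_matrix()].
#' @export
read_coexpression_csv <- function(path, gene_order = NULL) {
  if (!file.exists(path)) stop_(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  M <- as.matrix(df)
  if (nrow(M) != ncol(M)) stop_("coexpression table must be square")
  if (anyDuplicated(rownames(M)) || anyDuplicated(colnames(M)))
    stop_("duplicate gene labels")
  if (!setequal(rownames(M), colnames(M)))
    stop_("row and column labels differ")
  M <- M[, rownames(M)]
  if (anyNA(M)) M[is.na(M)] <- 0  # missing data set to zero
  asym <- max(abs(M - t(M)))
  if (asym > 1e-6)
    warning(sprintf("asymmetry %.3g resolved by averaging", asym),
            call. = FALSE)
  M <- (M + t(M)) / 2
  diag(M) <- 1
  if (!is.null(gene_order)) {
    if (!setequal(gene_order, rownames(M)))
      stop_(sprintf("gene_order does not match file labels; unmatched: %s",
                    paste(union(setdiff(gene_order, rownames(M)),
                                setdiff(rownames(M), gene_order)),
                          collapse = ", ")))
    M <- M[gene_order, gene_order]
  }
  correlation_matrix(M)
}

#' @rdname read_coexpression_csv
#' @param M a [correlation_matrix()].
#' @export
write_coexpression_csv <- function(M, path) {
  v <- as_corr_values(M)
  df <- data.frame(gene = rownames(v), format(v, digits = 15, trim = TRUE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Synthetic coexpression data from a known mixture
#'
#' Emulates the statistical structure the validation step assumes: samples
#' multimodal concentration profiles from a mixture and adds Gaussian
#' measurement noise (truncated at 0), returning both the raw samples and
#' their Pearson coexpression matrix.  Increasing `noise_sd` attenuates the
#' off-diagonal correlations toward 0.
#'
#' @param mix a [gamma_mixture()] (or Gaussian mixture).
#' @param m number of samples (>= 10).
#' @param noise_sd standard deviation of the additive measurement noise.
#' @param seed optional seed.
#' @return List with `samples` (`m x d` matrix) and `correlation`
#'   (a [correlation_matrix()]).
#' @export
synthetic_coexpression <- function(mix, m, noise_sd = 0, seed = NULL) {
  stopifnot(m >= 10)
  with_seed(seed, {
    X <- mixture_sample(mix, m)
    if (noise_sd > 0)
      X <- pmax(X + matrix(stats::rnorm(length(X), 0, noise_sd),
                           nrow(X), ncol(X)), 0)
    list(samples = X, correlation = pearson_matrix(X, mix$genes))
  })
}
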