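#' Translate a Boolean network into a continuous Hill-type ODE model
#'
#' Builds the deterministic model of protein concentrations `p` implied by a
#' Boolean GRN.  Each regulated gene `i` gets a saturating synthesis term
#' (a generalised Hill function of its regulators), a basal synthesis rate
#' `alpha0`, and linear degradation `delta * p_i`:
#'
#' \deqn{dp_i/dt = N_i(p)/D_i(p) + \alpha_{i,0} - \delta_i p_i}
#'
#' with denominator `D_i = 1 + |theta_i| + sum_j |w_ij| p_j^n` over *all*
#' regulators and numerator `N_i = sum_{j in activators} |w_ij| p_j^n`, plus
#' an additive basal numerator term `1 + |theta_i|` when `theta_i <= 0`
#' (a non-positive Boolean threshold marks a gene with basal synthesis).
#' Unregulated genes reduce to `dp_i/dt = alpha0 - delta p_i`.  Interaction
#' magnitudes are `|w_ij|`, with the sign of `w_ij` routing gene `j` to the
#' activator or repressor list.  All rates default to 1 (parsimonious
#' translation: the Boolean model carries no rate information).
#'
#' @param net a [gene_network()].
#' @param alpha0 basal synthesis rate(s), scalar or per-gene vector (>= 0).
#' @param delta degradation rate(s), scalar or per-gene (> 0).
#' @param hill_n Hill exponent(s), scalar or per-gene (>= 1).
#' @return An object of class `grn_model`.
#' @seealso [grn_drift()], [ode_fixed_points()], [fpe_model()]
#' @examples
#' mod <- continuous_model(at_flower_network())
#' grn_drift(mod, rep(0, 12))
#' @export
continuous_model <- function(net, alpha0 = 1, delta = 1, hill_n = 1) {
  stopifnot(inherits(net, "gene_network"))
  n <- length(net$genes)
  alpha0 <- expand_per_gene(alpha0, n, "alpha0")
  delta <- expand_per_gene(delta, n, "delta")
  hill_n <- expand_per_gene(hill_n, n, "hill_n")
  if (any(alpha0 < 0)) stop_("'alpha0' must be nonnegative")
  if (any(delta <= 0)) stop_("'delta' must be strictly positive")
  if (any(hill_n < 1)) stop_("'hill_n' must be >= 1")
  specs <- vector("list", n)
  for (i in seq_len(n)) {
    w <- net$W[i, ]
    act <- which(w > 0)
    rep_ <- which(w < 0)
    specs[[i]] <- list(
      activators = act, act_w = abs(w[act]),
      repressors = rep_, rep_w = abs(w[rep_]),
      theta_abs = abs(net$theta[[i]]),
      basal_numerator = net$theta[[i]] <= 0,
      alpha0 = alpha0[i], delta = delta[i], hill_n = hill_n[i])
  }
  structure(list(genes = net$genes, specs = specs, network = net),
            class = "grn_model")
}

#' @export
print.grn_model <- function(x, ...) {
  n <- length(x$genes)
  reg <- sum(vapply(x$specs, function(s)
    length(s$activators) + length(s$repressors) > 0, logical(1)))
  cat(sprintf("Continuous GRN model: %d genes (%d regulated)\n", n, reg))
  cat(drift_expressions(x), sep = "\n")
  invisible(x)
}

# Evaluate the saturating synthesis term (Hill ratio in [0, 1]) for all genes
# at a matrix of points P (rows = points, cols = genes).  Returns m x n.
hill_matrix <- function(model, P) {
  n <- length(model$genes)
  out <- matrix(0, nrow(P), n)
  for (i in seq_len(n)) {
    s <- model$specs[[i]]
    regs <- c(s$activators, s$repressors)
    if (length(regs) == 0L) next
    wall <- c(s$act_w, s$rep_w)
    Preg <- P[, regs, drop = FALSE] ^ s$hill_n
    den <- 1 + s$theta_abs + drop(Preg %*% wall)
    num <- if (length(s$activators))
      drop(P[, s$activators, drop = FALSE] ^ s$hill_n %*% s$act_w) else 0
    if (s$basal_numerator) num <- num + 1 + s$theta_abs
    out[, i] <- num / den
  }
  out
}

as_point_matrix <- function(p, n) {
  if (is.null(dim(p))) p <- matrix(as.numeric(p), nrow = 1)
  p <- as.matrix(p)
  if (ncol(p) != n)
    stop_(sprintf("points have %d columns but the model has %d genes",
                  ncol(p), n))
  if (any(p < 0)) stop_("concentrations must be nonnegative")
  p
}

# Positive part of the drift: synthesis B_i(p) = Hill_i(p) + alpha0_i.
synthesis_matrix <- function(model, P) {
  B <- hill_matrix(model, P)
  sweep(B, 2, vapply(model$specs, `[[`, numeric(1), "alpha0"), `+`)
}

#' Evaluate the deterministic drift of a continuous GRN model
#'
#' @param model a [continuous_model()].
#' @param p nonnegative concentration vector (or matrix of row-points).
#' @return The drift vector `dp/dt` (or matrix, one row per input point).
#' @export
grn_drift <- function(model, p) {
  stopifnot(inherits(model, "grn_model"))
  P <- as_point_matrix(p, length(model$genes))
  delta <- vapply(model$specs, `[[`, numeric(1), "delta")
  D <- synthesis_matrix(model, P) - sweep(P, 2, delta, `*`)
  if (is.null(dim(p))) drop(D) else D
}

#' Symbolic form of the model equations
#'
#' Returns one parseable R expression string per gene, with all numeric
#' parameters substituted, e.g.
#' `"(2 + 5*p3)/(2 + 1*p1 + 5*p3 + 1*p9) + 1 - 1*p4"`.
#' Useful for eyeballing the translation and for fidelity tests against
#' hand-coded reference equations.
#'
#' @param model a [continuous_model()].
#' @return Character vector of length `N` named by gene.
#' @export
drift_expressions <- function(model) {
  stopifnot(inherits(model, "grn_model"))
  n <- length(model$genes)
  fmt <- function(x) format(x, trim = TRUE, drop0trailing = TRUE)
  term <- function(w, j, hn) {
    pw <- if (hn == 1) sprintf("p%d", j) else sprintf("p%d^%s", j, fmt(hn))
    sprintf("%s*%s", fmt(w), pw)
  }
  out <- character(n)
  for (i in seq_len(n)) {
    s <- model$specs[[i]]
    regs <- c(s$activators, s$repressors)
    base <- sprintf("%s - %s*p%d", fmt(s$alpha0), fmt(s$delta), i)
    if (length(regs) == 0L) {
      out[i] <- base
    } else {
      den <- c(fmt(1 + s$theta_abs),
               mapply(term, c(s$act_w, s$rep_w), regs,
                      MoreArgs = list(hn = s$hill_n)))
      num <- mapply(term, s$act_w, s$activators,
                    MoreArgs = list(hn = s$hill_n))
      if (s$basal_numerator) num <- c(fmt(1 + s$theta_abs), num)
      out[i] <- sprintf("(%s)/(%s) + %s",
                        paste(num, collapse = " + "),
                        paste(den, collapse = " + "), base)
    }
  }
  names(out) <- model$genes
  out
}

#' Map a Boolean state to a concentration starting point
#'
#' Initialization heuristic for root finding and warm starts: an inactive gene
#' maps to concentration 0 and an active gene to its saturated steady level
#' `(1 + alpha0) / delta`.
#'
#' @param state binary vector.
#' @param model a [continuous_model()].
#' @return Nonnegative concentration vector.
#' @export
boolean_to_concentration <- function(state, model) {
  stopifnot(inherits(model, "grn_model"))
  state <- as.numeric(state)
  if (length(state) != length(model$genes))
    stop_("state length does not match the model")
  a0 <- vapply(model$specs, `[[`, numeric(1), "alpha0")
  de <- vapply(model$specs, `[[`, numeric(1), "delta")
  state * (1 + a0) / de
}

#' Locate stable fixed points of the deterministic model
#'
#' From each starting point the ODE is integrated to a settling time and the
#' result polished by damped Newton iterations on the drift; roots with
#' `||drift|| < tol` whose Jacobian has a strictly negative leading eigenvalue
#' (real part) are kept, deduplicated at `dedup_radius` (Euclidean).  Starts
#' that fail to converge are skipped with a message.
#'
#' @param model a [continuous_model()].
#' @param starts matrix of starting points (rows); default maps every Boolean
#'   fixed point of the source network through [boolean_to_concentration()].
#' @param tol residual norm below which a point counts as a root.
#' @param dedup_radius radius for merging duplicate roots.
#' @param t_settle ODE integration horizon before polishing.
#' @return Matrix of stable fixed points (possibly zero rows), columns named
#'   by gene, with attribute `"n_failed"` counting skipped starts.
#' @export
ode_fixed_points <- function(model, starts = NULL, tol = 1e-8,
                             dedup_radius = 1e-3, t_settle = 50) {
  stopifnot(inherits(model, "grn_model"))
  n <- length(model$genes)
  if (is.null(starts)) {
    bf <- boolean_fixed_points(model$network)
    starts <- t(apply(bf, 1, boolean_to_concentration, model = model))
    if (nrow(bf) == 0L) starts <- matrix(1, 1, n)
  }
  starts <- as_point_matrix(starts, n)
  f <- function(p) grn_drift(model, pmax(p, 0))
  rhs <- function(t, y, parms) list(f(y))
  roots <- NULL
  n_failed <- 0L
  for (k in seq_len(nrow(starts))) {
    y <- deSolve::ode(starts[k, ], c(0, t_settle), rhs, NULL,
                      method = "lsoda")
    p <- pmax(as.numeric(y[nrow(y), -1]), 0)
    ok <- FALSE
    for (it in 1:50) {  # damped Newton polish
      g <- f(p)
      if (sqrt(sum(g^2)) < tol) { ok <- TRUE; break }
      J <- pracma::jacobian(f, p)
      step <- tryCatch(solve(J, -g), error = function(e) NULL)
      if (is.null(step)) break
      lam <- 1
      repeat {
        pn <- pmax(p + lam * step, 0)
        if (sum(f(pn)^2) < sum(g^2) || lam < 1e-6) break
        lam <- lam / 2
      }
      p <- pn
    }
    if (!ok) {
      n_failed <- n_failed + 1L
      message(sprintf("start %d did not converge; skipped", k))
      next
    }
    ev <- eigen(pracma::jacobian(f, p), only.values = TRUE)$values
    if (max(Re(ev)) >= 0) next  # not locally stable
    if (!is.null(roots) &&
        any(sqrt(rowSums(sweep(roots, 2, p)^2)) < dedup_radius)) next
    roots <- rbind(roots, p)
  }
  if (is.null(roots)) roots <- matrix(numeric(0), 0, n)
  dimnames(roots) <- list(NULL, model$genes)
  structure(roots, n_failed = n_failed)
}
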