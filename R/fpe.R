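#' Stochastic (chemical Langevin / Fokker-Planck) model of a GRN
#'
#' Wraps a [continuous_model()] together with a system size `Omega` into the
#' chemical Langevin equation
#' \deqn{dp_i = (B_i(p) - \delta_i p_i)\,dt
#'       + \sqrt{(B_i(p) + \delta_i p_i)/\Omega}\; dW_i}
#' (Ito interpretation, independent Brownian increments per coordinate),
#' where `B_i` is the positive synthesis part of the drift.  The associated
#' Fokker-Planck equation has drift field `B_i - delta_i p_i` and *diagonal*
#' diffusion `Gamma_i = (B_i + delta_i p_i) / Omega`; large `Omega` recovers
#' the deterministic ODE.
#'
#' @param model a [continuous_model()].
#' @param omega system size (> 0); controls fluctuation magnitude.
#' @return An object of class `fpe_model`.
#' @seealso [drift_field()], [diffusion_field()], [simulate_langevin()],
#'   [fit_stationary()]
#' @export
fpe_model <- function(model, omega = 1) {
  stopifnot(inherits(model, "grn_model"))
  check_scalar(omega, "omega", 0, strict = TRUE)
  structure(list(model = model, omega = omega, genes = model$genes,
                 d = length(model$genes)),
            class = "fpe_model")
}

#' @export
print.fpe_model <- function(x, ...) {
  cat(sprintf("Fokker-Planck model: %d genes, system size Omega = %g\n",
              x$d, x$omega))
  invisible(x)
}

#' A Fokker-Planck model with user-supplied fields
#'
#' Builds an `fpe_model`-compatible object directly from drift and diffusion
#' functions instead of a GRN.  Intended for synthetic test problems whose
#' stationary density is known in closed form (e.g. a zero-flux construction
#' around a chosen mixture, or an Ornstein-Uhlenbeck process for the grid
#' oracle).
#'
#' @param drift function mapping an `m x d` point matrix to an `m x d` drift
#'   matrix.
#' @param diffusion like `drift`, returning the per-coordinate diffusion
#'   coefficients `Gamma_j >= 0`.
#' @param d state dimension.
#' @param genes optional coordinate names.
#' @return An object of class `c("fpe_custom", "fpe_model")`.
#' @export
fpe_custom <- function(drift, diffusion, d, genes = paste0("g", seq_len(d))) {
  stopifnot(is.function(drift), is.function(diffusion))
  structure(list(drift_fn = drift, diffusion_fn = diffusion,
                 d = as.integer(d), genes = genes, omega = NA_real_),
            class = c("fpe_custom", "fpe_model"))
}

#' Drift and diffusion fields of a Fokker-Planck model
#'
#' `drift_field` evaluates `B_j(p) - delta_j p_j` (identical to
#' [grn_drift()]); `diffusion_field` evaluates
#' `Gamma_j(p) = (B_j(p) + delta_j p_j) / Omega`, which is nonnegative
#' wherever the drift is defined and scales as `1/Omega`.
#'
#' @param fpe an [fpe_model()] or [fpe_custom()].
#' @param p nonnegative point vector or matrix of row-points.
#' @return Vector (or matrix) of per-coordinate field values.
#' @export
drift_field <- function(fpe, p) UseMethod("drift_field")

#' @export
drift_field.fpe_model <- function(fpe, p) grn_drift(fpe$model, p)

#' @export
drift_field.fpe_custom <- function(fpe, p) {
  P <- if (is.null(dim(p))) matrix(as.numeric(p), 1) else as.matrix(p)
  out <- fpe$drift_fn(P)
  if (is.null(dim(p))) drop(out) else out
}

#' @rdname drift_field
#' @export
diffusion_field <- function(fpe, p) UseMethod("diffusion_field")

#' @export
diffusion_field.fpe_model <- function(fpe, p) {
  P <- as_point_matrix(p, fpe$d)
  delta <- vapply(fpe$model$specs, `[[`, numeric(1), "delta")
  G <- (synthesis_matrix(fpe$model, P) + sweep(P, 2, delta, `*`)) / fpe$omega
  if (is.null(dim(p))) drop(G) else G
}

#' @export
diffusion_field.fpe_custom <- function(fpe, p) {
  P <- if (is.null(dim(p))) matrix(as.numeric(p), 1) else as.matrix(p)
  out <- fpe$diffusion_fn(P)
  if (is.null(dim(p))) drop(out) else out
}

#' Simulate sample paths by Euler-Maruyama
#'
#' Integrates the chemical Langevin equation with fixed step `dt` and
#' independent standard Gaussian increments per coordinate, scaled by
#' `sqrt(Gamma_j dt)` (Ito).  Nonnegativity is preserved by reflecting any
#' negative proposal at 0 (`p <- |p|`).  Multiple independent replicate
#' trajectories can be run in parallel from the same initial point; the whole
#' simulation is reproducible from `seed`.
#'
#' @param fpe an [fpe_model()].
#' @param p0 nonnegative initial state.
#' @param dt time step (> 0, < `t_end`).
#' @param t_end final time.
#' @param seed integer RNG seed (optional).
#' @param n_rep number of independent replicate paths.
#' @param thin record every `thin`-th step (the initial state is always
#'   recorded).
#' @return An object of class `grn_trajectory`: list with `times` (length T),
#'   `states` (T x d matrix; for `n_rep > 1` a T x d x n_rep array), `seed`.
#' @export
simulate_langevin <- function(fpe, p0, dt, t_end, seed = NULL, n_rep = 1L,
                              thin = 1L) {
  stopifnot(inherits(fpe, "fpe_model"))
  check_scalar(dt, "dt", 0, strict = TRUE)
  if (dt >= t_end) stop_("'dt' must be smaller than 't_end'")
  d <- fpe$d
  p0 <- as.numeric(p0)
  if (length(p0) != d) stop_("'p0' length does not match the model")
  if (any(p0 < 0)) stop_("'p0' must be nonnegative")
  n_steps <- floor(t_end / dt)
  keep <- seq(0, n_steps, by = thin)
  with_seed(seed, {
    P <- matrix(rep(p0, each = n_rep), n_rep, d)
    states <- array(NA_real_, c(length(keep), d, n_rep))
    states[1, , ] <- t(P)
    ki <- 2L
    for (s in seq_len(n_steps)) {
      A <- drift_field(fpe, P)
      G <- diffusion_field(fpe, P)
      if (is.null(dim(A))) { A <- matrix(A, 1); G <- matrix(G, 1) }
      P <- P + A * dt +
        sqrt(pmax(G, 0) * dt) * matrix(stats::rnorm(n_rep * d), n_rep, d)
      P <- abs(P)  # reflect at 0
      if (ki <= length(keep) && s == keep[ki]) {
        states[ki, , ] <- t(P)
        ki <- ki + 1L
      }
    }
    out <- list(times = keep * dt,
                states = if (n_rep == 1L) states[, , 1, drop = TRUE]
                         else states,
                genes = fpe$genes, seed = seed)
    if (d == 1L && n_rep == 1L) out$states <- matrix(out$states, ncol = 1)
    class(out) <- "grn_trajectory"
    out
  })
}

#' @export
print.grn_trajectory <- function(x, ...) {
  dms <- dim(x$states)
  cat(sprintf("Langevin trajectory: %d time points, %d genes%s\n",
              length(x$times), dms[2],
              if (length(dms) == 3) sprintf(", %d replicates", dms[3]) else ""))
  invisible(x)
}

#' @export
as.data.frame.grn_trajectory <- function(x, ...) {
  st <- if (length(dim(x$states)) == 3) x$states[, , 1] else x$states
  df <- data.frame(time = x$times, st)
  names(df) <- c("time", x$genes)
  df
}

#' Write a trajectory to CSV
#'
#' Header `time,gene1,...,geneN`; for replicated simulations only the first
#' replicate is written.
#'
#' @param traj a [simulate_langevin()] result.
#' @param path output file.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "grn_trajectory"))
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}
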