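#' Control parameters for the stationary-density fit
#'
#' Tuning knobs for the three-stage weighted-residual fit.  The defaults are
#' desk-scale: `n_points` collocation points per objective evaluation (the
#' full-scale protocol uses `1e6`), with fresh points drawn for every
#' optimization step and a fixed validation set used for stopping and
#' best-iterate selection.
#'
#' @param n_points collocation points per objective evaluation.
#' @param p_max domain box upper bound(s), `[0, p_max]` per gene.
#' @param sampling `"uniform"` (default, unbiased) or `"proxy"` importance
#'   sampling from the current proxy.
#' @param stage1_trials global-search trial budget.
#' @param stage2_steps,stage3_steps Adam iteration caps.
#' @param lr Adam learning rate (stages 2-3).
#' @param fd_h central-difference step for parameter gradients, taken in the
#'   unconstrained (log/logit) parameterization.
#' @param val_points,val_every size of the fixed validation collocation set
#'   and the step interval at which it is evaluated.
#' @param tol,patience stop when the relative improvement of the best
#'   validation residual stays below `tol` for `patience` consecutive
#'   validation evaluations.
#' @param target stop early once the validation mean `|R|` per point falls
#'   below this level.
#' @param anchor_radius when the fit is warm-started at located attractors,
#'   stage-1 candidates and stage-2 mean updates are confined to a box of
#'   this half-width (as a fraction of the largest domain span) around each
#'   component's anchor, and stage-2 variances to a window around the
#'   small-noise (Ornstein-Uhlenbeck) estimate.  The Gaussian-proxy stages
#'   refine the position and spread of each attractor region locally;
#'   without the trust region the residual objective can prefer parking a
#'   mis-shaped proxy component in a flat low-density region over sitting
#'   at a sharp well (the residual is linear in the density, so vacating a
#'   basin costs nothing, while a Gaussian can never match a skewed gamma
#'   well exactly).  Stage-3 fine-tuning keeps each component's mode inside
#'   the same trust region for the same reason; shapes and spreads are
#'   otherwise free.
#' @param fit_weights optimize the component weights (default `FALSE`)?
#'   The stationary residual is linear in the density, so the mass
#'   allocation across well-separated attractor basins is nearly
#'   unidentifiable from the collocation objective; by default the weights
#'   stay at their initialized values (uniform unless supplied) and only
#'   locations and shapes are optimized.
#' @param box_penalty weight of the domain-confinement penalty added to
#'   the fitted objective: `lambda * (1 - mass of the trial density inside
#'   the box)`.  Minimizing the residual integral over a fixed box alone is
#'   degenerate (densities displaced outside the box have vanishing residual
#'   on it); the penalty is zero for any solution contained in the box and
#'   does not enter reported residuals.
#' @param seed master seed for the whole fit.
#' @return A list of class `fit_control`.
#' @export
fit_control <- function(n_points = 1e4, p_max = 10, sampling = "uniform",
                        stage1_trials = 60, stage2_steps = 200,
                        stage3_steps = 300, lr = 0.05, fd_h = 1e-3,
                        val_points = 4000, val_every = 5, tol = 1e-3,
                        patience = 50, target = 1e-6, anchor_radius = 0.05,
                        fit_weights = FALSE, box_penalty = 1, seed = 1L) {
  structure(list(n_points = as.integer(n_points), p_max = p_max,
                 sampling = sampling, stage1_trials = as.integer(stage1_trials),
                 stage2_steps = as.integer(stage2_steps),
                 stage3_steps = as.integer(stage3_steps), lr = lr,
                 fd_h = fd_h, val_points = as.integer(val_points),
                 val_every = as.integer(val_every), tol = tol,
                 patience = as.integer(patience), target = target,
                 anchor_radius = anchor_radius, fit_weights = fit_weights,
                 box_penalty = box_penalty, seed = seed),
            class = "fit_control")
}

## ---- fast residual objective --------------------------------------------
## The objective is J(theta) = mean |R(p_k)| over a collocation point set.
## R is linear in the mixture density, and each component factorizes over
## genes, so perturbing one parameter of one component only changes that
## component's column-j quantities; the finite-difference gradient exploits
## this and costs O(m) per parameter instead of a full re-evaluation.

prepare_point_cache <- function(fpe, P, upper, lambda = 1) {
  list(P = P, lnP = log(P), invP = 1 / P, invP2 = 1 / P^2,
       coefs = residual_coefficients(fpe, P), m = nrow(P), d = ncol(P),
       upper = upper, lambda = lambda)
}

# Probability mass a component keeps inside [0, upper_j] along gene j.
# The objective penalizes mass leaving the domain box: minimizing the
# residual integral over a fixed box alone is degenerate (any density
# displaced far outside the box has residual ~ 0 on it), whereas the ansatz
# is meant to be the stationary law *on* the domain containing all
# attractors.  The penalty vanishes for any well-contained solution.
mass_column <- function(type, p1, p2, upper_j) {
  if (type == "gamma") stats::pgamma(upper_j, p1, p2)
  else stats::pnorm(upper_j, p1, sqrt(p2)) - stats::pnorm(0, p1, sqrt(p2))
}

# Column j quantities (log-density contribution Lc and residual term Tc)
# for one component.  type "gamma": p1 = shape, p2 = rate;
# type "gaussian": p1 = mean, p2 = variance.
comp_column <- function(type, p1, p2, j, cache) {
  Pj <- cache$P[, j]
  c0 <- cache$coefs$c0[, j]; c1 <- cache$coefs$c1[, j]
  c2 <- cache$coefs$c2[, j]
  if (type == "gamma") {
    Lc <- (p1 - 1) * cache$lnP[, j] - p2 * Pj + p1 * log(p2) - lgamma(p1)
    u <- (p1 - 1) * cache$invP[, j] - p2
    Tc <- c0 + c1 * u + c2 * (u * u - (p1 - 1) * cache$invP2[, j])
  } else {
    Lc <- -0.5 * (log(2 * pi * p2) + (Pj - p1)^2 / p2)
    u <- -(Pj - p1) / p2
    Tc <- c0 + c1 * u + c2 * (u * u - 1 / p2)
  }
  list(Lc = Lc, Tc = Tc)
}

build_component <- function(type, p1, p2, cache) {
  L <- Tm <- matrix(NA_real_, cache$m, cache$d)
  Fcol <- numeric(cache$d)
  for (j in seq_len(cache$d)) {
    cc <- comp_column(type, p1[j], p2[j], j, cache)
    L[, j] <- cc$Lc
    Tm[, j] <- cc$Tc
    Fcol[j] <- mass_column(type, p1[j], p2[j], cache$upper[j])
  }
  logPi <- rowSums(L)
  S <- rowSums(Tm)
  list(L = L, T = Tm, logPi = logPi, S = S, PS = exp(logPi) * S,
       Fcol = Fcol, mass = prod(Fcol))
}

softmax <- function(z) { e <- exp(z - max(z)); e / sum(e) }

# Packed parameter vector: c(weight logits, log/linear p1 (n*d), log p2 (n*d)).
pack_params <- function(type, weights, P1, P2) {
  n <- length(weights)
  c(log(pmax(weights, 1e-12)),
    if (type == "gamma") as.numeric(log(P1)) else as.numeric(P1),
    as.numeric(log(P2)))
}

unpack_params <- function(type, par, n, d) {
  A <- softmax(par[seq_len(n)])
  P1 <- matrix(par[n + seq_len(n * d)], n, d)
  if (type == "gamma") P1 <- exp(P1)
  P2 <- matrix(exp(par[n + n * d + seq_len(n * d)]), n, d)
  list(A = A, P1 = P1, P2 = P2)
}

objective_state <- function(type, par, n, d, cache) {
  th <- unpack_params(type, par, n, d)
  comps <- vector("list", n)
  PS <- matrix(NA_real_, cache$m, n)
  mass <- numeric(n)
  for (i in seq_len(n)) {
    comps[[i]] <- build_component(type, th$P1[i, ], th$P2[i, ], cache)
    PS[, i] <- comps[[i]]$PS
    mass[i] <- comps[[i]]$mass
  }
  R <- drop(PS %*% th$A)
  Jres <- mean(abs(R))
  list(J = Jres + cache$lambda * (1 - sum(th$A * mass)), Jres = Jres,
       R = R, comps = comps, PS = PS, mass = mass, theta = th)
}

objective_value <- function(type, par, n, d, cache)
  objective_state(type, par, n, d, cache)$J

# Central-difference gradient of J in the packed parameterization, using
# incremental single-column updates of the perturbed component.
objective_gradient <- function(type, par, n, d, cache, state, h,
                               fit_weights = FALSE) {
  grad <- numeric(length(par))
  A <- state$theta$A
  lam <- cache$lambda
  # weight logits: only the mixing proportions change
  if (fit_weights) for (k in seq_len(n)) {
    Jpm <- vapply(c(h, -h), function(dh) {
      z <- par[seq_len(n)]; z[k] <- z[k] + dh
      Ap <- softmax(z)
      mean(abs(drop(state$PS %*% Ap))) + lam * (1 - sum(Ap * state$mass))
    }, numeric(1))
    grad[k] <- (Jpm[1] - Jpm[2]) / (2 * h)
  }
  base_contrib <- sweep(state$PS, 2, A, `*`)  # m x n, A_i * P_i * S_i
  Rbase <- state$R
  perturbed_J <- function(i, j, block, dh) {
    idx <- n + (block - 1L) * n * d + (j - 1L) * n + i
    v <- par[idx] + dh
    th <- state$theta
    p1 <- th$P1[i, j]; p2 <- th$P2[i, j]
    if (block == 1L) p1 <- if (type == "gamma") exp(v) else v
    else p2 <- exp(v)
    cc <- comp_column(type, p1, p2, j, cache)
    comp <- state$comps[[i]]
    logPi <- comp$logPi - comp$L[, j] + cc$Lc
    S <- comp$S - comp$T[, j] + cc$Tc
    Rp <- Rbase - base_contrib[, i] + A[i] * exp(logPi) * S
    Fj <- mass_column(type, p1, p2, cache$upper[j])
    mass_i <- comp$mass / max(comp$Fcol[j], 1e-300) * Fj
    mean(abs(Rp)) +
      lam * (1 - sum(A * state$mass) + A[i] * (state$mass[i] - mass_i))
  }
  for (block in 1:2) for (j in seq_len(d)) for (i in seq_len(n)) {
    idx <- n + (block - 1L) * n * d + (j - 1L) * n + i
    grad[idx] <- (perturbed_J(i, j, block, h) -
                  perturbed_J(i, j, block, -h)) / (2 * h)
  }
  grad
}

# Clamp packed parameters to numerically safe ranges; Gaussian means are
# additionally confined to [mean_lo, mean_hi] (the anchor trust region).
clamp_params <- function(type, par, n, d, upper,
                         mean_lo = NULL, mean_hi = NULL, ls2_ref = NULL) {
  i1 <- n + seq_len(n * d)
  i2 <- n + n * d + seq_len(n * d)
  par[seq_len(n)] <- pmin(pmax(par[seq_len(n)], -30), 30)
  if (type == "gamma") {
    par[i1] <- pmin(pmax(par[i1], log(1e-3)), log(1e4))   # shapes
    par[i2] <- pmin(pmax(par[i2], log(1e-3)), log(1e4))   # rates
    if (!is.null(mean_lo)) {
      # anchored fine-tuning: project the implied mode (alpha-1)/beta
      # back into the trust region, adjusting the shape at fixed rate
      al <- exp(par[i1]); be <- exp(par[i2])
      mode <- pmax(al - 1, 0) / be
      tgt <- pmin(pmax(mode, pmax(as.numeric(mean_lo), 1e-3)),
                  as.numeric(mean_hi))
      adj <- tgt != mode
      if (any(adj)) par[i1][adj] <- log(1 + tgt[adj] * be[adj])
    }
  } else {
    ub <- rep(rep(upper, length.out = d), each = n)
    lo <- if (is.null(mean_lo)) 0 else pmax(as.numeric(mean_lo), 0)
    hi <- if (is.null(mean_hi)) ub else pmin(as.numeric(mean_hi), ub)
    par[i1] <- pmin(pmax(par[i1], lo), hi)                 # means
    lo2 <- 2 * log(1e-3); hi2 <- 2 * log(max(ub))
    if (!is.null(ls2_ref)) {                               # anchored window
      lo2 <- pmax(ls2_ref - log(6), lo2)
      hi2 <- pmin(ls2_ref + log(6), hi2)
    }
    par[i2] <- pmin(pmax(par[i2], lo2), hi2)               # variances
  }
  par
}

## ---- Adam with fixed-validation stopping --------------------------------

adam_minimize <- function(type, par, n, d, fpe, control, stage_label,
                          anchors = NULL, s2_ref = NULL) {
  steps <- if (type == "gamma") control$stage3_steps else control$stage2_steps
  upper <- rep(control$p_max, length.out = d)
  mean_lo <- mean_hi <- ls2_ref <- NULL
  if (!is.null(anchors)) {
    r <- control$anchor_radius * max(upper)
    mean_lo <- anchors - r
    mean_hi <- anchors + r
    if (!is.null(s2_ref) && type == "gaussian")
      ls2_ref <- log(as.numeric(s2_ref))
  }
  val_cache <- prepare_point_cache(fpe, draw_collocation_points(
    collocation_config(control$val_points, control$p_max), d),
    upper, control$box_penalty)
  par <- clamp_params(type, par, n, d, upper, mean_lo, mean_hi, ls2_ref)
  best_par <- par
  best_state <- objective_state(type, par, n, d, val_cache)
  best_val <- best_state$J
  best_res <- best_state$Jres
  if (!is.finite(best_val)) stop_(sprintf(
    "%s: residual not finite at the initial parameters", stage_label))
  trace <- data.frame(step = 0L, train = NA_real_, val = best_val)
  if (steps == 0L || control$lr == 0)
    return(list(par = best_par, val = best_val, mean_abs = best_res,
                trace = trace))
  mom <- vel <- numeric(length(par))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  stall <- 0L
  prev_best <- best_val
  for (s in seq_len(steps)) {
    cache <- prepare_point_cache(fpe, draw_collocation_points(
      collocation_config(control$n_points, control$p_max,
                         control$sampling), d),
      upper, control$box_penalty)
    st <- objective_state(type, par, n, d, cache)
    if (!is.finite(st$J)) stop_(sprintf(
      "%s: residual diverged (NaN) at iteration %d", stage_label, s))
    g <- objective_gradient(type, par, n, d, cache, st, control$fd_h,
                            isTRUE(control$fit_weights))
    mom <- b1 * mom + (1 - b1) * g
    vel <- b2 * vel + (1 - b2) * g^2
    mhat <- mom / (1 - b1^s); vhat <- vel / (1 - b2^s)
    lr_s <- control$lr / (1 + 4 * s / steps)  # decay to lr/5
    par <- clamp_params(type, par - lr_s * mhat / (sqrt(vhat) + eps),
                        n, d, upper, mean_lo, mean_hi, ls2_ref)
    if (s %% control$val_every == 0L || s == steps) {
      vs <- objective_state(type, par, n, d, val_cache)
      v <- vs$J
      trace <- rbind(trace, data.frame(step = s, train = st$J, val = v))
      if (is.finite(v) && v < best_val) {
        best_val <- v; best_par <- par; best_res <- vs$Jres
      }
      if (best_res <= control$target) break
      if (prev_best - best_val < control$tol * abs(prev_best)) {
        stall <- stall + 1L
        if (stall >= control$patience) break
      } else stall <- 0L
      prev_best <- best_val
    }
  }
  list(par = best_par, val = best_val, mean_abs = best_res, trace = trace)
}

## ---- the three fitting stages -------------------------------------------

#' Stage 1: global Monte Carlo search with a Gaussian proxy
#'
#' Samples `budget` candidate Gaussian mixtures (random means in the domain
#' box and log-uniform spreads; after the first half, candidates are
#' perturbations of the best-so-far, a simple sequential model-free
#' refinement) and returns the candidate with the smallest collocation
#' residual norm, all candidates being scored on one common point set.
#' Optional `init_means` (e.g. Boolean attractors mapped to concentrations)
#' are injected as additional first candidates.
#'
#' @param fpe an [fpe_model()] or [fpe_custom()].
#' @param n_components number of mixture components (>= 1).
#' @param budget number of candidate evaluations (> 0).
#' @param seed optional seed (omit when called inside [fit_stationary()]).
#' @param control a [fit_control()].
#' @param init_means optional `n_components x d` matrix of warm-start means.
#' @return The best [gaussian_mixture()] found; its scored residual norm is
#'   attached as attribute `"objective"`.
#' @export
fit_stage1_global <- function(fpe, n_components, budget = 60, seed = NULL,
                              control = fit_control(), init_means = NULL) {
  stopifnot(n_components >= 1)
  if (budget < 1) stop_("stage-1 trial budget must be positive")
  d <- fpe$d
  n <- as.integer(n_components)
  upper <- rep(control$p_max, length.out = d)
  with_seed(seed, {
    cache <- prepare_point_cache(fpe, draw_collocation_points(
      collocation_config(control$n_points, control$p_max), d),
      upper, control$box_penalty)
    span <- max(upper)
    random_candidate <- function() {
      mu <- matrix(stats::runif(n * d, 0, rep(upper, each = n)), n, d)
      sd_ <- matrix(exp(stats::runif(n * d, log(0.02 * span),
                                     log(0.3 * span))), n, d)
      list(w = rep(1 / n, n), mu = mu, s2 = sd_^2)
    }
    perturb <- function(cand) {
      mu <- pmin(pmax(cand$mu + stats::rnorm(n * d, 0, 0.05 * span), 0),
                 rep(upper, each = n))
      s2 <- cand$s2 * exp(stats::rnorm(n * d, 0, 0.3))
      list(w = cand$w, mu = matrix(mu, n, d), s2 = matrix(s2, n, d))
    }
    score <- function(cand) {
      par <- pack_params("gaussian", cand$w, cand$mu, cand$s2)
      objective_value("gaussian", par, n, d, cache)
    }
    best <- NULL; best_J <- Inf
    cands <- list()
    anchors <- NULL
    if (!is.null(init_means)) {
      im <- as_param_matrix(init_means)
      rows <- rep_len(seq_len(nrow(im)), n)
      anchors <- im[rows, , drop = FALSE] + 1e-3
      if (anyDuplicated(rows))  # fewer warm starts than components: jitter
        anchors <- anchors + matrix(stats::runif(n * d, 0, 0.05 * span), n, d)
      anchors <- pmin(anchors, rep(upper, each = n))
      r <- control$anchor_radius * span
      # leading candidate: small-noise (per-coordinate OU) spread estimate
      # sigma_j^2 = Gamma_j(p*) / (2 |da_j/dp_j|(p*)) at each anchor
      s2_ou <- matrix(NA_real_, n, d)
      for (i in seq_len(n)) {
        p0 <- pmax(anchors[i, ], 1e-6)
        hj <- pmax(1e-4, 1e-4 * p0)
        Gam <- diffusion_field(fpe, matrix(p0, 1))[1, ]
        dja <- numeric(d)
        for (j in seq_len(d)) {
          pp <- pm <- p0
          pp[j] <- p0[j] + hj[j]; pm[j] <- max(p0[j] - hj[j], 0)
          dja[j] <- (drift_field(fpe, matrix(pp, 1))[1, j] -
                     drift_field(fpe, matrix(pm, 1))[1, j]) / (pp[j] - pm[j])
        }
        s2_ou[i, ] <- pmin(pmax(Gam / (2 * pmax(abs(dja), 1e-6)), 1e-4),
                           (0.3 * span)^2)
      }
      # anchored search: OU-matched candidate, a fixed spread ladder, then
      # random local jitter of means (within the trust region) and spreads
      cands <- c(list(list(w = rep(1 / n, n), mu = anchors, s2 = s2_ou)),
                 lapply(c(0.03, 0.08, 0.15, 0.25), function(fr)
                   list(w = rep(1 / n, n), mu = anchors,
                        s2 = matrix((fr * span)^2, n, d))))
      anchored_candidate <- function() {
        mu <- anchors + matrix(stats::runif(n * d, -r, r), n, d)
        mu <- pmin(pmax(mu, 0), rep(upper, each = n))
        sd_ <- matrix(exp(stats::runif(n * d, log(0.02 * span),
                                       log(0.3 * span))), n, d)
        list(w = rep(1 / n, n), mu = mu, s2 = sd_^2)
      }
      random_candidate <- anchored_candidate
    }
    n_random <- ceiling(budget / 2)
    for (t in seq_len(budget)) {
      cand <- if (t <= length(cands)) cands[[t]]
        else if (t <= length(cands) + n_random || is.null(best))
          random_candidate()
        else perturb(best)
      J <- score(cand)
      if (is.finite(J) && J < best_J) { best_J <- J; best <- cand }
    }
    structure(gaussian_mixture(best$w, best$mu, best$s2, fpe$genes),
              objective = best_J, anchors = anchors,
              s2_ref = if (is.null(anchors)) NULL else s2_ou)
  })
}

#' Stage 2: gradient refinement of the Gaussian proxy
#'
#' Adam descent on the collocation residual norm over the proxy's means,
#' variances and weights (unconstrained log/logit parameterization,
#' central-difference gradients).  Collocation points are redrawn at every
#' step; a fixed validation set selects the best iterate, so the returned
#' proxy's validation residual never exceeds the entry value.
#'
#' @inheritParams fit_stage1_global
#' @param proxy the [gaussian_mixture()] to refine.
#' @return The refined [gaussian_mixture()], with attributes `"trace"`
#'   (data frame of train/validation residuals) and `"objective"` (best
#'   validation mean `|R|`).
#' @export
fit_stage2_refine <- function(fpe, proxy, control = fit_control(),
                              seed = NULL) {
  stopifnot(inherits(proxy, "gaussian_mixture"))
  n <- length(proxy$weights); d <- mixture_dim(proxy)
  with_seed(seed, {
    par <- pack_params("gaussian", proxy$weights, proxy$means,
                       proxy$variances)
    res <- adam_minimize("gaussian", par, n, d, fpe, control, "stage 2",
                         anchors = attr(proxy, "anchors"),
                         s2_ref = attr(proxy, "s2_ref"))
    th <- unpack_params("gaussian", res$par, n, d)
    structure(gaussian_mixture(th$A, th$P1, th$P2, proxy$genes),
              trace = res$trace, objective = res$mean_abs,
              anchors = attr(proxy, "anchors"),
              s2_ref = attr(proxy, "s2_ref"))
  })
}

#' Initialize gamma parameters from a Gaussian proxy by moment matching
#'
#' Each gamma factor is chosen so that its mode equals the proxy mean and
#' its variance equals the proxy variance: with mode `m` and variance `v`,
#' `beta = (m + sqrt(m^2 + 4 v)) / (2 v)` and `alpha = 1 + m * beta`, which
#' satisfies both `(alpha - 1)/beta = m` and `alpha/beta^2 = v` exactly.
#' Proxy means at or below `mode_floor` are clamped to `mode_floor` (gamma
#' support is positive).
#'
#' @param proxy a [gaussian_mixture()].
#' @param mode_floor smallest admissible mode (default `1e-3`).
#' @return A [gamma_mixture()] with the proxy's weights.
#' @export
gamma_init_from_proxy <- function(proxy, mode_floor = 1e-3) {
  stopifnot(inherits(proxy, "gaussian_mixture"))
  m0 <- pmax(proxy$means, mode_floor)
  v <- proxy$variances
  beta <- (m0 + sqrt(m0^2 + 4 * v)) / (2 * v)
  alpha <- 1 + m0 * beta
  gamma_mixture(proxy$weights, alpha, beta, proxy$genes)
}

#' Stage 3: gamma-mixture fine-tuning
#'
#' Initializes the gamma mixture from the refined Gaussian proxy by moment
#' matching ([gamma_init_from_proxy()]) and fine-tunes shapes, rates and
#' weights by Adam on the collocation residual norm, stopping when the
#' validation residual shows no significant decrease (or hits the target
#' level).
#'
#' @inheritParams fit_stage2_refine
#' @return A list with elements `mixture` (the fitted [gamma_mixture()]),
#'   `init` (the moment-matched starting mixture), `trace`, and
#'   `mean_abs_residual` (validation mean `|R|` per collocation point of the
#'   returned mixture).
#' @export
fit_stage3_gamma <- function(fpe, proxy, control = fit_control(),
                             seed = NULL) {
  stopifnot(inherits(proxy, "gaussian_mixture"))
  n <- length(proxy$weights); d <- mixture_dim(proxy)
  with_seed(seed, {
    init <- gamma_init_from_proxy(proxy)
    par <- pack_params("gamma", init$weights, init$shapes, init$rates)
    res <- adam_minimize("gamma", par, n, d, fpe, control, "stage 3",
                         anchors = attr(proxy, "anchors"))
    th <- unpack_params("gamma", res$par, n, d)
    list(mixture = gamma_mixture(th$A, th$P1, th$P2, proxy$genes),
         init = init, trace = res$trace, mean_abs_residual = res$mean_abs)
  })
}

#' Locate deterministic attractors of a Fokker-Planck model's drift field
#'
#' Integrates `dp/dt = drift(p)` from a set of starting points (the Boolean
#' fixed points mapped to concentrations for GRN models, plus random points
#' in the box) and polishes and deduplicates the settled states.  Used to
#' seed the mixture components: one per attractor region, which the
#' residual objective alone cannot be relied on to discover (a density
#' missing an attractor basin has a near-zero residual there).
#'
#' @param fpe an [fpe_model()] or [fpe_custom()].
#' @param p_max domain upper bound(s) for the random starts.
#' @param n_starts number of random starts added to any structural ones.
#' @param seed optional seed.
#' @param t_settle integration horizon.
#' @param dedup_radius merge radius for distinct attractors.
#' @return Matrix with one attractor per row.
#' @export
fpe_attractors <- function(fpe, p_max = 10, n_starts = 20, seed = NULL,
                           t_settle = 100, dedup_radius = 0.05) {
  d <- fpe$d
  upper <- rep(p_max, length.out = d)
  with_seed(seed, {
    starts <- matrix(stats::runif(n_starts * d), n_starts, d)
    starts <- sweep(starts, 2, upper, `*`)
    if (!inherits(fpe, "fpe_custom")) {
      bf <- boolean_fixed_points(fpe$model$network)
      if (nrow(bf) > 0)
        starts <- rbind(t(apply(bf, 1, boolean_to_concentration,
                                model = fpe$model)), starts)
    }
    f <- function(p) drift_field(fpe, matrix(pmax(p, 0), 1))[1, ]
    rhs <- function(t, y, parms) list(f(y))
    roots <- NULL
    for (k in seq_len(nrow(starts))) {
      y <- tryCatch(deSolve::ode(starts[k, ], c(0, t_settle), rhs, NULL),
                    error = function(e) NULL)
      if (is.null(y)) next
      p <- pmax(as.numeric(y[nrow(y), -1]), 0)
      if (any(!is.finite(p)) || sqrt(sum(f(p)^2)) > 1e-4) next
      if (!is.null(roots) &&
          any(sqrt(rowSums(sweep(roots, 2, p)^2)) < dedup_radius)) next
      roots <- rbind(roots, p)
    }
    if (is.null(roots)) roots <- matrix(numeric(0), 0, d)
    dimnames(roots) <- list(NULL, fpe$genes)
    roots
  })
}

## ---- the user-facing fit ------------------------------------------------

#' Fit the stationary Fokker-Planck density of a GRN model
#'
#' The main entry point of the package: approximates the stationary solution
#' of the Fokker-Planck equation of a stochastic GRN model by a gamma
#' mixture, fitted by minimizing the Monte Carlo collocation norm of the
#' stationary residual in three stages -- (1) a global Monte Carlo search
#' with a Gaussian proxy to locate the attractor regions, (2) gradient
#' refinement of the proxy, (3) moment-matched initialization and gradient
#' fine-tuning of the gamma mixture.  The negative log of the fitted density
#' is the epigenetic landscape of the network.
#'
#' @param fpe an [fpe_model()] (or [fpe_custom()]).
#' @param n_components number of mixture components; defaults to the number
#'   of Boolean fixed points of the source network.
#' @param control a [fit_control()].
#' @param warm_start `"boolean"` seeds the global search with the Boolean
#'   fixed points mapped to concentrations (the default for GRN models);
#'   `"none"` searches cold.
#' @param init_means optional explicit warm-start means, overriding
#'   `warm_start`.
#' @return An object of class `fpe_fit` with components `mixture` (the
#'   fitted [gamma_mixture()]), `proxy` (the refined Gaussian mixture),
#'   `init` (stage-3 starting mixture), `trace` (per-stage residual traces),
#'   `mean_abs_residual`, `residual_norm`, `n_components`, `control`, `fpe`.
#'   Methods: `print`, `summary`, `coef`, `predict`, `simulate`,
#'   `residuals`, `plot`.
#' @examples
#' \donttest{
#' fpe <- fpe_model(continuous_model(toy_network("single_gene")), omega = 50)
#' fit <- fit_stationary(fpe, n_components = 1,
#'                       control = fit_control(n_points = 2000,
#'                                             stage1_trials = 20,
#'                                             stage2_steps = 50,
#'                                             stage3_steps = 50, seed = 1))
#' mixture_modes(fit$mixture)
#' }
#' @export
fit_stationary <- function(fpe, n_components = NULL,
                           control = fit_control(),
                           warm_start = c("attractors", "boolean", "none"),
                           init_means = NULL) {
  stopifnot(inherits(fpe, "fpe_model"))
  warm_start <- match.arg(warm_start)
  bfp <- if (inherits(fpe, "fpe_custom")) NULL
         else boolean_fixed_points(fpe$model$network)
  if (is.null(n_components)) {
    if (is.null(bfp) || nrow(bfp) == 0)
      stop_("'n_components' must be given for this model")
    n_components <- nrow(bfp)
  }
  if (is.null(init_means) && warm_start != "none") {
    if (warm_start == "attractors") {
      att <- fpe_attractors(fpe, p_max = control$p_max,
                            seed = control$seed)
      if (nrow(att) > 0) init_means <- att
    }
    if (is.null(init_means) && !is.null(bfp) && nrow(bfp) > 0)
      init_means <- t(apply(bfp, 1, boolean_to_concentration,
                            model = fpe$model))
  }
  t0 <- proc.time()[["elapsed"]]
  res <- with_seed(control$seed, {
    proxy0 <- fit_stage1_global(fpe, n_components, control$stage1_trials,
                                seed = NULL, control = control,
                                init_means = init_means)
    proxy <- fit_stage2_refine(fpe, proxy0, control, seed = NULL)
    s3 <- fit_stage3_gamma(fpe, proxy, control, seed = NULL)
    list(proxy0 = proxy0, proxy = proxy, s3 = s3)
  })
  upper <- rep(control$p_max, length.out = fpe$d)
  structure(list(
    mixture = res$s3$mixture,
    proxy = res$proxy,
    init = res$s3$init,
    trace = list(stage1 = attr(res$proxy0, "objective"),
                 stage2 = attr(res$proxy, "trace"),
                 stage3 = res$s3$trace),
    mean_abs_residual = res$s3$mean_abs_residual,
    residual_norm = res$s3$mean_abs_residual * prod(upper),
    n_components = n_components,
    control = control, fpe = fpe, genes = fpe$genes,
    elapsed = proc.time()[["elapsed"]] - t0),
    class = "fpe_fit")
}

#' @export
print.fpe_fit <- function(x, ...) {
  cat(sprintf(
    "Stationary Fokker-Planck fit: %d-gene model, %d-component gamma mixture\n",
    x$fpe$d, x$n_components))
  cat(sprintf("  mean |R| per collocation point: %.3g\n", x$mean_abs_residual))
  cat("  attractor modes:\n")
  print(round(mixture_modes(x$mixture), 3))
  invisible(x)
}

#' @export
summary.fpe_fit <- function(object, ...) {
  ls <- landscape_summary(object$mixture)
  out <- list(n_components = object$n_components,
              mean_abs_residual = object$mean_abs_residual,
              residual_norm = object$residual_norm,
              modes = ls$modes, depths = ls$depths,
              mode_distances = ls$distances,
              active_gene_means = active_gene_summary(object$mixture),
              weights = object$mixture$weights,
              elapsed = object$elapsed)
  class(out) <- "summary.fpe_fit"
  out
}

#' @export
print.summary.fpe_fit <- function(x, ...) {
  cat(sprintf("%d-component stationary density fit (%.1f s)\n",
              x$n_components, x$elapsed))
  cat(sprintf("  mean |R| per point: %.3g; residual norm: %.3g\n",
              x$mean_abs_residual, x$residual_norm))
  cat("  component weights:", paste(signif(x$weights, 3), collapse = " "),
      "\n  modes:\n")
  print(round(x$modes, 3))
  cat("  mean concentration of active genes per attractor:",
      paste(round(x$active_gene_means, 2), collapse = " "), "\n")
  cat("  landscape depth U at each mode:",
      paste(signif(x$depths, 4), collapse = " "), "\n")
  invisible(x)
}

#' @export
coef.fpe_fit <- function(object, ...) {
  m <- object$mixture
  list(weights = m$weights, shapes = m$shapes, rates = m$rates)
}

#' @export
predict.fpe_fit <- function(object, newdata,
                            type = c("density", "landscape"), ...) {
  type <- match.arg(type)
  if (type == "density") mixture_pdf(object$mixture, newdata)
  else landscape(object$mixture, newdata)
}

#' @export
simulate.fpe_fit <- function(object, nsim = 1e5, seed = NULL, ...)
  mixture_sample(object$mixture, nsim, seed = seed)

#' @export
residuals.fpe_fit <- function(object, n_points = 4000, seed = 1L, ...) {
  P <- with_seed(seed, draw_collocation_points(
    collocation_config(n_points, object$control$p_max), object$fpe$d))
  stationary_residual(object$fpe, object$mixture, P)
}

#' @export
plot.fpe_fit <- function(x, what = c("density", "landscape"),
                         n_grid = 200, ...) {
  what <- match.arg(what)
  d <- x$fpe$d
  upper <- rep(x$control$p_max, length.out = d)
  f <- function(P) if (what == "density") mixture_pdf(x$mixture, P)
                   else landscape(x$mixture, P)
  if (d == 1) {
    g <- seq(1e-6, upper[1], length.out = n_grid)
    graphics::plot(g, f(matrix(g, ncol = 1)), type = "l",
                   xlab = x$genes[1], ylab = what, ...)
  } else if (d == 2) {
    g1 <- seq(1e-6, upper[1], length.out = n_grid)
    g2 <- seq(1e-6, upper[2], length.out = n_grid)
    z <- matrix(f(as.matrix(expand.grid(g1, g2))), n_grid, n_grid)
    graphics::contour(g1, g2, z, xlab = x$genes[1], ylab = x$genes[2], ...)
  } else {
    modes <- mixture_modes(x$mixture)
    graphics::image(seq_len(ncol(modes)), seq_len(nrow(modes)), t(modes),
                    xlab = "gene", ylab = "component (attractor)",
                    main = "fitted attractor modes",
                    col = grDevices::hcl.colors(64), axes = FALSE, ...)
    graphics::axis(1, seq_len(ncol(modes)), colnames(modes), las = 2,
                   cex.axis = 0.7)
    graphics::axis(2, seq_len(nrow(modes)))
  }
  invisible(x)
}
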