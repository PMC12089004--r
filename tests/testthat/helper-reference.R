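# Shared fixtures and independent reference implementations for the tests.

# Hand-coded reference drift for the A. thaliana model with all rates 1 and
# Hill exponent 1, written term by term from the published equation system
# (kept deliberately independent of the package's model builder).
at_reference_drift <- function(p) {
  c(1 - p[1],
    (1 + p[1]) / (1 + p[1] + 2 * p[3]) + 1 - p[2],
    (2 * p[4] + p[5]) /
      (4 + 2 * p[1] + p[2] + 2 * p[4] + p[5]) + 1 - p[3],
    (2 + 5 * p[3]) / (2 + p[1] + 5 * p[3] + p[9]) + 1 - p[4],
    2 * p[3] / (2 + 2 * p[3]) + 1 - p[5],
    1 - p[6],
    1 - p[7],
    (p[10] + p[11]) / (2 + p[10] + p[11]) + 1 - p[8],
    (2 + p[3]) / (2 + 2 * p[2] + p[3] + 2 * p[4] + p[6]) + 1 - p[9],
    (1 + 3 * p[3] + 2 * p[7] + p[8]) /
      (1 + 3 * p[3] + 2 * p[7] + p[8] + 2 * p[12]) + 1 - p[10],
    (1 + 4 * p[3] + p[7] + p[8]) /
      (1 + 4 * p[3] + p[7] + p[8] + p[12]) + 1 - p[11],
    1 - p[12])
}

# Pure central-finite-difference evaluation of the stationary residual,
# differencing the full products (a_j P) and (Gamma_j P); Richardson
# extrapolation removes the leading O(h^2) error.  Independent of the
# package's residual code path.
fd_residual <- function(fpe, mix, p, h = 2e-3) {
  one_pass <- function(h) {
    tot <- 0
    for (j in seq_along(p)) {
      f <- function(x) {
        q <- p; q[j] <- x
        a <- drift_field(fpe, q)
        g <- diffusion_field(fpe, q)
        P <- mixture_pdf(mix, q)
        c(a[j] * P, g[j] * P)
      }
      hj <- h * max(1, abs(p[j]))
      fp <- f(p[j] + hj); fm <- f(p[j] - hj); f0 <- f(p[j])
      tot <- tot - (fp[1] - fm[1]) / (2 * hj) +
        0.5 * (fp[2] - 2 * f0[2] + fm[2]) / hj^2
    }
    tot
  }
  (4 * one_pass(h / 2) - one_pass(h)) / 3
}

# The bistable two-gene mutual-repression configuration used by the 2-D
# demonstrations (basal synthesis off, slow degradation, cooperative
# repression); its deterministic attractors are near (1.917, 0.442) and
# (0.442, 1.917).
bistable_toggle_model <- function()
  continuous_model(toy_network("toggle"), alpha0 = 0, delta = 0.5, hill_n = 3)

# A synthetic Fokker-Planck model whose stationary density is a *known*
# gamma mixture: constant diagonal diffusion `cc` and gradient drift
# a_j = (cc/2) d log P*/dp_j, so the probability flux vanishes identically
# and P* is the exact stationary solution (and lies inside the ansatz
# family).  The score is computed analytically from the mixture.
zero_flux_fpe <- function(target, cc = 0.05) {
  score <- function(P) {
    P <- pmax(P, 1e-9)
    n <- length(target$weights)
    logc <- sapply(seq_len(n), function(i)
      rowSums(dgamma(P, matrix(target$shapes[i, ], nrow(P), ncol(P),
                               byrow = TRUE),
                     matrix(target$rates[i, ], nrow(P), ncol(P),
                            byrow = TRUE), log = TRUE)))
    logc <- matrix(logc, nrow(P), n)
    lw <- sweep(logc, 2, log(target$weights), `+`)
    M <- apply(lw, 1, max)
    post <- exp(lw - M) / rowSums(exp(lw - M))  # component responsibilities
    out <- matrix(0, nrow(P), ncol(P))
    for (i in seq_len(n)) {
      u <- sweep(1 / P, 2, target$shapes[i, ] - 1, `*`) -
        matrix(target$rates[i, ], nrow(P), ncol(P), byrow = TRUE)
      out <- out + post[, i] * u
    }
    out
  }
  fpe_custom(function(P) (cc / 2) * score(P),
             function(P) matrix(cc, nrow(P), ncol(P)),
             d = ncol(target$shapes), genes = target$genes)
}

# The known two-well, two-gene target mixture used by the recovery tests.
two_well_target <- function()
  gamma_mixture(c(0.5, 0.5), rbind(c(77, 9.1), c(9.1, 77)),
                rbind(c(40, 18), c(18, 40)), genes = c("g1", "g2"))

# Total variation distance between a sample and a 1-D grid solution,
# computed on the grid's own bins.
sample_grid_tv <- function(samples, gs) {
  x <- gs$grid[[1]]
  h <- gs$h[1]
  breaks <- c(x - h / 2, x[length(x)] + h / 2)
  samples <- pmin(pmax(samples, breaks[1]), breaks[length(breaks)])
  emp <- hist(samples, breaks = breaks, plot = FALSE)$counts /
    length(samples)
  0.5 * sum(abs(emp - gs$density * h))
}
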