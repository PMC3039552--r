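# Independent numerical oracles: grid quadrature of the exact posteriors on
# tiny graphs, used to cross-check the MCMC samplers. These integrate the
# model densities directly (marginalising the random-effect decomposition to
# the per-area linear predictors) and share no code with the samplers.

# Posterior mean of theta_i for the 3-area path-graph BYM model under
# gamma priors on both precisions. s_i = alpha + u_i + v_i is integrated on
# a box grid; (tau_u, tau_v) on log grids; the Gaussian prior of s given tau
# has covariance A*J + Lplus/tau_u + I/tau_v with Lplus the ICAR
# pseudo-inverse on the sum-to-zero subspace.
bym_quadrature_mean <- function(y, e, A = 1e10, au = 0.1, bu = 0.1,
                                av = 0.001, bv = 0.001,
                                ns = 41, ntu = 44, ntv = 48) {
  L <- matrix(c(1, -1, 0, -1, 2, -1, 0, -1, 1), 3, 3)
  eg <- eigen(L, symmetric = TRUE)
  pos <- eg$values > 1e-9
  Lp <- eg$vectors[, pos] %*% diag(1 / eg$values[pos]) %*% t(eg$vectors[, pos])
  J <- matrix(1, 3, 3)
  mle <- log(y / e)
  sdv <- 1 / sqrt(y)
  grids <- lapply(1:3, function(i) {
    seq(mle[i] - 5.5 * sdv[i], mle[i] + 5.5 * sdv[i], length.out = ns)
  })
  S <- as.matrix(expand.grid(grids[[1]], grids[[2]], grids[[3]]))
  loglik <- as.numeric(S %*% y - exp(S) %*% e)
  ES <- exp(S)
  tu <- exp(seq(log(1e-3), log(3e3), length.out = ntu))
  tv <- exp(seq(log(1e-3), log(3e4), length.out = ntv))
  parts <- matrix(NA_real_, ntu * ntv, 5)
  r <- 0L
  for (a in tu) for (b in tv) {
    Sig <- A * J + Lp / a + diag(3) / b
    Q <- chol(Sig)
    X <- forwardsolve(t(Q), t(S))
    lw <- dgamma(a, au, bu, log = TRUE) + log(a) +
      dgamma(b, av, bv, log = TRUE) + log(b) -
      0.5 * colSums(X^2) - sum(log(diag(Q))) + loglik
    m <- max(lw)
    w <- exp(lw - m)
    r <- r + 1L
    parts[r, ] <- c(m, sum(w), sum(w * ES[, 1]), sum(w * ES[, 2]),
                    sum(w * ES[, 3]))
  }
  f <- exp(parts[, 1] - max(parts[, 1]))
  den <- sum(f * parts[, 2])
  c(sum(f * parts[, 3]), sum(f * parts[, 4]), sum(f * parts[, 5])) / den
}

# Posterior mean of w_i = u_i + v_i for a 2-area, 2-cell excess-mortality
# toy (one follow-up year, one age band), gamma priors on both precisions.
excess_quadrature_mean_w <- function(y, d, dstar, cv, au, bu, av, bv,
                                     ns = 45, nt = 40, wlim = 4, alim = 3) {
  Lp <- matrix(c(0.25, -0.25, -0.25, 0.25), 2, 2)
  a0 <- log(mean((d - dstar) / y))
  ga <- seq(a0 - alim, a0 + alim, length.out = ns)
  gw <- seq(-wlim, wlim, length.out = ns)
  S <- as.matrix(expand.grid(ga, gw, gw))
  mu1 <- dstar[1] + y[1] * exp(S[, 1] + S[, 2])
  mu2 <- dstar[2] + y[2] * exp(S[, 1] + S[, 3])
  loglik <- d[1] * log(mu1) - mu1 + d[2] * log(mu2) - mu2
  lpa <- dnorm(S[, 1], 0, sqrt(cv), log = TRUE)
  tg <- exp(seq(log(1e-2), log(1e2), length.out = nt))
  parts <- matrix(NA_real_, nt * nt, 4)
  r <- 0L
  for (a in tg) for (b in tg) {
    Cw <- Lp / a + diag(2) / b
    Q <- chol(Cw)
    X <- forwardsolve(t(Q), t(S[, 2:3]))
    lw <- dgamma(a, au, bu, log = TRUE) + log(a) +
      dgamma(b, av, bv, log = TRUE) + log(b) -
      0.5 * colSums(X^2) - sum(log(diag(Q))) + loglik + lpa
    m <- max(lw)
    w <- exp(lw - m)
    r <- r + 1L
    parts[r, ] <- c(m, sum(w), sum(w * S[, 2]), sum(w * S[, 3]))
  }
  f <- exp(parts[, 1] - max(parts[, 1]))
  den <- sum(f * parts[, 2])
  c(sum(f * parts[, 3]), sum(f * parts[, 4])) / den
}

# Monte-Carlo standard error of a chain's mean via the spectral density at
# zero (same convention the Geweke diagnostic uses).
chain_mcse <- function(ch) {
  sp <- stats::ar(ch, aic = TRUE, order.max = 30, method = "yule-walker")
  s0 <- if (length(sp$ar) == 0) sp$var.pred else sp$var.pred / (1 - sum(sp$ar))^2
  sqrt(s0 / length(ch))
}
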