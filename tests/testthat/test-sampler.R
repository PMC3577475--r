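# Helpers building tiny sampler states by hand -------------------------------

tiny_dat <- function(I = 2, J = 2, seed = 5, nobs = NULL) {
  set.seed(seed)
  list(y = matrix(runif(I * J, 0, 1.2), I, J),
       x = matrix(runif(I * J, 0.2, 0.9), I, J),
       nobs = if (is.null(nobs)) sample(1:5, I, replace = TRUE) else nobs)
}

tiny_state <- function(dat, K = 2, L = 2, hyper = nirm_hyperpriors(),
                       seed = 9) {
  set.seed(seed)
  nirmreg:::init_state(nrow(dat$y), ncol(dat$y), K, L, hyper)
}

# inverse-gamma density under the package convention (rate = 1/b)
dig <- function(t, a, b) stats::dgamma(1 / t, a, rate = 1 / b) / t^2

# the likelihood variance: var when phi = 0, var / n when phi != 0
vtilde <- function(phi, var, n) if (phi != 0) var / n else var

test_that("cell log likelihood matches closed forms", {
  expect_equal(nirmreg:::loglik_cell(0, 0.5, 3, 0, 0.04),
               -0.5 * log(2 * pi * 0.04))
  # nonzero coefficient: the variance is divided by n_obs
  expect_equal(nirmreg:::loglik_cell(0.7, 0.5, 4, 1, 0.04),
               dnorm(0.7, 0.5, sqrt(0.04 / 4), log = TRUE))
  # doubling n_obs strictly increases the density at the regression mean
  l1 <- nirmreg:::loglik_cell(0.5, 0.5, 2, 1, 0.04)
  l2 <- nirmreg:::loglik_cell(0.5, 0.5, 4, 1, 0.04)
  expect_gt(l2, l1)
  expect_error(nirmreg:::loglik_cell(0, 0.5, 1, 0, -1))
})

test_that("column indicator probabilities match exhaustive enumeration", {
  dat <- tiny_dat()
  st <- tiny_state(dat)
  lp <- nirmreg:::column_indicator_logprobs(st, dat)
  for (j in 1:2) {
    oracle <- sapply(1:2, function(k) {
      prod(sapply(1:2, function(i) {
        phi <- st$phi[st$xi[i, k], k]
        v <- vtilde(phi, st$th2[st$xi[i, k], k], dat$nobs[i])
        dnorm(dat$y[i, j], phi * dat$x[i, j], sqrt(v))
      })) * exp(st$logPi[k])
    })
    got <- exp(lp[j, ] - max(lp[j, ]))
    got <- got / sum(got)
    expect_equal(got, oracle / sum(oracle), tolerance = 1e-9)
  }
})

test_that("identical atoms make column probabilities equal the weights", {
  dat <- tiny_dat()
  st <- tiny_state(dat)
  st$phi[] <- 0.8
  st$th2[] <- 0.02
  st$psi[] <- 1L
  lp <- nirmreg:::column_indicator_logprobs(st, dat)
  p <- exp(lp - apply(lp, 1, max))
  p <- p / rowSums(p)
  expect_equal(p[1, ], exp(st$logPi) / sum(exp(st$logPi)), tolerance = 1e-12)
})

test_that("K = 1 and L = 1 truncations are degenerate", {
  dat <- tiny_dat()
  st1 <- tiny_state(dat, K = 1, L = 3)
  expect_identical(unique(nirmreg:::sample_column_indicators(st1, dat)), 1L)
  st2 <- tiny_state(dat, K = 3, L = 1)
  expect_identical(unique(as.vector(nirmreg:::sample_row_indicators(st2,
                                                                    dat))),
                   1L)
})

test_that("row indicator probabilities match enumeration and empty-product rule", {
  dat <- tiny_dat()
  st <- tiny_state(dat)
  st$zeta <- c(1L, 1L)    # cluster 2 owns no columns
  lp2 <- nirmreg:::row_indicator_logprobs(st, dat, 2)
  p2 <- exp(lp2 - apply(lp2, 1, max))
  p2 <- p2 / rowSums(p2)
  expect_equal(p2[1, ], st$w[, 2], tolerance = 1e-12)
  lp1 <- nirmreg:::row_indicator_logprobs(st, dat, 1)
  for (i in 1:2) {
    oracle <- sapply(1:2, function(l) {
      st$w[l, 1] * prod(sapply(1:2, function(j) {
        v <- vtilde(st$phi[l, 1], st$th2[l, 1], dat$nobs[i])
        dnorm(dat$y[i, j], st$phi[l, 1] * dat$x[i, j], sqrt(v))
      }))
    })
    got <- exp(lp1[i, ] - max(lp1[i, ]))
    expect_equal(got / sum(got), oracle / sum(oracle), tolerance = 1e-9)
  }
})

test_that("stick conditionals use the printed Beta parameters", {
  p <- nirmreg:::stick_beta_params(c(2, 1, 0), conc = 1)
  expect_equal(p$shape1, c(3, 2))
  expect_equal(p$shape2, c(2, 1))
  # weights reconstructed from sticks always sum to one
  set.seed(1)
  for (rep in 1:20) {
    v <- nirmreg:::sample_sticks(rpois(6, 2), rgamma(1, 2))
    expect_equal(sum(exp(nirmreg:::stick_logweights(v))), 1,
                 tolerance = 1e-12)
  }
  # all-empty clusters: sticks are i.i.d. Beta(1, conc); the mean of the
  # first weight under conc = 1 is E[Beta(1,1)] = 1/2
  set.seed(2)
  pi1 <- replicate(1e5, nirmreg:::sample_sticks(c(0, 0, 0), 1)[1])
  expect_equal(mean(pi1), 0.5, tolerance = 0.01)
})

test_that("spike probability matches 2-D quadrature on single-cell sets", {
  hyper <- nirm_hyperpriors()
  set.seed(21)
  for (rep in 1:5) {
    y <- runif(1, 0, 1.3)
    x <- runif(1, 0.2, 0.9)
    n <- sample(1:5, 1)
    alpha <- rnorm(1, 1, 0.5)
    stats <- list(count = 1, s_yy = y^2, s_nyy = n * y^2, s_nxy = n * x * y,
                  s_nxx = n * x^2, s_logn = log(n))
    mar <- nirmreg:::atom_log_marginals(stats, alpha, hyper)
    # integrate over the precision u = 1/theta^2 (gamma-distributed), which
    # integrate() handles much more accurately than the heavy-tailed t scale
    m0 <- integrate(function(u) {
      dnorm(y, 0, sqrt(1 / u)) * dgamma(u, hyper$a_kappa,
                                        rate = 1 / hyper$b_kappa)
    }, 0, Inf, rel.tol = 1e-12)$value
    m1 <- integrate(Vectorize(function(u) {
      t <- 1 / u
      # center the phi integral on the product-of-Gaussians ridge so the
      # quadrature cannot miss the (possibly extremely narrow) spike
      ctr <- (alpha * hyper$V0 + n * x * y) / (hyper$V0 + n * x^2)
      hw <- 15 * sqrt(t / (hyper$V0 + n * x^2))
      integrate(function(phi) {
        dnorm(y, phi * x, sqrt(t / n)) * dnorm(phi, alpha, sqrt(t / hyper$V0))
      }, ctr - hw, ctr + hw, rel.tol = 1e-12)$value *
        dgamma(u, hyper$a_sigma, rate = 1 / hyper$b_sigma)
    }), 0, Inf, rel.tol = 1e-12, subdivisions = 400L)$value
    expect_equal(exp(mar$lm0), m0, tolerance = 1e-6)
    expect_equal(exp(mar$lm1), m1, tolerance = 1e-6)
    lam <- 0.3
    p1_oracle <- (1 - lam) * m1 / (lam * m0 + (1 - lam) * m1)
    p1 <- 1 / (1 + exp(log(lam) + mar$lm0 - log1p(-lam) - mar$lm1))
    expect_equal(p1, p1_oracle, tolerance = 1e-6)
  }
})

test_that("atom cell statistics match a naive double loop", {
  dat <- tiny_dat(I = 4, J = 3, seed = 8)
  st <- tiny_state(dat, K = 3, L = 2, seed = 4)
  stats <- nirmreg:::atom_cell_stats(st, dat)
  for (k in 1:3) {
    for (l in 1:2) {
      idx <- (k - 1) * 2 + l
      cells <- list()
      s <- c(count = 0, s_yy = 0, s_nyy = 0, s_nxy = 0, s_nxx = 0,
             s_logn = 0)
      for (i in 1:4) {
        for (j in 1:3) {
          if (st$zeta[j] == k && st$xi[i, k] == l) {
            s <- s + c(1, dat$y[i, j]^2, dat$nobs[i] * dat$y[i, j]^2,
                       dat$nobs[i] * dat$x[i, j] * dat$y[i, j],
                       dat$nobs[i] * dat$x[i, j]^2, log(dat$nobs[i]))
          }
        }
      }
      got <- c(stats$count[idx], stats$s_yy[idx], stats$s_nyy[idx],
               stats$s_nxy[idx], stats$s_nxx[idx], stats$s_logn[idx])
      expect_equal(unname(got), unname(s), tolerance = 1e-12)
    }
  }
})

test_that("spike-only base measure zeroes every atom", {
  dat <- tiny_dat()
  st <- tiny_state(dat)
  st$lam <- 1 - 1e-300    # lambda = 1 is excluded by the Beta support
  at <- nirmreg:::sample_atoms(st, dat, nirm_hyperpriors())
  expect_true(all(at$psi == 0))
  expect_true(all(at$phi == 0))
})

test_that("empty atoms are refreshed from the base measure", {
  hyper <- nirm_hyperpriors()
  dat <- tiny_dat()
  st <- tiny_state(dat, K = 3, L = 2)
  st$zeta <- c(1L, 1L)      # clusters 2 and 3 own nothing
  set.seed(31)
  draws <- replicate(4000, {
    at <- nirmreg:::sample_atoms(st, dat, hyper)
    c(phi = at$phi[1, 3], psi = at$psi[1, 3], th2 = at$th2[1, 3])
  })
  # spike frequency equals lambda
  expect_equal(mean(draws["psi", ] == 0), st$lam, tolerance = 0.04)
  # slab coefficient draws center on alpha_3
  slab <- draws["phi", draws["psi", ] == 1]
  expect_equal(mean(slab), st$alpha[3], tolerance = 0.05)
  # spike-branch variances follow the IG(a_kappa, b_kappa) prior median
  spike_t <- draws["th2", draws["psi", ] == 0]
  med_oracle <- 1 / qgamma(0.5, hyper$a_kappa, rate = 1 / hyper$b_kappa)
  expect_equal(median(spike_t), med_oracle, tolerance = 0.05)
})

test_that("lambda conditional counts the spike indicators", {
  dat <- tiny_dat()
  st <- tiny_state(dat, K = 5, L = 5)
  st$psi <- matrix(0L, 5, 5)
  st$psi[1:3] <- 1L
  hyper <- nirm_hyperpriors()
  set.seed(77)
  got <- nirmreg:::sample_lambda(st, hyper)
  set.seed(77)
  oracle <- rbeta(1, hyper$a_lambda + 22, hyper$b_lambda + 3)
  expect_identical(got, oracle)
})

test_that("alpha conditional matches an independent conjugate-normal oracle", {
  hyper <- nirm_hyperpriors()
  set.seed(13)
  for (rep in 1:10) {
    dat <- tiny_dat(I = 3, J = 3, seed = rep)
    st <- tiny_state(dat, K = 2, L = 4, seed = rep + 50)
    p <- nirmreg:::alpha_posterior_params(st, hyper)
    for (k in 1:2) {
      sel <- which(st$psi[, k] == 1)
      prec <- 1 / hyper$C_alpha
      num <- hyper$m_alpha / hyper$C_alpha
      for (l in sel) {
        prec <- prec + hyper$V0 / st$th2[l, k]
        num <- num + hyper$V0 * st$phi[l, k] / st$th2[l, k]
      }
      expect_equal(p$C[k], 1 / prec, tolerance = 1e-12)
      expect_equal(p$m[k], num / prec, tolerance = 1e-12)
    }
  }
  # no slab atoms in a cluster: posterior reduces to the prior
  dat <- tiny_dat()
  st <- tiny_state(dat)
  st$psi[] <- 0L
  p <- nirmreg:::alpha_posterior_params(st, hyper)
  expect_equal(p$m, rep(hyper$m_alpha, 2))
  expect_equal(p$C, rep(hyper$C_alpha, 2))
  # one atom with th2 = V0 * C_alpha has the same precision as the prior:
  # the posterior mean is the midpoint
  st$psi[1, 1] <- 1L
  st$phi[1, 1] <- 0.5
  st$th2[1, 1] <- hyper$V0 * hyper$C_alpha
  p <- nirmreg:::alpha_posterior_params(st, hyper)
  expect_equal(p$m[1], (hyper$m_alpha + 0.5) / 2)
})

test_that("truncation rule matches the closed-form tail and a MC estimate", {
  expect_identical(choose_truncation(1, 0.5), 2L)
  # tail mass expectation at the chosen K is below tol, at K - 1 above
  for (rho in c(0.5, 1, 3)) {
    K <- choose_truncation(rho, 0.01)
    expect_lte((rho / (1 + rho))^(K - 1), 0.01)
    expect_gt((rho / (1 + rho))^(K - 2), 0.01)
  }
  # monotone in rho
  Ks <- sapply(c(0.2, 0.5, 1, 2, 5), choose_truncation, tol = 1e-3)
  expect_true(all(diff(Ks) >= 0))
  # Monte-Carlo check of the tail-mass expectation identity
  set.seed(4)
  K <- choose_truncation(1, 0.01)
  tails <- replicate(2e4, {
    v <- rbeta(K - 1, 1, 1)
    1 - sum(v * cumprod(c(1, 1 - v[-(K - 1)])))
  })
  expect_equal(mean(tails), 0.5^(K - 1), tolerance = 0.2)
})

test_that("with the likelihood switched off the concentration keeps its prior", {
  # joint prior chain: sticks | partition, partition | sticks (no data),
  # concentration | partition; its stationary rho marginal is Ga(1, 1)
  set.seed(88)
  K <- 10
  J <- 6
  rho <- 1
  zeta <- sample.int(K, J, replace = TRUE)
  draws <- numeric(2e4)
  for (it in seq_along(draws)) {
    v <- nirmreg:::sample_sticks(tabulate(zeta, K), rho)
    Pi <- exp(nirmreg:::stick_logweights(v))
    zeta <- sample.int(K, J, replace = TRUE, prob = Pi)
    rho <- nirmreg:::sample_concentration(rho, length(unique(zeta)), J, 1, 1)
    draws[it] <- rho
  }
  draws <- draws[-(1:2000)]
  qs <- quantile(draws, c(0.25, 0.5, 0.75, 0.9))
  oracle <- qgamma(c(0.25, 0.5, 0.75, 0.9), 1, 1)
  expect_equal(unname(qs), oracle, tolerance = 0.08)
  expect_equal(mean(draws), 1, tolerance = 0.06)
})

test_that("stick-breaking normalization holds after every sweep", {
  dat <- tiny_dat(I = 5, J = 4, seed = 3)
  hyper <- nirm_hyperpriors()
  set.seed(10)
  state <- nirmreg:::init_state(5, 4, 4, 4, hyper)
  for (it in 1:25) {
    state <- nirmreg:::gibbs_sweep(state, dat, hyper)
    expect_equal(sum(exp(state$logPi)), 1, tolerance = 1e-10)
    expect_equal(unname(colSums(state$w)), rep(1, 4), tolerance = 1e-10)
    expect_true(all((state$psi == 0) == (state$phi == 0)))
    expect_true(all(state$th2 > 0))
    expect_true(state$lam > 0 && state$lam < 1)
  }
})

test_that("Geweke-style joint distribution check holds on a 4 x 3 problem", {
  # successive-conditional simulator: alternate y | state with one Gibbs
  # sweep; its stationary law for the parameters is the prior. Compare
  # moments against direct prior draws.
  hyper <- nirm_hyperpriors(C_alpha = 0.2, b_kappa = 20, b_sigma = 5)
  I <- 4; J <- 3; K <- 3; L <- 3
  set.seed(101)
  x <- matrix(runif(I * J, 0.2, 0.9), I, J)
  nobs <- c(1, 2, 3, 5)
  M <- 6000
  state <- nirmreg:::init_state(I, J, K, L, hyper)
  succ <- matrix(NA_real_, M, 4)
  for (m in seq_len(M)) {
    dat <- list(y = nirmreg:::simulate_y_given_state(state,
                                                     list(x = x,
                                                          nobs = nobs)),
                x = x, nobs = nobs)
    state <- nirmreg:::gibbs_sweep(state, dat, hyper)
    at <- nirmreg:::atom_at_xi(state)
    beta_cells <- at$phi[, state$zeta, drop = FALSE]
    succ[m, ] <- c(state$rho, state$lam, mean(state$alpha),
                   mean(beta_cells))
  }
  fwd <- matrix(NA_real_, M, 4)
  for (m in seq_len(M)) {
    st <- nirmreg:::init_state(I, J, K, L, hyper)
    at <- nirmreg:::atom_at_xi(st)
    beta_cells <- at$phi[, st$zeta, drop = FALSE]
    fwd[m, ] <- c(st$rho, st$lam, mean(st$alpha), mean(beta_cells))
  }
  # z-scores with batch-means standard errors for the dependent chain
  batch_se <- function(z, n_batch = 40) {
    bm <- tapply(z, rep(seq_len(n_batch), each = length(z) / n_batch), mean)
    sd(bm) / sqrt(n_batch)
  }
  for (c in 1:4) {
    se <- sqrt(batch_se(succ[, c])^2 + var(fwd[, c]) / M)
    z <- (mean(succ[, c]) - mean(fwd[, c])) / se
    expect_lt(abs(z), 5)
  }
})

test_that("fits are bit-reproducible given the seed", {
  sim <- simulate_block_data(sim_block_scenario(n_sites = 8,
                                                n_properties = 4,
                                                row_clusters = c(1, 1)),
                             seed = 3)
  f1 <- fit_nirm(sim$data, K = 4, L = 4, iterations = 120, burn_in = 40,
                 thin = 2, seed = 42)
  f2 <- fit_nirm(sim$data, K = 4, L = 4, iterations = 120, burn_in = 40,
                 thin = 2, seed = 42)
  expect_identical(f1$draws, f2$draws)
  # exactly (iterations - burn_in) / thin draws are retained
  expect_identical(length(f1$draws$rho), 40L)
  f3 <- fit_nirm(sim$data, K = 4, L = 4, iterations = 41, burn_in = 40,
                 thin = 1, seed = 42)
  expect_identical(length(f3$draws$rho), 1L)
})

test_that("invalid sampler configurations are rejected", {
  sim <- simulate_block_data(sim_block_scenario(n_sites = 4,
                                                n_properties = 2,
                                                row_clusters = 1),
                             seed = 1)
  expect_error(fit_nirm(sim$data, iterations = 100, burn_in = 100),
               "burn_in")
  expect_error(fit_nirm(sim$data, K = 0), "K and L")
  expect_error(nirm_hyperpriors(C_alpha = -1), "strictly positive")
})

test_that("prior-implied moments match the printed statements", {
  # Beta(2, 8) spike prior: 20% of unique coefficients expected to be zero
  hyper <- nirm_hyperpriors()
  expect_equal(hyper$a_lambda / (hyper$a_lambda + hyper$b_lambda), 0.2)
  # inverse-gamma prior means under the adopted parameterization
  expect_equal(nirmreg:::ig_mean(2, 100), 0.01)
  expect_equal(nirmreg:::ig_mean(2, 4), 0.25)
  expect_equal(nirmreg:::ig_mean(2, 10), 0.1)
})
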