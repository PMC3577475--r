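# Internal machinery of the truncated blocked Gibbs sampler.
#
# State layout (see fit_nirm() for the user-facing surface):
#   zeta  : integer J        column (property) cluster indicators in 1..K
#   v     : K column sticks,   logPi = log stick-breaking weights
#   xi    : integer I x K     row (site) indicators in 1..L, kept for every
#                             column cluster k (also currently empty ones)
#   u,w   : L x K row sticks / weights per column cluster
#   phi   : L x K atom regression coefficients (0 under the spike)
#   th2   : L x K atom variances
#   psi   : L x K 0/1 spike indicators (psi = 1 <=> phi != 0)
#   alpha : K slab means; gamma: K row concentrations; rho, lam scalars
#
# The implied cell parameters are beta[i,j] = phi[xi[i, zeta[j]], zeta[j]]
# and sigma2[i,j] = th2[...]; the likelihood variance is sigma2 when
# beta = 0 and sigma2 / n_obs[i] when beta != 0.

VAR_FLOOR <- 1e-30  # bug trap only: variances this small signal a defect

as_sampler_data <- function(data) {
  need <- c("site", "property", "y_star", "x_star", "n_obs")
  missing <- setdiff(need, names(data))
  if (length(missing) > 0) {
    stop("distance data is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  props <- unique(data$property)
  sites <- unique(data$site)
  wide_y <- tidyr::pivot_wider(data[, c("site", "property", "y_star")],
                               names_from = "property",
                               values_from = "y_star")
  wide_x <- tidyr::pivot_wider(data[, c("site", "property", "x_star")],
                               names_from = "property",
                               values_from = "x_star")
  y <- as.matrix(wide_y[, props, drop = FALSE])
  x <- as.matrix(wide_x[, props, drop = FALSE])
  if (anyNA(y) || anyNA(x)) {
    stop("distance data must be complete over site x property", call. = FALSE)
  }
  nobs <- data |>
    dplyr::distinct(.data$site, .data$n_obs) |>
    dplyr::arrange(match(.data$site, sites))
  if (nrow(nobs) != length(sites)) {
    stop("n_obs must be constant within site", call. = FALSE)
  }
  if (any(nobs$n_obs < 1)) stop("n_obs must be >= 1", call. = FALSE)
  list(y = y, x = x, nobs = as.numeric(nobs$n_obs),
       sites = wide_y$site, properties = props)
}

# log N(y | phi * x, v) with v = var (phi == 0) or var / n_obs (phi != 0);
# the single-cell version of the likelihood, used by tests and oracles
loglik_cell <- function(y_star, x_star, n_obs, phi, var) {
  stopifnot(var > 0, n_obs >= 1)
  v <- if (phi != 0) var / n_obs else var
  stats::dnorm(y_star, phi * x_star, sqrt(v), log = TRUE)
}

stick_logweights <- function(v) {
  K <- length(v)
  lv <- log(v)
  lq <- log1p(-v)
  lv + c(0, cumsum(lq)[-K])
}

# Beta parameters of the stick full conditionals given cluster counts and a
# concentration; the last stick is fixed at 1.
stick_beta_params <- function(counts, conc) {
  K <- length(counts)
  tail_counts <- rev(cumsum(rev(counts)))      # sum_{s >= k} counts_s
  list(shape1 = 1 + counts[-K],
       shape2 = conc + tail_counts[-K] - counts[-K])
}

sample_sticks <- function(counts, conc) {
  K <- length(counts)
  if (K == 1) return(1)
  p <- stick_beta_params(counts, conc)
  c(stats::rbeta(K - 1, p$shape1, p$shape2), 1)
}

# one categorical draw per row of a matrix of unnormalized log probabilities
rcat_logprob_rows <- function(logp) {
  mx <- apply(logp, 1, max)
  if (any(!is.finite(mx))) {
    stop("all candidate clusters have zero posterior probability; ",
         "the sampler state is numerically degenerate", call. = FALSE)
  }
  p <- exp(logp - mx)
  cs <- t(apply(p, 1, cumsum))
  u <- stats::runif(nrow(p)) * cs[, ncol(p)]
  pmin(as.integer(rowSums(cs < u)) + 1L, ncol(p))
}

# per-cell atom parameters implied by the current indicators:
# I x K matrices of phi, th2, psi at atom (xi[i,k], k)
atom_at_xi <- function(state) {
  I <- nrow(state$xi); K <- ncol(state$xi)
  idx <- cbind(as.vector(state$xi), rep(seq_len(K), each = I))
  list(phi = matrix(state$phi[idx], I, K),
       th2 = matrix(state$th2[idx], I, K),
       psi = matrix(state$psi[idx], I, K))
}

# J x K unnormalized log probabilities for the column indicators:
# log Pi_k + sum_i log N(y*_ij | phi_{xi_ik,k} x*_ij, thtilde2)
column_indicator_logprobs <- function(state, dat) {
  at <- atom_at_xi(state)
  V <- at$th2 / ifelse(at$psi == 1, dat$nobs, 1)   # nobs recycles over rows
  S <- sqrt(V)
  J <- ncol(dat$y); K <- ncol(state$xi)
  out <- matrix(0, J, K)
  I <- nrow(dat$y)
  for (j in seq_len(J)) {
    M <- at$phi * dat$x[, j]
    out[j, ] <- colSums(matrix(stats::dnorm(dat$y[, j], M, S, log = TRUE),
                               I))
  }
  sweep(out, 2, state$logPi, `+`)
}

sample_column_indicators <- function(state, dat) {
  rcat_logprob_rows(column_indicator_logprobs(state, dat))
}

sample_column_weights <- function(state, dat) {
  K <- length(state$logPi)
  m <- tabulate(state$zeta, nbins = K)
  v <- sample_sticks(m, state$rho)
  list(v = v, logPi = stick_logweights(v))
}

# I x L unnormalized log probabilities for the row indicators of column
# cluster k; for a cluster owning no columns the likelihood product is empty
row_indicator_logprobs <- function(state, dat, k) {
  I <- nrow(dat$y); L <- nrow(state$phi)
  cols <- which(state$zeta == k)
  out <- matrix(rep(log(state$w[, k]), each = I), I, L)
  if (length(cols) == 0) return(out)
  Y <- dat$y[, cols, drop = FALSE]
  X <- dat$x[, cols, drop = FALSE]
  for (l in seq_len(L)) {
    v <- if (state$psi[l, k] == 1) state$th2[l, k] / dat$nobs
         else rep(state$th2[l, k], I)
    out[, l] <- out[, l] +
      rowSums(matrix(stats::dnorm(Y, state$phi[l, k] * X, sqrt(v),
                                  log = TRUE), I))
  }
  out
}

sample_row_indicators <- function(state, dat) {
  K <- ncol(state$xi)
  xi <- state$xi
  for (k in seq_len(K)) {
    xi[, k] <- rcat_logprob_rows(row_indicator_logprobs(state, dat, k))
  }
  xi
}

sample_row_weights <- function(state, dat) {
  L <- nrow(state$phi); K <- ncol(state$phi)
  u <- matrix(0, L, K); w <- matrix(0, L, K)
  for (k in seq_len(K)) {
    # n_{l,k}: number of row indicators xi_{i,k} assigned to atom l; one
    # indicator per site and column cluster, shared by all columns in k
    n_lk <- tabulate(state$xi[, k], nbins = L)
    u[, k] <- sample_sticks(n_lk, state$gamma[k])
    w[, k] <- exp(stick_logweights(u[, k]))
  }
  list(u = u, w = w)
}

# sufficient statistics of the cells governed by each atom, vectorized over
# the L*K atom grid; Omega_{l,k} = {(i,j): zeta_j = k, xi_{i,k} = l}
atom_cell_stats <- function(state, dat) {
  I <- nrow(dat$y); J <- ncol(dat$y)
  L <- nrow(state$phi); K <- ncol(state$phi)
  # linear atom index of each cell (i, j)
  idx <- state$xi[, state$zeta, drop = FALSE] +
    L * (rep(state$zeta, each = I) - 1L)
  idx <- as.vector(idx)
  nb <- L * K
  acc <- function(vals) {
    out <- numeric(nb)
    s <- rowsum(vals, idx)
    out[as.integer(rownames(s))] <- s
    out
  }
  nobs_cell <- rep(dat$nobs, times = J)
  y <- as.vector(dat$y); x <- as.vector(dat$x)
  list(count = acc(rep(1, length(idx))),
       s_yy = acc(y * y),                 # unweighted, spike branch
       s_nyy = acc(nobs_cell * y * y),
       s_nxy = acc(nobs_cell * x * y),
       s_nxx = acc(nobs_cell * x * x),
       s_logn = acc(log(nobs_cell)))
}

# log marginal likelihoods of the cells in Omega_{l,k} under the spike
# (phi = 0, variance prior IG(a_kappa, b_kappa)) and the slab (phi and
# variance integrated out under the normal-inverse-gamma base measure)
atom_log_marginals <- function(stats, alpha_rep, hyper) {
  r0 <- ig_rate(hyper$b_kappa)
  r1 <- ig_rate(hyper$b_sigma)
  a0 <- hyper$a_kappa
  a1 <- hyper$a_sigma
  V0 <- hyper$V0
  n <- stats$count
  lm0 <- lgamma(a0 + n / 2) - lgamma(a0) + a0 * log(r0) -
    (a0 + n / 2) * log(r0 + stats$s_yy / 2) - (n / 2) * log(2 * pi)
  A <- V0 + stats$s_nxx
  m <- (alpha_rep * V0 + stats$s_nxy) / A
  C2 <- (stats$s_nyy + V0 * alpha_rep^2 - A * m^2) / 2
  if (any(C2 < -1e-8)) {
    stop("negative slab scale: implementation defect in atom update",
         call. = FALSE)
  }
  C2 <- pmax(C2, 0)
  lm1 <- 0.5 * (log(V0) - log(A)) + 0.5 * stats$s_logn +
    lgamma(a1 + n / 2) - lgamma(a1) + a1 * log(r1) -
    (a1 + n / 2) * log(r1 + C2) - (n / 2) * log(2 * pi)
  list(lm0 = lm0, lm1 = lm1, A = A, m = m, C2 = C2)
}

# joint update of (psi, th2, phi) for all L*K atoms; atoms governing no cell
# are refreshed from the base measure (the same formulas with empty sums)
sample_atoms <- function(state, dat, hyper) {
  L <- nrow(state$phi); K <- ncol(state$phi)
  stats <- atom_cell_stats(state, dat)
  alpha_rep <- rep(state$alpha, each = L)
  mar <- atom_log_marginals(stats, alpha_rep, hyper)
  l0 <- log(state$lam) + mar$lm0
  l1 <- log1p(-state$lam) + mar$lm1
  p1 <- 1 / (1 + exp(l0 - l1))
  psi <- as.integer(stats::runif(L * K) < p1)
  shape <- ifelse(psi == 1, hyper$a_sigma, hyper$a_kappa) + stats$count / 2
  rate <- ifelse(psi == 1, ig_rate(hyper$b_sigma) + mar$C2,
                 ig_rate(hyper$b_kappa) + stats$s_yy / 2)
  th2 <- rinvgamma(L * K, shape, rate)
  if (any(th2 <= VAR_FLOOR)) {
    stop("atom variance underflow: implementation defect", call. = FALSE)
  }
  phi <- ifelse(psi == 1,
                stats::rnorm(L * K, mar$m, sqrt(th2 / mar$A)), 0)
  list(phi = matrix(phi, L, K), th2 = matrix(th2, L, K),
       psi = matrix(psi, L, K))
}

sample_lambda <- function(state, hyper) {
  n0 <- sum(state$psi == 0)
  n1 <- sum(state$psi == 1)
  stats::rbeta(1, hyper$a_lambda + n0, hyper$b_lambda + n1)
}

alpha_posterior_params <- function(state, hyper) {
  sel <- state$psi == 1
  V0 <- hyper$V0
  prec_add <- colSums(sel * V0 / state$th2)
  mean_add <- colSums(sel * V0 * state$phi / state$th2)
  C_star <- 1 / (1 / hyper$C_alpha + prec_add)
  m_star <- C_star * (hyper$m_alpha / hyper$C_alpha + mean_add)
  list(m = m_star, C = C_star)
}

sample_alpha <- function(state, hyper) {
  p <- alpha_posterior_params(state, hyper)
  stats::rnorm(length(p$m), p$m, sqrt(p$C))
}

# Escobar-West style auxiliary-variable update of a DP concentration given
# the number of occupied clusters n_star among N items
sample_concentration <- function(conc, n_star, N, a, b) {
  eta <- stats::rbeta(1, conc + 1, N)
  rate <- b - log(eta)
  w1 <- (a + n_star - 1) / (a + n_star - 1 + N * rate)
  shape <- if (stats::runif(1) < w1) a + n_star else a + n_star - 1
  stats::rgamma(1, shape, rate = rate)
}

sample_concentrations <- function(state, dat, hyper) {
  J <- ncol(dat$y)
  I <- nrow(dat$y)
  rho <- sample_concentration(state$rho, length(unique(state$zeta)), J,
                              hyper$a_rho, hyper$b_rho)
  gamma <- vapply(seq_len(ncol(state$xi)), function(k) {
    sample_concentration(state$gamma[k], length(unique(state$xi[, k])), I,
                         hyper$a_gamma, hyper$b_gamma)
  }, numeric(1))
  list(rho = rho, gamma = gamma)
}

init_state <- function(I, J, K, L, hyper) {
  # random but dispersed start: columns are spread across distinct clusters
  # (balanced random assignment). Starting from mixed clusters lets early
  # compromise fits inflate atom variances and freeze wrong merges in place;
  # a dispersed random partition avoids those absorbing states while keeping
  # the chain initialization random.
  zeta <- as.integer(sample(rep_len(seq_len(K), J)))
  xi <- matrix(sample.int(L, I * K, replace = TRUE), I, K)
  rho <- stats::rgamma(1, hyper$a_rho, rate = hyper$b_rho)
  gamma <- stats::rgamma(K, hyper$a_gamma, rate = hyper$b_gamma)
  lam <- stats::rbeta(1, hyper$a_lambda, hyper$b_lambda)
  alpha <- stats::rnorm(K, hyper$m_alpha, sqrt(hyper$C_alpha))
  v <- c(stats::rbeta(K - 1, 1, rho), 1)
  u <- matrix(1, L, K)
  w <- matrix(0, L, K)
  for (k in seq_len(K)) {
    u[, k] <- c(stats::rbeta(L - 1, 1, gamma[k]), 1)
    w[, k] <- exp(stick_logweights(u[, k]))
  }
  psi <- matrix(as.integer(stats::runif(L * K) >= lam), L, K)
  th2 <- matrix(ifelse(psi == 1,
                       rinvgamma(L * K, hyper$a_sigma,
                                 ig_rate(hyper$b_sigma)),
                       rinvgamma(L * K, hyper$a_kappa,
                                 ig_rate(hyper$b_kappa))), L, K)
  phi <- matrix(0, L, K)
  slab <- psi == 1
  phi[slab] <- stats::rnorm(sum(slab),
                            rep(alpha, each = L)[as.vector(slab)],
                            sqrt(th2[slab] / hyper$V0))
  list(zeta = zeta, v = v, logPi = stick_logweights(v), xi = xi, u = u,
       w = w, phi = phi, th2 = th2, psi = psi, alpha = alpha, gamma = gamma,
       rho = rho, lam = lam)
}

gibbs_sweep <- function(state, dat, hyper) {
  state$zeta <- sample_column_indicators(state, dat)
  cw <- sample_column_weights(state, dat)
  state$v <- cw$v; state$logPi <- cw$logPi
  state$xi <- sample_row_indicators(state, dat)
  rw <- sample_row_weights(state, dat)
  state$u <- rw$u; state$w <- rw$w
  at <- sample_atoms(state, dat, hyper)
  state$phi <- at$phi; state$th2 <- at$th2; state$psi <- at$psi
  state$lam <- sample_lambda(state, hyper)
  state$alpha <- sample_alpha(state, hyper)
  cc <- sample_concentrations(state, dat, hyper)
  state$rho <- cc$rho; state$gamma <- cc$gamma
  state
}

# draw y from the likelihood given the current state (Geweke-style
# joint-distribution checks)
simulate_y_given_state <- function(state, dat) {
  at <- atom_at_xi(state)
  I <- nrow(dat$x); J <- ncol(dat$x)
  phi_cell <- at$phi[, state$zeta, drop = FALSE]
  th2_cell <- at$th2[, state$zeta, drop = FALSE]
  psi_cell <- at$psi[, state$zeta, drop = FALSE]
  v <- th2_cell / ifelse(psi_cell == 1, dat$nobs, 1)
  matrix(stats::rnorm(I * J, phi_cell * dat$x, sqrt(v)), I, J)
}
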