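#' Fit the nested-DP regression model to distance data
#'
#' Runs the truncated blocked Gibbs sampler for the hierarchical regression of
#' standardized observed on expected property distances,
#' \deqn{y^*_{i,j} \sim N(\beta_{i,j} x^*_{i,j},\; \sigma^2_{i,j} / c_{i,j}),}
#' with \eqn{c_{i,j} = n_i^O} when \eqn{\beta_{i,j} \neq 0} and 1 otherwise,
#' where the matrix \eqn{[\beta_{i,j}, \sigma^2_{i,j}]} carries a nested
#' infinite relational model prior: properties (columns) are clustered by a
#' stick-breaking Dirichlet process and, within each property cluster, sites
#' (rows) are clustered by a nested Dirichlet process whose spike-and-slab
#' base measure puts positive mass on exact conservation
#' (\eqn{\beta_{i,j} = 0}).
#'
#' Both truncations are finite stick-breaking approximations; pick `K` and
#' `L` with [choose_truncation()] (values of 25-35 are typical). Chains are
#' initialized from the prior with random partitions. No relabeling is done:
#' use the label-invariant summaries ([cocluster_properties()],
#' [cocluster_sites()], [beta_summary()]).
#'
#' @param data Distance tibble from [distance_data()],
#'   [read_distance_data()] or [simulate_block_data()] (columns `site`,
#'   `property`, `y_star`, `x_star`, `n_obs`).
#' @param K,L Truncation levels for the property (column) and site (row)
#'   stick-breaking processes.
#' @param iterations,burn_in,thin MCMC schedule; draws
#'   `burn_in + 1, burn_in + thin, ...` up to `iterations` are retained.
#' @param hyper A [nirm_hyperpriors()] object.
#' @param seed Integer seed; the run is bit-reproducible given the seed.
#' @param chains Number of independent chains (distinct seeds derived from
#'   `seed`, each with its own random initial partition). Draws are pooled in
#'   the summaries; per-chain identity is kept in the traces.
#' @param verbose Emit a progress message every 1000 iterations with the
#'   occupied-cluster counts.
#' @return An object of class `"nirm_fit"`: a list with `draws` (retained
#'   posterior draws of all latent quantities), `data` (the matrices the
#'   sampler saw plus site/property labels), `hyper`, and the run
#'   configuration.
#' @examples
#' \donttest{
#' sim <- simulate_block_data(sim_block_scenario(n_sites = 20,
#'   n_properties = 6, row_clusters = c(2, 2)), seed = 1)
#' fit <- fit_nirm(sim$data, K = 8, L = 8, iterations = 500, burn_in = 200,
#'                 seed = 1)
#' glance(fit)
#' }
#' @export
fit_nirm <- function(data, K = 25, L = 25, iterations = 15000,
                     burn_in = 5000, thin = 5,
                     hyper = nirm_hyperpriors(), seed = 1, chains = 1,
                     verbose = FALSE) {
  stopifnot(inherits(hyper, "nirm_hyperpriors"))
  if (K < 1 || L < 1) stop("K and L must be >= 1", call. = FALSE)
  if (burn_in >= iterations) {
    stop("burn_in must be smaller than iterations", call. = FALSE)
  }
  if (thin < 1) stop("thin must be >= 1", call. = FALSE)
  dat <- as_sampler_data(data)
  chain_seeds <- as.integer(seed) + seq_len(chains) - 1L
  runs <- lapply(chain_seeds, function(s) {
    run_chain(dat, K, L, iterations, burn_in, thin, hyper, s, verbose)
  })
  draws <- pool_chain_draws(runs)
  structure(
    list(draws = draws, data = dat, hyper = hyper,
         config = list(K = K, L = L, iterations = iterations,
                       burn_in = burn_in, thin = thin, seed = seed,
                       chains = chains, chain_seeds = chain_seeds)),
    class = "nirm_fit")
}

run_chain <- function(dat, K, L, iterations, burn_in, thin, hyper, seed,
                      verbose) {
  set.seed(seed)
  I <- nrow(dat$y); J <- ncol(dat$y)
  state <- init_state(I, J, K, L, hyper)
  keep <- seq(burn_in + 1, iterations, by = thin)
  S <- length(keep)
  out <- list(
    zeta = matrix(NA_integer_, S, J),
    xi = array(NA_integer_, c(S, I, K)),
    phi = array(NA_real_, c(S, L, K)),
    th2 = array(NA_real_, c(S, L, K)),
    psi = array(NA_integer_, c(S, L, K)),
    alpha = matrix(NA_real_, S, K),
    gamma = matrix(NA_real_, S, K),
    rho = numeric(S), lambda = numeric(S), chain = rep(seed, S)
  )
  s <- 0L
  for (it in seq_len(iterations)) {
    state <- gibbs_sweep(state, dat, hyper)
    if (it > burn_in && (it - burn_in - 1) %% thin == 0) {
      s <- s + 1L
      out$zeta[s, ] <- state$zeta
      out$xi[s, , ] <- state$xi
      out$phi[s, , ] <- state$phi
      out$th2[s, , ] <- state$th2
      out$psi[s, , ] <- state$psi
      out$alpha[s, ] <- state$alpha
      out$gamma[s, ] <- state$gamma
      out$rho[s] <- state$rho
      out$lambda[s] <- state$lam
    }
    if (verbose && it %% 1000 == 0) {
      message(sprintf("iter %d: %d property clusters, mean %.1f site clusters",
                      it, length(unique(state$zeta)),
                      mean(apply(state$xi, 2,
                                 function(z) length(unique(z))))))
    }
  }
  out
}

pool_chain_draws <- function(runs) {
  if (length(runs) == 1) return(runs[[1]])
  bind_arr <- function(name) {
    parts <- lapply(runs, `[[`, name)
    if (is.matrix(parts[[1]])) return(do.call(rbind, parts))
    if (is.array(parts[[1]])) {
      d <- dim(parts[[1]])
      out <- array(vector(mode = typeof(parts[[1]]), 0),
                   c(sum(vapply(parts, function(p) dim(p)[1], numeric(1))),
                     d[2], d[3]))
      at <- 0L
      for (p in parts) {
        out[at + seq_len(dim(p)[1]), , ] <- p
        at <- at + dim(p)[1]
      }
      return(out)
    }
    do.call(c, parts)
  }
  stats::setNames(lapply(names(runs[[1]]), bind_arr), names(runs[[1]]))
}

#' @export
print.nirm_fit <- function(x, ...) {
  S <- length(x$draws$rho)
  cat("Nested-DP property-distance regression fit\n")
  cat(sprintf("  %d sites x %d properties; K = %d, L = %d\n",
              nrow(x$data$y), ncol(x$data$y), x$config$K, x$config$L))
  cat(sprintf("  %d retained draws (%d chain%s, %d iterations, %d burn-in, thin %d)\n",
              S, x$config$chains, if (x$config$chains > 1) "s" else "",
              x$config$iterations, x$config$burn_in, x$config$thin))
  nk <- n_property_clusters(x)
  cat(sprintf("  posterior modal number of property clusters: %d\n",
              modal_count(nk)))
  invisible(x)
}

# occupied property clusters per retained draw
n_property_clusters <- function(fit) {
  apply(fit$draws$zeta, 1, function(z) length(unique(z)))
}

modal_count <- function(counts) {
  tab <- table(counts)
  as.integer(names(tab)[which.max(tab)])
}

#' Tidy posterior draws of the scalar model parameters
#'
#' @param x A `"nirm_fit"`.
#' @param ... Unused.
#' @return A long tibble with columns `chain`, `draw`, `parameter`, `value`
#'   covering \eqn{\rho}, \eqn{\lambda}, the number of occupied property
#'   clusters, and each \eqn{\alpha_k}.
#' @method tidy nirm_fit
#' @export
tidy.nirm_fit <- function(x, ...) {
  S <- length(x$draws$rho)
  base <- tibble::tibble(
    chain = rep(x$draws$chain, 3),
    draw = rep(seq_len(S), 3),
    parameter = rep(c("rho", "lambda", "n_property_clusters"), each = S),
    value = c(x$draws$rho, x$draws$lambda,
              as.numeric(n_property_clusters(x)))
  )
  K <- ncol(x$draws$alpha)
  alphas <- tibble::tibble(
    chain = rep(x$draws$chain, K),
    draw = rep(seq_len(S), K),
    parameter = rep(paste0("alpha_", seq_len(K)), each = S),
    value = as.vector(x$draws$alpha)
  )
  dplyr::bind_rows(base, alphas)
}

#' One-row model summary
#'
#' @param x A `"nirm_fit"`.
#' @param ... Unused.
#' @return A one-row tibble: draw count, truncations, posterior modal and
#'   mean number of occupied property clusters, posterior means of
#'   \eqn{\rho} and \eqn{\lambda}, and the posterior fraction of
#'   spike (exactly conserved) cells.
#' @method glance nirm_fit
#' @export
glance.nirm_fit <- function(x, ...) {
  nk <- n_property_clusters(x)
  bd <- beta_draws(x)
  tibble::tibble(
    draws = length(x$draws$rho), chains = x$config$chains,
    K = x$config$K, L = x$config$L,
    modal_property_clusters = modal_count(nk),
    mean_property_clusters = mean(nk),
    rho_mean = mean(x$draws$rho),
    lambda_mean = mean(x$draws$lambda),
    prop_beta_zero = mean(bd$beta == 0)
  )
}

#' Trace plot of scalar parameters
#'
#' @param object A `"nirm_fit"`.
#' @param parameters Which parameters from [tidy.nirm_fit()] to show.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot nirm_fit
#' @export
autoplot.nirm_fit <- function(object,
                              parameters = c("rho", "lambda",
                                             "n_property_clusters"),
                              ...) {
  td <- tidy.nirm_fit(object)
  td <- td[td$parameter %in% parameters, ]
  ggplot2::ggplot(td, ggplot2::aes(x = .data$draw, y = .data$value,
                                   colour = factor(.data$chain))) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::facet_wrap(~parameter, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "retained draw", y = NULL, colour = "chain")
}
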