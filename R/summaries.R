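# Reconstruct the per-cell regression coefficients implied by each retained
# draw: beta[s, i, j] = phi[s, xi[s, i, zeta[s, j]], zeta[s, j]], plus the
# spike indicator of the governing atom. All posterior summaries are built
# from these label-invariant quantities, so no relabeling is ever needed.
beta_draws <- function(fit) {
  dr <- fit$draws
  S <- length(dr$rho)
  I <- dim(dr$xi)[2]
  J <- ncol(dr$zeta)
  L <- dim(dr$phi)[2]
  beta <- array(NA_real_, c(S, I, J))
  zero <- array(NA_integer_, c(S, I, J))
  for (s in seq_len(S)) {
    zeta <- dr$zeta[s, ]
    xi <- matrix(dr$xi[s, , ], I)
    l_cell <- xi[, zeta, drop = FALSE]                    # I x J atom rows
    idx <- cbind(as.vector(l_cell), rep(zeta, each = I))
    phi_s <- matrix(dr$phi[s, , ], L)
    psi_s <- matrix(dr$psi[s, , ], L)
    beta[s, , ] <- matrix(phi_s[idx], I, J)
    zero[s, , ] <- matrix(1L - psi_s[idx], I, J)
  }
  list(beta = beta, zero = zero)
}

#' Posterior co-clustering of properties
#'
#' The posterior probability, for every pair of properties, of being assigned
#' to the same column cluster — the label-invariant summary of the property
#' partition.
#'
#' @param fit A `"nirm_fit"`.
#' @return A symmetric matrix of class `"nirm_cocluster"` with unit diagonal,
#'   rows/columns named by property.
#' @export
cocluster_properties <- function(fit) {
  zeta <- fit$draws$zeta
  S <- nrow(zeta)
  J <- ncol(zeta)
  probs <- matrix(0, J, J)
  for (s in seq_len(S)) {
    probs <- probs + outer(zeta[s, ], zeta[s, ], `==`)
  }
  probs <- probs / S
  dimnames(probs) <- list(fit$data$properties, fit$data$properties)
  structure(probs, class = c("nirm_cocluster", "matrix"))
}

#' Posterior co-clustering of sites within a property cluster
#'
#' The site partition is defined within a column (property) cluster, and
#' cluster labels are arbitrary, so the site partition is summarized
#' *conditionally on the cluster currently containing a named anchor
#' property*: in each retained draw, two sites co-cluster when their row
#' indicators agree in the column cluster that holds the anchor. This
#' reproduces the per-cluster row co-clustering figures without any
#' relabeling.
#'
#' @param fit A `"nirm_fit"`.
#' @param anchor_property Name of the property whose cluster's row partition
#'   is summarized.
#' @return A symmetric `"nirm_cocluster"` matrix over sites.
#' @export
cocluster_sites <- function(fit, anchor_property) {
  j <- match(anchor_property, fit$data$properties)
  if (is.na(j)) {
    stop("unknown property: ", anchor_property, call. = FALSE)
  }
  dr <- fit$draws
  S <- length(dr$rho)
  I <- dim(dr$xi)[2]
  probs <- matrix(0, I, I)
  for (s in seq_len(S)) {
    xi_k <- dr$xi[s, , dr$zeta[s, j]]
    probs <- probs + outer(xi_k, xi_k, `==`)
  }
  probs <- probs / S
  labs <- as.character(fit$data$sites)
  dimnames(probs) <- list(labs, labs)
  structure(probs, class = c("nirm_cocluster", "matrix"))
}

#' @method tidy nirm_cocluster
#' @export
tidy.nirm_cocluster <- function(x, ...) {
  m <- unclass(x)
  tibble::tibble(
    item1 = rep(rownames(m), times = ncol(m)),
    item2 = rep(colnames(m), each = nrow(m)),
    probability = as.vector(m)
  )
}

#' Heatmap of a co-clustering matrix
#'
#' @param object A `"nirm_cocluster"` matrix.
#' @param ... Unused.
#' @return A ggplot tile heatmap of pairwise same-cluster probabilities.
#' @method autoplot nirm_cocluster
#' @export
autoplot.nirm_cocluster <- function(object, ...) {
  td <- tidy.nirm_cocluster(object)
  lv <- rownames(object)
  td$item1 <- factor(td$item1, levels = lv)
  td$item2 <- factor(td$item2, levels = lv)
  ggplot2::ggplot(td, ggplot2::aes(.data$item1, .data$item2,
                                   fill = .data$probability)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "P(same cluster)") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}

#' Per-site, per-property posterior summary of the regression coefficients
#'
#' For every cell \eqn{(i, j)} of the coefficient matrix: the posterior mean
#' of \eqn{\beta_{i,j}} (spike draws enter as exact zeros), the posterior
#' probability that \eqn{\beta_{i,j} = 0}, quantiles of the *nonzero* draws,
#' and a classification of the site-property pair. A coefficient near 1 means
#' observed property change matches the neutral single-step expectation;
#' well below 1 means the property is conserved at the site; well above 1
#' means it changes radically.
#'
#' Only the strong-conservation cutoff (posterior mean < 0.4) is anchored in
#' the lysin analysis; the remaining cutoffs are reporting conventions,
#' recorded in the `thresholds` attribute of the result, and can be changed
#' freely — they do not affect the model.
#'
#' @param fit A `"nirm_fit"`.
#' @param strongly_conserved Posterior-mean cutoff below which a cell is
#'   called strongly conserved.
#' @param conserved Upper edge of the conserved band.
#' @param radical Posterior-mean cutoff above which a cell is called
#'   radical.
#' @return A tibble with one row per (site, property): `beta_mean`,
#'   `p_zero`, quantiles `q2.5`, `q25`, `q50`, `q75`, `q97.5` of the nonzero
#'   draws (`NA` when every draw is zero), and `class` in
#'   strongly_conserved / conserved / neutral / radical.
#' @export
beta_summary <- function(fit, strongly_conserved = 0.4, conserved = 0.8,
                         radical = 1.2) {
  stopifnot(strongly_conserved <= conserved, conserved <= radical)
  bd <- beta_draws(fit)
  I <- dim(bd$beta)[2]
  J <- dim(bd$beta)[3]
  qs <- c(0.025, 0.25, 0.5, 0.75, 0.975)
  out <- tidyr::expand_grid(site = fit$data$sites,
                            property = fit$data$properties)
  stats_cell <- function(i, j) {
    b <- bd$beta[, i, j]
    nz <- b[b != 0]
    q <- if (length(nz) > 0) stats::quantile(nz, qs, names = FALSE)
         else rep(NA_real_, 5)
    c(mean(b), mean(bd$zero[, i, j]), q)
  }
  m <- mapply(stats_cell,
              rep(seq_len(I), each = J),
              rep(seq_len(J), times = I))
  out$beta_mean <- m[1, ]
  out$p_zero <- m[2, ]
  out$q2.5 <- m[3, ]
  out$q25 <- m[4, ]
  out$q50 <- m[5, ]
  out$q75 <- m[6, ]
  out$q97.5 <- m[7, ]
  out$class <- cut(out$beta_mean,
                   breaks = c(-Inf, strongly_conserved, conserved, radical,
                              Inf),
                   labels = c("strongly_conserved", "conserved", "neutral",
                              "radical"),
                   right = FALSE)
  # the neutral band is closed at its upper edge: beta_mean == radical is
  # still neutral, only values strictly above are radical
  out$class[out$beta_mean == radical] <- "neutral"
  attr(out, "thresholds") <- c(strongly_conserved = strongly_conserved,
                               conserved = conserved, radical = radical)
  out
}

#' Plot posterior coefficient means by site
#'
#' Sites ordered by posterior mean for one property, with the central 90%
#' interval and quartiles of the nonzero draws — the per-cluster site
#' summary figure.
#'
#' @param fit A `"nirm_fit"`.
#' @param property Property to display.
#' @param summary Optional precomputed [beta_summary()] table.
#' @return A ggplot.
#' @export
plot_beta_sites <- function(fit, property, summary = NULL) {
  if (is.null(summary)) summary <- beta_summary(fit)
  d <- summary[summary$property == property, ]
  if (nrow(d) == 0) stop("unknown property: ", property, call. = FALSE)
  d <- d[order(d$beta_mean), ]
  d$rank <- seq_len(nrow(d))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rank)) +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$q2.5,
                                         ymax = .data$q97.5),
                            colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(y = .data$q25), shape = 8, size = 0.8) +
    ggplot2::geom_point(ggplot2::aes(y = .data$q75), shape = 8, size = 0.8) +
    ggplot2::geom_point(ggplot2::aes(y = .data$q50), size = 1.2) +
    ggplot2::geom_point(ggplot2::aes(y = .data$beta_mean), colour = "firebrick",
                        size = 0.8) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(x = "site (ordered by posterior mean)",
                  y = expression(beta[ij]), title = property)
}
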