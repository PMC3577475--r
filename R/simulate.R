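#' Block-structured coefficient scenario
#'
#' Describes a block-structured true coefficient matrix: properties (columns)
#' fall into clusters, and within each property cluster the sites (rows) fall
#' into groups; each (row group, column cluster) block shares one regression
#' coefficient. Defaults reproduce the first simulation study: 94 sites, 32
#' properties, four property clusters whose row partitions yield twelve
#' distinct blocks, block coefficients drawn from N(1, 0.25), observation
#' noise variance 0.001. The expected distances there came from a real
#' alignment; absent such data, synthetic `x*` is drawn uniformly on
#' `x_range`.
#'
#' @param n_sites,n_properties Matrix dimensions (I, J).
#' @param row_clusters Integer vector: one entry per property cluster giving
#'   its number of site groups. Its length is the number of property
#'   clusters; its sum, the number of distinct blocks.
#' @param phi_mean,phi_var Normal mean/variance for the block coefficients.
#' @param noise_var Observation noise variance.
#' @param x_range Range of the synthetic expected distances.
#' @param n_obs Constant nonsynonymous-change count attached to every site
#'   (this generator has no sequence layer).
#' @return A list of class `"sim_block_scenario"`.
#' @export
sim_block_scenario <- function(n_sites = 94, n_properties = 32,
                               row_clusters = c(3, 4, 2, 3),
                               phi_mean = 1, phi_var = 0.25,
                               noise_var = 0.001, x_range = c(0.2, 0.9),
                               n_obs = 1) {
  stopifnot(n_sites >= 1, n_properties >= length(row_clusters),
            all(row_clusters >= 1), all(row_clusters <= n_sites),
            phi_var > 0, noise_var > 0, length(x_range) == 2,
            x_range[1] > 0, x_range[2] <= 1, x_range[1] < x_range[2],
            n_obs >= 1)
  structure(list(n_sites = n_sites, n_properties = n_properties,
                 row_clusters = row_clusters, phi_mean = phi_mean,
                 phi_var = phi_var, noise_var = noise_var,
                 x_range = x_range, n_obs = n_obs),
            class = "sim_block_scenario")
}

# split n indices into g contiguous groups, as even as possible
contiguous_groups <- function(n, g) {
  sizes <- rep(n %/% g, g) + c(rep(1, n %% g), rep(0, g - n %% g))
  rep(seq_len(g), times = sizes)
}

#' Generate block-structured distance data
#'
#' Draws one block coefficient \eqn{\phi_{l,k}} per (row group, property
#' cluster) block and observations
#' \eqn{y^*_{i,j} \sim N(\phi_{block} x^*_{i,j}, \sigma^2)}. In the
#' zero-noise limit \eqn{y^*/x^*} recovers the block coefficients exactly.
#'
#' @param scenario A [sim_block_scenario()].
#' @param seed Integer seed; generation is bit-reproducible.
#' @param x_star Optional I x J matrix of expected distances in (0, 1] (e.g.
#'   from real data); when `NULL`, drawn uniformly on `scenario$x_range`.
#' @return List with `data` (tibble: `site`, `property`, `y_star`, `x_star`,
#'   `n_obs`) and `truth` (tibble: `site`, `property`, `beta_true`,
#'   `column_cluster`, `row_cluster`).
#' @examples
#' sim <- simulate_block_data(sim_block_scenario(n_sites = 10,
#'   n_properties = 4, row_clusters = c(2, 1)), seed = 7)
#' head(sim$data)
#' @export
simulate_block_data <- function(scenario, seed, x_star = NULL) {
  stopifnot(inherits(scenario, "sim_block_scenario"))
  set.seed(seed)
  I <- scenario$n_sites
  J <- scenario$n_properties
  Kc <- length(scenario$row_clusters)
  col_cluster <- contiguous_groups(J, Kc)
  row_cluster <- vapply(seq_len(Kc),
                        function(k) contiguous_groups(I,
                                                      scenario$row_clusters[k]),
                        integer(I))                       # I x Kc
  n_blocks <- sum(scenario$row_clusters)
  phi <- stats::rnorm(n_blocks, scenario$phi_mean, sqrt(scenario$phi_var))
  block_offset <- c(0, cumsum(scenario$row_clusters))[seq_len(Kc)]
  # block id and true coefficient of each cell
  block_id <- row_cluster[, col_cluster, drop = FALSE] +
    rep(block_offset[col_cluster], each = I)
  beta_true <- matrix(phi[block_id], I, J)
  if (is.null(x_star)) {
    x_star <- matrix(stats::runif(I * J, scenario$x_range[1],
                                  scenario$x_range[2]), I, J)
  } else {
    x_star <- as.matrix(x_star)
    stopifnot(nrow(x_star) == I, ncol(x_star) == J,
              all(x_star > 0), all(x_star <= 1))
  }
  y_star <- beta_true * x_star +
    stats::rnorm(I * J, 0, sqrt(scenario$noise_var))
  props <- sprintf("P%02d", seq_len(J))
  grid <- tidyr::expand_grid(site = seq_len(I), property = props)
  data <- grid |>
    dplyr::mutate(y_star = as.vector(t(y_star)),
                  x_star = as.vector(t(x_star)),
                  n_obs = scenario$n_obs)
  truth <- grid |>
    dplyr::mutate(beta_true = as.vector(t(beta_true)),
                  column_cluster = rep(col_cluster, times = I),
                  row_cluster = as.vector(t(
                    row_cluster[, col_cluster, drop = FALSE])))
  list(data = data, truth = truth)
}

#' Sequence-evolution scenario with property-biased regimes
#'
#' Describes the second simulation study: codon sequences evolve down a tree
#' under a GY94-style Markov substitution process (single-nucleotide changes
#' only, transition/transversion ratio `kappa`, uniform codon frequencies,
#' synonymous and nonsynonymous changes at equal baseline rate), with
#' disjoint site regions following different regimes. A `conserve` region
#' multiplies each nonsynonymous rate by
#' \eqn{\exp(-b \cdot d/d_{max})} for its property's distance \eqn{d}
#' (favoring property-conserving changes); a `radicalize` region uses
#' \eqn{\exp(+b \cdot d/d_{max})}. After tilting, every regime's generator is
#' rescaled to one expected substitution per codon per unit branch length, so
#' regimes stay comparable. Defaults follow the published setup: 20 sequences
#' of 90 codons, sites 1-30 neutral, 31-60 conserving volume (`M_v`), 61-90
#' radicalizing hydropathy (`h`).
#'
#' @param n_sequences,n_codons Number of tip sequences and codon sites.
#' @param regions Tibble with columns `start`, `end`, `regime`
#'   (neutral / conserve / radicalize) and `property` (`NA` for neutral);
#'   regions must disjointly cover `1:n_codons`. Default: thirds as above.
#' @param bias_strength Exponential tilting strength \eqn{b \ge 0}. The
#'   default 6 makes the conserve regime strongly property-conserving (mean
#'   per-substitution volume distance roughly half the neutral value) while
#'   keeping the process irreducible; 0 reduces every regime to the neutral
#'   baseline.
#' @param kappa Transition/transversion rate ratio of the baseline process.
#' @param branch_length Expected substitutions per codon on every branch of
#'   the balanced genealogy.
#' @return A list of class `"sim_sequence_scenario"`.
#' @export
sim_sequence_scenario <- function(n_sequences = 20, n_codons = 90,
                                  regions = NULL, bias_strength = 6,
                                  kappa = 2, branch_length = 0.2) {
  stopifnot(n_sequences >= 2, n_codons >= 3, bias_strength >= 0, kappa > 0,
            branch_length > 0)
  if (is.null(regions)) {
    b <- round(n_codons / 3)
    regions <- tibble::tibble(
      start = c(1, b + 1, 2 * b + 1),
      end = c(b, 2 * b, n_codons),
      regime = c("neutral", "conserve", "radicalize"),
      property = c(NA, "M_v", "h"))
  }
  covered <- unlist(purrr::map2(regions$start, regions$end, seq))
  if (anyDuplicated(covered) ||
      !setequal(covered, seq_len(n_codons))) {
    stop("regions must disjointly cover 1:n_codons", call. = FALSE)
  }
  if (!all(regions$regime %in% c("neutral", "conserve", "radicalize"))) {
    stop("regime must be neutral, conserve or radicalize", call. = FALSE)
  }
  if (any(regions$regime != "neutral" & is.na(regions$property))) {
    stop("biased regimes need a property", call. = FALSE)
  }
  structure(list(n_sequences = n_sequences, n_codons = n_codons,
                 regions = regions, bias_strength = bias_strength,
                 kappa = kappa, branch_length = branch_length),
            class = "sim_sequence_scenario")
}

# balanced rooted binary tree: recursively halve the tip set
balanced_tree <- function(n_tips, branch_length) {
  build <- function(labs) {
    if (length(labs) == 1) return(labs)
    h <- ceiling(length(labs) / 2)
    paste0("(", build(labs[seq_len(h)]), ",",
           build(labs[-seq_len(h)]), ")")
  }
  labs <- sprintf("t%02d", seq_len(n_tips))
  tree <- ape::read.tree(text = paste0(build(labs), ";"))
  tree$edge.length <- rep(branch_length, nrow(tree$edge))
  tree$node.label <- paste0("nd", seq_len(tree$Nnode))
  tree
}

# GY94-style baseline rate matrix over the 61 sense codons, rescaled to one
# expected substitution per unit time under uniform codon frequencies
baseline_codon_rates <- function(kappa = 2, code = genetic_code()) {
  nbhd <- codon_neighborhood(code)
  sense <- attr(nbhd, "sense_codons")
  Q <- matrix(0, length(sense), length(sense),
              dimnames = list(sense, sense))
  pos <- nbhd$position
  from_nt <- substr(nbhd$codon, pos, pos)
  to_nt <- substr(nbhd$neighbor, pos, pos)
  transition <- (from_nt %in% c("A", "G") & to_nt %in% c("A", "G")) |
    (from_nt %in% c("C", "T") & to_nt %in% c("C", "T"))
  Q[cbind(nbhd$codon, nbhd$neighbor)] <- ifelse(transition, kappa, 1)
  normalize_rates(Q)
}

normalize_rates <- function(Q) {
  diag(Q) <- 0
  rate <- mean(rowSums(Q))   # uniform equilibrium frequencies
  Q <- Q / rate
  diag(Q) <- -rowSums(Q)
  Q
}

# exponential tilting of the nonsynonymous rates by property distance
tilt_codon_rates <- function(Q, scores, maxd, bias, direction,
                             code = genetic_code()) {
  sense <- rownames(Q)
  aa <- translate_codons(sense, code)
  d <- abs(outer(scores[aa], scores[aa], `-`)) / maxd
  nonsyn <- outer(aa, aa, `!=`)
  diag(Q) <- 0
  fac <- exp(direction * bias * d)
  Q[nonsyn] <- Q[nonsyn] * fac[nonsyn]
  normalize_rates(Q)
}

#' Simulate codon sequences under property-biased regimes
#'
#' Evolves a uniformly drawn root codon sequence down the balanced genealogy
#' of the scenario, using one substitution process per regime region (see
#' [sim_sequence_scenario()]). Transition probabilities per branch are the
#' matrix exponential of the regime's rate matrix.
#'
#' @param scenario A [sim_sequence_scenario()].
#' @param seed Integer seed; generation is bit-reproducible.
#' @param table Property table supplying the scores of the regime properties.
#' @param code Genetic code.
#' @return List with `sequences` (named character vector, tips only), `tree`
#'   (the genealogy, internal nodes labeled), `node_sequences` (all nodes,
#'   including the true ancestral sequences) and `scenario`.
#' @export
simulate_codon_sequences <- function(scenario, seed,
                                     table = default_property_table(),
                                     code = genetic_code()) {
  stopifnot(inherits(scenario, "sim_sequence_scenario"))
  set.seed(seed)
  tree <- balanced_tree(scenario$n_sequences, scenario$branch_length)
  Q0 <- baseline_codon_rates(scenario$kappa, code)
  sense <- rownames(Q0)
  scores <- property_score_matrix(table)
  maxd <- property_max_distance(table)
  regime_P <- vector("list", nrow(scenario$regions))
  site_regime <- integer(scenario$n_codons)
  for (r in seq_len(nrow(scenario$regions))) {
    reg <- scenario$regions[r, ]
    Q <- if (reg$regime == "neutral" || scenario$bias_strength == 0) {
      Q0
    } else {
      if (!reg$property %in% rownames(scores)) {
        stop("property '", reg$property, "' not in the property table",
             call. = FALSE)
      }
      tilt_codon_rates(Q0, scores[reg$property, ],
                       maxd$max_distance[maxd$property == reg$property],
                       scenario$bias_strength,
                       if (reg$regime == "conserve") -1 else 1, code)
    }
    P <- as.matrix(Matrix::expm(Matrix::Matrix(Q * scenario$branch_length)))
    regime_P[[r]] <- t(apply(P, 1, cumsum))
    site_regime[reg$start:reg$end] <- r
  }

  labs <- c(tree$tip.label, tree$node.label)
  n_tip <- ape::Ntip(tree)
  states <- matrix(NA_integer_, length(labs), scenario$n_codons)
  root <- n_tip + 1L
  states[root, ] <- sample.int(length(sense), scenario$n_codons,
                               replace = TRUE)
  edges <- ape::reorder.phylo(tree, "postorder")$edge
  for (e in rev(seq_len(nrow(edges)))) {        # preorder: parents first
    parent <- edges[e, 1]; child <- edges[e, 2]
    u <- stats::runif(scenario$n_codons)
    child_state <- integer(scenario$n_codons)
    for (r in seq_along(regime_P)) {
      idx <- which(site_regime == r)
      cp <- regime_P[[r]][states[parent, idx], , drop = FALSE]
      child_state[idx] <- rowSums(cp < u[idx]) + 1L
    }
    states[child, ] <- pmin(child_state, length(sense))
  }
  seqs <- apply(states, 1, function(s) paste(sense[s], collapse = ""))
  names(seqs) <- labs
  list(sequences = seqs[tree$tip.label], tree = tree,
       node_sequences = seqs, scenario = scenario)
}

#' End-to-end simulated distance data
#'
#' Simulates tip sequences per the scenario, reconstructs ancestral sequences
#' with the Fitch parsimony fallback (production analyses should supply
#' model-based reconstructions instead) and computes the distance table for
#' the requested properties.
#'
#' @inheritParams simulate_codon_sequences
#' @param properties Properties to analyse; defaults to the five scales of
#'   the sequence simulation study — hydropathy `h`, volume `M_v`, polarity
#'   `p`, isoelectric point `pH_i`, partial specific volume `V^0`.
#' @return A distance tibble as from [distance_data()], with the simulation
#'   (`sequences`, `tree`) attached as attribute `"simulation"`.
#' @export
simulate_distance_data <- function(scenario, seed,
                                   properties = c("h", "M_v", "p", "pH_i",
                                                  "V^0"),
                                   table = default_property_table(),
                                   code = genetic_code()) {
  sim <- simulate_codon_sequences(scenario, seed, table, code)
  anc <- fitch_ancestral(sim$tree, sim$sequences)
  out <- distance_data(attr(anc, "tree"), anc,
                       new_property_table(as.data.frame(table),
                                          properties = properties),
                       code)
  attr(out, "simulation") <- sim[c("sequences", "tree")]
  out
}
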