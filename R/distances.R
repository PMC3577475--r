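#' Read a codon alignment from FASTA
#'
#' Sequence identifiers must match the tree labels exactly (tip labels for
#' extant sequences, internal node labels for reconstructed ancestral
#' sequences).
#'
#' @param path FASTA file path.
#' @return Named character vector of uppercase DNA sequences.
#' @export
read_codon_alignment <- function(path) {
  bin <- ape::read.FASTA(path)
  seqs <- toupper(vapply(as.character(bin), paste, character(1),
                         collapse = ""))
  if (length(unique(nchar(seqs))) != 1) {
    stop("sequences are not aligned (unequal lengths)", call. = FALSE)
  }
  seqs
}

# Split aligned sequences into a node x codon-site character matrix.
codon_matrix <- function(sequences) {
  if (is.null(names(sequences)) || anyDuplicated(names(sequences))) {
    stop("sequences must carry unique names matching tree node labels",
         call. = FALSE)
  }
  len <- unique(nchar(sequences))
  if (length(len) != 1) stop("sequences have unequal lengths", call. = FALSE)
  if (len %% 3 != 0) {
    stop("alignment length ", len, " is not a multiple of 3", call. = FALSE)
  }
  n_sites <- len %/% 3
  m <- matrix(NA_character_, length(sequences), n_sites,
              dimnames = list(names(sequences), NULL))
  for (s in seq_along(sequences)) {
    m[s, ] <- substring(sequences[[s]], 3 * seq_len(n_sites) - 2,
                        3 * seq_len(n_sites))
  }
  m
}

# Drop codon sites where any sequence carries a gap or an ambiguous base;
# returns the filtered matrix with the retained original 1-based site indices
# in attr "sites".
drop_gap_sites <- function(cmat, code = genetic_code()) {
  clean <- apply(cmat, 2, function(col) all(col %in% names(code)))
  out <- cmat[, clean, drop = FALSE]
  attr(out, "sites") <- which(clean)
  out
}

#' Per-site codon frequencies among extant sequences
#'
#' The frequency \eqn{F_k^i} of codon \eqn{k} at site \eqn{i} is computed from
#' the tip (extant) sequences only; reconstructed ancestral sequences do not
#' contribute.
#'
#' @param tip_matrix Character matrix of codons, tips in rows, sites in
#'   columns.
#' @return Tibble with columns `site`, `codon`, `freq`.
#' @keywords internal
site_codon_freqs <- function(tip_matrix) {
  purrr::map_dfr(seq_len(ncol(tip_matrix)), function(i) {
    tab <- table(tip_matrix[, i])
    tibble::tibble(site = i, codon = names(tab),
                   freq = as.numeric(tab) / sum(tab))
  })
}

#' Expected mean property distance at a site
#'
#' The neutral expectation of the property distance at a site: a codon
#' frequency weighted average of the absolute score differences over all
#' single-nucleotide nonsynonymous neighbors,
#' \deqn{x = \sum_k F_k \sum_l D_{k,l} \Big/ \sum_k F_k N_k,}
#' where \eqn{N_k} counts the nonsynonymous single-step neighbors of codon
#' \eqn{k} and \eqn{D_{k,l}} is the absolute score difference between the
#' amino acids of codon \eqn{k} and its \eqn{l}-th nonsynonymous neighbor.
#'
#' @param freqs Named numeric vector of codon frequencies at the site
#'   (nonnegative, summing to one over sense codons).
#' @param scores Named numeric vector of property scores over the 20 amino
#'   acids.
#' @param nbhd A [codon_neighborhood()].
#' @return The unstandardized expected distance; `NA_real_` if no
#'   nonsynonymous single-step mutation is possible at the site (such sites
#'   are dropped downstream).
#' @export
expected_site_distance <- function(freqs, scores, nbhd) {
  stopifnot(inherits(nbhd, "codon_neighborhood"))
  if (any(freqs < 0) || abs(sum(freqs) - 1) > 1e-8) {
    stop("codon frequencies must be nonnegative and sum to 1", call. = FALSE)
  }
  ns <- nbhd[nbhd$nonsynonymous, ]
  f <- freqs[match(ns$codon, names(freqs))]
  f[is.na(f)] <- 0
  d <- abs(scores[ns$aa] - scores[ns$neighbor_aa])
  denom <- sum(f)           # == sum_k F_k * N_k
  if (denom <= 0) return(NA_real_)
  sum(f * d) / denom
}

#' Nonsynonymous substitution events on a phylogeny
#'
#' Compares the codon of every parent-child node pair at every site; each
#' pair whose encoded amino acids differ is one substitution event,
#' regardless of how many nucleotides changed within the codon.
#'
#' @param tree Rooted `phylo` tree whose tip and internal node labels match
#'   the names of `sequences`.
#' @param sequences Named character vector of codon sequences for every node
#'   (tips and internal), or a codon matrix from the same.
#' @return Tibble with columns `parent`, `child`, `site`, `from_codon`,
#'   `to_codon`, `from_aa`, `to_aa`, `nonsynonymous`. Only pairs whose codons
#'   differ are listed.
#' @param code Genetic code.
#' @export
substitution_events <- function(tree, sequences, code = genetic_code()) {
  cmat <- if (is.matrix(sequences)) sequences else codon_matrix(sequences)
  labs <- node_labels(tree)
  missing <- setdiff(labs, rownames(cmat))
  if (length(missing) > 0) {
    stop("no sequence for tree node(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  cmat <- cmat[labs, , drop = FALSE]
  par_lab <- labs[tree$edge[, 1]]
  chi_lab <- labs[tree$edge[, 2]]
  empty <- tibble::tibble(parent = character(0), child = character(0),
                          site = integer(0), from_codon = character(0),
                          to_codon = character(0))
  purrr::map_dfr(seq_len(nrow(tree$edge)), function(e) {
    from <- cmat[par_lab[e], ]
    to <- cmat[chi_lab[e], ]
    hit <- which(from != to)
    if (length(hit) == 0) return(NULL)
    tibble::tibble(parent = par_lab[e], child = chi_lab[e], site = hit,
                   from_codon = unname(from[hit]),
                   to_codon = unname(to[hit]))
  }) |>
    dplyr::bind_rows(empty) |>
    dplyr::mutate(from_aa = translate_codons(.data$from_codon, code),
                  to_aa = translate_codons(.data$to_codon, code),
                  nonsynonymous = .data$from_aa != .data$to_aa)
}

node_labels <- function(tree) {
  if (!inherits(tree, "phylo")) stop("tree must be a 'phylo'", call. = FALSE)
  if (!ape::is.rooted(tree)) stop("tree must be rooted", call. = FALSE)
  if (is.null(tree$node.label) || any(tree$node.label == "")) {
    stop("internal nodes must be labeled to match ancestral sequences",
         call. = FALSE)
  }
  c(tree$tip.label, tree$node.label)
}

#' Observed and expected distance data for a site-by-property analysis
#'
#' Builds the model input: for every retained codon site \eqn{i} and property
#' \eqn{j}, the observed mean distance \eqn{y_{i,j}} (mean absolute score
#' difference over the nonsynonymous substitution events at the site, counted
#' on every branch of the phylogeny), the expected mean distance
#' \eqn{x_{i,j}} under single-step neutral mutation, their standardized
#' versions \eqn{y^*, x^*} (divided by the property's maximum pairwise
#' distance), and the number of observed nonsynonymous changes
#' \eqn{n_i^O}.
#'
#' Codon sites with an alignment gap or ambiguity in any sequence are removed
#' first; sites with no nonsynonymous change, or where no single-step
#' nonsynonymous mutation is possible, are dropped (with a message).
#'
#' @inheritParams substitution_events
#' @param table An `"aa_property_table"` of the properties to analyse.
#' @return A tibble with columns `site` (1-based position in the gap-filtered
#'   alignment), `property`, `y`, `x`, `y_star`, `x_star`, `n_obs`, ordered
#'   by site then property. Attribute `"n_sites_dropped"` records filtering.
#' @examples
#' \donttest{
#' sim <- simulate_codon_sequences(sim_sequence_scenario(n_sequences = 8,
#'                                                       n_codons = 30),
#'                                 seed = 1)
#' anc <- fitch_ancestral(sim$tree, sim$sequences)
#' dd <- distance_data(sim$tree, anc, default_property_table(c("h", "M_v")))
#' }
#' @export
distance_data <- function(tree, sequences, table, code = genetic_code()) {
  nbhd <- codon_neighborhood(code)
  cmat <- codon_matrix(sequences)
  n_raw <- ncol(cmat)
  cmat <- drop_gap_sites(cmat, code)
  if (ncol(cmat) == 0) stop("no gap-free codon sites left", call. = FALSE)
  labs <- node_labels(tree)
  tips <- tree$tip.label
  events <- substitution_events(tree, cmat, code)
  ns_events <- events[events$nonsynonymous, ]
  scores <- property_score_matrix(table)
  maxd <- property_max_distance(table)$max_distance
  names(maxd) <- table$property
  if (any(maxd == 0)) {
    stop("constant property (max distance 0): ",
         paste(names(maxd)[maxd == 0], collapse = ", "), call. = FALSE)
  }

  freqs <- site_codon_freqs(cmat[tips, , drop = FALSE])
  sites_all <- seq_len(ncol(cmat))
  x_mat <- matrix(NA_real_, length(sites_all), nrow(table))
  for (i in sites_all) {
    fr <- freqs[freqs$site == i, ]
    fv <- stats::setNames(fr$freq, fr$codon)
    for (j in seq_len(nrow(table))) {
      x_mat[i, j] <- expected_site_distance(fv, scores[j, ], nbhd)
    }
  }

  n_obs <- integer(length(sites_all))
  y_mat <- matrix(NA_real_, length(sites_all), nrow(table))
  if (nrow(ns_events) > 0) {
    for (i in sites_all) {
      ev <- ns_events[ns_events$site == i, ]
      n_obs[i] <- nrow(ev)
      if (nrow(ev) > 0) {
        for (j in seq_len(nrow(table))) {
          y_mat[i, j] <- mean(abs(scores[j, ev$from_aa] -
                                    scores[j, ev$to_aa]))
        }
      }
    }
  }

  keep <- n_obs >= 1 & !apply(x_mat, 1, anyNA)
  if (!any(keep)) {
    stop("no site retained: every site lacks a nonsynonymous change",
         call. = FALSE)
  }
  if (any(n_obs >= 1 & !keep)) {
    message(sum(n_obs >= 1 & !keep),
            " site(s) dropped: no single-step nonsynonymous mutation possible")
  }

  out <- tidyr::expand_grid(site = sites_all[keep],
                            property = table$property) |>
    dplyr::mutate(
      y = as.vector(t(y_mat[keep, , drop = FALSE])),
      x = as.vector(t(x_mat[keep, , drop = FALSE])),
      y_star = as.numeric(.data$y / maxd[.data$property]),
      x_star = as.numeric(.data$x / maxd[.data$property]),
      n_obs = rep(n_obs[keep], each = nrow(table))
    )
  attr(out, "n_sites_dropped") <-
    c(gaps = n_raw - length(sites_all), no_event = sum(!keep))
  out
}

#' Write / read the distance table
#'
#' Round-trippable TSV serialization of the table produced by
#' [distance_data()], so that distances computed once (or produced by other
#' software) can be fed straight to [fit_nirm()].
#'
#' @param data Distance tibble with columns `site`, `property`, `y`, `x`,
#'   `y_star`, `x_star`, `n_obs` (`y`, `x` optional on read).
#' @param path File path.
#' @return `read_distance_data()` returns the tibble; `write_distance_data()`
#'   returns `path` invisibly.
#' @export
write_distance_data <- function(data, path) {
  utils::write.table(data, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_data
#' @export
read_distance_data <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("site", "property", "y_star", "x_star", "n_obs")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("distance table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(df)
}
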