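#' Codon-level Fitch parsimony ancestral states
#'
#' A deterministic maximum-parsimony assignment of codon states to internal
#' nodes, treating each codon column as one multistate character. This is a
#' convenience fallback that makes the pipeline self-contained (tests,
#' simulations): it is *not* equivalent to model-based ancestral
#' reconstruction under a codon substitution model, which is what production
#' analyses should supply.
#'
#' Ties in the Fitch top-down pass are broken by lexicographic codon order.
#' Polytomies are resolved arbitrarily but deterministically via
#' [ape::multi2di()] (with a message); the returned sequences are keyed to the
#' resolved topology's node labels, and the resolved tree is attached as
#' attribute `"tree"`.
#'
#' @param tree Rooted `phylo`. Internal node labels are added (`"nd1"`,
#'   `"nd2"`, ...) where missing.
#' @param tip_sequences Named character vector of aligned codon sequences for
#'   the tips.
#' @return Named character vector of sequences for all nodes (tips first,
#'   then internal nodes), with the labeled tree as attribute `"tree"`.
#' @export
fitch_ancestral <- function(tree, tip_sequences) {
  if (!inherits(tree, "phylo")) stop("tree must be a 'phylo'", call. = FALSE)
  if (!ape::is.rooted(tree)) stop("tree must be rooted", call. = FALSE)
  if (!ape::is.binary(tree)) {
    message("resolving polytomies deterministically before Fitch pass")
    tree <- ape::multi2di(tree, random = FALSE)
  }
  if (is.null(tree$node.label) || any(tree$node.label == "")) {
    tree$node.label <- paste0("nd", seq_len(tree$Nnode))
  }
  missing <- setdiff(tree$tip.label, names(tip_sequences))
  if (length(missing) > 0) {
    stop("no sequence for tip(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  cmat <- codon_matrix(tip_sequences[tree$tip.label])

  n_tip <- ape::Ntip(tree)
  n_node <- tree$Nnode
  # post-order edge traversal: children before parents
  edges <- ape::reorder.phylo(tree, "postorder")$edge
  anc <- matrix(NA_character_, n_node, ncol(cmat))

  for (s in seq_len(ncol(cmat))) {
    sets <- vector("list", n_tip + n_node)
    for (t in seq_len(n_tip)) sets[[t]] <- cmat[t, s]
    # bottom-up: combine the children of each internal node (postorder
    # guarantees children sets are ready when the parent first appears)
    for (p in unique(edges[, 1])) {
      ch_sets <- sets[edges[edges[, 1] == p, 2]]
      inter <- Reduce(intersect, ch_sets)
      sets[[p]] <- if (length(inter) > 0) inter
                   else sort(unique(unlist(ch_sets)))
    }
    # top-down: root takes the lexicographically smallest member of its set;
    # a child keeps the parent state when allowed, else its smallest member
    state <- character(n_tip + n_node)
    root <- n_tip + 1L
    state[root] <- min(sets[[root]])
    for (e in rev(seq_len(nrow(edges)))) {
      child <- edges[e, 2]
      if (child <= n_tip) next
      p_state <- state[edges[e, 1]]
      state[child] <- if (p_state %in% sets[[child]]) p_state
                      else min(sets[[child]])
    }
    anc[, s] <- state[(n_tip + 1):(n_tip + n_node)]
  }

  anc_seq <- apply(anc, 1, paste, collapse = "")
  names(anc_seq) <- tree$node.label
  out <- c(tip_sequences[tree$tip.label], anc_seq)
  attr(out, "tree") <- tree
  out
}
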