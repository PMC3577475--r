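#' The standard genetic code
#'
#' Returns a genetic code as a named character vector mapping each of the 64
#' codons (DNA alphabet, e.g. `"ATG"`) to a one-letter amino acid code, with
#' `"*"` for stop codons. Only NCBI translation table 1 (the standard nuclear
#' code) ships with the package; the abalone lysin cDNA that motivates the
#' model uses this code.
#'
#' @param table NCBI translation table identifier. Only `1` is supported.
#' @return Named character vector of length 64.
#' @examples
#' code <- genetic_code()
#' code["ATG"]
#' @export
genetic_code <- function(table = 1) {
  if (!identical(as.integer(table), 1L)) {
    stop("only the standard genetic code (NCBI table 1) is shipped; ",
         "supply a full 64-codon map to codon_neighborhood() for other codes",
         call. = FALSE)
  }
  bases <- c("T", "C", "A", "G")
  # TCAG order, third position fastest: the conventional codon-table layout
  g <- expand.grid(b3 = bases, b2 = bases, b1 = bases,
                   stringsAsFactors = FALSE)
  codons <- paste0(g$b1, g$b2, g$b3)
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1]]
  stats::setNames(aa, codons)
}

#' Translate codons
#'
#' @param codons Character vector of codons.
#' @param code Genetic code (named character vector over 64 codons).
#' @return Character vector of one-letter amino acids (`"*"` for stops).
#' @export
translate_codons <- function(codons, code = genetic_code()) {
  validate_genetic_code(code)
  aa <- unname(code[codons])
  if (anyNA(aa)) {
    bad <- unique(codons[is.na(aa)])
    stop("not codons of the supplied genetic code: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  aa
}

validate_genetic_code <- function(code) {
  if (length(code) != 64 || is.null(names(code)) ||
      anyDuplicated(names(code)) || !all(nchar(names(code)) == 3)) {
    stop("genetic code must map all 64 codons exactly once", call. = FALSE)
  }
  if (!all(code %in% c(LETTERS, "*")) || sum(code == "*") < 1) {
    stop("genetic code values must be one-letter amino acids or '*'",
         call. = FALSE)
  }
  invisible(code)
}

#' Single-nucleotide codon neighborhoods
#'
#' Enumerates, for every sense codon, the codons reachable by a single
#' nucleotide substitution (at most nine, fewer once neighbors that are stop
#' codons are discarded) and counts the nonsynonymous ones, `N_k`. These
#' counts are the combinatorial backbone of the expected-distance computation:
#' they say how many single-step mutations away from codon `k` change the
#' encoded amino acid.
#'
#' @param code Genetic code, as returned by [genetic_code()].
#' @return A tibble with one row per (sense codon, non-stop neighbor) pair and
#'   columns `codon`, `aa`, `neighbor`, `neighbor_aa`, `position` (1-3, the
#'   nucleotide that changed) and `nonsynonymous`. The tibble carries class
#'   `"codon_neighborhood"`; use [nonsyn_counts()] for the per-codon `N_k`.
#' @examples
#' nbhd <- codon_neighborhood()
#' nonsyn_counts(nbhd)
#' @export
codon_neighborhood <- function(code = genetic_code()) {
  validate_genetic_code(code)
  sense <- sort(names(code)[code != "*"])
  bases <- c("A", "C", "G", "T")
  rows <- purrr::map_dfr(sense, function(k) {
    nt <- strsplit(k, "")[[1]]
    purrr::map_dfr(1:3, function(pos) {
      alt <- setdiff(bases, nt[pos])
      nb <- vapply(alt, function(b) {
        v <- nt; v[pos] <- b; paste(v, collapse = "")
      }, character(1))
      tibble::tibble(codon = k, neighbor = unname(nb), position = pos)
    })
  })
  rows$aa <- unname(code[rows$codon])
  rows$neighbor_aa <- unname(code[rows$neighbor])
  rows <- rows[rows$neighbor_aa != "*", ]          # changes to stops ignored
  rows$nonsynonymous <- rows$neighbor_aa != rows$aa
  out <- tibble::as_tibble(rows[, c("codon", "aa", "neighbor", "neighbor_aa",
                                    "position", "nonsynonymous")])
  class(out) <- c("codon_neighborhood", class(out))
  attr(out, "sense_codons") <- sense
  out
}

#' Per-codon nonsynonymous neighbor counts
#'
#' @param nbhd A [codon_neighborhood()] table.
#' @return Tibble with columns `codon`, `aa`, `n_neighbors` (non-stop
#'   single-step neighbors) and `n_nonsyn` (`N_k`).
#' @export
nonsyn_counts <- function(nbhd) {
  stopifnot(inherits(nbhd, "codon_neighborhood"))
  sense <- attr(nbhd, "sense_codons")
  counts <- nbhd |>
    dplyr::group_by(.data$codon, .data$aa) |>
    dplyr::summarise(n_neighbors = dplyr::n(),
                     n_nonsyn = sum(.data$nonsynonymous), .groups = "drop")
  # every sense codon appears (all have >= 1 non-stop neighbor in table 1)
  counts[match(sense, counts$codon), ]
}
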