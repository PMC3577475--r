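AA_ONE_LETTER <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Read a table of amino-acid property scores
#'
#' Properties are physicochemical scales over the 20 amino acids (hydropathy,
#' molecular volume, polarity, ...), AAindex style. The file must be
#' tab-separated with a header row and columns `property`, `accession`
#' (may be empty) and the 20 one-letter amino acid codes.
#'
#' The maximum pairwise score difference per property — the standardization
#' denominator used throughout the package so that all distances live on
#' \eqn{[0,1]} — is precomputed and attached; see [property_max_distance()].
#'
#' @param path Path to the TSV file.
#' @param properties Optional character vector of property identifiers to
#'   keep, in the requested order.
#' @return A tibble of class `"aa_property_table"` with columns `property`,
#'   `accession` and the 20 amino acids.
#' @seealso [default_property_table()] for the scales shipped with the
#'   package.
#' @export
read_property_table <- function(path, properties = NULL) {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  missing_aa <- setdiff(AA_ONE_LETTER, names(raw))
  if (length(missing_aa) > 0) {
    stop("property table is missing amino-acid column(s): ",
         paste(missing_aa, collapse = ", "), call. = FALSE)
  }
  if (!"property" %in% names(raw)) {
    stop("property table must have a 'property' column", call. = FALSE)
  }
  if (!"accession" %in% names(raw)) raw$accession <- NA_character_
  new_property_table(raw, properties = properties)
}

new_property_table <- function(df, properties = NULL) {
  if (anyDuplicated(df$property)) {
    stop("duplicate property identifier(s): ",
         paste(unique(df$property[duplicated(df$property)]), collapse = ", "),
         call. = FALSE)
  }
  for (a in AA_ONE_LETTER) {
    v <- df[[a]]
    if (is.character(v)) v <- suppressWarnings(as.numeric(v))
    if (anyNA(v)) {
      stop("non-numeric or missing score for property '",
           paste(df$property[is.na(v)], collapse = "', '"),
           "' in amino-acid column ", a, call. = FALSE)
    }
    df[[a]] <- v
  }
  if (!is.null(properties)) {
    unknown <- setdiff(properties, df$property)
    if (length(unknown) > 0) {
      stop("unknown propert", if (length(unknown) > 1) "ies: " else "y: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    df <- df[match(properties, df$property), ]
  }
  out <- tibble::as_tibble(df[, c("property", "accession", AA_ONE_LETTER)])
  class(out) <- c("aa_property_table", class(out))
  out
}

#' Property scales shipped with the package
#'
#' Seven classical scales whose published values are embedded in the package:
#' Kyte-Doolittle hydropathy (`h`), Grantham molecular volume (`M_v`),
#' polarity (`p`) and composition (`c`), Zimmerman isoelectric point (`pH_i`),
#' residue molecular weight (`M_w`) and Cohn-Edsall partial specific volume
#' (`V^0`). For other scales supply an AAindex-style TSV to
#' [read_property_table()].
#'
#' @inheritParams read_property_table
#' @return An `"aa_property_table"` tibble.
#' @examples
#' default_property_table(c("h", "M_v"))
#' @export
default_property_table <- function(properties = NULL) {
  path <- system.file("extdata", "aa_properties.tsv", package = "nirmreg",
                      mustWork = TRUE)
  read_property_table(path, properties = properties)
}

#' Maximum pairwise property distances
#'
#' For each property, the maximum absolute score difference over all 190
#' unordered pairs of amino acids. Observed and expected distances are
#' divided by this quantity, which puts every property on a common
#' \eqn{[0,1]} scale so the regression coefficients share one prior scale.
#'
#' @param table An `"aa_property_table"`.
#' @return Tibble with columns `property` and `max_distance`.
#' @export
property_max_distance <- function(table) {
  m <- property_score_matrix(table)
  tibble::tibble(
    property = rownames(m),
    max_distance = as.numeric(apply(m, 1, function(s) max(s) - min(s)))
  )
}

# rows = properties, columns = the 20 amino acids
property_score_matrix <- function(table) {
  stopifnot(inherits(table, "aa_property_table"))
  m <- as.matrix(table[, AA_ONE_LETTER])
  rownames(m) <- table$property
  m
}
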