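## The canonical BLOSUM62 amino-acid substitution matrix, embedded as a
## package constant (20 standard residues, one-letter codes). Log-odds
## half-bit scores; symmetric, non-negative diagonal.

.blosum62_aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

.blosum62 <- matrix(
  c(
     4, -1, -2, -2,  0, -1, -1,  0, -2, -1, -1, -1, -1, -2, -1,  1,  0, -3, -2,  0,
    -1,  5,  0, -2, -3,  1,  0, -2,  0, -3, -2,  2, -1, -3, -2, -1, -1, -3, -2, -3,
    -2,  0,  6,  1, -3,  0,  0,  0,  1, -3, -3,  0, -2, -3, -2,  1,  0, -4, -2, -3,
    -2, -2,  1,  6, -3,  0,  2, -1, -1, -3, -4, -1, -3, -3, -1,  0, -1, -4, -3, -3,
     0, -3, -3, -3,  9, -3, -4, -3, -3, -1, -1, -3, -1, -2, -3, -1, -1, -2, -2, -1,
    -1,  1,  0,  0, -3,  5,  2, -2,  0, -3, -2,  1,  0, -3, -1,  0, -1, -2, -1, -2,
    -1,  0,  0,  2, -4,  2,  5, -2,  0, -3, -3,  1, -2, -3, -1,  0, -1, -3, -2, -2,
     0, -2,  0, -1, -3, -2, -2,  6, -2, -4, -4, -2, -3, -3, -2,  0, -2, -2, -3, -3,
    -2,  0,  1, -1, -3,  0,  0, -2,  8, -3, -3, -1, -2, -1, -2, -1, -2, -2,  2, -3,
    -1, -3, -3, -3, -1, -3, -3, -4, -3,  4,  2, -3,  1,  0, -3, -2, -1, -3, -1,  3,
    -1, -2, -3, -4, -1, -2, -3, -4, -3,  2,  4, -2,  2,  0, -3, -2, -1, -2, -1,  1,
    -1,  2,  0, -1, -3,  1,  1, -2, -1, -3, -2,  5, -1, -3, -1,  0, -1, -3, -2, -2,
    -1, -1, -2, -3, -1,  0, -2, -3, -2,  1,  2, -1,  5,  0, -2, -1, -1, -1, -1,  1,
    -2, -3, -3, -3, -2, -3, -3, -3, -1,  0,  0, -3,  0,  6, -4, -2, -2,  1,  3, -1,
    -1, -2, -2, -1, -3, -1, -1, -2, -2, -3, -3, -1, -2, -4,  7, -1, -1, -4, -3, -2,
     1, -1,  1,  0, -1,  0,  0,  0, -1, -2, -2,  0, -1, -2, -1,  4,  1, -3, -2, -2,
     0, -1,  0, -1, -1, -1, -1, -2, -2, -1, -1, -1, -1, -2, -1,  1,  5, -2, -2,  0,
    -3, -3, -4, -4, -2, -2, -3, -2, -2, -3, -2, -3, -1,  1, -4, -3, -2, 11,  2, -3,
    -2, -2, -2, -3, -2, -1, -2, -3,  2, -1, -1, -2, -1,  3, -3, -2, -2,  2,  7, -1,
     0, -3, -3, -3, -1, -2, -2, -3, -3,  3,  1, -2,  1, -1, -2, -2,  0, -3, -1,  4
  ),
  nrow = 20, byrow = TRUE,
  dimnames = list(.blosum62_aa, .blosum62_aa)
)

#' BLOSUM62 substitution score for a pair of amino acids
#'
#' Symmetric lookup in the packaged BLOSUM62 matrix (one-letter codes for the
#' 20 standard amino acids). A score of 0 denotes a substitution neither
#' favored nor penalized by the log-odds model; for example an
#' alanine-to-valine replacement scores 0.
#'
#' @param aa1,aa2 One-letter amino-acid codes (vectors recycle).
#' @return Integer vector of substitution scores.
#' @export
#' @examples
#' blosum62_score("A", "V")
#' blosum62_score("A", "A")
blosum62_score <- function(aa1, aa2) {
  aa1 <- toupper(aa1)
  aa2 <- toupper(aa2)
  bad <- setdiff(unique(c(aa1, aa2)), .blosum62_aa)
  if (length(bad) > 0) {
    abort(paste0(
      "Nonstandard amino-acid code(s): ", paste(bad, collapse = ", "),
      ". BLOSUM62 is defined for the 20 standard residues."
    ))
  }
  unname(.blosum62[cbind(aa1, aa2)])
}

#' The packaged BLOSUM62 matrix
#'
#' Returns the embedded 20x20 BLOSUM62 matrix as a tibble in long form
#' (one row per ordered residue pair), convenient for joins and plotting.
#'
#' @return A tibble with columns `aa1`, `aa2`, `score`.
#' @export
blosum62_matrix <- function() {
  tibble(
    aa1 = rep(.blosum62_aa, each = 20L),
    aa2 = rep(.blosum62_aa, times = 20L),
    score = as.integer(t(.blosum62))[seq_len(400L)]
  )
}
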