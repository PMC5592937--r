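## Candidate-variant triage: classify coding variants against a single-gene,
## single-transcript model and rank them by predicted impact.

# Translate complete codons of a nucleotide string; incomplete trailing
# bases are ignored; codons with ambiguous bases translate to "X".
translate_codons <- function(seq) {
  n <- nchar(seq) %/% 3L
  if (n == 0L) return(character(0))
  codons <- substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  unname(aa)
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Define a single-transcript gene model
#'
#' @param name Gene label.
#' @param strand `"+"` or `"-"`.
#' @param exons A data frame with 1-based inclusive genomic `start`, `end`
#'   columns, in ascending genomic order.
#' @param cds_sequence The spliced coding sequence, 5' to 3' (already
#'   reverse-complemented for `-`-strand genes). Must be a whole number of
#'   codons, begin with a start codon, and end with a stop codon.
#' @return A list of class `gene_model`.
#' @export
gene_model <- function(name, strand, exons, cds_sequence) {
  strand <- match.arg(strand, c("+", "-"))
  exons <- as_tibble(exons)[, c("start", "end")]
  if (any(exons$end < exons$start)) abort("Exon ends precede starts.")
  if (nrow(exons) > 1 && any(diff(exons$start) <= 0)) {
    abort("Exons must be in ascending genomic order.")
  }
  cds_sequence <- toupper(cds_sequence)
  width <- sum(exons$end - exons$start + 1L)
  if (width != nchar(cds_sequence)) {
    abort(sprintf("Exons span %d bases but the CDS has %d.", width,
                  nchar(cds_sequence)))
  }
  if (nchar(cds_sequence) %% 3L != 0L) abort("CDS length is not a whole number of codons.")
  aa <- translate_codons(cds_sequence)
  if (aa[1] != "M") abort("CDS must begin with a start codon.")
  if (aa[length(aa)] != "*") abort("CDS must end with a stop codon.")
  if (any(aa[-length(aa)] == "*")) abort("CDS contains a premature stop codon.")
  structure(
    list(name = name, strand = strand, exons = exons,
         cds_sequence = cds_sequence),
    class = "gene_model"
  )
}

# Map a genomic position to its 1-based CDS coordinate, or NA when outside
# all exons.
cds_position <- function(gene, gpos) {
  ex <- gene$exons
  widths <- ex$end - ex$start + 1L
  offsets <- cumsum(c(0L, utils::head(widths, -1L)))
  hit <- which(gpos >= ex$start & gpos <= ex$end)
  if (length(hit) == 0) return(NA_integer_)
  plus_pos <- as.integer(offsets[hit] + (gpos - ex$start[hit]) + 1L)
  if (gene$strand == "+") plus_pos else as.integer(sum(widths) - plus_pos + 1L)
}

#' Maximal homopolymer run containing a position
#'
#' @param sequence A nucleotide string.
#' @param pos 1-based position within it.
#' @return A list with `base` and `run_length` of the maximal single-base
#'   run containing `pos`.
#' @export
#' @examples
#' homopolymer_run("ATGGGGGGGC", 5) # the heptaguanine run
homopolymer_run <- function(sequence, pos) {
  n <- nchar(sequence)
  if (pos < 1 || pos > n) abort("`pos` is outside the sequence.")
  chars <- strsplit(toupper(sequence), "")[[1]]
  b <- chars[pos]
  lo <- pos
  while (lo > 1 && chars[lo - 1] == b) lo <- lo - 1
  hi <- pos
  while (hi < n && chars[hi + 1] == b) hi <- hi + 1
  list(base = b, run_length = hi - lo + 1L)
}

#' Classify the coding effect of a variant
#'
#' Single-nucleotide variants are classified by comparing the translated
#' reference and alternate codons (synonymous / missense / nonsense; missense
#' calls carry the BLOSUM62 score of the substitution). Indels (VCF-style,
#' anchored on a shared leading base) whose length change is not a multiple
#' of three are frameshifts; `codons_to_stop` counts the complete novel
#' codons translated strictly before the first premature stop in the shifted
#' frame (a stop arriving as the `k+1`-th novel codon gives `k`). In-frame
#' indels are classified `inframe_indel`. Variants outside all exons are
#' `noncoding`. The homopolymer context (maximal single-base run in the CDS
#' at the variant) is reported for every coding variant.
#'
#' @param variant A one-row data frame (or list) with `pos`, `ref`, `alt`
#'   (genomic, plus-strand alleles; for `-`-strand genes alleles are
#'   reverse-complemented internally before CDS projection).
#' @param gene A [gene_model()].
#' @return A one-row tibble: `pos`, `ref`, `alt`, `category`, `ref_aa`,
#'   `alt_aa`, `blosum62`, `codons_to_stop`, `homopolymer_base`,
#'   `homopolymer_length`, `cds_pos`.
#' @export
classify_effect <- function(variant, gene) {
  stopifnot(inherits(gene, "gene_model"))
  pos <- as.integer(variant$pos)
  ref <- toupper(variant$ref)
  alt <- toupper(variant$alt)
  out <- tibble(
    pos = pos, ref = ref, alt = alt, category = NA_character_,
    ref_aa = NA_character_, alt_aa = NA_character_, blosum62 = NA_integer_,
    codons_to_stop = NA_integer_, homopolymer_base = NA_character_,
    homopolymer_length = NA_integer_, cds_pos = NA_integer_
  )
  span <- pos:(pos + nchar(ref) - 1L)
  cpos <- vapply(span, function(p) cds_position(gene, p), integer(1))
  if (all(is.na(cpos))) {
    out$category <- "noncoding"
    return(out)
  }
  cds <- gene$cds_sequence
  L <- nchar(cds)
  if (gene$strand == "-") {
    ref_c <- revcomp(ref)
    alt_c <- revcomp(alt)
    cstart <- min(cpos, na.rm = TRUE) # revcomp flips the interval
  } else {
    ref_c <- ref
    alt_c <- alt
    cstart <- cpos[1]
  }
  out$cds_pos <- cstart
  hp <- homopolymer_run(cds, min(max(cstart, 1L), L))
  out$homopolymer_base <- hp$base
  out$homopolymer_length <- hp$run_length
  if (substr(cds, cstart, cstart + nchar(ref_c) - 1L) != ref_c) {
    warn(sprintf("REF allele '%s' does not match the CDS at position %d.",
                 ref_c, cstart))
  }
  len_change <- nchar(alt_c) - nchar(ref_c)
  if (len_change == 0L && nchar(ref_c) == 1L) {
    codon_i <- (cstart - 1L) %/% 3L + 1L
    codon <- substr(cds, 3L * codon_i - 2L, 3L * codon_i)
    within <- (cstart - 1L) %% 3L + 1L
    mut_codon <- codon
    substr(mut_codon, within, within) <- alt_c
    ref_aa <- translate_codons(codon)
    alt_aa <- translate_codons(mut_codon)
    out$ref_aa <- ref_aa
    out$alt_aa <- alt_aa
    if (ref_aa == alt_aa) {
      out$category <- "synonymous"
    } else if (alt_aa == "*") {
      out$category <- "nonsense"
    } else {
      out$category <- "missense"
      out$blosum62 <- blosum62_score(ref_aa, alt_aa)
    }
    return(out)
  }
  if (len_change == 0L) abort("Multi-nucleotide substitutions are not supported.")
  # VCF-style indels share a leading anchor base on the plus strand; on the
  # minus strand the reverse-complemented anchor sits at the end.
  anchored_start <- substr(ref_c, 1L, 1L) == substr(alt_c, 1L, 1L)
  anchored_end <- substr(ref_c, nchar(ref_c), nchar(ref_c)) ==
    substr(alt_c, nchar(alt_c), nchar(alt_c))
  if (!anchored_start && !anchored_end) {
    abort("Indels must be VCF-style, anchored on a shared base.")
  }
  mutant <- paste0(
    substr(cds, 1L, cstart - 1L), alt_c,
    substr(cds, cstart + nchar(ref_c), L)
  )
  if (len_change %% 3L == 0L) {
    out$category <- "inframe_indel"
    return(out)
  }
  out$category <- "frameshift"
  # first novel base: the base after the leading anchor (or the first base
  # when the anchor trails)
  first_novel <- if (anchored_start) cstart + 1L else cstart
  first_novel_codon <- (first_novel - 1L) %/% 3L + 1L
  aa <- translate_codons(mutant)
  stops <- which(aa == "*")
  stops <- stops[stops >= first_novel_codon]
  out$codons_to_stop <- if (length(stops) == 0) {
    NA_integer_
  } else {
    as.integer(stops[1] - first_novel_codon)
  }
  out
}

#' Classify every variant in a table against a gene model
#'
#' @param records A variant table (or any data frame with `pos`, `ref`,
#'   `alt`); multi-allelic `alt` strings are split and classified per allele.
#' @param gene A [gene_model()].
#' @return A tibble with one row per (variant, alternate allele).
#' @export
classify_effects <- function(records, gene) {
  rows <- purrr::pmap_dfr(
    records[, c("pos", "ref", "alt")],
    function(pos, ref, alt) {
      purrr::map_dfr(strsplit(alt, ",", fixed = TRUE)[[1]], function(a) {
        classify_effect(list(pos = pos, ref = ref, alt = a), gene)
      })
    }
  )
  rows
}

#' Rank classified variants by predicted impact
#'
#' Ordering: frameshift and nonsense first, then missense with a negative
#' BLOSUM62 score, then missense scoring `>= 0` (neutral or conservative),
#' then in-frame indels, synonymous changes, and noncoding variants. Ties
#' keep their input order.
#'
#' @param effects A tibble of [classify_effect()] rows.
#' @return The same tibble, reordered, with an `impact_rank` column (1 =
#'   highest predicted impact class).
#' @export
rank_candidates <- function(effects) {
  if (nrow(effects) == 0) return(dplyr::mutate(effects, impact_rank = integer()))
  pri <- dplyr::case_when(
    effects$category %in% c("frameshift", "nonsense") ~ 1L,
    effects$category == "missense" & effects$blosum62 < 0 ~ 2L,
    effects$category == "missense" ~ 3L,
    effects$category == "inframe_indel" ~ 4L,
    effects$category == "synonymous" ~ 5L,
    TRUE ~ 6L
  )
  out <- effects[order(pri), , drop = FALSE]
  out$impact_rank <- sort(pri)
  out
}
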