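## Indel calling in Sanger-sequenced clones of CRISPR/Cas9-edited amplicons,
## and the single- vs paired-guide comparisons built on the calls.

#' Annotate guide RNA targets on an amplicon
#'
#' Validates that each 20-nt protospacer matches the amplicon at its stated
#' location and adds the predicted blunt cut site, 3 bp 5' of the PAM on the
#' protospacer side (standard SpCas9 geometry). `pam_pos` is the 1-based
#' amplicon coordinate of the first PAM base on the amplicon's plus strand;
#' for `-`-strand guides the protospacer is the reverse complement of the
#' amplicon downstream of the PAM. The cut site is reported as the amplicon
#' base immediately 5' (in amplicon coordinates) of the cut.
#'
#' @param guides A data frame with columns `protospacer`, `pam_pos`, `strand`
#'   (and optionally `name`).
#' @param amplicon Reference amplicon sequence.
#' @return The guides tibble with a `cut_site` column.
#' @export
guide_targets <- function(guides, amplicon) {
  guides <- as_tibble(guides)
  if (nrow(guides) == 0) abort("At least one guide target is required.")
  if (!"name" %in% names(guides)) guides$name <- paste0("g", seq_len(nrow(guides)))
  amplicon <- toupper(amplicon)
  guides$cut_site <- NA_integer_
  for (i in seq_len(nrow(guides))) {
    ps <- toupper(guides$protospacer[i])
    if (nchar(ps) != 20) abort("Protospacers must be 20 nt.")
    p <- guides$pam_pos[i]
    if (guides$strand[i] == "+") {
      found <- substr(amplicon, p - 20L, p - 1L)
      cut <- p - 4L
    } else {
      found <- revcomp(substr(amplicon, p + 3L, p + 22L))
      cut <- p + 3L
    }
    if (found != ps) {
      abort(sprintf("Protospacer of guide %s does not match the amplicon (found '%s').",
                    guides$name[i], found))
    }
    guides$cut_site[i] <- as.integer(cut)
  }
  guides
}

#' Globally align a clone sequence to the reference amplicon
#'
#' End-to-end pairwise alignment under affine gap scoring (defaults tuned for
#' near-identical Sanger clones carrying few, possibly large, indels). If the
#' reverse complement of the clone aligns better, it is flipped
#' automatically.
#'
#' @param clone_seq Clone sequence.
#' @param amplicon_ref Reference amplicon sequence.
#' @param match,mismatch Substitution scores (defaults +2 / -3).
#' @param gap_open,gap_extend Affine gap penalties, given as positive costs
#'   (defaults 10 and 1).
#' @return A list of class `clone_alignment`: gapped reference and clone
#'   strings, `score`, and `flipped`.
#' @export
align_clone <- function(clone_seq, amplicon_ref, match = 2, mismatch = -3,
                        gap_open = 10, gap_extend = 1) {
  if (nchar(clone_seq) == 0 || nchar(amplicon_ref) == 0) {
    abort("Sequences must be non-empty.")
  }
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = TRUE
  )
  ref <- Biostrings::DNAString(toupper(amplicon_ref))
  one <- function(seq) {
    Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAString(seq), subject = ref,
      type = "global", substitutionMatrix = submat,
      gapOpening = gap_open, gapExtension = gap_extend
    )
  }
  fwd <- one(toupper(clone_seq))
  rev <- one(revcomp(clone_seq))
  flipped <- Biostrings::score(rev) > Biostrings::score(fwd)
  aln <- if (flipped) rev else fwd
  structure(
    list(
      ref_gapped = as.character(Biostrings::alignedSubject(aln)),
      clone_gapped = as.character(Biostrings::alignedPattern(aln)),
      score = Biostrings::score(aln),
      flipped = flipped
    ),
    class = "clone_alignment"
  )
}

# Shift an indel to its leftmost equivalent placement within repeats
# (VCF left-alignment convention), so coordinates are reproducible.
left_align_insertion <- function(ref_chars, after, inserted) {
  q <- strsplit(inserted, "")[[1]]
  while (after >= 1 && ref_chars[after] == q[length(q)]) {
    q <- c(ref_chars[after], q[-length(q)])
    after <- after - 1L
  }
  list(after = after, inserted = paste(q, collapse = ""))
}

left_align_deletion <- function(ref_chars, start, end) {
  while (start > 1 && ref_chars[start - 1] == ref_chars[end]) {
    start <- start - 1L
    end <- end - 1L
  }
  list(start = start, end = end)
}

#' Call indels from a clone alignment
#'
#' Each contiguous gap run in the alignment becomes one indel call:
#' insertions have positive size (with the inserted sequence), deletions
#' negative size. Coordinates are on the amplicon; `start` is the first
#' deleted base for deletions and the base after which sequence is inserted
#' for insertions (0 = before the first base). Indels in repeats are
#' left-aligned.
#'
#' @param alignment A [align_clone()] result.
#' @return A tibble with columns `start`, `size`, `inserted_seq`.
#' @export
call_indels <- function(alignment) {
  stopifnot(inherits(alignment, "clone_alignment"))
  ref <- strsplit(alignment$ref_gapped, "")[[1]]
  clone <- strsplit(alignment$clone_gapped, "")[[1]]
  stopifnot(length(ref) == length(clone))
  ref_coord <- cumsum(ref != "-") # amplicon coordinate at each column
  ref_chars <- ref[ref != "-"]
  out <- tibble(start = integer(), size = integer(), inserted_seq = character())
  # deletions: gap runs in the clone
  runs <- rle(clone == "-")
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (k in which(runs$values)) {
    s <- ref_coord[starts[k]]
    e <- ref_coord[ends[k]]
    la <- left_align_deletion(ref_chars, s, e)
    out <- dplyr::bind_rows(out, tibble(
      start = la$start, size = -(e - s + 1L), inserted_seq = NA_character_
    ))
  }
  # insertions: gap runs in the reference
  runs <- rle(ref == "-")
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (k in which(runs$values)) {
    after <- if (starts[k] == 1L) 0L else ref_coord[starts[k] - 1L]
    ins <- paste(clone[starts[k]:ends[k]], collapse = "")
    la <- left_align_insertion(ref_chars, after, ins)
    out <- dplyr::bind_rows(out, tibble(
      start = la$after, size = runs$lengths[k], inserted_seq = la$inserted
    ))
  }
  dplyr::arrange(out, .data$start)
}

# Distance (bp) from an indel to a cut site; the cut falls between cut_site
# and cut_site + 1.
indel_cut_distance <- function(start, size, cut_site) {
  if (size < 0) {
    lo <- start
    hi <- start - size - 1L # last deleted base
  } else {
    lo <- start
    hi <- start + 1L
  }
  if (cut_site >= lo && cut_site <= hi) 0L else min(abs(cut_site - lo), abs(cut_site - hi))
}

#' Classify a clone's editing outcome
#'
#' `unedited` when no indels were called; `intervening_deletion` when any
#' single deletion spans two or more cut sites (the hallmark of paired-guide
#' coinjection); `local_single_site` when all indels lie within `window` bp
#' of one and the same cut site; otherwise `complex`.
#'
#' @param indels A [call_indels()] tibble.
#' @param guides A [guide_targets()] tibble (with `cut_site`).
#' @param window Radius in bp around a cut site that counts as "near"
#'   (default 10).
#' @return A one-row tibble: `classification`, `n_indels`, `edited` (any
#'   indel near a cut site).
#' @export
classify_outcome <- function(indels, guides, window = 10) {
  if (nrow(guides) == 0 || is.null(guides$cut_site)) {
    abort("`guides` must be a guide_targets() table with cut sites.")
  }
  cuts <- guides$cut_site
  if (nrow(indels) == 0) {
    return(tibble(classification = "unedited", n_indels = 0L, edited = FALSE))
  }
  dist <- vapply(seq_len(nrow(indels)), function(i) {
    vapply(cuts, function(c) indel_cut_distance(indels$start[i], indels$size[i], c),
           integer(1))
  }, integer(length(cuts)))
  dist <- matrix(dist, nrow = length(cuts)) # cuts x indels
  near <- dist <= window
  edited <- any(near)
  spans_two <- vapply(seq_len(nrow(indels)), function(i) {
    indels$size[i] < 0 && sum(dist[, i] == 0L) >= 2L
  }, logical(1))
  classification <- if (any(spans_two)) {
    "intervening_deletion"
  } else {
    near_cuts <- which(apply(near, 1, any))
    if (all(apply(near, 2, any)) && length(near_cuts) == 1L) {
      "local_single_site"
    } else {
      "complex"
    }
  }
  tibble(classification = classification, n_indels = nrow(indels), edited = edited)
}

#' Align, call, and classify a set of clones
#'
#' @param clones A data frame with `clone_id` and `seq` columns.
#' @param amplicon Reference amplicon sequence.
#' @param guides A [guide_targets()] tibble.
#' @param window Near-cut radius in bp (default 10).
#' @param ... Alignment parameters passed to [align_clone()].
#' @return A tibble with one row per clone: `clone_id`, `n_indels`,
#'   `classification`, `edited`, and an `indels` list-column.
#' @export
classify_clones <- function(clones, amplicon, guides, window = 10, ...) {
  purrr::pmap_dfr(clones[, c("clone_id", "seq")], function(clone_id, seq) {
    ind <- call_indels(align_clone(seq, amplicon, ...))
    cls <- classify_outcome(ind, guides, window)
    tibble(
      clone_id = clone_id, n_indels = cls$n_indels,
      classification = cls$classification, edited = cls$edited,
      indels = list(ind)
    )
  })
}

#' Editing efficiency tally
#'
#' Counts clones with at least one indel near a guide cut site and reports
#' the edited fraction, with the percentage rounded to the nearest integer
#' (the convention of editing-efficiency reports, e.g. 8/9 -> 89%).
#'
#' @param outcomes A [classify_clones()] tibble (or any data frame with an
#'   `edited` logical column).
#' @return A one-row tibble: `n_clones`, `n_edited`, `fraction`, `percent`.
#' @export
efficiency_tally <- function(outcomes) {
  n <- nrow(outcomes)
  k <- sum(outcomes$edited)
  tibble(
    n_clones = n, n_edited = k,
    fraction = if (n == 0) NA_real_ else k / n,
    percent = if (n == 0) NA_real_ else format_pct(k / n)
  )
}

#' One-sided exact Mann-Whitney comparison of indel sizes
#'
#' Tests whether paired-guide clones carry larger indels than single-guide
#' clones. Sizes are compared as absolute lengths. The U statistic counts
#' pairs where the paired-guide indel exceeds the single-guide indel (ties
#' count one half). The one-sided p-value (alternative: paired > single) is
#' computed by full enumeration of all group assignments when the combined
#' sample size is at most `exact_max`, and by the normal approximation with
#' tie correction and continuity correction otherwise.
#'
#' @param single_sizes,paired_sizes Numeric vectors of indel sizes (signed
#'   values are accepted; absolute lengths are compared).
#' @param exact_max Combined sample size up to which the exact enumeration is
#'   used (default 12).
#' @return A one-row tibble: `statistic` (U), `p_value`, `sidedness`,
#'   `method`.
#' @export
compare_indel_sizes <- function(single_sizes, paired_sizes, exact_max = 12) {
  if (length(single_sizes) == 0 || length(paired_sizes) == 0) {
    abort("Both groups must be non-empty.")
  }
  x <- abs(single_sizes) # group 1: single guide
  y <- abs(paired_sizes) # group 2: paired guides
  n1 <- length(x)
  n2 <- length(y)
  all_v <- c(x, y)
  r <- rank(all_v)
  u_obs <- sum(r[n1 + seq_len(n2)]) - n2 * (n2 + 1) / 2
  if (n1 + n2 <= exact_max) {
    assigns <- combn(n1 + n2, n2)
    u_all <- colSums(matrix(r[assigns], nrow = n2)) - n2 * (n2 + 1) / 2
    p <- mean(u_all >= u_obs - 1e-9)
    method <- "exact Mann-Whitney U (full enumeration)"
  } else {
    mu <- n1 * n2 / 2
    ties <- table(all_v)
    n <- n1 + n2
    sigma <- sqrt(n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1))))
    z <- (u_obs - mu - 0.5) / sigma
    p <- pnorm(z, lower.tail = FALSE)
    method <- "Mann-Whitney U (normal approximation, tie-corrected)"
  }
  tibble(statistic = u_obs, p_value = p, sidedness = "one", method = method)
}

#' Implant an indel into a sequence (fixture mutagenizer)
#'
#' Utility for constructing synthetic edited clones with known truth: insert
#' `insertion` after position `at` (`size > 0`), or delete `|size|` bases
#' starting at `at` (`size < 0`).
#'
#' @param sequence Template sequence.
#' @param at 1-based coordinate (anchor for insertions, first deleted base
#'   for deletions).
#' @param size Signed indel size.
#' @param insertion Sequence to insert (defaults to a run of `"A"` of the
#'   requested size).
#' @return The mutated sequence.
#' @export
implant_indel <- function(sequence, at, size, insertion = NULL) {
  n <- nchar(sequence)
  if (size == 0) abort("`size` must be nonzero.")
  if (size > 0) {
    insertion <- insertion %||% strrep("A", size)
    if (nchar(insertion) != size) abort("`insertion` length must equal `size`.")
    paste0(substr(sequence, 1, at), insertion, substr(sequence, at + 1, n))
  } else {
    if (at < 1 || at - size - 1 > n) abort("Deletion exceeds the sequence.")
    paste0(substr(sequence, 1, at - 1), substr(sequence, at - size, n))
  }
}

#' Random amplicon sequence
#'
#' @param length Sequence length (default 400).
#' @param seed Integer seed.
#' @return A random ACGT string.
#' @export
random_amplicon <- function(length = 400, seed = 1) {
  with_substream(seed, "amplicon", {
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
  })
}
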