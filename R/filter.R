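#' Filter variant records before scanning
#'
#' Applies the pre-scan filters: keep records whose QUAL is strictly greater
#' than `min_qual`, whose pooled sample has at least `min_depth` reads
#' covering the variant ("more than five reads" at the default 6), and whose
#' alternate allele is not found in the excluded sample (subtraction of
#' maternal variation: by default the allele must be absent from both the
#' excluded sample's genotype call and its allele depths). A multi-allelic
#' record survives if any of its alternate alleles passes all rules. Input
#' order is preserved and the filter is idempotent.
#'
#' @param records A variant table (see [read_vcf()]).
#' @param min_qual QUAL threshold, exclusive (default 40).
#' @param min_depth Minimum total reads in `pool_sample` covering the
#'   variant, inclusive (default 6).
#' @param pool_sample Sample whose depth is tested (default `"POOL"`).
#' @param exclude_sample Sample whose variants are subtracted (default
#'   `"F0_FEMALE"`); `NULL` disables subtraction.
#' @param exclude_mode How "not found in" is judged: `"both"` (default)
#'   requires zero supporting reads and no genotype call containing the
#'   allele; `"depth"` and `"genotype"` test only one of the two.
#' @return The surviving records, same schema, original order.
#' @export
filter_variants <- function(records, min_qual = 40, min_depth = 6,
                            pool_sample = "POOL", exclude_sample = "F0_FEMALE",
                            exclude_mode = c("both", "depth", "genotype")) {
  exclude_mode <- match.arg(exclude_mode)
  if (nrow(records) == 0) return(records)
  if (!paste0("ad_", pool_sample) %in% names(records)) {
    abort(sprintf("Pool sample '%s' is not present in the variant table.", pool_sample))
  }
  qual_ok <- !is.na(records$qual) & records$qual > min_qual

  pool_ad <- allele_depths(records, pool_sample)
  depth_ok <- vapply(pool_ad, sum, numeric(1)) >= min_depth

  if (is.null(exclude_sample)) {
    alt_ok <- rep(TRUE, nrow(records))
  } else {
    gt_col <- paste0("gt_", exclude_sample)
    if (!gt_col %in% names(records)) {
      abort(sprintf("Excluded sample '%s' is not present in the variant table.",
                    exclude_sample))
    }
    ex_ad <- allele_depths(records, exclude_sample)
    ex_gt <- gt_allele_indices(records[[gt_col]])
    n_alt <- lengths(strsplit(records$alt, ",", fixed = TRUE))
    alt_ok <- vapply(seq_len(nrow(records)), function(i) {
      alt_idx <- seq_len(n_alt[i]) # allele indices of alternates
      in_depth <- ex_ad[[i]][alt_idx + 1L] > 0
      in_gt <- alt_idx %in% ex_gt[[i]]
      found <- switch(exclude_mode,
        both = in_depth | in_gt,
        depth = in_depth,
        genotype = in_gt
      )
      any(!found) # record survives if ANY alternate allele is absent
    }, logical(1))
  }
  records[qual_ok & depth_ok & alt_ok, ]
}
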