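#' Proportion of pooled reads supporting the target allele
#'
#' Per record, the fraction of the pooled sample's reads that support the
#' given target ("casper") allele. Records with zero pooled depth are
#' undefined and return `NA`.
#'
#' @param records A variant table.
#' @param casper_allele Allele sequence(s) (e.g. `"G"`), recycled over
#'   records; must be the REF or one of the ALT alleles of each record.
#' @param pool_sample Pooled sample label (default `"POOL"`).
#' @return Numeric vector in `[0, 1]` (or `NA` at zero depth).
#' @export
casper_allele_proportion <- function(records, casper_allele,
                                     pool_sample = "POOL") {
  ad <- allele_depths(records, pool_sample)
  casper_allele <- rep_len(casper_allele, nrow(records))
  vapply(seq_along(ad), function(i) {
    d <- ad[[i]]
    total <- sum(d)
    if (total == 0) return(NA_real_)
    k <- match(casper_allele[i], names(d))
    if (is.na(k)) {
      abort(sprintf("Allele '%s' is not an allele of record %d.",
                    casper_allele[i], i))
    }
    d[k] / total
  }, numeric(1))
}

#' Is a record's pooled evidence mixed?
#'
#' A record is "mixed" when the pooled sample's reads support two or more
#' distinct alleles, where an allele counts as supported by at least
#' `min_support` reads. The windowed frequency of mixed records is expected
#' to be 0 at a locus where all pooled hemizygous mutants are identical by
#' descent.
#'
#' @inheritParams casper_allele_proportion
#' @param min_support Reads required to call an allele supported (default 1).
#' @return Logical vector (`NA` at zero pooled depth).
#' @export
is_mixed <- function(records, pool_sample = "POOL", min_support = 1) {
  ad <- allele_depths(records, pool_sample)
  vapply(ad, function(d) {
    if (sum(d) == 0) return(NA)
    sum(d >= min_support) >= 2L
  }, logical(1))
}

#' Enumerate sliding-window index ranges
#'
#' Windows of `window_size` variants advancing `step` variants at a time;
#' trailing partial windows are dropped. Indices are 0-based half-open.
#'
#' @param n_variants Number of variants available.
#' @param window_size Variants per window (default 50).
#' @param step Variants advanced per window (default 5).
#' @return A tibble with columns `start`, `end` (0-based, half-open); empty
#'   (with a warning) when `n_variants < window_size`.
#' @export
#' @examples
#' make_windows(60, 50, 5)
make_windows <- function(n_variants, window_size = 50, step = 5) {
  if (window_size < 1) abort("`window_size` must be at least 1.")
  if (step < 1 || step > window_size) abort("`step` must be in [1, window_size].")
  if (n_variants < window_size) {
    warn(sprintf("Only %d variants for windows of %d: no windows.",
                 n_variants, window_size))
    return(tibble(start = integer(), end = integer()))
  }
  starts <- seq.int(0L, n_variants - window_size, by = step)
  tibble(start = as.integer(starts), end = as.integer(starts + window_size))
}

#' Dual-statistic sliding-window bulk-segregant scan
#'
#' Computes, along the chromosome, two windowed statistics over the filtered
#' variants: the mean per-variant proportion of pooled reads matching the
#' target ("casper") allele, and the proportion of window variants whose
#' pooled reads are mixed (support more than one allele). The target allele
#' at each site is the allele called hemizygous/homozygous in
#' `casper_sample`; sites where that sample's call is heterozygous or
#' missing, or where the pool has zero depth, are skipped with a message.
#'
#' @param records A filtered variant table sorted by position.
#' @param window_size,step Window geometry in variants (defaults 50 and 5).
#' @param casper_sample Sample defining the target allele
#'   (default `"CASPER_MALE"`).
#' @param pool_sample Pooled sample label (default `"POOL"`).
#' @param min_support Reads needed to call an allele supported when judging
#'   mixedness (default 1).
#' @param pooled_reads If `TRUE`, the window target-allele statistic is
#'   computed from pooled read totals, `sum(target reads) / sum(all reads)`,
#'   instead of the default mean of per-variant proportions.
#' @return An object of class `casper_scan`: a list with `windows` (tibble:
#'   `window`, `start_index`, `end_index`, `start_bp`, `end_bp`,
#'   `midpoint_bp`, `n_variants`, `casper_proportion`, `mixed_proportion`,
#'   `is_peak`), `variants` (the per-variant track), `peak` (peak window
#'   number), `n_skipped`, and the scan parameters. Supports [tidy()],
#'   [glance()], [autoplot()].
#' @export
scan_bsa <- function(records, window_size = 50, step = 5,
                     casper_sample = "CASPER_MALE", pool_sample = "POOL",
                     min_support = 1, pooled_reads = FALSE) {
  if (nrow(records) == 0) abort("No variant records to scan.")
  if (is.unsorted(records$pos)) {
    abort("Records must be sorted by position; sort before scanning.")
  }
  gt_col <- paste0("gt_", casper_sample)
  if (!gt_col %in% names(records)) {
    abort(sprintf("Sample '%s' is not present in the variant table.", casper_sample))
  }
  gt_idx <- gt_allele_indices(records[[gt_col]])
  called <- lengths(gt_idx) == 1L
  ad <- allele_depths(records, pool_sample)
  depth <- vapply(ad, sum, numeric(1))
  usable <- called & depth > 0
  n_skipped <- sum(!usable)
  if (n_skipped > 0) {
    inform(sprintf(
      "Skipping %d record(s): %d without a hemizygous/homozygous '%s' call, %d with zero pooled depth.",
      n_skipped, sum(!called), casper_sample, sum(called & depth == 0)
    ))
  }
  kept <- records[usable, ]
  ad <- ad[usable]
  gt_k <- vapply(gt_idx[usable], identity, integer(1)) + 1L
  casper_reads <- vapply(seq_along(ad), function(i) ad[[i]][gt_k[i]], numeric(1))
  total_reads <- vapply(ad, sum, numeric(1))
  variants <- tibble(
    chrom = kept$chrom, pos = kept$pos,
    casper_allele = vapply(seq_along(ad), function(i) names(ad[[i]])[gt_k[i]],
                           character(1)),
    casper_reads = casper_reads, total_reads = total_reads,
    proportion = casper_reads / total_reads,
    mixed = vapply(ad, function(d) sum(d >= min_support) >= 2L, logical(1))
  )
  win <- make_windows(nrow(variants), window_size, step)
  stats <- purrr::pmap_dfr(win, function(start, end) {
    i <- (start + 1L):end
    cp <- if (pooled_reads) {
      sum(variants$casper_reads[i]) / sum(variants$total_reads[i])
    } else {
      mean(variants$proportion[i])
    }
    tibble(
      start_bp = variants$pos[start + 1L],
      end_bp = variants$pos[end],
      midpoint_bp = variants$pos[start + window_size %/% 2 + 1L],
      casper_proportion = cp,
      mixed_proportion = mean(variants$mixed[i])
    )
  })
  windows <- dplyr::bind_cols(
    tibble(
      window = seq_len(nrow(win)),
      start_index = win$start, end_index = win$end,
      chrom = rep(kept$chrom[1] %||% NA_character_, nrow(win)),
      n_variants = rep(as.integer(window_size), nrow(win))
    ),
    stats
  )
  out <- structure(
    list(
      windows = windows, variants = variants, peak = NA_integer_,
      n_skipped = n_skipped,
      params = list(
        window_size = window_size, step = step,
        casper_sample = casper_sample, pool_sample = pool_sample,
        min_support = min_support, pooled_reads = pooled_reads
      )
    ),
    class = "casper_scan"
  )
  if (nrow(windows) > 0) {
    out$peak <- locate_peak(windows)$window
    out$windows$is_peak <- out$windows$window == out$peak
  } else {
    out$windows$is_peak <- logical(0)
  }
  out
}

#' Call the peak window of a scan
#'
#' The peak is the window maximizing the target-allele proportion; ties are
#' broken by minimal mixed proportion, then by the smallest start index.
#'
#' @param x A `casper_scan` or its `windows` tibble.
#' @return The peak window as a one-row tibble.
#' @export
locate_peak <- function(x) {
  windows <- if (inherits(x, "casper_scan")) x$windows else x
  if (is.null(windows) || nrow(windows) == 0) abort("The scan has no windows.")
  ord <- order(-windows$casper_proportion, windows$mixed_proportion,
               windows$start_index)
  windows[ord[1L], ]
}

#' Windows of a scan that contain a given position
#'
#' Returns the scan windows whose variant span covers `pos`, most informative
#' first (ordered as in [locate_peak()]). Useful for reading off the
#' statistics of the window containing a known causative site.
#'
#' @param scan A `casper_scan`.
#' @param pos A 1-based bp coordinate.
#' @return A tibble of windows (possibly empty).
#' @export
windows_containing <- function(scan, pos) {
  stopifnot(inherits(scan, "casper_scan"))
  w <- scan$windows
  hit <- w[w$start_bp <= pos & w$end_bp >= pos, ]
  if (nrow(hit) == 0) return(hit)
  hit[order(-hit$casper_proportion, hit$mixed_proportion, hit$start_index), ]
}

#' @export
print.casper_scan <- function(x, ...) {
  cat(sprintf("<casper_scan> %d windows of %d variants (step %d), %d variants scanned\n",
              nrow(x$windows), x$params$window_size, x$params$step,
              nrow(x$variants)))
  if (!is.na(x$peak)) {
    p <- x$windows[x$windows$window == x$peak, ]
    cat(sprintf(
      "  peak: window %d, %s:%d-%d, casper proportion %.3f, mixed proportion %.3f\n",
      p$window, p$chrom, p$start_bp, p$end_bp,
      p$casper_proportion, p$mixed_proportion
    ))
  }
  invisible(x)
}

#' @rdname scan_bsa
#' @param x A `casper_scan`.
#' @param ... Unused.
#' @method tidy casper_scan
#' @export
tidy.casper_scan <- function(x, ...) {
  as_tibble(x$windows)
}

#' @rdname scan_bsa
#' @method glance casper_scan
#' @export
glance.casper_scan <- function(x, ...) {
  p <- locate_peak(x)
  tibble(
    n_windows = nrow(x$windows), n_variants = nrow(x$variants),
    n_skipped = x$n_skipped, peak_window = p$window,
    peak_start_bp = p$start_bp, peak_end_bp = p$end_bp,
    peak_midpoint_bp = p$midpoint_bp,
    peak_casper_proportion = p$casper_proportion,
    peak_mixed_proportion = p$mixed_proportion
  )
}

#' @rdname scan_bsa
#' @param object A `casper_scan`.
#' @method autoplot casper_scan
#' @export
autoplot.casper_scan <- function(object, ...) {
  w <- tidy(object)
  long <- tibble(
    midpoint_bp = rep(w$midpoint_bp, 2L),
    track = rep(c("casper-allele proportion", "mixed-variant proportion"),
                each = nrow(w)),
    value = c(w$casper_proportion, w$mixed_proportion)
  )
  peak <- w[w$is_peak, ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$midpoint_bp, y = .data$value,
                                     colour = .data$track)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = peak$midpoint_bp, linetype = "dashed") +
    ggplot2::scale_colour_manual(
      values = c("casper-allele proportion" = "#c0392b",
                 "mixed-variant proportion" = "#2e6da4")
    ) +
    ggplot2::labs(x = "position (bp)", y = "windowed proportion",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Write scan windows as TSV
#'
#' @param scan A `casper_scan`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scan <- function(scan, path) {
  w <- tidy(scan)
  cols <- c("chrom", "start_bp", "end_bp", "midpoint_bp", "n_variants",
            "casper_proportion", "mixed_proportion", "is_peak")
  utils::write.table(w[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
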