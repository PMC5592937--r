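## Variant tables
##
## A variant table is a tibble with one row per variant site: columns
## `chrom`, `pos`, `id`, `ref`, `alt` (comma-separated alternates), `qual`,
## `filter`, `info`, plus per-sample columns `gt_<SAMPLE>` (genotype string)
## and `ad_<SAMPLE>` (comma-separated allele read depths, ref first). This
## mirrors the minimal VCF v4.2 dialect read and written below, so write ->
## read round trips are lossless.

variant_table <- function(chrom, pos, ref, alt, qual,
                          samples, id = ".", filter = "PASS", info = ".") {
  n <- length(pos)
  out <- tibble(
    chrom = rep_len(chrom, n), pos = as.integer(pos),
    id = rep_len(id, n), ref = ref, alt = alt,
    qual = as.numeric(rep_len(qual, n)),
    filter = rep_len(filter, n), info = rep_len(info, n)
  )
  for (s in names(samples)) {
    out[[paste0("gt_", s)]] <- rep_len(samples[[s]]$gt, n)
    out[[paste0("ad_", s)]] <- rep_len(samples[[s]]$ad, n)
  }
  dplyr::arrange(out, .data$chrom, .data$pos)
}

#' Sample names of a variant table
#'
#' @param records A variant table.
#' @return Character vector of sample labels.
#' @export
vcf_samples <- function(records) {
  sub("^gt_", "", grep("^gt_", names(records), value = TRUE))
}

# Parsed allele depths for one sample: a list (one element per record) of
# integer vectors named by allele (ref first, then alternates).
allele_depths <- function(records, sample) {
  col <- paste0("ad_", sample)
  if (!col %in% names(records)) {
    abort(sprintf("Sample '%s' is not present in the variant table.", sample))
  }
  ad <- strsplit(records[[col]], ",", fixed = TRUE)
  alleles <- Map(c, records$ref, strsplit(records$alt, ",", fixed = TRUE))
  Map(function(d, a) {
    d <- suppressWarnings(as.integer(d))
    d[is.na(d)] <- 0L
    length(d) <- length(a)
    d[is.na(d)] <- 0L
    setNames(d, a)
  }, ad, alleles)
}

# Allele indices (0 = ref) present in a genotype string like "0/1", "1", "1|1".
gt_allele_indices <- function(gt) {
  lapply(strsplit(gt, "[/|]"), function(g) {
    g <- suppressWarnings(as.integer(g[g != "."]))
    unique(g[!is.na(g)])
  })
}

#' Write a variant table as a minimal VCF
#'
#' Emits VCF v4.2 with `GT:AD` FORMAT fields for each sample. Files written
#' here round-trip losslessly through [read_vcf()].
#'
#' @param records A variant table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(records, path) {
  samples <- vcf_samples(records)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=hemimapper",
    paste0("##contig=<ID=", unique(records$chrom), ">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele read depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  if (nrow(records) == 0) {
    body <- character(0)
  } else {
    cols <- list(
      records$chrom, records$pos, records$id, records$ref, records$alt,
      format_num(records$qual), records$filter, records$info, "GT:AD"
    )
    for (s in samples) {
      cols <- c(cols, list(paste(records[[paste0("gt_", s)]],
                                 records[[paste0("ad_", s)]], sep = ":")))
    }
    body <- do.call(paste, c(cols, sep = "\t"))
  }
  con <- file(path, open = "wb") # avoid platform CRLF so round trips are exact
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Read a minimal VCF into a variant table
#'
#' Parses the dialect written by [write_vcf()] (and any tab-separated VCF
#' whose FORMAT includes `GT` and `AD`). One record per body line, input
#' order preserved; malformed lines raise an error naming the line number.
#'
#' @param path Path to an uncompressed VCF file.
#' @return A variant table (tibble).
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  lines <- readLines(path)
  hdr_i <- grep("^#CHROM\t", lines)
  if (length(hdr_i) != 1) abort("Not a VCF: missing #CHROM header line.")
  hdr <- strsplit(lines[hdr_i], "\t", fixed = TRUE)[[1]]
  samples <- hdr[-(1:9)]
  body_idx <- seq_along(lines)[-seq_len(hdr_i)]
  body_idx <- body_idx[!startsWith(lines[body_idx], "#") & nzchar(lines[body_idx])]
  n_fields <- 9L + length(samples)
  parse_record <- function(i) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) != n_fields) {
      abort(sprintf(
        "Malformed VCF record at line %d: expected %d fields, found %d.",
        i, n_fields, length(fields)
      ))
    }
    fields
  }
  recs <- lapply(body_idx, parse_record)
  if (length(recs) == 0) {
    out <- tibble(
      chrom = character(), pos = integer(), id = character(),
      ref = character(), alt = character(), qual = numeric(),
      filter = character(), info = character()
    )
    for (s in samples) {
      out[[paste0("gt_", s)]] <- character()
      out[[paste0("ad_", s)]] <- character()
    }
    return(out)
  }
  m <- do.call(rbind, recs)
  pos <- suppressWarnings(as.integer(m[, 2]))
  if (anyNA(pos)) {
    abort(sprintf("Malformed VCF record at line %d: POS is not an integer.",
                  body_idx[which(is.na(pos))[1]]))
  }
  out <- tibble(
    chrom = m[, 1], pos = pos, id = m[, 3], ref = m[, 4], alt = m[, 5],
    qual = suppressWarnings(as.numeric(m[, 6])),
    filter = m[, 7], info = m[, 8]
  )
  fmt <- strsplit(m[, 9], ":", fixed = TRUE)
  gt_at <- vapply(fmt, function(f) match("GT", f), integer(1))
  ad_at <- vapply(fmt, function(f) match("AD", f), integer(1))
  if (anyNA(gt_at) || anyNA(ad_at)) {
    bad <- body_idx[which(is.na(gt_at) | is.na(ad_at))[1]]
    abort(sprintf("Malformed VCF record at line %d: FORMAT lacks GT or AD.", bad))
  }
  for (j in seq_along(samples)) {
    cells <- strsplit(m[, 9L + j], ":", fixed = TRUE)
    out[[paste0("gt_", samples[j])]] <-
      mapply(function(cell, k) cell[k], cells, gt_at)
    out[[paste0("ad_", samples[j])]] <-
      mapply(function(cell, k) cell[k], cells, ad_at)
  }
  out
}
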