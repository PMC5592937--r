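#' Build a genetic map for one chromosome
#'
#' A genetic map ties physical marker coordinates (base pairs, 1-based,
#' strictly increasing) to genetic positions (centimorgans, non-decreasing).
#' Markers at identical cM positions are fully linked: no crossover can fall
#' between them.
#'
#' @param positions Integer vector of 1-based bp coordinates, strictly
#'   increasing.
#' @param map_cM Numeric vector of genetic positions in centimorgans,
#'   non-decreasing, same length as `positions`.
#' @param chrom Chromosome label (default `"chr19"`, a fish X chromosome).
#' @return A tibble of class `genetic_map` with columns `chrom`, `pos`, `cM`.
#' @export
#' @examples
#' genetic_map(c(100L, 200L, 300L), c(0, 0.5, 1))
genetic_map <- function(positions, map_cM, chrom = "chr19") {
  if (length(positions) != length(map_cM)) {
    abort("`positions` and `map_cM` must have the same length.")
  }
  if (length(positions) < 1L) abort("A genetic map needs at least one marker.")
  if (any(diff(positions) <= 0)) abort("`positions` must be strictly increasing.")
  if (any(diff(map_cM) < 0)) abort("`map_cM` must be non-decreasing.")
  if (any(positions < 1)) abort("`positions` are 1-based bp coordinates (>= 1).")
  out <- tibble(chrom = chrom, pos = as.integer(positions), cM = as.numeric(map_cM))
  class(out) <- c("genetic_map", class(out))
  out
}

#' Uniformly spaced genetic map
#'
#' Convenience constructor: `n_sites` markers evenly spaced in both bp and cM.
#'
#' @param n_sites Number of marker sites.
#' @param span_cM Total genetic length in centimorgans.
#' @param spacing_bp Physical spacing between markers.
#' @param start_bp Coordinate of the first marker.
#' @inheritParams genetic_map
#' @return A `genetic_map` tibble.
#' @export
map_uniform <- function(n_sites = 500, span_cM = 100, spacing_bp = 20000L,
                        start_bp = 1000000L, chrom = "chr19") {
  genetic_map(
    positions = start_bp + spacing_bp * (seq_len(n_sites) - 1L),
    map_cM = seq(0, span_cM, length.out = n_sites),
    chrom = chrom
  )
}

#' Genetic map with a fully linked central block
#'
#' `n_block` consecutive markers share one cM position (a zero-recombination
#' block, emulating tight linkage around a causative site), flanked on each
#' side by `n_flank` markers spaced `flank_spacing_cM` apart.
#'
#' @param n_block Markers inside the linked block.
#' @param n_flank Markers on each flank.
#' @param flank_spacing_cM Genetic spacing between flanking markers.
#' @inheritParams map_uniform
#' @return A `genetic_map` tibble; the attribute `block` holds the (1-based)
#'   marker index range of the linked block.
#' @export
map_linked_block <- function(n_block = 80, n_flank = 60, flank_spacing_cM = 2,
                             spacing_bp = 20000L, start_bp = 1000000L,
                             chrom = "chr19") {
  n <- n_flank + n_block + n_flank
  left <- flank_spacing_cM * seq_len(n_flank)
  block_cM <- max(c(0, left))
  cM <- c(left, rep(block_cM, n_block), block_cM + flank_spacing_cM * seq_len(n_flank))
  out <- genetic_map(
    positions = start_bp + spacing_bp * (seq_len(n) - 1L),
    map_cM = cM,
    chrom = chrom
  )
  attr(out, "block") <- c(n_flank + 1L, n_flank + n_block)
  out
}

#' Simulate founder X haplotypes for the mapping cross
#'
#' Generates the four founder X haplotypes of the pedigree: the X of the
#' original mutant male (carrying the causative allele), the two X's of the
#' F0 female he was outcrossed to, and the X contributed to F2 females by
#' wild-type males. Marker sites are scan-informative by construction -- the
#' mutant male's X carries the alternate allele and the F0 female is
#' homozygous reference -- because those are exactly the sites that survive
#' the F0-subtraction filter and inform the scan. A configurable fraction of
#' additional sites carry the alternate allele in the F0 female (shared
#' population variation); these exercise the subtraction filter and are
#' removed by it.
#'
#' @param map A `genetic_map`.
#' @param causative_index Marker index (1-based) of the causative site.
#' @param shared_frac Fraction of sites (besides the causative one) where the
#'   F0 female also carries the alternate allele (default 0.3).
#' @param seed Integer seed.
#' @return A tibble of class `founder_haplotypes` with columns `site`, `pos`,
#'   `ref`, `alt`, `casper_X`, `grandmother_X`, `f0_female_X1`, `f0_female_X2`
#'   (alleles coded 0 = ref, 1 = alt) and attribute `causative_index`.
#' @export
simulate_founders <- function(map, causative_index = NULL, shared_frac = 0.3,
                              seed = 1) {
  stopifnot(inherits(map, "genetic_map"))
  n <- nrow(map)
  causative_index <- causative_index %||% as.integer(ceiling(n / 2))
  if (causative_index < 1 || causative_index > n) {
    abort("`causative_index` must index a map site.")
  }
  if (shared_frac < 0 || shared_frac >= 1) abort("`shared_frac` must be in [0, 1).")
  bases <- c("A", "C", "G", "T")
  with_substream(seed, "founders", {
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
    shared <- runif(n) < shared_frac
    shared[causative_index] <- FALSE
    # informative sites: mutant X = alt, F0 female hom ref
    casper_X <- rep(1L, n)
    f0_1 <- rep(0L, n)
    f0_2 <- rep(0L, n)
    # shared sites: F0 female carries the alt (het or hom), mutant X either
    casper_X[shared] <- rbinom(sum(shared), 1L, 0.5)
    f0_1[shared] <- 1L
    f0_2[shared] <- rbinom(sum(shared), 1L, 0.5)
    out <- tibble(
      site = seq_len(n), pos = map$pos, ref = ref, alt = unname(alt),
      casper_X = casper_X, grandmother_X = 0L,
      f0_female_X1 = f0_1, f0_female_X2 = f0_2
    )
    attr(out, "causative_index") <- as.integer(causative_index)
    class(out) <- c("founder_haplotypes", class(out))
    out
  })
}

#' Describe the mapping cross to simulate
#'
#' Bundles founders, map, F2 cohort size, mutant-male pool size, and
#' sequencing parameters into one design object consumed by
#' [simulate_f2_cohort()] and [simulate_pooled_reads()].
#'
#' @param founders A `founder_haplotypes` tibble.
#' @param map The `genetic_map` the founders were simulated on.
#' @param n_f2 Number of F2 offspring to simulate.
#' @param pool_size Number of mutant F2 males pooled for sequencing
#'   (default 47). Must not exceed the expected number of mutant males,
#'   `n_f2 / 4`.
#' @param mean_depth Expected pooled read depth per site (default 12).
#' @param error_rate Per-read probability of substitution to the other
#'   allele (default 0; must be `< 0.5`).
#' @param qual Constant QUAL value stamped on simulated variant records
#'   (default 60, interacting with the downstream `qual > 40` filter).
#' @param seed Integer seed fanned out to named substreams.
#' @return A list of class `cross_design`.
#' @export
cross_design <- function(founders, map, n_f2 = 300, pool_size = 47,
                         mean_depth = 12, error_rate = 0, qual = 60, seed = 1) {
  stopifnot(inherits(founders, "founder_haplotypes"), inherits(map, "genetic_map"))
  if (nrow(founders) != nrow(map)) abort("founders and map describe different site sets.")
  if (n_f2 <= 0) abort("`n_f2` must be positive.")
  if (pool_size < 1 || pool_size > n_f2 / 4) {
    abort("`pool_size` must be at least 1 and no larger than the expected number of mutant males (n_f2 / 4).")
  }
  if (mean_depth <= 0) abort("`mean_depth` must be positive.")
  if (error_rate < 0 || error_rate >= 0.5) abort("`error_rate` must be in [0, 0.5).")
  structure(
    list(
      founders = founders, map = map, n_f2 = as.integer(n_f2),
      pool_size = as.integer(pool_size), mean_depth = mean_depth,
      error_rate = error_rate, qual = qual, seed = seed
    ),
    class = "cross_design"
  )
}

#' @export
print.cross_design <- function(x, ...) {
  cat("<cross_design>\n")
  cat(sprintf(
    "  %d map sites on %s; causative site index %d\n",
    nrow(x$map), x$map$chrom[1], attr(x$founders, "causative_index")
  ))
  cat(sprintf(
    "  n_f2 = %d, pool_size = %d, mean_depth = %g, error_rate = %g, seed = %s\n",
    x$n_f2, x$pool_size, x$mean_depth, x$error_rate, format(x$seed)
  ))
  invisible(x)
}
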