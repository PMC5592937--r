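#' Simulate one meiotic gamete
#'
#' Draws a recombinant gamete from a pair of parental haplotypes under a
#' no-interference (Haldane) model: the crossover count in each marker
#' interval is Poisson with mean equal to the interval's genetic length in
#' Morgans, and the transmitted parent switches at each crossover. Uses the
#' current RNG state.
#'
#' @param hapA,hapB Parental allele vectors (same length as the map).
#' @param map A [genetic_map()] with one row per site.
#' @return An allele vector; each element equals one parent's allele at that
#'   site.
#' @export
simulate_meiosis <- function(hapA, hapB, map) {
  stopifnot(inherits(map, "genetic_map"))
  n <- nrow(map)
  if (length(hapA) != n || length(hapB) != n) {
    abort("Parental haplotypes must match the map length.")
  }
  start <- rbinom(1L, 1L, 0.5)
  if (n == 1L) {
    use_b <- start
  } else {
    crossovers <- rpois(n - 1L, diff(map$cM) / 100)
    use_b <- (start + c(0L, cumsum(crossovers))) %% 2L
  }
  ifelse(use_b == 1L, hapB, hapA)
}

#' Simulate the F2 cohort of the mapping cross
#'
#' Realizes the pedigree: the original hemizygous mutant male is outcrossed
#' to the F0 female; all F1 females are carriers (paternal X = the mutant
#' X); F1 females are outcrossed to wild-type males, and each F2 draws its
#' maternal X from an F1 female gamete. Sex is an independent fair coin. An
#' F2 is mutant iff it is male and its maternal X carries the causative
#' allele (X-linked recessive, males hemizygous).
#'
#' @param design A [cross_design()].
#' @param n_f1_females Number of F1 carrier females mothering the cohort
#'   (default 6, one per outcross).
#' @return A tibble with one row per F2: `id`, `sex`, `is_mutant`,
#'   `maternal_X` (list-column of allele vectors), `paternal` (list-column:
#'   `"Y"` for males, an X allele vector for females).
#' @export
simulate_f2_cohort <- function(design, n_f1_females = 6L) {
  stopifnot(inherits(design, "cross_design"))
  f <- design$founders
  map <- design$map
  ci <- attr(f, "causative_index")
  causative_allele <- f$casper_X[ci]
  with_substream(design$seed, "cohort", {
    # F1 carrier females: paternal X is the mutant male's X; maternal X is a
    # gamete of the F0 female.
    f1_maternal <- lapply(seq_len(n_f1_females), function(i) {
      simulate_meiosis(f$f0_female_X1, f$f0_female_X2, map)
    })
    n <- design$n_f2
    mothers <- sample.int(n_f1_females, n, replace = TRUE)
    sex <- ifelse(runif(n) < 0.5, "male", "female")
    maternal_X <- lapply(seq_len(n), function(i) {
      simulate_meiosis(f$casper_X, f1_maternal[[mothers[i]]], map)
    })
    paternal <- lapply(seq_len(n), function(i) {
      if (sex[i] == "male") "Y" else f$grandmother_X
    })
    is_mutant <- sex == "male" &
      vapply(maternal_X, function(h) h[ci] == causative_allele, logical(1))
    tibble(
      id = seq_len(n), sex = sex, is_mutant = is_mutant,
      maternal_X = maternal_X, paternal = paternal
    )
  })
}

#' Simulate pooled sequencing of mutant F2 males
#'
#' Emulates pooled short-read sequencing of the hemizygous mutant males plus
#' the two founder libraries (original mutant male, F0 female). Per site the
#' pooled depth is Poisson(`mean_depth`); each read's allele is drawn
#' uniformly from the pooled X haplotypes and corrupted to the other allele
#' with probability `error_rate` (reads being i.i.d. given the pool allele
#' frequency q, the alternate-read count is drawn as one
#' Binomial(depth, q(1-e) + (1-q)e) variate). Founder samples are sequenced
#' at the same mean depth; their GT columns carry the true genotypes.
#'
#' @param pool A tibble of F2 individuals (rows of [simulate_f2_cohort()]
#'   output); all must be mutant males.
#' @param design The [cross_design()] used to simulate them.
#' @return A variant table (see [read_vcf()]) with samples `POOL`,
#'   `CASPER_MALE`, `F0_FEMALE`, sorted by position.
#' @export
simulate_pooled_reads <- function(pool, design) {
  stopifnot(inherits(design, "cross_design"))
  if (nrow(pool) == 0) abort("The sequencing pool is empty.")
  if (!all(pool$is_mutant)) abort("All pooled individuals must be mutant males.")
  f <- design$founders
  n <- nrow(f)
  e <- design$error_rate
  hap <- do.call(cbind, pool$maternal_X) # sites x individuals
  q_alt <- rowMeans(hap == 1L)
  with_substream(design$seed, "reads", {
    depth <- rpois(n, design$mean_depth)
    alt_reads <- rbinom(n, depth, q_alt * (1 - e) + (1 - q_alt) * e)
    ref_reads <- depth - alt_reads

    cm_depth <- rpois(n, design$mean_depth)
    cm_p <- ifelse(f$casper_X == 1L, 1 - e, e)
    cm_alt <- rbinom(n, cm_depth, cm_p)

    f0_dose <- (f$f0_female_X1 + f$f0_female_X2) / 2
    f0_depth <- rpois(n, design$mean_depth)
    f0_alt <- rbinom(n, f0_depth, f0_dose * (1 - e) + (1 - f0_dose) * e)

    pool_gt <- dplyr::case_when(
      alt_reads > 0 & ref_reads > 0 ~ "0/1",
      alt_reads > 0 ~ "1/1",
      TRUE ~ "0/0"
    )
    variant_table(
      chrom = design$map$chrom,
      pos = f$pos,
      ref = f$ref,
      alt = f$alt,
      qual = rep(design$qual, n),
      samples = list(
        POOL = list(gt = pool_gt, ad = paste(ref_reads, alt_reads, sep = ",")),
        CASPER_MALE = list(
          gt = as.character(f$casper_X),
          ad = paste(cm_depth - cm_alt, cm_alt, sep = ",")
        ),
        F0_FEMALE = list(
          gt = c("0/0", "0/1", "1/1")[f$f0_female_X1 + f$f0_female_X2 + 1L],
          ad = paste(f0_depth - f0_alt, f0_alt, sep = ",")
        )
      )
    )
  })
}

#' Simulate the full mapping experiment
#'
#' Convenience wrapper: simulates the F2 cohort, pools the first
#' `pool_size` mutant males, and simulates pooled sequencing.
#'
#' @param design A [cross_design()].
#' @return A variant table of simulated variant records.
#' @export
simulate_experiment <- function(design) {
  cohort <- simulate_f2_cohort(design)
  mutants <- dplyr::filter(cohort, .data$is_mutant)
  if (nrow(mutants) < design$pool_size) {
    abort(sprintf(
      "Cohort yielded %d mutant males but pool_size is %d; increase n_f2.",
      nrow(mutants), design$pool_size
    ))
  }
  simulate_pooled_reads(utils::head(mutants, design$pool_size), design)
}
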