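# Small in-code fixtures shared across tests.

# A hand-built variant table in the package schema (samples POOL,
# CASPER_MALE, F0_FEMALE). Vector arguments recycle.
toy_records <- function(pos = NULL,
                        qual = 60,
                        ref = "A", alt = "G",
                        pool_ad = "6,6", pool_gt = "0/1",
                        cm_ad = "0,10", cm_gt = "1",
                        f0_ad = "10,0", f0_gt = "0/0",
                        chrom = "chr19", n = NULL) {
  if (is.null(n)) {
    n <- max(length(pos), length(qual), length(pool_ad),
             length(f0_ad), length(f0_gt), length(cm_gt),
             length(ref), length(alt), 1L)
  }
  if (is.null(pos)) pos <- seq_len(n) * 100L
  tibble::tibble(
    chrom = rep_len(chrom, n), pos = as.integer(rep_len(pos, n)),
    id = ".", ref = rep_len(ref, n), alt = rep_len(alt, n),
    qual = as.numeric(rep_len(qual, n)), filter = "PASS", info = ".",
    gt_POOL = rep_len(pool_gt, n), ad_POOL = rep_len(pool_ad, n),
    gt_CASPER_MALE = rep_len(cm_gt, n), ad_CASPER_MALE = rep_len(cm_ad, n),
    gt_F0_FEMALE = rep_len(f0_gt, n), ad_F0_FEMALE = rep_len(f0_ad, n)
  )
}

# A small mapping design that runs in well under a second.
small_design <- function(seed = 1, n_f2 = 200, pool_size = 20,
                         error_rate = 0, shared_frac = 0,
                         map = map_uniform(n_sites = 120, span_cM = 60)) {
  founders <- simulate_founders(map, shared_frac = shared_frac, seed = seed)
  cross_design(founders, map, n_f2 = n_f2, pool_size = pool_size,
               mean_depth = 12, error_rate = error_rate, seed = seed)
}

# Independent Mann-Whitney oracle: enumerate every assignment of the pooled
# values into the two groups and count, per assignment, the pairs where a
# "paired" value exceeds a "single" value (ties half). Deliberately avoids
# the rank-sum formulation used by the implementation.
mw_enumeration_oracle <- function(single, paired) {
  x <- abs(single)
  y <- abs(paired)
  v <- c(x, y)
  n2 <- length(y)
  u_of <- function(yy, xx) sum(outer(yy, xx, ">")) + 0.5 * sum(outer(yy, xx, "=="))
  u_obs <- u_of(y, x)
  assigns <- utils::combn(length(v), n2)
  u_all <- apply(assigns, 2, function(idx) u_of(v[idx], v[-idx]))
  mean(u_all >= u_obs - 1e-9)
}
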