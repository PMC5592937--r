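# A fixed 120-bp amplicon with a '+' guide (PAM "TGG" at 61) and a '-'
# guide (PAM "CCA" at 88), mirroring a paired-guide editing experiment.
edit_fixture <- function(seed = 17) {
  amp <- random_amplicon(120, seed = seed)
  substr(amp, 61, 63) <- "TGG"
  substr(amp, 88, 90) <- "CCA"
  guides <- guide_targets(
    data.frame(
      name = c("g1", "g2"),
      protospacer = c(substr(amp, 41, 60),
                      as.character(Biostrings::reverseComplement(
                        Biostrings::DNAString(substr(amp, 91, 110))))),
      pam_pos = c(61L, 88L),
      strand = c("+", "-")
    ),
    amp
  )
  list(amp = amp, guides = guides)
}

test_that("guide targets validate protospacers and place the cut 3 bp from the PAM", {
  fx <- edit_fixture()
  expect_equal(fx$guides$cut_site, c(61L - 4L, 88L + 3L))
  bad <- fx$guides
  bad$protospacer[1] <- strrep("A", 20)
  expect_error(guide_targets(bad[, -ncol(bad)], fx$amp), "does not match")
})

test_that("self-alignment is gapless and scores as pure matches", {
  amp <- random_amplicon(80, seed = 3)
  aln <- align_clone(amp, amp)
  expect_false(grepl("-", aln$ref_gapped, fixed = TRUE))
  expect_equal(aln$score, 2 * 80)
  expect_equal(nrow(call_indels(aln)), 0)
  expect_error(align_clone("", amp), "non-empty")
})

test_that("a clean deletion yields one call with the affine-gap score", {
  amp <- random_amplicon(100, seed = 5)
  clone <- implant_indel(amp, at = 40, size = -5)
  aln <- align_clone(clone, amp)
  calls <- call_indels(aln)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$size, -5)
  # all 95 aligned bases match; one affine gap of length 5
  expect_equal(aln$score, 2 * 95 - (10 + 1 * 5))
  # applying the (left-aligned) call to the reference reproduces the clone
  expect_equal(implant_indel(amp, at = calls$start, size = -5), clone)
})

test_that("reverse-complemented clones are flipped automatically", {
  amp <- random_amplicon(100, seed = 6)
  clone <- implant_indel(amp, at = 50, size = -4)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(clone)))
  aln <- align_clone(rc, amp)
  expect_true(aln$flipped)
  expect_equal(call_indels(aln)$size, -4)
})

test_that("insertions in homopolymers are left-aligned", {
  #          123456789012345
  ref <-   "AACTGGGGTCAACTG"
  clone <- "AACTGGGGGTCAACTG" # one G added to the GGGG run (positions 5-8)
  calls <- call_indels(align_clone(clone, ref))
  expect_equal(nrow(calls), 1)
  expect_equal(calls$size, 1)
  expect_equal(calls$start, 4L) # 5' end of the run
  expect_equal(calls$inserted_seq, "G")
})

test_that("implanted indels are recovered exactly (size) across a size range", {
  fx <- edit_fixture()
  cut <- fx$guides$cut_site[1]
  for (size in c(1, 3, 8, 20, -1, -6, -20)) {
    clone <- implant_indel(fx$amp, at = cut, size = size)
    calls <- call_indels(align_clone(clone, fx$amp))
    expect_equal(nrow(calls), 1)
    expect_equal(calls$size, size)
    out <- classify_outcome(calls, fx$guides, window = 10)
    expect_true(out$edited)
  }
  expect_error(implant_indel("ACGT", 2, 0), "nonzero")
})

test_that("outcomes classify as unedited / local / intervening / complex", {
  fx <- edit_fixture()
  g <- fx$guides # cuts at 57 and 91

  expect_equal(classify_outcome(tibble::tibble(start = integer(), size = integer(),
                                               inserted_seq = character()),
                                g)$classification, "unedited")

  local <- tibble::tibble(start = 58L, size = 2L, inserted_seq = "AA")
  expect_equal(classify_outcome(local, g)$classification, "local_single_site")

  # a deletion spanning both cut sites
  spanning <- tibble::tibble(start = 50L, size = -45L, inserted_seq = NA)
  expect_equal(classify_outcome(spanning, g)$classification,
               "intervening_deletion")

  far <- tibble::tibble(start = 5L, size = -3L, inserted_seq = NA)
  expect_equal(classify_outcome(far, g)$classification, "complex")
  expect_false(classify_outcome(far, g)$edited)

  # indels local to each of the two cuts: edited, but not a single site
  both <- tibble::tibble(start = c(58L, 90L), size = c(2L, -2L),
                         inserted_seq = c("AA", NA))
  expect_equal(classify_outcome(both, g)$classification, "complex")
  # order invariance
  expect_equal(classify_outcome(both[2:1, ], g), classify_outcome(both, g))

  expect_error(classify_outcome(local, data.frame()), "guide")
})

test_that("clone sets classify end-to-end and tally efficiency", {
  fx <- edit_fixture()
  cuts <- fx$guides$cut_site
  clones <- tibble::tibble(
    clone_id = paste0("c", 1:5),
    seq = c(
      fx$amp,                                                    # unedited
      implant_indel(fx$amp, at = cuts[1], size = 2),             # local
      implant_indel(fx$amp, at = cuts[1] - 2, size = -6),        # local del
      implant_indel(fx$amp, at = cuts[1] - 5,
                    size = -(cuts[2] - cuts[1] + 10)),           # intervening
      implant_indel(fx$amp, at = cuts[2] - 1, size = 4)          # local at g2
    )
  )
  res <- classify_clones(clones, fx$amp, fx$guides)
  expect_equal(res$classification,
               c("unedited", "local_single_site", "local_single_site",
                 "intervening_deletion", "local_single_site"))
  tally <- efficiency_tally(res)
  expect_equal(tally$n_edited, 4L)
  expect_equal(tally$percent, 80)
})

test_that("the exact Mann-Whitney test matches hand-enumerable cases", {
  # identical groups: no shift, p >= 0.5
  same <- compare_indel_sizes(c(2, 5, 9), c(2, 5, 9))
  expect_gte(same$p_value, 0.5)

  # complete separation of 3 vs 3: a single extreme assignment of C(6,3)=20
  sep <- compare_indel_sizes(c(1, 2, 3), c(10, 11, 12))
  expect_equal(sep$statistic, 9)
  expect_equal(sep$p_value, 1 / 20)

  # swapping the labels of strictly shifted data moves p to the other tail
  swap <- compare_indel_sizes(c(10, 11, 12), c(1, 2, 3))
  expect_equal(swap$p_value, 1)

  # signed sizes compare as absolute lengths
  expect_equal(compare_indel_sizes(c(-1, 2, -3), c(-10, 11, -12))$p_value, 1 / 20)

  expect_error(compare_indel_sizes(numeric(0), 1), "non-empty")
})

test_that("exact enumeration matches the independent pairwise-count oracle", {
  set.seed(33)
  for (i in 1:200) {
    n1 <- sample(1:6, 1)
    n2 <- sample(1:6, 1)
    x <- sample(1:12, n1, replace = TRUE) # integer sizes: ties are common
    y <- sample(1:12, n2, replace = TRUE)
    got <- compare_indel_sizes(x, y)
    expect_equal(got$p_value, mw_enumeration_oracle(x, y))
  }
  # and, on tie-free data, matches the classical exact distribution
  for (i in 1:50) {
    v <- sample(1:1000, 10)
    x <- v[1:5]
    y <- v[6:10]
    expect_equal(
      compare_indel_sizes(x, y)$p_value,
      stats::wilcox.test(abs(y), abs(x), alternative = "greater",
                         exact = TRUE)$p.value
    )
  }
})

test_that("large samples use the tie-corrected normal approximation", {
  set.seed(44)
  x <- rpois(15, 4) + 1
  y <- rpois(15, 12) + 1
  res <- compare_indel_sizes(x, y)
  expect_match(res$method, "normal approximation")
  ref <- suppressWarnings(
    stats::wilcox.test(y, x, alternative = "greater", correct = TRUE)
  )
  expect_equal(res$statistic, unname(ref$statistic))
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-10)
})
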