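toy_gene <- function(cds = "ATGGCTTAA", start = 101L, strand = "+",
                     name = "toy") {
  gene_model(name, strand,
             exons = data.frame(start = start, end = start + nchar(cds) - 1L),
             cds_sequence = cds)
}

test_that("gene models enforce CDS invariants", {
  expect_s3_class(toy_gene(), "gene_model")
  expect_error(toy_gene("ATGGCTTA"), "codons")
  expect_error(toy_gene("TTGGCTTAA"), "start codon")
  expect_error(toy_gene("ATGGCTGCT"), "stop codon")
  expect_error(toy_gene("ATGTAAGCTTAA"), "premature stop")
  expect_error(gene_model("g", "+", data.frame(start = 1, end = 3),
                          "ATGGCTTAA"), "span")
})

test_that("SNVs classify as synonymous, missense (with BLOSUM62), or nonsense", {
  gene <- toy_gene("ATGGCTTAA") # M A *
  syn <- classify_effect(list(pos = 106, ref = "T", alt = "C"), gene) # GCT->GCC
  expect_equal(syn$category, "synonymous")
  expect_equal(syn$ref_aa, "A")

  mis <- classify_effect(list(pos = 105, ref = "C", alt = "T"), gene) # GCT->GTT
  expect_equal(mis$category, "missense")
  expect_equal(c(mis$ref_aa, mis$alt_aa), c("A", "V"))
  expect_equal(mis$blosum62, 0)

  non <- classify_effect(list(pos = 106, ref = "C", alt = "A"),
                         toy_gene("ATGTACTAA")) # TAC->TAA
  expect_equal(non$category, "nonsense")
  expect_equal(non$alt_aa, "*")

  # degenerate guard: alt equal to ref is synonymous with identical codons
  same <- classify_effect(list(pos = 105, ref = "C", alt = "C"), gene)
  expect_equal(same$category, "synonymous")

  outside <- classify_effect(list(pos = 400, ref = "A", alt = "G"), gene)
  expect_equal(outside$category, "noncoding")
})

test_that("frameshifts count complete novel codons before the premature stop", {
  # ATG CAT CCT AAC TGA; inserting G after base 3 shifts to
  # ATG GCA TCC TAA: the stop is the third novel codon, so 2 codons precede it
  gene <- toy_gene("ATGCATCCTAACTGA")
  fs <- classify_effect(list(pos = 103, ref = "G", alt = "GG"), gene)
  expect_equal(fs$category, "frameshift")
  expect_equal(fs$codons_to_stop, 2)

  # deletion shifting the frame
  del <- classify_effect(list(pos = 103, ref = "GC", alt = "G"), gene)
  expect_equal(del$category, "frameshift")

  # in-frame indel
  inf <- classify_effect(list(pos = 103, ref = "GCAT", alt = "G"), gene)
  expect_equal(inf$category, "inframe_indel")
})

test_that("a single G inserted into a heptaguanine run stops 7 codons on", {
  # synthetic analog of the mapped mutation: the CDS carries a GGGGGGG run;
  # inserting one more G shifts the frame and the first premature stop is
  # the eighth novel codon
  cds <- paste0("ATGGGGGGG", strrep("C", 14), "TAAC", "TGA")
  gene <- toy_gene(cds)
  fs <- classify_effect(list(pos = 104, ref = "G", alt = "GG"), gene)
  expect_equal(fs$category, "frameshift")
  expect_equal(fs$codons_to_stop, 7)
  expect_equal(fs$homopolymer_base, "G")
  expect_equal(fs$homopolymer_length, 7)
})

test_that("minus-strand variants are reverse-complemented before projection", {
  cds <- "ATGGCTTAA"
  gseq <- "TTAAGCCAT" # reverse complement of the CDS
  gene <- gene_model("toy_minus", "-",
                     exons = data.frame(start = 201, end = 209),
                     cds_sequence = cds)
  # genomic G>A at position 205 is CDS C>T at position 5: Ala -> Val
  mis <- classify_effect(list(pos = 205, ref = "G", alt = "A"), gene)
  expect_equal(mis$category, "missense")
  expect_equal(c(mis$ref_aa, mis$alt_aa), c("A", "V"))
  expect_equal(substr(gseq, 5, 5), "G") # fixture sanity
})

test_that("homopolymer runs are maximal and handle boundaries", {
  expect_equal(homopolymer_run("ATGGGGGGGC", 5),
               list(base = "G", run_length = 7L))
  expect_equal(homopolymer_run("ACGT", 2), list(base = "C", run_length = 1L))
  expect_equal(homopolymer_run("AAGGG", 5), list(base = "G", run_length = 3L))
  expect_equal(homopolymer_run("GGGTT", 1), list(base = "G", run_length = 3L))
  expect_error(homopolymer_run("ACGT", 5), "outside")
})

test_that("the embedded BLOSUM62 matches the canonical matrix", {
  expect_equal(blosum62_score("A", "V"), 0)
  expect_equal(blosum62_score("A", "A"), 4)
  expect_error(blosum62_score("A", "B"), "Nonstandard")

  long <- blosum62_matrix()
  expect_equal(nrow(long), 400)
  # symmetry over all 400 pairs
  swapped <- blosum62_score(long$aa2, long$aa1)
  expect_equal(long$score, swapped)
  # entry-for-entry against an independently curated copy
  e <- new.env()
  data("BLOSUM62", package = "Biostrings", envir = e)
  B <- get("BLOSUM62", envir = e)
  expect_equal(long$score,
               mapply(function(a, b) B[a, b], long$aa1, long$aa2,
                      USE.NAMES = FALSE))
})

test_that("candidates rank frameshift > damaging missense > neutral missense > synonymous", {
  gene <- toy_gene("ATGCATCCTAACTGA")
  effects <- dplyr::bind_rows(
    classify_effect(list(pos = 106, ref = "T", alt = "C"), gene),  # synonymous (CAT->CAC)
    classify_effect(list(pos = 104, ref = "C", alt = "G"), gene),  # missense (CAT->GAT)
    classify_effect(list(pos = 103, ref = "G", alt = "GG"), gene), # frameshift
    classify_effect(list(pos = 400, ref = "A", alt = "G"), gene)   # noncoding
  )
  ranked <- rank_candidates(effects)
  expect_equal(ranked$category[1], "frameshift")
  expect_equal(ranked$category[nrow(ranked)], "noncoding")
  expect_true(!is.unsorted(ranked$impact_rank))

  # stability: equal-priority rows keep input order
  syns <- dplyr::bind_rows(
    classify_effect(list(pos = 106, ref = "T", alt = "C"), gene),
    classify_effect(list(pos = 112, ref = "C", alt = "T"), gene)  # AAC->AAT
  )
  expect_equal(rank_candidates(syns)$pos, syns$pos)
  empty <- rank_candidates(effects[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("classify_effects handles variant tables and multi-allelic records", {
  gene <- toy_gene("ATGGCTTAA")
  recs <- toy_records(pos = c(105L, 106L), ref = "C", alt = c("T,G", "A"))
  recs$ref[2] <- "T"
  eff <- classify_effects(recs, gene)
  expect_equal(nrow(eff), 3)
  expect_equal(eff$category, c("missense", "missense", "synonymous"))
})
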