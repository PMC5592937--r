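# hemimapper

Bulked segregant analysis (BSA) for X-linked recessive mutations mapped from
pooled hemizygous mutants.

## The problem

When a recessive mutation sits on the X chromosome, every affected XY male is
hemizygous: all of his reads at any X-linked site come from a single maternal
haplotype. If DNA from many mutant F2 males is pooled and sequenced, two
complementary signals localize the causative locus along the chromosome:

1. **Target-allele proportion.** At each variant site, the fraction of pooled
   reads matching the original mutant male's allele. Far from the locus this
   hovers near the background transmission rate (~0.5); approaching the locus
   it rises to 1, because selection on the phenotype forces every pooled X
   onto the mutant haplotype.
2. **Mixed-variant proportion.** The fraction of sites, within a window,
   whose pooled reads support more than one allele. Because all pooled males
   are identical by descent around the causative site, this drops to exactly
   0 there — a hemizygosity-specific null with no counterpart in autosomal
   BSA.

Both statistics are smoothed over a 50-variant sliding window advancing 5
variants at a time, after filtering variants to QUAL > 40, pooled depth >= 6,
and subtraction of every variant carried by the F0 female founder.

`hemimapper` implements this analysis end to end for simulated crosses:

* a forward simulator of the mapping pedigree (Haldane no-interference
  recombination, Mendelian X-linked transmission, Poisson pooled read depths,
  substitution errors) emitting a minimal 3-sample VCF
  (`POOL`, `CASPER_MALE`, `F0_FEMALE`);
* the variant filters and the dual-statistic sliding-window scan with peak
  calling;
* triage of candidate coding variants: synonymous / missense / nonsense /
  frameshift classification, BLOSUM62 scoring of substitutions, codons to
  the first premature stop after a frameshift, homopolymer-run context;
* indel calling from Sanger-sequenced clones of CRISPR/Cas9-edited amplicons
  (global affine-gap alignment, VCF-style left alignment, single- vs
  paired-guide outcome classification, editing-efficiency tallies, exact
  one-sided Mann-Whitney U);
* the exact segregation statistics: binomial and Fisher tests computed by
  explicit tail/enumeration sums.

Everything takes and returns tibbles, so the stages chain with the pipe, and
scan results support `tidy()`, `glance()`, and `autoplot()`.

## Worked example

The packaged demonstration reconstructs the canonical study design: 47
mutant F2 males pooled at 12x coverage over an X chromosome carrying a fully
linked marker block around the causative site.

```r
library(hemimapper)
run_casper_demo(seed = 1)
#> Pooled mapping of 47 hemizygous mutant males (12x):
#>   peak window 9: chr19:2260000-3700000
#>   casper-allele proportion 0.998, mixed-variant proportion 0.020
#>   causative site at chr19:2980000 is inside the peak window
```

The peak window is the one maximizing the windowed target-allele proportion
(ties broken by lower mixed proportion): here it reaches 0.998 with only 2%
of window variants showing mixed reads (the residual comes from the 0.002
per-read error rate), and it contains the causative site. With the error
rate set to 0 the causative window is exactly (1.0, 0).

The stages are ordinary functions if you want them individually:

```r
map      <- map_linked_block()
founders <- simulate_founders(map, seed = 1)
design   <- cross_design(founders, map, n_f2 = 300, pool_size = 47,
                         mean_depth = 12, error_rate = 0, seed = 1)
scan <- simulate_experiment(design) |>
  filter_variants(min_qual = 40, min_depth = 6, exclude_sample = "F0_FEMALE") |>
  scan_bsa(window_size = 50, step = 5)
locate_peak(scan)
autoplot(scan)
```

Segregation and editing statistics mirror the study's count tables:

```r
binomial_exact_test(47, 47, 0.5)$p_value   # 1.421085e-14 (all mutants male)
format_pct(103 / 419, 1)                   # 24.6 (% mutant F2, X-linked 25%)
blosum62_score("A", "V")                   # 0  (neutral substitution)
fisher_exact_2x2(matrix(c(14, 2, 1, 19), 2))$p_value  # 4.34e-07
```

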