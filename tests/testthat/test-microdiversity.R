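test_that("codon spectrum matches the exhaustive enumeration oracle for all sense codons", {
  gc_codons <- names(Biostrings::GENETIC_CODE)
  sense <- gc_codons[Biostrings::GENETIC_CODE != "*"]
  for (cd in sense) {
    expect_identical(neutral_codon_spectrum(cd),
                     c(n_syn = 0L, n_nonsyn = 0L) + oracle_spectrum(cd),
                     info = cd)
  }
  expect_error(neutral_codon_spectrum("TAA"), "stop")
  expect_error(neutral_codon_spectrum("ANA"), "invalid")
})

test_that("neutral fractions sum to one and match hand enumeration", {
  fr <- gene_neutral_fractions("TTTTTTATG")
  expect_equal(fr[["f_S"]], 2 / 27)
  expect_equal(fr[["f_N"]] + fr[["f_S"]], 1)

  # poly-ATG gene has no synonymous opportunity
  expect_equal(gene_neutral_fractions("ATGATGATG")[["f_S"]], 0)

  # stop codons are excluded from the totals
  expect_equal(gene_neutral_fractions("TTTTAA"),
               gene_neutral_fractions("TTT"))

  # property: f_N + f_S = 1 over random genes
  set.seed(42)
  for (i in 1:50) {
    cds <- paste(sample(names(Biostrings::GENETIC_CODE), 60, replace = TRUE),
                 collapse = "")
    fr <- gene_neutral_fractions(cds)
    expect_equal(fr[["f_N"]] + fr[["f_S"]], 1)
  }
})

test_that("pileups count only reads spanning whole codons", {
  cds <- "ATGAAATTTTAA"
  scaf <- simple_scaffold(cds)          # gene at 11..22
  gene <- simple_gene(cds)
  aln <- make_aln(
    c("full", "partial", "wide"),
    "sc1",
    c(11, 12, 1),
    c(substr(scaf, 11, 22),   # spans all four codons
      substr(scaf, 12, 23),   # misses first base of codon 0
      substr(scaf, 1, 30)))   # spans everything
  pu <- pileup_codons(aln, gene, scaf)
  cov <- tapply(pu$count, pu$codon_index, sum)
  expect_equal(as.vector(cov[c("0", "1", "2", "3")]), c(2, 3, 3, 3))
  expect_true(all(pu$codon == pu$ref_codon))  # no variants planted
})

test_that("reverse-strand pileups compare reverse-complemented read codons", {
  # gene on '-' strand: scaffold carries revcomp(cds)
  cds <- "ATGAAATTTTAA"
  seg <- viromicro:::revcomp(cds)
  scaf <- paste0(strrep("G", 10), seg, strrep("G", 10))
  gene <- data.frame(gene_id = "g1", scaffold_id = "sc1", start = 11L,
                     end = 22L, strand = "-", stringsAsFactors = FALSE)
  ref_read <- substr(scaf, 11, 22)
  # plant a variant in gene codon 1 (AAA -> AGA): scaffold-oriented codon
  # occupies positions end-5..end-3 = 17..19 and reads revcomp there
  var_read <- ref_read
  substr(var_read, 7, 9) <- viromicro:::revcomp("AGA")
  aln <- make_aln(c("r1", "r2"), "sc1", c(11, 11), c(ref_read, var_read))
  pu <- pileup_codons(aln, gene, scaf)
  expect_setequal(unique(pu$ref_codon[pu$codon_index == 1]), "AAA")
  v <- pu[pu$codon_index == 1 & pu$codon != pu$ref_codon, ]
  expect_identical(v$codon, "AGA")
  expect_equal(v$count, 1)
})

test_that("variant validity filters are inclusive at the stated boundaries", {
  # the nine constructed pileups around (count 4, freq 1%, cov 5)
  cases <- list(
    list(count = 4, cov = 5, valid = TRUE),    # all at boundary (freq 0.8)
    list(count = 3, cov = 5, valid = FALSE),   # count below
    list(count = 5, cov = 5, valid = TRUE),    # count above
    list(count = 4, cov = 4, valid = FALSE),   # coverage below
    list(count = 4, cov = 6, valid = TRUE),    # coverage above
    list(count = 4, cov = 400, valid = TRUE),  # freq exactly 1%
    list(count = 4, cov = 401, valid = FALSE), # freq just below 1%
    list(count = 4, cov = 399, valid = TRUE),  # freq just above 1%
    list(count = 5, cov = 1000, valid = FALSE))# 0.5% < 1%
  for (cs in cases) {
    pu <- make_pileup("AAA", "AGA", cs$count, cs$cov)
    calls <- call_variants(pu)
    expect_equal(calls$valid, cs$valid,
                 info = sprintf("count=%d cov=%d", cs$count, cs$cov))
  }
})

test_that("variant effects come from the genetic code, stop-gain nonsynonymous", {
  pu <- rbind(make_pileup("TTT", "TTC", 10, 50, codon_index = 0L),
              make_pileup("TTT", "TTA", 10, 50, codon_index = 1L),
              make_pileup("TGC", "TGA", 10, 50, codon_index = 2L))
  calls <- call_variants(pu)
  expect_identical(calls$effect,
                   c("synonymous", "nonsynonymous", "nonsynonymous"))
  expect_true(all(calls$valid))
})

test_that("reference stop codons are excluded from calls and assayability", {
  pu <- rbind(make_pileup("TAA", "TAC", 10, 50, codon_index = 0L),
              make_pileup("AAA", "AGA", 10, 50, codon_index = 1L))
  calls <- call_variants(pu)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$codon_index, 1L)
  md <- gene_microdiversity(calls, pu, "TAAAAA", "g1")
  expect_equal(md$n_assayable, 1)
})

test_that("worked example: one syn + one nonsyn on TTT-TTT-ATG gives pN/pS 0.08", {
  cds <- "TTTTTTATG"
  pu <- rbind(make_pileup("TTT", "TTC", 10, 100, codon_index = 0L),
              make_pileup("ATG", "ATA", 10, 100, codon_index = 2L))
  calls <- call_variants(pu)
  md <- gene_microdiversity(calls, pu, cds, "g1")
  expect_equal(md$obs_S, 1)
  expect_equal(md$obs_N, 1)
  expect_equal(md$pnps, 0.08)
  expect_equal(md$pnps, (md$obs_N / md$obs_S) * (md$f_S / md$f_N))
  expect_equal(md$n_polymorphic, 2)
  expect_equal(md$percent_polymorphic, 100)
})

test_that("genes without variants report zero polymorphism and undefined pN/pS", {
  cds <- "ATGAAATTTTAA"
  scaf <- simple_scaffold(cds)
  gene <- simple_gene(cds)
  reads <- rep(substr(scaf, 11, 22), 10)
  aln <- make_aln(sprintf("r%d", 1:10), "sc1", rep(11, 10), reads)
  pu <- pileup_codons(aln, gene, scaf)
  md <- gene_microdiversity(call_variants(pu), pu, cds, "g1")
  expect_equal(md$obs_N + md$obs_S, 0)
  expect_true(is.na(md$pnps))
  expect_equal(md$percent_polymorphic, 0)
  expect_equal(md$n_assayable, 3)  # stop codon excluded
})

test_that("category medians apply the inclusion rules", {
  base <- data.frame(
    sample_id = "15m", fraction = "viral",
    category_broad = "replication",
    pN = 1, pS = 1, pnps = NA_real_, n_polymorphic = 2L,
    percent_polymorphic = 5, n_assayable = 100L, mean_coverage = 50,
    obs_N = 1, obs_S = 1, f_N = 0.75, f_S = 0.25, gene_id = NA_character_,
    stringsAsFactors = FALSE)
  mk <- function(pnps, cat = "replication", pS = 1, pp = 5, npoly = 2L) {
    g <- base
    g$pnps <- pnps; g$category_broad <- cat; g$pS <- pS
    g$percent_polymorphic <- pp; g$n_polymorphic <- npoly
    g
  }
  stats <- rbind(mk(0.1), mk(0.3), mk(0.5),          # full group of 3
                 mk(0.2, cat = "structural"), mk(0.4, cat = "structural"),
                 mk(9, cat = "replication", pS = 0)) # pS=0 excluded
  med <- category_medians(stats, c("sample_id", "fraction",
                                   "category_broad"))
  rep_row <- med[med$category_broad == "replication", ]
  expect_equal(rep_row$median_pnps, 0.3)   # pS=0 gene excluded
  expect_equal(rep_row$n_genes_pnps, 3)
  str_row <- med[med$category_broad == "structural", ]
  expect_true(is.na(str_row$median_pnps))  # fewer than three genes
  expect_equal(str_row$n_genes_pnps, 2)

  # percent-polymorphic threshold: a gene below 1% drops out of pnps
  stats2 <- rbind(mk(0.1), mk(0.3), mk(0.5, pp = 0.5))
  med2 <- category_medians(stats2, "category_broad")
  expect_true(is.na(med2$median_pnps))
  expect_equal(med2$n_genes_pnps, 2)
})

test_that("consensus profile reports reference-favouring ties and flags", {
  # coverage 10: 9 reference AAA, 1 nonsyn AGA (below count filter)
  pu1 <- make_pileup("AAA", "AGA", 1, 10)
  pr1 <- consensus_profile(pu1)
  expect_equal(pr1$consensus_frequency, 0.9)
  expect_equal(pr1$consensus_aa, "K")
  expect_false(pr1$polymorphic)

  # 5/5 tie with one amino acid matching reference -> reference wins
  pu2 <- make_pileup("AAA", "AGA", 5, 10)
  pr2 <- consensus_profile(pu2)
  expect_equal(pr2$consensus_aa, "K")
  expect_equal(pr2$consensus_frequency, 0.5)
  expect_true(pr2$polymorphic)

  # synonymous variants pool into the same amino acid
  pu3 <- make_pileup("TTT", "TTC", 4, 10)
  pr3 <- consensus_profile(pu3)
  expect_equal(pr3$consensus_aa, "F")
  expect_equal(pr3$consensus_frequency, 1.0)
  expect_true(pr3$polymorphic)
})

test_that("coverage correlation matches the direct formula and handles degeneracy", {
  stats <- data.frame(mean_coverage = c(10, 20, 30, 40),
                      percent_polymorphic = c(1, 3, 2, 5),
                      pnps = c(2, 2, 2, 2))
  x <- stats$mean_coverage; y <- stats$percent_polymorphic
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(coverage_correlation(stats, "percent_polymorphic"), r_oracle)
  expect_true(is.na(coverage_correlation(stats, "pnps")))  # zero variance
  expect_equal(coverage_correlation(
    data.frame(mean_coverage = 1:5, percent_polymorphic = 2 * (1:5)),
    "percent_polymorphic"), 1.0)
  expect_true(is.na(coverage_correlation(stats[1:2, ], "pnps")))
})

test_that("percent polymorphic is invariant to read input order", {
  cds <- paste(rep("AAATTTGGGCCC", 5), collapse = "")
  scaf <- simple_scaffold(cds)
  gene <- simple_gene(cds)
  set.seed(7)
  spec <- microdiv_spec(coverage = 20, n_variant_sites = 5,
                        maf_range = c(0.2, 0.4), seed = 3)
  sim <- simulate_reads(gene, scaf, spec)
  pu1 <- pileup_codons(sim$aln, gene, scaf)
  shuffled <- sim$aln[sample(nrow(sim$aln)), , drop = FALSE]
  pu2 <- pileup_codons(shuffled, gene, scaf)
  md1 <- gene_microdiversity(call_variants(pu1), pu1, cds, "g1")
  md2 <- gene_microdiversity(call_variants(pu2), pu2, cds, "g1")
  expect_equal(md1$percent_polymorphic, md2$percent_polymorphic)
  expect_equal(md1$pnps, md2$pnps)
})
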