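genes_for <- function(scaffold_id, n) {
  data.frame(gene_id = sprintf("%s_g%02d", scaffold_id, seq_len(n)),
             scaffold_id = scaffold_id, stringsAsFactors = FALSE)
}

test_that("AVQ round applies inclusive thresholds on percent and quotient sum", {
  quot <- c(og1 = 1, og2 = 1, og3 = 0.5)

  # 10 ORFs, 2 hits with quotient 1 each: 20%, AVQ 2 -> passes
  g <- genes_for("s1", 10)
  h <- hit_row(g$gene_id[1:2], c("og1", "og2"))
  r <- avq_round1(g, h, quot)
  expect_equal(r$percent_hit, 20)
  expect_equal(r$avq, 2)
  expect_true(r$passed_round1)

  # 20 ORFs, 2 hits quotient 1: exactly 10% and AVQ exactly 2 -> passes
  g <- genes_for("s1", 20)
  r <- avq_round1(g, hit_row(g$gene_id[1:2], c("og1", "og2")), quot)
  expect_equal(r$percent_hit, 10)
  expect_true(r$passed_round1)

  # 10 ORFs, 1 hit quotient 1: AVQ 1 < 2 -> fails
  g <- genes_for("s1", 10)
  r <- avq_round1(g, hit_row(g$gene_id[1], "og1"), quot)
  expect_false(r$passed_round1)

  # hits above the e-value ceiling are ignored
  r <- avq_round1(g, hit_row(g$gene_id[1:2], c("og1", "og2"),
                             evalue = 1e-3), quot)
  expect_equal(r$n_orfs_with_hit, 0)

  # unknown orthologous group errors by name
  expect_error(avq_round1(g, hit_row(g$gene_id[1], "og_missing"), quot),
               "og_missing")
})

test_that("AVQ best hit per ORF follows evalue, bitscore, then id", {
  g <- genes_for("s1", 10)
  quot <- c(low = 0.1, high = 1, other = 0.9)
  h <- rbind(hit_row(g$gene_id[1], "low", evalue = 1e-30, bitscore = 50),
             hit_row(g$gene_id[1], "high", evalue = 1e-10, bitscore = 500))
  expect_equal(avq_round1(g, h, quot)$avq, 0.1)  # lowest e-value wins

  h2 <- rbind(hit_row(g$gene_id[1], "low", evalue = 1e-10, bitscore = 600),
              hit_row(g$gene_id[1], "high", evalue = 1e-10, bitscore = 50))
  expect_equal(avq_round1(g, h2, quot)$avq, 0.1)  # bitscore tie-break

  h3 <- rbind(hit_row(g$gene_id[1], "other", evalue = 1e-10, bitscore = 50),
              hit_row(g$gene_id[1], "high", evalue = 1e-10, bitscore = 50))
  expect_equal(avq_round1(g, h3, quot)$avq, 1)    # lexicographic: "high"
})

test_that("adding a hit never turns a passing scaffold into a failing one", {
  set.seed(31)
  quot <- setNames(runif(20, 0.3, 1), paste0("og", 1:20))
  g <- genes_for("s1", 12)
  hits <- hit_row(sample(g$gene_id, 4), sample(names(quot), 4))
  for (i in 1:20) {
    before <- avq_round1(g, hits, quot)$passed_round1
    extra <- hit_row(sample(g$gene_id, 1), sample(names(quot), 1))
    hits <- rbind(hits, extra)
    after <- avq_round1(g, hits, quot)$passed_round1
    if (before) expect_true(after)
  }
})

test_that("bait recruitment needs three distinct ORFs and 20% on one bait scaffold", {
  bait_genes <- genes_for("bait1", 8)
  bait2 <- genes_for("bait2", 8)
  all_bait <- rbind(bait_genes, bait2)

  # 10 ORFs, 3 distinct ORFs hit bait1: 30% and 3 matches -> recruited
  g <- genes_for("cand", 10)
  h <- hit_row(g$gene_id[1:3], bait_genes$gene_id[1:3])
  r <- bait_round2(g, h, all_bait)
  expect_true(r$recruited)
  expect_equal(r$best_bait_scaffold, "bait1")

  # 20 ORFs, 3 hits: 15% < 20% -> not recruited
  g20 <- genes_for("cand", 20)
  r <- bait_round2(g20, hit_row(g20$gene_id[1:3], bait_genes$gene_id[1:3]),
                   all_bait)
  expect_false(r$recruited)

  # hits split 2 + 2 across bait scaffolds: max 2 < 3 -> not recruited
  h_split <- rbind(hit_row(g$gene_id[1:2], bait_genes$gene_id[1:2]),
                   hit_row(g$gene_id[3:4], bait2$gene_id[1:2]))
  r <- bait_round2(g, h_split, all_bait)
  expect_false(r$recruited)
  expect_equal(r$n_matched_to_best, 2)

  # repeated hits from the same ORF count once
  h_dup <- rbind(hit_row(g$gene_id[c(1, 1, 1)], bait_genes$gene_id[1:3]),
                 hit_row(g$gene_id[2:3], bait_genes$gene_id[1:2]))
  r <- bait_round2(g, h_dup, all_bait)
  expect_equal(r$n_matched_to_best, 3)

  # per-hit filters: failing any one of the four excludes the hit
  base <- hit_row(g$gene_id[1:3], bait_genes$gene_id[1:3])
  for (mod in list(list(col = "percent_identity", val = 29.9),
                   list(col = "bitscore", val = 49),
                   list(col = "aln_length", val = 29),
                   list(col = "evalue", val = 2e-5))) {
    h_bad <- base
    h_bad[[mod$col]][1] <- mod$val
    r <- bait_round2(g, h_bad, all_bait)
    expect_equal(r$n_matched_to_best, 2, info = mod$col)
  }
})

test_that("curation promotes unclassified ids only, warning on already-viral", {
  info <- data.frame(scaffold_id = c("a", "b", "c"),
                     classification = c("unclassified", "viral_round1",
                                        "unclassified"),
                     stringsAsFactors = FALSE)
  out <- apply_curation(info, "a")
  expect_equal(out$classification[out$scaffold_id == "a"], "viral_curated")
  expect_warning(out2 <- apply_curation(info, "b"), "unchanged")
  expect_equal(out2$classification[out2$scaffold_id == "b"], "viral_round1")
  expect_identical(apply_curation(info, character(0)), info)
  expect_error(apply_curation(info, "zz"), "zz")
})

test_that("external-classifier concordance reproduces the headline fraction", {
  # 7,164 bona fide scaffolds of which 166 flagged by neither tool -> 2.3%
  n <- 7164; n_miss <- 166
  ids <- sprintf("s%04d", seq_len(n))
  labels <- data.frame(
    scaffold_id = ids,
    virsorter_category = c(rep(NA, n_miss), rep(1:6, length.out = n - n_miss)),
    virfinder_score = 0, virfinder_p = 1, stringsAsFactors = FALSE)
  r <- concordance(ids, labels)
  expect_equal(r$n_discordant, 166)
  expect_equal(r$percent, 2.3)

  # all category 1 -> no discordance
  labels$virsorter_category <- 1
  expect_equal(concordance(ids, labels)$n_discordant, 0)

  # score and p exactly at the boundary are concordant
  lab1 <- data.frame(scaffold_id = "x", virsorter_category = NA,
                     virfinder_score = 0.7, virfinder_p = 0.05)
  expect_equal(concordance("x", lab1)$n_discordant, 0)

  # missing label rows are discordant, with a warning
  expect_warning(r2 <- concordance(c("x", "y"), lab1), "without label")
  expect_equal(r2$n_discordant, 1)
})

test_that("population clustering links near-identical scaffolds only", {
  set.seed(17)
  s1 <- random_dna(10000)
  s2 <- s1                                   # identical
  s3 <- mutate_seq(s1, sample(10000, 1000))  # ~90% identity
  s4 <- random_dna(8000)                     # unrelated

  # oracle: direct Hamming identity on the constructed pairs
  hamming_id <- function(a, b) {
    mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
  }
  expect_equal(hamming_id(s1, s2), 1)
  expect_lt(hamming_id(s1, s3), 0.95)

  pops <- cluster_populations(c(a = s1, b = s2, c = s3, d = s4))
  expect_equal(pops[["a"]], pops[["b"]])
  expect_false(pops[["a"]] == pops[["c"]])
  expect_false(pops[["a"]] == pops[["d"]])
  expect_equal(length(unique(pops)), 3)

  # all singletons
  singles <- cluster_populations(c(x = random_dna(6000),
                                   y = random_dna(6000)))
  expect_equal(length(unique(singles)), 2)

  # permutation yields identical component memberships
  pops_perm <- cluster_populations(c(d = s4, c = s3, b = s2, a = s1))
  split_sets <- function(p) unname(lapply(split(names(p), p), sort))
  expect_setequal(split_sets(pops), split_sets(pops_perm))
})

test_that("three-round orchestration honours round order and truth labels", {
  comm <- generate_community(community_config(seed = 8))
  cls <- classify_scaffolds(comm$scaffold_info, comm$genes, comm$pvog_hits,
                            comm$quotients, comm$bait_hits)
  got <- setNames(cls$scaffold_info$classification,
                  cls$scaffold_info$scaffold_id)
  t <- comm$truth
  expect_true(all(got[t$scaffold_id[t$planted_round %in% "round1"]] ==
                    "viral_round1"))
  expect_true(all(got[t$scaffold_id[t$planted_round %in% "round2"]] ==
                    "viral_round2"))
  expect_true(all(got[t$scaffold_id[t$planted_class == "nonviral"]] ==
                    "unclassified"))
  # round 2 recruits are attributed to round-1 scaffolds only
  b <- cls$bait[cls$bait$recruited, ]
  expect_true(all(b$best_bait_scaffold %in%
                    t$scaffold_id[t$planted_round %in% "round1"]))
})
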