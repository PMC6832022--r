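test_that("closest relative follows majority rule with mean-identity tie-break", {
  g <- data.frame(gene_id = sprintf("g%d", 1:8), scaffold_id = "s1",
                  stringsAsFactors = FALSE)
  myo <- "Myoviridae;Myovirus;sp1"
  podo <- "Podoviridae;Podovirus;sp2"

  # majority: 5 Myoviridae vs 3 Podoviridae
  h <- rbind(hit_row(g$gene_id[1:5], paste0("m", 1:5), taxonomy = myo),
             hit_row(g$gene_id[6:8], paste0("p", 1:3), taxonomy = podo))
  r <- closest_relative(g, h, "family")
  expect_equal(r$taxon, "Myoviridae")
  expect_equal(r$n_orfs_matched, 5)
  expect_false(r$tie_broken)

  # tie on counts: higher mean identity wins
  h2 <- rbind(hit_row(g$gene_id[1:3], paste0("m", 1:3), identity = 45,
                      taxonomy = myo),
              hit_row(g$gene_id[4:6], paste0("p", 1:3), identity = 60,
                      taxonomy = podo))
  r2 <- closest_relative(g, h2, "family")
  expect_equal(r2$taxon, "Podoviridae")
  expect_true(r2$tie_broken)

  # zero passing hits -> no call
  h3 <- hit_row(g$gene_id[1], "m1", identity = 20, taxonomy = myo)
  r3 <- closest_relative(g, h3, "family")
  expect_true(is.na(r3$taxon))

  # rank-specific calls read the right path element
  r4 <- closest_relative(g, h, "genus")
  expect_equal(r4$taxon, "Myovirus")

  # invariant to ORF/hit input order
  r5 <- closest_relative(g[sample(nrow(g)), , drop = FALSE],
                         h[sample(nrow(h)), , drop = FALSE], "family")
  expect_equal(r5$taxon, r$taxon)
  expect_equal(r5$n_orfs_matched, r$n_orfs_matched)
})

test_that("functional categories come from the first matching keyword", {
  r <- assign_category(c("putative tail fiber protein", "DNA polymerase I",
                         "hypothetical protein", NA))
  expect_equal(r$category_broad,
               c("structural", "replication", "unknown", "unknown"))
  expect_equal(r$category_specific,
               c("tail_fiber", "dna_polymerase", "unknown", "unknown"))
  # priority: "tail fiber" outranks the bare "tail" row; case-insensitive
  expect_equal(assign_category("TAIL FIBER")$category_specific, "tail_fiber")
  expect_equal(assign_category("tail tube protein")$category_specific,
               "tail")
})

test_that("homology host signal needs both length and identity", {
  set.seed(23)
  viral <- random_dna(6000)
  host0 <- random_dna(20000)

  # 1.5 kb verbatim shared segment -> signal with the segment length
  seg <- substr(viral, 2001, 3500)
  host <- paste0(substr(host0, 1, 8000), seg,
                 substr(host0, 8001, nchar(host0)))
  sig <- detect_homology(viral, host)
  expect_equal(sig$signal, "homology")
  expect_gte(sig$score, 1500)

  # 500 bp identical segment: below the length floor
  host500 <- paste0(substr(host0, 1, 8000), substr(viral, 2001, 2500),
                    substr(host0, 8001, nchar(host0)))
  expect_null(detect_homology(viral, host500))

  # 1.2 kb segment at ~85% identity: below the identity floor
  # (oracle: direct positional comparison of the planted segment)
  seg85 <- mutate_seq(substr(viral, 2001, 3200), sample(1200, 180))
  direct_id <- mean(strsplit(substr(viral, 2001, 3200), "")[[1]] ==
                      strsplit(seg85, "")[[1]])
  expect_lt(direct_id, 0.90)
  host85 <- paste0(substr(host0, 1, 8000), seg85,
                   substr(host0, 8001, nchar(host0)))
  expect_null(detect_homology(viral, host85))
})

test_that("spacer matching allows one mismatch and both strands", {
  set.seed(29)
  scaf <- random_dna(5000)
  sp_exact <- substr(scaf, 1001, 1032)
  sp_rc <- viromicro:::revcomp(substr(scaf, 2001, 2032))
  sp_1mm <- mutate_seq(substr(scaf, 3001, 3032), 5)
  sp_3mm <- mutate_seq(substr(scaf, 4001, 4032), c(3, 10, 20))

  # oracle: exhaustive sliding-window Hamming distance
  min_hamming <- function(pat, subj) {
    pc <- strsplit(pat, "")[[1]]
    n <- nchar(pat)
    min(vapply(1:(nchar(subj) - n + 1), function(i) {
      sum(pc != strsplit(substr(subj, i, i + n - 1), "")[[1]])
    }, numeric(1)))
  }
  expect_equal(min_hamming(sp_exact, scaf), 0)
  expect_equal(min_hamming(sp_1mm, scaf), 1)
  expect_equal(min_hamming(sp_3mm, scaf), 3)

  hits <- match_spacers(c(e = sp_exact, rc = sp_rc, one = sp_1mm,
                          three = sp_3mm), scaf)
  expect_setequal(hits$spacer_id, c("e", "rc", "one"))
  expect_equal(hits$strand[hits$spacer_id == "rc"], "-")
  expect_true(all(hits$score == 32))

  # spacers shorter than 20 bp are ignored
  expect_equal(nrow(match_spacers(c(short = substr(scaf, 1, 15)), scaf)), 0)
})

test_that("tRNA sharing requires exact full-length identity", {
  t1 <- random_dna(72)
  t2 <- mutate_seq(t1, 36)
  hits <- shared_trnas(c("v|t1" = t1), c("h|t1" = t1, "h|t2" = t2))
  expect_equal(nrow(hits), 1)
  expect_equal(hits$score, 72)
  expect_equal(nrow(shared_trnas(c("v|t1" = t2), c("h|t1" = t1))), 0)
  expect_equal(nrow(shared_trnas(character(0), c("h|t1" = t1))), 0)
})

test_that("consensus host demands agreement across all signals", {
  sig <- function(taxa) data.frame(signal = seq_along(taxa),
                                   host_taxonomy = taxa,
                                   stringsAsFactors = FALSE)
  expect_equal(consensus_host(sig(c("Proteobacteria;Pelagibacter",
                                    "Proteobacteria;Pelagibacter"))),
               "Proteobacteria")
  expect_true(is.na(consensus_host(sig(c("Proteobacteria;Pelagibacter",
                                         "Cyanobacteria;Prochlorococcus")))))
  expect_equal(consensus_host(sig("Proteobacteria;Pelagibacter")),
               "Proteobacteria")
  expect_true(is.na(consensus_host(sig(character(0)))))
  # genus-rank consensus reads the second path element
  expect_equal(consensus_host(sig(c("Proteobacteria;Pelagibacter",
                                    "Proteobacteria;Pelagibacter")),
                              rank = 2L), "Pelagibacter")
})

test_that("every unambiguous planted virus-host pair is recovered at phylum rank", {
  cc <- community_config(n_viral = 6, n_nonviral = 0, host_fraction = 1,
                         seed = 21)
  comm <- generate_community(cc)
  fix <- emit_host_fixtures(comm)
  pred <- predict_hosts(comm$scaffolds, fix$host_genomes, fix$host_taxonomy,
                        fix$spacers, fix$viral_trnas, fix$host_trnas)
  t <- comm$truth
  planted_phylum <- vapply(strsplit(t$host_taxonomy, ";"), `[[`, "", 1)
  got <- setNames(pred$host_taxon, pred$scaffold_id)
  expect_identical(unname(got[t$scaffold_id]), planted_phylum)
})
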