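# Seeded synthetic communities: scaffolds with ORFs and functional
# categories, virus-orthologous-group hits with viral quotients, taxonomy
# reference hits, protein bait hits for round-2 recruits, host-signal
# fixtures and reads carrying codon variants at controlled frequencies and
# selection strength — plus a truth table, so every downstream stage can be
# validated against known ground truth.
#
# Determinism: one top-level seed; per-scaffold RNG streams are derived by
# stable hashing of scaffold ids, so adding a scaffold to a community never
# perturbs the sequences of the others.

CATEGORY_PRODUCTS <- list(
  replication = c("DNA polymerase I", "DNA primase", "ATP-dependent helicase",
                  "ribonucleotide reductase", "DNA ligase",
                  "nucleotide pyrophosphohydrolase"),
  structural = c("major capsid protein", "putative tail fiber protein",
                 "baseplate wedge protein", "portal protein",
                 "tail tube protein", "neck protein"),
  metabolism = c("thioredoxin", "ferrochelatase", "2OG-Fe(II) oxygenase",
                 "phosphate starvation protein", "lysin"),
  regulation = c("transcriptional regulator", "sigma factor"),
  unknown = c("hypothetical protein", "uncharacterized protein"))

VIRAL_FAMILIES <- c("Myoviridae", "Podoviridae", "Siphoviridae")

HOST_TAXA <- c(h_pelagibacter = "Proteobacteria;Pelagibacter",
               h_prochlorococcus = "Cyanobacteria;Prochlorococcus",
               h_puniceispirillum = "Proteobacteria;Puniceispirillum",
               h_polaribacter = "Bacteroidetes;Polaribacter")

#' Configuration for a synthetic viral community
#'
#' Defaults give a small but fully featured community: viral scaffolds
#' whose orthologous-group hit density and quotients are drawn so that the
#' round-1 share passes the AVQ thresholds by construction, a share of
#' viral scaffolds left for round-2 baiting, and non-viral scaffolds with
#' no hits (so they can never pass round 1).
#'
#' @param n_viral,n_nonviral Scaffold counts (defaults 8, 4).
#' @param scaffold_length_range Scaffold length range in bp (default
#'   5000-8000; the pipeline's minimum scaffold length is 5000).
#' @param genes_per_scaffold Range of ORFs per scaffold (default 8-14).
#' @param gene_codons Range of codons per ORF, excluding the stop codon
#'   (default 80-200).
#' @param round1_hit_fraction Fraction of a round-1 scaffold's ORFs given
#'   orthologous-group hits (floored so thresholds are met; default 0.35).
#' @param nonviral_hit_fraction Hit fraction for non-viral scaffolds
#'   (default 0).
#' @param quotient_range Viral quotient range for round-1 hits (default
#'   0.7-1).
#' @param round2_fraction Fraction of viral scaffolds reserved as round-2
#'   recruits (no orthologous-group hits, bait hits instead; default 0.25).
#' @param host_fraction Fraction of viral scaffolds given a planted host
#'   (default 0.5).
#' @param category_proportions Named proportions over broad functional
#'   categories; must sum to 1.
#' @param sample_id Depth label for the community (default `"15m"`).
#' @param seed Integer seed.
#' @return List of class `community_config`.
#' @export
community_config <- function(n_viral = 8, n_nonviral = 4,
                             scaffold_length_range = c(5000, 8000),
                             genes_per_scaffold = c(8, 14),
                             gene_codons = c(80, 200),
                             round1_hit_fraction = 0.35,
                             nonviral_hit_fraction = 0,
                             quotient_range = c(0.7, 1),
                             round2_fraction = 0.25,
                             host_fraction = 0.5,
                             category_proportions = c(
                               replication = 0.2, structural = 0.3,
                               metabolism = 0.15, regulation = 0.05,
                               unknown = 0.3),
                             sample_id = "15m", seed = 1L) {
  stopifnot(n_viral >= 0, n_nonviral >= 0,
            abs(sum(category_proportions) - 1) < 1e-8)
  structure(as.list(environment()), class = "community_config")
}

# random sense-codon CDS: ATG + random non-stop codons + stop
random_cds <- function(n_codons) {
  gc <- genetic_code()
  sense <- names(gc)[gc != "*"]
  stops <- names(gc)[gc == "*"]
  body <- sample(sense, n_codons - 1L, replace = TRUE)
  paste(c("ATG", body, sample(stops, 1L)), collapse = "")
}

# build one scaffold: returns list(seq, genes data.frame)
build_scaffold <- function(id, cfg) {
  n_genes <- sample(seq(cfg$genes_per_scaffold[1], cfg$genes_per_scaffold[2]),
                    1L)
  cats <- sample(names(cfg$category_proportions), n_genes, replace = TRUE,
                 prob = cfg$category_proportions)
  target_len <- sample(seq(cfg$scaffold_length_range[1],
                           cfg$scaffold_length_range[2]), 1L)
  pieces <- character(0)
  genes <- list()
  pos <- 1L
  for (g in seq_len(n_genes)) {
    gap <- sample(30:80, 1L)
    pieces <- c(pieces, paste(sample(BASES, gap, replace = TRUE),
                              collapse = ""))
    pos <- pos + gap
    nc <- sample(seq(cfg$gene_codons[1], cfg$gene_codons[2]), 1L)
    cds <- random_cds(nc)
    strand <- sample(c("+", "-"), 1L)
    seg <- if (strand == "-") revcomp(cds) else cds
    glen <- nchar(cds)
    product <- sample(CATEGORY_PRODUCTS[[cats[[g]]]], 1L)
    genes[[g]] <- data.frame(
      gene_id = sprintf("%s_g%02d", id, g), scaffold_id = id,
      start = pos, end = pos + glen - 1L, strand = strand,
      product = product, category_broad = cats[[g]],
      protein = translate_cds(cds), stringsAsFactors = FALSE)
    pieces <- c(pieces, seg)
    pos <- pos + glen
  }
  tail_len <- max(0L, target_len - (pos - 1L))
  if (tail_len > 0) {
    pieces <- c(pieces, paste(sample(BASES, tail_len, replace = TRUE),
                              collapse = ""))
  }
  seq <- paste(pieces, collapse = "")
  if (nchar(seq) < sum(vapply(genes, function(g) g$end - g$start + 1,
                              numeric(1)))) {
    stop("impossible geometry: genes exceed scaffold length for ", id)
  }
  list(seq = seq, genes = do.call(rbind, genes))
}

#' Generate a synthetic viral community
#'
#' Emits a complete, internally consistent set of pipeline inputs:
#' scaffolds, gene coordinates and proteins, orthologous-group hits with a
#' quotient table, taxonomy reference hits, a bait hit table for planted
#' round-2 recruits, and a truth table recording every planted label.
#' Round-1 viral scaffolds receive enough high-quotient hits to pass the
#' AVQ thresholds by construction; round-2 scaffolds receive no
#' orthologous-group hits but bait hits concentrating on a single round-1
#' scaffold; non-viral scaffolds receive hits at `nonviral_hit_fraction`
#' (default none).
#'
#' @param cfg A [community_config()].
#' @param dir Optional directory; when given, all files are written there
#'   (`scaffolds.fasta`, `genes.gff3`, `proteins.faa`, `pvog_hits.tsv`,
#'   `quotients.tsv`, `ref_hits.tsv`, `bait_hits.tsv`,
#'   `truth_scaffolds.tsv`).
#' @return List with `scaffolds` (named sequences), `scaffold_info`,
#'   `genes`, `pvog_hits`, `quotients`, `ref_hits`, `bait_hits`, `truth`
#'   and `config`.
#' @export
generate_community <- function(cfg, dir = NULL) {
  stopifnot(inherits(cfg, "community_config"))
  n_round2 <- floor(cfg$n_viral * cfg$round2_fraction)
  if (cfg$n_viral > 0 && n_round2 >= cfg$n_viral) n_round2 <- cfg$n_viral - 1L
  ids <- c(sprintf("virsc_%03d", seq_len(cfg$n_viral)),
           sprintf("cellsc_%03d", seq_len(cfg$n_nonviral)))
  planted_class <- rep(c("viral", "nonviral"),
                       c(cfg$n_viral, cfg$n_nonviral))
  planted_round <- rep(NA_character_, length(ids))
  if (cfg$n_viral > 0) {
    planted_round[seq_len(cfg$n_viral)] <-
      c(rep("round1", cfg$n_viral - n_round2), rep("round2", n_round2))
  }

  scaffolds <- character(0)
  genes <- list()
  for (i in seq_along(ids)) {
    sc <- with_seed(stream_seed(cfg$seed, ids[[i]]),
                    build_scaffold(ids[[i]], cfg))
    scaffolds[[ids[[i]]]] <- sc$seq
    genes[[i]] <- sc$genes
  }
  genes <- do.call(rbind, genes)

  # planted taxonomy and hosts (viral scaffolds only)
  truth <- with_seed(stream_seed(cfg$seed, "truth"), {
    fam <- ifelse(planted_class == "viral",
                  sample(VIRAL_FAMILIES, length(ids), replace = TRUE),
                  NA_character_)
    host <- rep(NA_character_, length(ids))
    sig <- rep(NA_character_, length(ids))
    vir_idx <- which(planted_class == "viral")
    n_host <- round(length(vir_idx) * cfg$host_fraction)
    if (n_host > 0) {
      chosen <- vir_idx[seq_len(n_host)]
      host[chosen] <- sample(names(HOST_TAXA), n_host, replace = TRUE)
      sig[chosen] <- rep(c("crispr", "homology", "trna"),
                         length.out = n_host)
    }
    data.frame(scaffold_id = ids, sample_id = cfg$sample_id,
               planted_class = planted_class,
               planted_round = planted_round,
               family = fam,
               genus = ifelse(is.na(fam), NA, paste0(sub("viridae", "", fam),
                                                     "virus")),
               species = ifelse(is.na(fam), NA,
                                paste0("virus_sp_", seq_along(ids))),
               host_id = host,
               host_taxonomy = ifelse(is.na(host), NA,
                                      unname(HOST_TAXA[host])),
               host_signal = sig, stringsAsFactors = FALSE)
  })

  rbind_rows <- function(lst) {
    lst <- lst[!vapply(lst, is.null, logical(1))]
    if (!length(lst)) return(NULL)
    out <- do.call(rbind, lst)
    rownames(out) <- NULL
    out
  }
  empty_hits <- data.frame(
    query_gene_id = character(0), subject_id = character(0),
    percent_identity = numeric(0), aln_length = numeric(0),
    mismatches = numeric(0), gaps = numeric(0), qstart = numeric(0),
    qend = numeric(0), sstart = numeric(0), send = numeric(0),
    evalue = numeric(0), bitscore = numeric(0), stringsAsFactors = FALSE)

  # orthologous-group hits + quotients
  hit_rows <- list()
  quot <- c(low_vq_og = 0.05)
  for (i in seq_along(ids)) {
    id <- ids[[i]]
    g <- genes[genes$scaffold_id == id, , drop = FALSE]
    frac <- if (planted_class[[i]] == "nonviral") cfg$nonviral_hit_fraction
            else if (identical(planted_round[[i]], "round1"))
              cfg$round1_hit_fraction else 0
    if (frac <= 0) next
    hit_rows[[id]] <- with_seed(stream_seed(cfg$seed, paste0("pvog_", id)), {
      n_hit <- if (identical(planted_round[[i]], "round1")) {
        max(3L, ceiling(frac * nrow(g)), ceiling(0.1 * nrow(g)))
      } else max(1L, floor(frac * nrow(g)))
      n_hit <- min(n_hit, nrow(g))
      which_g <- sample(g$gene_id, n_hit)
      q <- if (identical(planted_round[[i]], "round1")) {
        runif(n_hit, cfg$quotient_range[1], cfg$quotient_range[2])
      } else runif(n_hit, 0.01, 0.1)
      ogs <- sprintf("VOG%s_%02d", id, seq_len(n_hit))
      quot[ogs] <- q
      data.frame(query_gene_id = which_g, subject_id = ogs,
                 percent_identity = round(runif(n_hit, 35, 90), 1),
                 aln_length = sample(40:200, n_hit, replace = TRUE),
                 mismatches = 0, gaps = 0, qstart = 1, qend = 50,
                 sstart = 1, send = 50,
                 evalue = 10^-runif(n_hit, 6, 30),
                 bitscore = round(runif(n_hit, 60, 300), 1),
                 stringsAsFactors = FALSE)
    })
  }
  pvog_hits <- rbind_rows(hit_rows)
  if (is.null(pvog_hits)) pvog_hits <- empty_hits

  # taxonomy reference hits (viral scaffolds; majority to planted family)
  ref_rows <- list()
  for (i in which(planted_class == "viral")) {
    id <- ids[[i]]
    g <- genes[genes$scaffold_id == id, , drop = FALSE]
    ref_rows[[id]] <- with_seed(stream_seed(cfg$seed, paste0("ref_", id)), {
      n_hit <- max(2L, floor(0.6 * nrow(g)))
      which_g <- sample(g$gene_id, n_hit)
      tax <- paste(truth$family[[i]], truth$genus[[i]], truth$species[[i]],
                   sep = ";")
      # one minority hit to a different family keeps majority voting honest
      other <- setdiff(VIRAL_FAMILIES, truth$family[[i]])[[1]]
      taxes <- c(rep(tax, n_hit - 1L),
                 paste(other, paste0(sub("viridae", "", other), "virus"),
                       "virus_other", sep = ";"))
      data.frame(query_gene_id = which_g,
                 subject_id = sprintf("ref_%s_%02d", id, seq_len(n_hit)),
                 percent_identity = round(runif(n_hit, 35, 80), 1),
                 aln_length = sample(40:200, n_hit, replace = TRUE),
                 mismatches = 0, gaps = 0, qstart = 1, qend = 50,
                 sstart = 1, send = 50,
                 evalue = 10^-runif(n_hit, 6, 30),
                 bitscore = round(runif(n_hit, 60, 300), 1),
                 subject_taxonomy = taxes, stringsAsFactors = FALSE)
    })
  }
  ref_hits <- rbind_rows(ref_rows)

  # bait hits: round-2 scaffolds concentrate on one round-1 scaffold
  bait_rows <- list()
  r1_ids <- ids[planted_class == "viral" & planted_round %in% "round1"]
  for (i in which(planted_round %in% "round2")) {
    id <- ids[[i]]
    g <- genes[genes$scaffold_id == id, , drop = FALSE]
    bait_rows[[id]] <- with_seed(stream_seed(cfg$seed, paste0("bait_", id)), {
      bait_sc <- sample(r1_ids, 1L)
      bg <- genes[genes$scaffold_id == bait_sc, , drop = FALSE]
      m <- min(nrow(g), max(3L, ceiling(0.2 * nrow(g))))
      which_g <- sample(g$gene_id, m)
      data.frame(query_gene_id = which_g,
                 subject_id = sample(bg$gene_id, m, replace = TRUE),
                 percent_identity = round(runif(m, 35, 70), 1),
                 aln_length = sample(50:200, m, replace = TRUE),
                 mismatches = 0, gaps = 0, qstart = 1, qend = 50,
                 sstart = 1, send = 50,
                 evalue = 10^-runif(m, 8, 40),
                 bitscore = round(runif(m, 80, 250), 1),
                 stringsAsFactors = FALSE)
    })
  }
  bait_hits <- rbind_rows(bait_rows)
  if (is.null(bait_hits)) bait_hits <- empty_hits
  if (is.null(ref_hits)) {
    ref_hits <- cbind(empty_hits, subject_taxonomy = character(0))
  }

  scaffold_info <- data.frame(
    scaffold_id = ids, sample_id = cfg$sample_id,
    length = nchar(scaffolds)[ids],
    classification = "unclassified", stringsAsFactors = FALSE)

  out <- list(scaffolds = scaffolds, scaffold_info = scaffold_info,
              genes = genes, pvog_hits = pvog_hits, quotients = quot,
              ref_hits = ref_hits, bait_hits = bait_hits, truth = truth,
              config = cfg)
  if (!is.null(dir)) write_community(out, dir)
  out
}

#' Write a synthetic community to disk in the standard formats
#'
#' @param community Result of [generate_community()].
#' @param dir Output directory (created if absent).
#' @return Named vector of file paths, invisibly.
#' @export
write_community <- function(community, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_fasta(community$scaffolds, p("scaffolds.fasta"))
  write_genes_gff(community$genes, p("genes.gff3"))
  write_fasta(setNames(community$genes$protein, community$genes$gene_id),
              p("proteins.faa"))
  write_hits_table(community$pvog_hits, p("pvog_hits.tsv"))
  write.table(data.frame(og_id = names(community$quotients),
                         quotient = unname(community$quotients)),
              p("quotients.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write_hits_table(community$ref_hits, p("ref_hits.tsv"))
  write_hits_table(community$bait_hits, p("bait_hits.tsv"))
  write.table(community$truth, p("truth_scaffolds.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, na = "")
  invisible(setNames(
    p(c("scaffolds.fasta", "genes.gff3", "proteins.faa", "pvog_hits.tsv",
        "quotients.tsv", "ref_hits.tsv", "bait_hits.tsv",
        "truth_scaffolds.tsv")),
    c("scaffolds", "genes", "proteins", "pvog_hits", "quotients",
      "ref_hits", "bait_hits", "truth")))
}

#' Emit host-signal fixtures for a community's planted virus-host pairs
#'
#' For each planted pair, exactly one signal is embedded verbatim according
#' to the truth table's `host_signal`: a 35 bp spacer copied from the viral
#' scaffold into the host's spacer set, an identical 72 nt tRNA placed in
#' both tRNA sets, or a 1.5 kb viral segment copied into the host genome.
#' Host genomes are synthetic random sequences.
#'
#' @param community Result of [generate_community()].
#' @param dir Optional output directory (`host_genomes.fasta`,
#'   `spacers.fasta`, `viral_trnas.fasta`, `host_trnas.fasta`,
#'   `host_taxonomy.tsv`).
#' @param host_genome_length Length of each synthetic host genome bp.
#' @return List with `host_genomes`, `host_taxonomy`, `spacers`,
#'   `viral_trnas`, `host_trnas`.
#' @export
emit_host_fixtures <- function(community, dir = NULL,
                               host_genome_length = 20000L) {
  truth <- community$truth
  seed <- community$config$seed
  hosts <- unique(truth$host_id[!is.na(truth$host_id)])
  genomes <- setNames(vapply(hosts, function(h) {
    with_seed(stream_seed(seed, paste0("host_", h)),
              paste(sample(BASES, host_genome_length, replace = TRUE),
                    collapse = ""))
  }, character(1)), hosts)
  spacers <- character(0)
  viral_trnas <- character(0)
  host_trnas <- character(0)
  planted <- which(!is.na(truth$host_id))
  for (i in planted) {
    vid <- truth$scaffold_id[[i]]
    hid <- truth$host_id[[i]]
    vseq <- community$scaffolds[[vid]]
    sig <- truth$host_signal[[i]]
    if (sig == "crispr") {
      start <- with_seed(stream_seed(seed, paste0("sp_", vid)),
                         sample.int(nchar(vseq) - 35L, 1L))
      spacers[[paste0(hid, "|spacer_", vid)]] <-
        substr(vseq, start, start + 34L)
    } else if (sig == "trna") {
      trna <- with_seed(stream_seed(seed, paste0("trna_", vid)),
                        paste(sample(BASES, 72L, replace = TRUE),
                              collapse = ""))
      viral_trnas[[paste0(vid, "|trna_1")]] <- trna
      host_trnas[[paste0(hid, "|trna_", vid)]] <- trna
    } else if (sig == "homology") {
      start <- with_seed(stream_seed(seed, paste0("hom_", vid)),
                         sample.int(nchar(vseq) - 1500L, 1L))
      seg <- substr(vseq, start, start + 1499L)
      ins <- 5000L
      genomes[[hid]] <- paste0(substr(genomes[[hid]], 1, ins), seg,
                               substr(genomes[[hid]], ins + 1L,
                                      nchar(genomes[[hid]])))
    }
  }
  out <- list(host_genomes = genomes,
              host_taxonomy = HOST_TAXA[hosts],
              spacers = spacers, viral_trnas = viral_trnas,
              host_trnas = host_trnas)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(genomes, file.path(dir, "host_genomes.fasta"))
    write_fasta(spacers, file.path(dir, "spacers.fasta"))
    write_fasta(viral_trnas, file.path(dir, "viral_trnas.fasta"))
    write_fasta(host_trnas, file.path(dir, "host_trnas.fasta"))
    write.table(data.frame(host_id = hosts,
                           taxonomy = unname(HOST_TAXA[hosts])),
                file.path(dir, "host_taxonomy.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  out
}

#' Specification for microdiversity read simulation
#'
#' @param coverage Target mean reads fully covering each codon (default
#'   50).
#' @param n_variant_sites Number of planted variant codons (default 20).
#' @param maf_range Per-site variant frequency range (default 0.05-0.5).
#' @param alpha Selection factor in (0, 1]: acceptance probability of a
#'   proposed nonsynonymous variant (synonymous proposals are always
#'   accepted), so `alpha = 1` is neutrality and smaller values mimic
#'   purifying selection; by construction the expected pN/pS of the
#'   planted variants is `alpha`.
#' @param read_length Read length in bp (default 150, emitted single-end).
#' @param seed Integer seed.
#' @return List of class `microdiv_spec`.
#' @export
microdiv_spec <- function(coverage = 50, n_variant_sites = 20,
                          maf_range = c(0.05, 0.5), alpha = 1,
                          read_length = 150L, seed = 1L) {
  stopifnot(alpha > 0, alpha <= 1, all(maf_range > 0), all(maf_range < 1))
  structure(as.list(environment()), class = "microdiv_spec")
}

codon_neighbors <- function(ref_codon) {
  chars <- strsplit(ref_codon, "")[[1]]
  unlist(lapply(1:3, function(i) {
    vapply(setdiff(BASES, chars[i]), function(b) {
      m <- chars; m[i] <- b; paste(m, collapse = "")
    }, character(1))
  }), use.names = FALSE)
}

# Plant n_sites variants under selection strength alpha: propose a (site,
# neighbor) pair — site uniform over unplanted plantable codons, variant
# uniform over that codon's 9 single-nucleotide neighbors — accept
# synonymous proposals always and nonsynonymous ones with probability
# alpha, redrawing the whole pair until acceptance. Rejection re-draws the
# site as well, so across the gene the accepted syn:nonsyn ratio is
# f_S : alpha * f_N and the expected pN/pS of the planted set is exactly
# alpha. Returns a data.frame of planted sites (gene orientation).
plant_variants <- function(ref_codons, plantable, n_sites, alpha) {
  gc <- genetic_code()
  planted <- list()
  open <- plantable
  while (length(planted) < n_sites && length(open)) {
    i <- open[sample.int(length(open), 1L)]
    cand <- sample(codon_neighbors(ref_codons[[i + 1L]]), 1L)
    syn <- gc[[cand]] == gc[[ref_codons[[i + 1L]]]]
    if (syn || runif(1) <= alpha) {
      planted[[length(planted) + 1L]] <- data.frame(
        codon_index = i, ref_codon = ref_codons[[i + 1L]],
        variant_codon = cand,
        effect = if (syn) "synonymous" else "nonsynonymous",
        stringsAsFactors = FALSE)
      open <- setdiff(open, i)
    }
  }
  out <- do.call(rbind, planted)
  out[order(out$codon_index), , drop = FALSE]
}

#' Simulate reads over a gene with planted codon variants
#'
#' Reads of fixed length tile the gene with uniform start placement at the
#' target mean per-codon coverage. Variant sites are planted at distinct
#' codon positions (the initial ATG and terminal stop are excluded): a
#' (site, neighbor) proposal is drawn uniformly — the variant codon from
#' the site's nine single-nucleotide neighbors — accepted always when
#' synonymous and with probability `alpha` when nonsynonymous, and redrawn
#' in full on rejection, so the expected pN/pS of the planted set is
#' exactly `alpha`. Each read fully covering a planted site carries the
#' variant with the planted frequency (independent Bernoulli per read).
#' Sites no read fully covers are dropped from the truth with a warning.
#'
#' @param gene One-row gene `data.frame` (`gene_id`, `scaffold_id`,
#'   `start`, `end`, `strand`).
#' @param scaffold_seq Scaffold sequence string.
#' @param spec A [microdiv_spec()].
#' @return List with `aln` (alignment `data.frame` compatible with
#'   [read_sam()] output) and `truth` (`codon_index`, `ref_codon`,
#'   `variant_codon`, `frequency`, `effect`, `alpha`; gene orientation).
#' @export
simulate_reads <- function(gene, scaffold_seq, spec) {
  stopifnot(inherits(spec, "microdiv_spec"), nrow(gene) == 1)
  slen <- nchar(scaffold_seq)
  # reads cannot exceed the scaffold; clamp for short test scaffolds
  rl <- min(as.integer(spec$read_length), slen)
  glen <- gene$end - gene$start + 1L
  n_codons <- glen %/% 3L
  with_seed(stream_seed(spec$seed, gene$gene_id), {
    # plant variants (gene orientation)
    plantable <- seq.int(1L, n_codons - 2L)  # skip ATG and stop codon
    n_sites <- min(spec$n_variant_sites, length(plantable))
    cds <- gene_cds(scaffold_seq, gene$start, gene$end, gene$strand)
    ref_codons <- split_codons(cds)
    truth <- plant_variants(ref_codons, plantable, n_sites, spec$alpha)
    truth$frequency <- runif(nrow(truth), spec$maf_range[1],
                             spec$maf_range[2])
    truth$alpha <- spec$alpha

    # uniform read placement over the gene's window
    lo <- max(1L, gene$start - rl + 3L)
    hi <- min(slen - rl + 1L, gene$end - 2L)
    stopifnot(hi >= lo)
    w <- hi - lo + 1L
    n_reads <- max(1L, round(spec$coverage * w / (rl - 2L)))
    starts <- sort(sample.int(w, n_reads, replace = TRUE) + lo - 1L)
    seqs <- substring(scaffold_seq, starts, starts + rl - 1L)

    # scaffold-oriented codon start positions and variant codons
    covered <- logical(nrow(truth))
    for (t in seq_len(nrow(truth))) {
      i <- truth$codon_index[[t]]
      s <- if (gene$strand == "+") gene$start + 3L * i
           else gene$end - 3L * i - 2L
      var_sc <- if (gene$strand == "-") revcomp(truth$variant_codon[[t]])
                else truth$variant_codon[[t]]
      spans <- which(starts <= s & starts + rl - 1L >= s + 2L)
      if (!length(spans)) next
      covered[t] <- TRUE
      carry <- spans[runif(length(spans)) < truth$frequency[[t]]]
      if (length(carry)) {
        off <- s - starts[carry] + 1L
        substr(seqs[carry], off, off + 2L) <- rep(var_sc, length(carry))
      }
    }
    if (any(!covered)) {
      warning(sum(!covered),
              " planted site(s) spanned by no read; dropped from truth")
      truth <- truth[covered, , drop = FALSE]
    }
    aln <- data.frame(
      read_id = sprintf("%s_r%05d", gene$gene_id, seq_len(n_reads)),
      scaffold_id = gene$scaffold_id, pos = starts,
      cigar = paste0(rl, "M"), seq = seqs,
      sample_id = NA_character_, fraction = NA_character_,
      stringsAsFactors = FALSE)
    aln$blocks <- I(lapply(starts, function(p) {
      m <- matrix(c(1L, p, rl), 1, 3)
      colnames(m) <- c("read_off", "ref_pos", "len")
      m
    }))
    list(aln = aln, truth = truth)
  })
}

#' Simulate a selection experiment and recover per-gene pN/pS
#'
#' Builds `n_genes` standalone single-gene scaffolds, simulates reads with
#' the given selection factor, runs the full pileup / variant-filter /
#' pN-pS stage, and returns the per-gene microdiversity table. Used to
#' verify that neutral simulations recover pN/pS near 1 and that
#' selection-factor `alpha` simulations recover pN/pS near `alpha`.
#'
#' @param n_genes Number of independent genes (default 50).
#' @param n_codons Codons per gene excluding the stop (default 300).
#' @param alpha Selection factor (default 1).
#' @param coverage Mean per-codon coverage (default 50).
#' @param n_variant_sites Planted variant codons per gene (default 200).
#' @param maf_range Variant frequency range (default 0.05-0.5).
#' @param seed Integer seed.
#' @return Per-gene `data.frame` from [gene_microdiversity()].
#' @export
simulate_selection_experiment <- function(n_genes = 50, n_codons = 300,
                                          alpha = 1, coverage = 50,
                                          n_variant_sites = 200,
                                          maf_range = c(0.05, 0.5),
                                          seed = 1L) {
  rows <- lapply(seq_len(n_genes), function(g) {
    gid <- sprintf("selgene_a%s_%03d", format(alpha), g)
    cds <- with_seed(stream_seed(seed, paste0("cds_", gid)),
                     random_cds(n_codons))
    pad <- strrep("A", 30)
    scaffold <- paste0(pad, cds, pad)
    gene <- data.frame(gene_id = gid, scaffold_id = gid,
                       start = 31L, end = 30L + nchar(cds), strand = "+",
                       stringsAsFactors = FALSE)
    spec <- microdiv_spec(coverage = coverage,
                          n_variant_sites = n_variant_sites,
                          maf_range = maf_range, alpha = alpha,
                          seed = stream_seed(seed, gid))
    sim <- simulate_reads(gene, scaffold, spec)
    pu <- pileup_codons(sim$aln, gene, scaffold)
    calls <- call_variants(pu)
    gene_microdiversity(calls, pu, cds, gid)
  })
  do.call(rbind, rows)
}
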