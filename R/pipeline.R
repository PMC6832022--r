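# End-to-end orchestration: simulate -> classify -> annotate -> abundance ->
# microdiversity, from one configuration, with a run manifest recording the
# config snapshot, seeds, input checksums and per-stage row counts.

#' Run the full synthetic-community pipeline
#'
#' Generates a seeded synthetic community, writes its files, classifies
#' scaffolds (AVQ round, baiting, optional curation), annotates taxonomy,
#' functional categories and hosts, computes abundance profiles with
#' Shannon diversity, simulates reads over the genes of a subset of
#' scaffolds and computes per-gene microdiversity with group medians. Every
#' stage's outputs are TSVs in `outdir`; a `manifest.json` records the
#' configuration, file checksums and row counts. Identical config + seed
#' reproduce identical outputs.
#'
#' @param config List (or path to a YAML file) with optional entries
#'   `seed`, `outdir`, `community` (arguments to [community_config()]),
#'   `reads` (arguments to [microdiv_spec()] plus `n_scaffolds`, the
#'   number of viral scaffolds whose genes receive simulated reads),
#'   `thresholds` (overrides for [viromicro_config()]) and `curated_ids`.
#'   `outdir` is required.
#' @return Invisibly, a list with all stage results and the manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$outdir)) stop("config validation: 'outdir' is required")
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  if (!is.null(config$reads$maf_range)) {
    config$reads$maf_range <- as.numeric(config$reads$maf_range)
  }
  bad <- setdiff(names(config),
                 c("seed", "outdir", "community", "reads", "thresholds",
                   "curated_ids", "subsample_n"))
  if (length(bad)) {
    stop("config validation: unknown entr(ies): ", paste(bad, collapse = ", "))
  }
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cfg <- viromicro_config()
  if (!is.null(config$thresholds)) {
    cfg <- utils::modifyList(cfg, config$thresholds)
  }

  # stage 1: simulate community
  ccfg <- do.call(community_config,
                  c(config$community, list(seed = seed)))
  comm <- generate_community(ccfg, dir = file.path(outdir, "community"))
  hostfix <- emit_host_fixtures(comm, dir = file.path(outdir, "community"))

  # stage 2: classify
  cls <- classify_scaffolds(comm$scaffold_info, comm$genes, comm$pvog_hits,
                            comm$quotients, comm$bait_hits,
                            config$curated_ids, cfg)
  class_tab <- merge(cls$scaffold_info,
                     cls$avq[, c("scaffold_id", "n_orfs", "percent_hit",
                                 "avq")], by = "scaffold_id", all.x = TRUE)
  write.table(class_tab, file.path(outdir, "classification.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE, na = "")

  # stage 3: annotate
  viral_ids <- cls$scaffold_info$scaffold_id[
    grepl("^viral", cls$scaffold_info$classification)]
  viral_genes <- comm$genes[comm$genes$scaffold_id %in% viral_ids, ,
                            drop = FALSE]
  tax <- closest_relative(viral_genes, comm$ref_hits, "family",
                          cfg$taxonomy$min_identity, cfg$taxonomy$min_bitscore,
                          cfg$taxonomy$min_aln_len, cfg$taxonomy$max_evalue)
  cats <- cbind(comm$genes[, c("gene_id", "scaffold_id", "product")],
                assign_category(comm$genes$product))
  hosts <- predict_hosts(comm$scaffolds[viral_ids], hostfix$host_genomes,
                         hostfix$host_taxonomy, hostfix$spacers,
                         hostfix$viral_trnas, hostfix$host_trnas,
                         rank = 1L, config = cfg)
  write.table(tax, file.path(outdir, "taxonomy.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, na = "")
  write.table(cats, file.path(outdir, "categories.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, na = "")
  write.table(hosts, file.path(outdir, "hosts.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, na = "")

  # stage 4+5: simulate reads over genes of the first viral scaffolds,
  # abundance + microdiversity
  rcfg <- config$reads
  n_sc <- if (is.null(rcfg$n_scaffolds)) 2L else rcfg$n_scaffolds
  rcfg$n_scaffolds <- NULL
  sim_ids <- utils::head(viral_ids, n_sc)
  sim_genes <- comm$genes[comm$genes$scaffold_id %in% sim_ids, , drop = FALSE]
  alns <- list(); truths <- list()
  for (i in seq_len(nrow(sim_genes))) {
    g <- sim_genes[i, , drop = FALSE]
    spec <- do.call(microdiv_spec,
                    c(rcfg, list(seed = stream_seed(seed, g$gene_id))))
    sim <- simulate_reads(g, comm$scaffolds[[g$scaffold_id]], spec)
    alns[[i]] <- sim$aln
    truths[[i]] <- cbind(gene_id = g$gene_id, sim$truth)
  }
  aln <- do.call(rbind, alns)
  sam_path <- file.path(outdir, "reads.sam")
  write_sam(aln, setNames(nchar(comm$scaffolds), names(comm$scaffolds)),
            sam_path)
  aln <- read_sam(sam_path, sample_id = ccfg$sample_id, fraction = "viral")
  if (!is.null(config$subsample_n)) {
    aln <- subsample_reads(aln, config$subsample_n, seed)
  }
  prof <- abundance_profile(aln, ccfg$sample_id, "viral")
  fam_key <- setNames(tax$taxon, tax$scaffold_id)
  fam_ab <- aggregate_by(prof$percent, fam_key)
  ab_tab <- data.frame(scaffold_id = names(prof$percent),
                       reads = unname(prof$counts[names(prof$percent)]),
                       percent = unname(prof$percent),
                       family = unname(fam_key[names(prof$percent)]),
                       stringsAsFactors = FALSE)
  write.table(ab_tab, file.path(outdir, "abundance.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, na = "")

  md <- microdiversity_run(aln, sim_genes, comm$scaffolds,
                           cfg$snp$min_count, cfg$snp$min_freq,
                           cfg$snp$min_cov)
  md$sample_id <- ccfg$sample_id
  md$fraction <- "viral"
  md$category_broad <- cats$category_broad[match(md$gene_id, cats$gene_id)]
  med <- category_medians(md, c("sample_id", "fraction", "category_broad"),
                          cfg$medians$min_genes)
  write.table(md, file.path(outdir, "microdiversity_genes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, na = "")
  write.table(med, file.path(outdir, "microdiversity_medians.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE, na = "")

  # manifest
  files <- list.files(outdir, recursive = TRUE, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest <- list(
    tool = "viromicro", version = as.character(packageVersion("viromicro")),
    seed = seed,
    thresholds = cfg,
    community = config$community,
    reads = config$reads,
    checksums = as.list(tools::md5sum(sort(files))),
    rows = list(scaffolds = nrow(cls$scaffold_info),
                genes = nrow(comm$genes),
                alignments = nrow(aln),
                taxonomy = nrow(tax), hosts = nrow(hosts),
                microdiversity = nrow(md), medians = nrow(med)),
    shannon = prof$shannon)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(community = comm, classification = cls, taxonomy = tax,
                 categories = cats, hosts = hosts, abundance = prof,
                 microdiversity = md, medians = med, manifest = manifest))
}
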