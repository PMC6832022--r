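# Three-round identification of bona fide viral scaffolds:
#   round 1 — AVQ scoring against virus-orthologous-group (pVOG-style)
#             hits: a scaffold passes when >= 10% of its ORFs have hits and
#             the sum of best-hit viral quotients (AVQ) is >= 2;
#   round 2 — protein baiting: an unclassified scaffold is recruited when
#             >= 20% of its ORFs (minimum three) match ORFs of a single
#             round-1 scaffold under identity/bitscore/length/E filters;
#   round 3 — manual curation from a supplied id list.
# Plus concordance scoring against external classifier labels and viral
# population clustering by nucleotide identity.

#' AVQ scoring (classification round 1)
#'
#' For each scaffold, finds the best hit per ORF among orthologous-group
#' hits with `evalue <= max_evalue` (best = lowest e-value; ties broken by
#' higher bitscore, then lexicographic subject id), sums the viral
#' quotients of those best hits (the AVQ) and computes the percentage of
#' ORFs with any qualifying hit. A scaffold passes when
#' `percent_hit >= min_percent` and `avq >= min_avq`, both inclusive.
#'
#' @param genes Gene table (`gene_id`, `scaffold_id`).
#' @param hits Hit table from [read_hits_table()] with `query_gene_id` in
#'   `genes$gene_id` and `subject_id` naming orthologous groups.
#' @param quotients Named numeric vector mapping orthologous-group id to
#'   its viral quotient in `[0, 1]`. Hits to groups absent from the table
#'   are an error.
#' @param min_percent,min_avq,max_evalue Thresholds (defaults 10, 2, 1e-5).
#' @return `data.frame`, one row per scaffold: `scaffold_id`, `n_orfs`,
#'   `n_orfs_with_hit`, `percent_hit`, `avq`, `passed_round1`.
#' @export
avq_round1 <- function(genes, hits, quotients, min_percent = 10,
                       min_avq = 2, max_evalue = 1e-5) {
  hits <- hits[hits$evalue <= max_evalue, , drop = FALSE]
  hits <- hits[hits$query_gene_id %in% genes$gene_id, , drop = FALSE]
  unknown <- setdiff(unique(hits$subject_id), names(quotients))
  if (length(unknown)) {
    stop("hit(s) to orthologous group(s) with no viral quotient: ",
         paste(unknown, collapse = ", "))
  }
  if (nrow(hits)) {
    ord <- order(hits$query_gene_id, hits$evalue, -hits$bitscore,
                 hits$subject_id)
    hits <- hits[ord, , drop = FALSE]
    best <- hits[!duplicated(hits$query_gene_id), , drop = FALSE]
    best$quotient <- unname(quotients[best$subject_id])
  } else {
    best <- data.frame(query_gene_id = character(0),
                       quotient = numeric(0))
  }
  gene_scaffold <- setNames(genes$scaffold_id, genes$gene_id)
  best$scaffold_id <- unname(gene_scaffold[best$query_gene_id])
  scaffs <- unique(genes$scaffold_id)
  n_orfs <- as.integer(table(genes$scaffold_id)[scaffs])
  n_hit <- integer(length(scaffs))
  avq <- numeric(length(scaffs))
  if (nrow(best)) {
    th <- table(best$scaffold_id)
    ta <- tapply(best$quotient, best$scaffold_id, sum)
    n_hit <- ifelse(scaffs %in% names(th), as.integer(th[scaffs]), 0L)
    avq <- ifelse(scaffs %in% names(ta), as.numeric(ta[scaffs]), 0)
  }
  percent <- 100 * n_hit / n_orfs
  data.frame(scaffold_id = scaffs, n_orfs = n_orfs,
             n_orfs_with_hit = n_hit, percent_hit = percent, avq = avq,
             passed_round1 = percent >= min_percent & avq >= min_avq,
             stringsAsFactors = FALSE)
}

#' Protein baiting (classification round 2)
#'
#' Candidate scaffolds (not classified in round 1) are recruited when
#' enough of their ORFs match ORFs from a single round-1 scaffold. Hits
#' are filtered on identity, bitscore, alignment length and e-value; then,
#' for each bait (round-1) scaffold, the number of distinct candidate ORFs
#' with at least one passing hit to it is counted. A candidate is recruited
#' iff the maximum such count is `>= min_matches` and covers
#' `>= min_percent` of the candidate's ORFs, attributed to the arg-max bait
#' scaffold (ties broken by higher summed bitscore, then lexicographic id).
#'
#' @param genes Gene table of the candidate scaffolds.
#' @param hits Candidate-ORF vs round-1-ORF hit table.
#' @param bait_genes Gene table of the round-1 scaffolds (resolves hit
#'   subjects to bait scaffolds).
#' @param min_percent,min_matches Recruitment thresholds (defaults 20, 3).
#' @param min_identity,min_bitscore,min_aln_len,max_evalue Hit filters
#'   (defaults 30, 50, 30, 1e-5).
#' @return `data.frame`, one row per candidate scaffold: `scaffold_id`,
#'   `n_orfs`, `best_bait_scaffold`, `n_matched_to_best`,
#'   `percent_matched`, `recruited`.
#' @export
bait_round2 <- function(genes, hits, bait_genes, min_percent = 20,
                        min_matches = 3, min_identity = 30,
                        min_bitscore = 50, min_aln_len = 30,
                        max_evalue = 1e-5) {
  keep <- hits$percent_identity >= min_identity &
          hits$bitscore >= min_bitscore &
          hits$aln_length >= min_aln_len &
          hits$evalue <= max_evalue
  hits <- hits[keep, , drop = FALSE]
  gene_scaffold <- setNames(genes$scaffold_id, genes$gene_id)
  bait_scaffold <- setNames(bait_genes$scaffold_id, bait_genes$gene_id)
  hits <- hits[hits$query_gene_id %in% names(gene_scaffold) &
                 hits$subject_id %in% names(bait_scaffold), , drop = FALSE]
  hits$cand <- unname(gene_scaffold[hits$query_gene_id])
  hits$bait <- unname(bait_scaffold[hits$subject_id])

  scaffs <- unique(genes$scaffold_id)
  n_orfs <- setNames(as.integer(table(genes$scaffold_id)[scaffs]), scaffs)
  rows <- lapply(scaffs, function(sc) {
    h <- hits[hits$cand == sc, , drop = FALSE]
    if (!nrow(h)) {
      return(data.frame(scaffold_id = sc, n_orfs = n_orfs[[sc]],
                        best_bait_scaffold = NA_character_,
                        n_matched_to_best = 0L, percent_matched = 0,
                        recruited = FALSE, stringsAsFactors = FALSE))
    }
    # distinct candidate ORFs per bait scaffold
    per_bait <- tapply(h$query_gene_id, h$bait,
                       function(q) length(unique(q)))
    best_n <- max(per_bait)
    cands <- names(per_bait)[per_bait == best_n]
    if (length(cands) > 1) {
      bsum <- tapply(h$bitscore[h$bait %in% cands], h$bait[h$bait %in% cands],
                     sum)
      cands <- names(bsum)[order(-bsum, names(bsum))]
    }
    best <- cands[[1]]
    pct <- 100 * best_n / n_orfs[[sc]]
    data.frame(scaffold_id = sc, n_orfs = n_orfs[[sc]],
               best_bait_scaffold = best,
               n_matched_to_best = as.integer(best_n),
               percent_matched = pct,
               recruited = best_n >= min_matches & pct >= min_percent,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Apply a manual curation list (classification round 3)
#'
#' Listed scaffolds that are still unclassified become `viral_curated`;
#' scaffolds already classified viral are left unchanged with a warning.
#'
#' @param scaffold_info `data.frame` with `scaffold_id` and
#'   `classification`.
#' @param curated_ids Character vector of scaffold ids (or a path to a file
#'   of one id per line).
#' @return Updated `scaffold_info`.
#' @export
apply_curation <- function(scaffold_info, curated_ids) {
  if (length(curated_ids) == 1 && file.exists(curated_ids)) {
    curated_ids <- readLines(curated_ids, warn = FALSE)
    curated_ids <- curated_ids[nzchar(trimws(curated_ids))]
  }
  unknown <- setdiff(curated_ids, scaffold_info$scaffold_id)
  if (length(unknown)) {
    stop("curated id(s) not present: ", paste(unknown, collapse = ", "))
  }
  idx <- match(curated_ids, scaffold_info$scaffold_id)
  already <- grepl("^viral", scaffold_info$classification[idx])
  if (any(already)) {
    warning("already-viral id(s) left unchanged: ",
            paste(curated_ids[already], collapse = ", "))
  }
  take <- idx[!already & scaffold_info$classification[idx] == "unclassified"]
  scaffold_info$classification[take] <- "viral_curated"
  scaffold_info
}

#' Concordance with external viral classifiers
#'
#' A bona fide scaffold is concordant if it is flagged viral by either
#' rule: external category in `virsorter_ok`, or score `>= virfinder_score`
#' with p-value `<= virfinder_p` (boundaries inclusive). Scaffolds flagged
#' by neither are discordant; scaffolds without a label row are counted
#' discordant with a warning.
#'
#' @param bona_fide_ids Character vector of bona fide scaffold ids.
#' @param labels `data.frame` with `scaffold_id`, `virsorter_category`,
#'   `virfinder_score`, `virfinder_p` (NAs allowed).
#' @param virsorter_ok Accepted categories (default `1:6`).
#' @param virfinder_score,virfinder_p Score/p thresholds (defaults 0.7,
#'   0.05).
#' @return List with `n_bona_fide`, `n_discordant` and `percent`
#'   (discordant percentage, rounded to 1 decimal).
#' @export
concordance <- function(bona_fide_ids, labels, virsorter_ok = 1:6,
                        virfinder_score = 0.7, virfinder_p = 0.05) {
  idx <- match(bona_fide_ids, labels$scaffold_id)
  missing <- is.na(idx)
  if (any(missing)) {
    warning(sum(missing), " bona fide id(s) without label rows; counted discordant")
  }
  vs <- labels$virsorter_category[idx]
  sc <- labels$virfinder_score[idx]
  pv <- labels$virfinder_p[idx]
  by_vs <- !is.na(vs) & vs %in% virsorter_ok
  by_vf <- !is.na(sc) & !is.na(pv) & sc >= virfinder_score & pv <= virfinder_p
  flagged <- !missing & (by_vs | by_vf)
  n_disc <- sum(!flagged)
  list(n_bona_fide = length(bona_fide_ids), n_discordant = n_disc,
       percent = round(100 * n_disc / length(bona_fide_ids), 1))
}

#' Run the full three-round classification
#'
#' @param scaffold_info `data.frame` with `scaffold_id` and
#'   `classification` (`"unclassified"` at entry).
#' @param genes Gene table for all scaffolds.
#' @param pvog_hits,quotients Round-1 inputs (see [avq_round1()]).
#' @param bait_hits Candidate-vs-round-1 protein hit table, or `NULL` to
#'   skip round 2.
#' @param curated_ids Manual curation ids (or file path), or `NULL`.
#' @param config Configuration list from [viromicro_config()].
#' @return List with updated `scaffold_info`, the `avq` table and the
#'   `bait` table.
#' @export
classify_scaffolds <- function(scaffold_info, genes, pvog_hits, quotients,
                               bait_hits = NULL, curated_ids = NULL,
                               config = viromicro_config()) {
  a <- config$avq
  avq <- avq_round1(genes, pvog_hits, quotients, a$min_percent, a$min_avq,
                    a$max_evalue)
  r1 <- avq$scaffold_id[avq$passed_round1]
  i <- scaffold_info$scaffold_id %in% r1 &
       scaffold_info$classification == "unclassified"
  scaffold_info$classification[i] <- "viral_round1"

  bait <- NULL
  if (!is.null(bait_hits) && nrow(bait_hits)) {
    cand <- scaffold_info$scaffold_id[
      scaffold_info$classification == "unclassified"]
    cand_genes <- genes[genes$scaffold_id %in% cand, , drop = FALSE]
    bait_genes <- genes[genes$scaffold_id %in% r1, , drop = FALSE]
    if (nrow(cand_genes) && nrow(bait_genes)) {
      b <- config$bait
      bait <- bait_round2(cand_genes, bait_hits, bait_genes, b$min_percent,
                          b$min_matches, b$min_identity, b$min_bitscore,
                          b$min_aln_len, b$max_evalue)
      rec <- bait$scaffold_id[bait$recruited]
      j <- scaffold_info$scaffold_id %in% rec &
           scaffold_info$classification == "unclassified"
      scaffold_info$classification[j] <- "viral_round2"
    }
  }
  if (!is.null(curated_ids) && length(curated_ids)) {
    scaffold_info <- apply_curation(scaffold_info, curated_ids)
  }
  list(scaffold_info = scaffold_info, avq = avq, bait = bait)
}

# Best ungapped-diagonal identity between two sequences, seeded by shared
# k-mers. Returns identity (fraction) and coverage (aligned overlap as a
# fraction of the shorter sequence) of the best diagonal.
pair_identity <- function(a, b, k = 15L) {
  la <- nchar(a); lb <- nchar(b)
  if (la < k || lb < k) return(c(identity = 0, coverage = 0))
  ka <- substring(a, 1:(la - k + 1L), k:la)
  kb <- substring(b, 1:(lb - k + 1L), k:lb)
  pos_b <- split(seq_along(kb), kb)
  hit <- which(ka %in% names(pos_b))
  if (!length(hit)) return(c(identity = 0, coverage = 0))
  diags <- unlist(lapply(hit, function(i) pos_b[[ka[[i]]]] - i),
                  use.names = FALSE)
  top <- as.integer(names(sort(table(diags), decreasing = TRUE)))
  top <- top[seq_len(min(5L, length(top)))]
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  best <- c(identity = 0, coverage = 0)
  for (d in top) {
    i_lo <- max(1L, 1L - d); i_hi <- min(la, lb - d)
    if (i_lo > i_hi) next
    idx <- i_lo:i_hi
    ident <- mean(ca[idx] == cb[idx + d])
    covg <- length(idx) / min(la, lb)
    if (ident * covg > best[["identity"]] * best[["coverage"]]) {
      best <- c(identity = ident, coverage = covg)
    }
  }
  best
}

#' Cluster scaffolds into viral populations
#'
#' Pairwise nucleotide identity is estimated by k-mer-seeded ungapped
#' comparison on the best shared diagonal; two scaffolds are linked iff the
#' identity is at least `ani_min` percent over at least `cov_min` percent
#' of the shorter sequence. Populations are the connected components of the
#' link graph (singletons allowed). Intended to be run per sample.
#'
#' @param sequences Named character vector of scaffold sequences.
#' @param ani_min Minimum average nucleotide identity, percent (default
#'   95).
#' @param cov_min Minimum alignment coverage of the shorter sequence,
#'   percent (default 80).
#' @param k Seed k-mer length.
#' @return Named character vector mapping scaffold id to population id
#'   (`"pop_<n>"`, numbered by first member in input order).
#' @export
cluster_populations <- function(sequences, ani_min = 95, cov_min = 80,
                                k = 15L) {
  n <- length(sequences)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      pi <- pair_identity(sequences[[i]], sequences[[j]], k)
      if (pi[["identity"]] * 100 >= ani_min &&
          pi[["coverage"]] * 100 >= cov_min) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  ids <- match(roots, unique(roots))
  setNames(paste0("pop_", ids), names(sequences))
}
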