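# Codon-resolved microdiversity: per-codon pileups from read alignments,
# variant calls filtered on count / frequency / codon coverage, and per-gene
# pN/pS against a neutral single-substitution expectation.
#
# The neutral model enumerates, for every sense codon, its 9 single
# nucleotide substitutions under the standard genetic code and classifies
# each as synonymous (amino acid unchanged) or nonsynonymous (changed,
# including stop gains). A gene's neutral opportunity fractions are
#   f_S = sum(n_syn) / (9 * n_codons),   f_N = 1 - f_S
# and, with observed valid variant counts obs_S / obs_N,
#   pN = obs_N / ((obs_N + obs_S) * f_N)
#   pS = obs_S / ((obs_N + obs_S) * f_S)
# so pN/pS = (obs_N / obs_S) * (f_S / f_N): the excess of nonsynonymous
# polymorphism over its neutral share. No transition/transversion weighting
# is applied.

BASES <- c("A", "C", "G", "T")

# cached spectrum table for the 61 sense codons
.codon_env <- new.env(parent = emptyenv())

#' Synonymous/nonsynonymous spectrum of a codon's nine single-substitution
#' neighbors
#'
#' Enumerates all 9 single-nucleotide substitutions of a sense codon under
#' the standard genetic code. A substitution is synonymous iff the encoded
#' amino acid is unchanged; stop gains count as nonsynonymous.
#'
#' @param codon 3-letter codon over `{A,C,G,T}`; must not be a stop codon.
#' @return Named numeric vector `c(n_syn =, n_nonsyn =)`; the two always
#'   sum to 9.
#' @export
#' @examples
#' neutral_codon_spectrum("TTT")  # 1 synonymous (TTC), 8 nonsynonymous
neutral_codon_spectrum <- function(codon) {
  gc <- genetic_code()
  aa <- gc[codon]
  if (is.na(aa)) stop("invalid codon: ", codon)
  if (aa == "*") stop("stop codon has no neutral spectrum: ", codon)
  n_syn <- 0L
  chars <- strsplit(codon, "")[[1]]
  for (i in 1:3) {
    for (b in setdiff(BASES, chars[i])) {
      mut <- chars
      mut[i] <- b
      if (gc[[paste(mut, collapse = "")]] == aa) n_syn <- n_syn + 1L
    }
  }
  c(n_syn = n_syn, n_nonsyn = 9L - n_syn)
}

# n_syn for every sense codon, computed once per session
codon_syn_table <- function() {
  if (is.null(.codon_env$syn)) {
    gc <- genetic_code()
    sense <- names(gc)[gc != "*"]
    .codon_env$syn <- vapply(sense,
                             function(cd) neutral_codon_spectrum(cd)[["n_syn"]],
                             numeric(1))
  }
  .codon_env$syn
}

#' Neutral opportunity fractions of a gene
#'
#' Computes the fraction of the gene's 9-per-codon single-substitution
#' opportunities that are synonymous (`f_S`) and nonsynonymous (`f_N`).
#' Stop codons and codons containing `N` are excluded from the totals.
#'
#' @param cds Gene-oriented coding sequence (length a multiple of 3), or a
#'   character vector of codons.
#' @return Named numeric vector `c(f_N =, f_S =)`, summing to 1.
#' @export
#' @examples
#' gene_neutral_fractions("TTTTTTATG")  # f_S = 2/27
gene_neutral_fractions <- function(cds) {
  codons <- if (length(cds) == 1 && nchar(cds[[1]]) > 3) split_codons(cds)
            else cds
  syn <- codon_syn_table()
  codons <- codons[codons %in% names(syn)]
  if (!length(codons)) stop("no includable (sense, N-free) codons in gene")
  f_s <- sum(syn[codons]) / (9 * length(codons))
  c(f_N = 1 - f_s, f_S = f_s)
}

#' Per-codon pileup of read alignments over a gene
#'
#' A read contributes to a codon only if a single aligned block covers all
#' three codon bases (reads ending mid-codon, or with an indel inside the
#' codon, are excluded there). Read codons are taken in gene orientation:
#' for `-` strand genes the reverse complement of the read bases is
#' compared. Read codons containing `N` are ignored.
#'
#' @param aln Alignment `data.frame` from [read_sam()].
#' @param gene One-row gene `data.frame` (`gene_id`, `scaffold_id`, `start`,
#'   `end`, `strand`).
#' @param scaffold_seq Scaffold sequence string.
#' @return `data.frame` with one row per observed (codon, read codon) pair:
#'   `gene_id`, `codon_index` (0-based, gene orientation), `ref_codon`,
#'   `codon`, `count`. Per-codon coverage is the sum of `count` within a
#'   `codon_index`.
#' @export
pileup_codons <- function(aln, gene, scaffold_seq) {
  stopifnot(nrow(gene) == 1)
  glen <- gene$end - gene$start + 1L
  stopifnot(glen %% 3 == 0)
  n_codons <- glen %/% 3L
  cds <- gene_cds(scaffold_seq, gene$start, gene$end, gene$strand)
  ref_codons <- split_codons(cds)

  aln <- aln[aln$scaffold_id == gene$scaffold_id, , drop = FALSE]
  empty <- data.frame(gene_id = character(0), codon_index = integer(0),
                      ref_codon = character(0), codon = character(0),
                      count = integer(0), stringsAsFactors = FALSE)
  if (!nrow(aln)) return(empty)

  # flatten aligned blocks: one row per block with its read's sequence
  nb <- vapply(aln$blocks, nrow, integer(1))
  if (!sum(nb)) return(empty)
  bm <- do.call(rbind, aln$blocks[nb > 0])
  bseq <- rep(aln$seq[nb > 0], nb[nb > 0])
  lo <- bm[, "ref_pos"]
  hi <- bm[, "ref_pos"] + bm[, "len"] - 1L
  # codon i (0-based, gene orientation) fully inside [lo, hi]
  if (gene$strand == "+") {
    i_min <- ceiling((lo - gene$start) / 3)
    i_max <- floor((hi - 2L - gene$start) / 3)
  } else {
    i_min <- ceiling((gene$end - hi) / 3)
    i_max <- floor((gene$end - 2L - lo) / 3)
  }
  i_min <- pmax(as.integer(i_min), 0L)
  i_max <- pmin(as.integer(i_max), n_codons - 1L)
  n_i <- pmax(0L, i_max - i_min + 1L)
  keep <- n_i > 0L
  if (!any(keep)) return(empty)
  idx <- sequence(n_i[keep]) - 1L + rep(i_min[keep], n_i[keep])
  # scaffold-coordinate codon starts and read offsets, per expanded row
  s <- if (gene$strand == "+") gene$start + 3L * idx
       else gene$end - 3L * idx - 2L
  off <- rep(bm[keep, "read_off"], n_i[keep]) +
         (s - rep(bm[keep, "ref_pos"], n_i[keep]))
  cod <- substring(rep(bseq[keep], n_i[keep]), off, off + 2L)
  if (gene$strand == "-") cod <- revcomp_fast(cod)
  ok <- !grepl("N", cod, fixed = TRUE)
  if (!any(ok)) return(empty)
  dt <- data.table::data.table(codon_index = idx[ok], codon = cod[ok])
  dt <- dt[, list(count = .N), by = c("codon_index", "codon")]
  out <- as.data.frame(dt)
  out <- out[order(out$codon_index, out$codon), , drop = FALSE]
  data.frame(gene_id = gene$gene_id,
             codon_index = out$codon_index,
             ref_codon = ref_codons[out$codon_index + 1L],
             codon = out$codon,
             count = out$count,
             stringsAsFactors = FALSE)
}

#' Call codon variants with the validity filters
#'
#' A variant codon (any observed codon differing from the reference) is
#' valid iff it was seen at least `min_count` times, in at least a
#' `min_freq` fraction of the reads covering the codon, and the codon
#' coverage is at least `min_cov` — all thresholds inclusive. Effects are
#' classified by comparing translations: identical amino acid is
#' synonymous; anything else (including stop gain) is nonsynonymous.
#' Columns whose reference codon is a stop codon or contains `N` are
#' excluded.
#'
#' @param pileup Pileup `data.frame` from [pileup_codons()].
#' @param min_count Minimum variant read count (default 4).
#' @param min_freq Minimum variant frequency among reads covering the codon
#'   (default 0.01).
#' @param min_cov Minimum codon coverage (default 5).
#' @return `data.frame`: `gene_id`, `codon_index`, `ref_codon`,
#'   `variant_codon`, `count`, `coverage`, `frequency`, `effect`
#'   (`"synonymous"`/`"nonsynonymous"`), `valid`.
#' @export
call_variants <- function(pileup, min_count = 4, min_freq = 0.01,
                          min_cov = 5) {
  empty <- data.frame(gene_id = character(0), codon_index = integer(0),
                      ref_codon = character(0), variant_codon = character(0),
                      count = integer(0), coverage = integer(0),
                      frequency = numeric(0), effect = character(0),
                      valid = logical(0), stringsAsFactors = FALSE)
  if (!nrow(pileup)) return(empty)
  gc <- genetic_code()
  ref_aa <- gc[pileup$ref_codon]
  keep <- !is.na(ref_aa) & ref_aa != "*"
  pileup <- pileup[keep, , drop = FALSE]
  if (!nrow(pileup)) return(empty)
  cov <- tapply(pileup$count, pileup$codon_index, sum)
  pileup$coverage <- as.integer(cov[as.character(pileup$codon_index)])
  v <- pileup[pileup$codon != pileup$ref_codon, , drop = FALSE]
  if (!nrow(v)) return(empty)
  v$frequency <- v$count / v$coverage
  ref_aa <- unname(gc[v$ref_codon])
  var_aa <- unname(gc[v$codon])
  effect <- ifelse(!is.na(var_aa) & var_aa == ref_aa,
                   "synonymous", "nonsynonymous")
  data.frame(gene_id = v$gene_id, codon_index = v$codon_index,
             ref_codon = v$ref_codon, variant_codon = v$codon,
             count = v$count, coverage = v$coverage,
             frequency = v$frequency, effect = effect,
             valid = v$count >= min_count & v$frequency >= min_freq &
                     v$coverage >= min_cov,
             stringsAsFactors = FALSE)
}

#' Per-gene microdiversity summary
#'
#' Counts valid variants by effect, evaluates the neutral opportunity
#' fractions from the gene's reference coding sequence and derives `pN`,
#' `pS`, `pN/pS` and the percentage of polymorphic sites. By default each
#' distinct valid variant codon at a site counts once (`count_mode =
#' "alleles"`); `"reads"` weights variants by their read counts instead.
#' The polymorphic-site denominator is the number of assayable codons
#' (coverage at least `min_cov`, reference codon sense and N-free);
#' `denominator = "codons"` uses the gene's full codon count instead.
#'
#' @param calls Variant calls from [call_variants()].
#' @param pileup Pileup from [pileup_codons()] (for coverage/assayability).
#' @param cds Gene-oriented reference coding sequence.
#' @param gene_id Gene identifier for the output row.
#' @param min_cov Assayability threshold, matching the variant filter.
#' @param count_mode `"alleles"` (default) or `"reads"`.
#' @param denominator `"assayable"` (default) or `"codons"`.
#' @return One-row `data.frame`: `gene_id`, `obs_N`, `obs_S`, `f_N`, `f_S`,
#'   `pN`, `pS`, `pnps` (`NA` when `obs_S` is 0 or no variants),
#'   `n_polymorphic`, `n_assayable`, `percent_polymorphic`,
#'   `mean_coverage`.
#' @export
gene_microdiversity <- function(calls, pileup, cds, gene_id,
                                min_cov = 5,
                                count_mode = c("alleles", "reads"),
                                denominator = c("assayable", "codons")) {
  count_mode <- match.arg(count_mode)
  denominator <- match.arg(denominator)
  fr <- gene_neutral_fractions(cds)
  gc <- genetic_code()

  if (nrow(pileup)) {
    ok_ref <- !is.na(gc[pileup$ref_codon]) & gc[pileup$ref_codon] != "*"
    cov <- tapply(pileup$count[ok_ref], pileup$codon_index[ok_ref], sum)
  } else cov <- numeric(0)
  n_assayable <- sum(cov >= min_cov)
  mean_coverage <- if (length(cov)) mean(cov) else 0

  vc <- calls[calls$valid, , drop = FALSE]
  w <- if (count_mode == "reads") vc$count else rep(1L, nrow(vc))
  obs_N <- sum(w[vc$effect == "nonsynonymous"])
  obs_S <- sum(w[vc$effect == "synonymous"])
  tot <- obs_N + obs_S
  pN <- if (tot > 0) obs_N / (tot * fr[["f_N"]]) else 0
  pS <- if (tot > 0) obs_S / (tot * fr[["f_S"]]) else 0
  pnps <- if (tot > 0 && obs_S > 0) pN / pS else NA_real_
  n_poly <- length(unique(vc$codon_index))
  denom <- if (denominator == "assayable") n_assayable
           else nchar(cds) %/% 3L
  data.frame(gene_id = gene_id, obs_N = obs_N, obs_S = obs_S,
             f_N = fr[["f_N"]], f_S = fr[["f_S"]],
             pN = pN, pS = pS, pnps = pnps,
             n_polymorphic = n_poly, n_assayable = n_assayable,
             percent_polymorphic = if (denom > 0) 100 * n_poly / denom else 0,
             mean_coverage = mean_coverage,
             stringsAsFactors = FALSE)
}

#' Group medians of pN/pS and percent polymorphic sites
#'
#' For pN/pS medians, only genes with `pN > 0`, `pS > 0`, at least one
#' polymorphic site and a percentage of polymorphic sites of at least 1%
#' are included, and groups with fewer than `min_genes` qualifying genes
#' report no value. Percent-polymorphic medians are computed over all genes
#' with at least one assayable codon.
#'
#' @param stats Per-gene `data.frame` (rows from [gene_microdiversity()])
#'   carrying the grouping columns in `by`.
#' @param by Character vector of grouping column names (e.g. sample,
#'   fraction, category).
#' @param min_genes Minimum qualifying genes per group (default 3).
#' @return `data.frame` with the grouping columns plus `median_pnps`,
#'   `n_genes_pnps`, `median_percent_polymorphic`, `n_genes_poly`.
#' @export
category_medians <- function(stats, by, min_genes = 3) {
  stopifnot(all(by %in% names(stats)))
  key <- interaction(stats[, by, drop = FALSE], drop = TRUE, sep = "\r")
  groups <- split(stats, key)
  rows <- lapply(groups, function(g) {
    qual <- g[!is.na(g$pnps) & g$pN > 0 & g$pS > 0 &
                g$n_polymorphic >= 1 & g$percent_polymorphic >= 1, ,
              drop = FALSE]
    med_pnps <- if (nrow(qual) >= min_genes) median(qual$pnps) else NA_real_
    pp <- g[g$n_assayable >= 1, , drop = FALSE]
    med_pp <- if (nrow(pp)) median(pp$percent_polymorphic) else NA_real_
    out <- g[1, by, drop = FALSE]
    out$median_pnps <- med_pnps
    out$n_genes_pnps <- nrow(qual)
    out$median_percent_polymorphic <- med_pp
    out$n_genes_poly <- nrow(pp)
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-site consensus amino-acid frequency profile
#'
#' For each codon column, translates every spanning read codon and reports
#' the frequency of the consensus (most frequent) amino acid among reads;
#' ties are resolved in favour of the reference amino acid. The polymorphic
#' flag marks sites with at least one valid variant under the standard
#' filters.
#'
#' @param pileup Pileup from [pileup_codons()].
#' @param min_count,min_freq,min_cov Variant validity filters (defaults 4,
#'   0.01, 5).
#' @return `data.frame`: `codon_index`, `ref_aa`, `consensus_aa`,
#'   `consensus_frequency`, `coverage`, `polymorphic`.
#' @export
consensus_profile <- function(pileup, min_count = 4, min_freq = 0.01,
                              min_cov = 5) {
  empty <- data.frame(codon_index = integer(0), ref_aa = character(0),
                      consensus_aa = character(0),
                      consensus_frequency = numeric(0),
                      coverage = integer(0), polymorphic = logical(0))
  if (!nrow(pileup)) return(empty)
  gc <- genetic_code()
  calls <- call_variants(pileup, min_count, min_freq, min_cov)
  poly_sites <- unique(calls$codon_index[calls$valid])
  rows <- lapply(split(pileup, pileup$codon_index), function(col) {
    ref_aa <- unname(gc[col$ref_codon[[1]]])
    aa <- unname(gc[col$codon])
    ok <- !is.na(aa)
    counts <- tapply(col$count[ok], aa[ok], sum)
    coverage <- sum(col$count)
    top <- counts[counts == max(counts)]
    cons <- if (!is.na(ref_aa) && ref_aa %in% names(top)) ref_aa
            else sort(names(top))[[1]]
    data.frame(codon_index = col$codon_index[[1]], ref_aa = ref_aa,
               consensus_aa = cons,
               consensus_frequency = unname(counts[cons]) / coverage,
               coverage = coverage,
               polymorphic = col$codon_index[[1]] %in% poly_sites,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$codon_index), , drop = FALSE]
}

#' Pearson correlation between scaffold coverage and a microdiversity metric
#'
#' @param stats Per-gene `data.frame` with `mean_coverage` and the metric
#'   column.
#' @param metric `"percent_polymorphic"` or `"pnps"`.
#' @return Pearson r, or `NA` if fewer than 3 defined pairs or zero
#'   variance.
#' @export
coverage_correlation <- function(stats,
                                 metric = c("percent_polymorphic", "pnps")) {
  metric <- match.arg(metric)
  x <- stats$mean_coverage
  y <- stats[[metric]]
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) return(NA_real_)
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(NA_real_)
  cor(x[ok], y[ok])
}

#' Run the microdiversity stage over a gene table
#'
#' Convenience wrapper: pileup, variant calls and per-gene summary for every
#' gene of the supplied table.
#'
#' @param aln Alignments from [read_sam()].
#' @param genes Gene table (`gene_id`, `scaffold_id`, `start`, `end`,
#'   `strand`).
#' @param scaffolds Named character vector of scaffold sequences.
#' @param min_count,min_freq,min_cov Variant validity filters.
#' @param count_mode,denominator Passed to [gene_microdiversity()].
#' @return Per-gene `data.frame` of microdiversity summaries.
#' @export
microdiversity_run <- function(aln, genes, scaffolds, min_count = 4,
                               min_freq = 0.01, min_cov = 5,
                               count_mode = "alleles",
                               denominator = "assayable") {
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, , drop = FALSE]
    seq <- scaffolds[[g$scaffold_id]]
    pu <- pileup_codons(aln, g, seq)
    calls <- call_variants(pu, min_count, min_freq, min_cov)
    gene_microdiversity(calls, pu, gene_cds(seq, g$start, g$end, g$strand),
                        g$gene_id, min_cov, count_mode, denominator)
  })
  do.call(rbind, rows)
}
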