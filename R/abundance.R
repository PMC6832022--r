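# Mapped-read relative abundances (percentages of sample reads), taxon and
# host aggregation, Shannon diversity (natural log) and cellular:viral
# fraction ratios. A read counts once, to its best alignment (most aligned
# bases; ties broken by lexicographic scaffold id).

#' Subsample alignments by read id
#'
#' Uniform sample without replacement over distinct read ids, keeping all
#' alignments of the sampled reads. Deterministic per seed; if `n` is at
#' least the number of available reads, everything is kept.
#'
#' @param aln Alignment `data.frame` from [read_sam()].
#' @param n Number of reads to keep.
#' @param seed Integer seed.
#' @return Subsampled alignment `data.frame`.
#' @export
subsample_reads <- function(aln, n, seed) {
  stopifnot(n > 0)
  ids <- sort(unique(aln$read_id))
  if (length(ids) <= n) return(aln)
  keep <- with_seed(seed, sample(ids, n))
  aln[aln$read_id %in% keep, , drop = FALSE]
}

#' Count mapped reads per scaffold (one count per read)
#'
#' Multi-mapped reads are assigned to their best alignment: the one with
#' the most aligned reference bases, ties broken by lexicographic scaffold
#' id.
#'
#' @param aln Alignment `data.frame` from [read_sam()].
#' @return Named integer vector of read counts per scaffold.
#' @export
count_mapped_reads <- function(aln) {
  if (!nrow(aln)) return(setNames(integer(0), character(0)))
  nb <- vapply(aln$blocks, function(b) sum(b[, "len"]), numeric(1))
  ord <- order(aln$read_id, -nb, aln$scaffold_id)
  best <- aln[ord, , drop = FALSE]
  best <- best[!duplicated(best$read_id), , drop = FALSE]
  tab <- table(best$scaffold_id)
  setNames(as.integer(tab), names(tab))
}

#' Relative abundances as percentages of sample reads
#'
#' @param counts Named numeric vector of per-scaffold mapped-read counts.
#' @param total_reads Total reads in the sample (mapped + unmapped); must
#'   be positive and at least `sum(counts)`.
#' @return Named numeric vector of percentages.
#' @export
#' @examples
#' relative_abundance(c(s1 = 75, s2 = 25), 100)
relative_abundance <- function(counts, total_reads) {
  if (total_reads <= 0) stop("total_reads must be positive")
  if (sum(counts) > total_reads) {
    stop("sum of counts exceeds total_reads")
  }
  100 * counts / total_reads
}

#' Aggregate per-scaffold abundances by a grouping key
#'
#' Sums member percentages per group; scaffolds whose key is missing go to
#' the `"unassigned"` bucket. The grand total is preserved.
#'
#' @param percents Named numeric vector of per-scaffold percentages.
#' @param key Named character vector mapping scaffold id to group (e.g.
#'   viral family or host phylum); NAs and absent ids are unassigned.
#' @return Named numeric vector of per-group percentages.
#' @export
aggregate_by <- function(percents, key) {
  grp <- unname(key[names(percents)])
  grp[is.na(grp)] <- "unassigned"
  out <- tapply(percents, grp, sum)
  setNames(as.numeric(out), names(out))
}

#' Shannon diversity index (natural log)
#'
#' `H = -sum(p_i * ln(p_i))` over the positive entries after renormalising
#' the input to proportions.
#'
#' @param abundances Non-negative numeric vector (counts or percentages;
#'   scale-invariant), at least one positive.
#' @return Shannon index.
#' @export
#' @examples
#' shannon_index(rep(1, 4))  # ln(4)
shannon_index <- function(abundances) {
  if (any(abundances < 0)) stop("abundances must be non-negative")
  s <- sum(abundances)
  if (s <= 0) stop("at least one abundance must be positive")
  p <- abundances[abundances > 0] / s
  -sum(p * log(p))
}

#' Build an abundance profile for one sample and fraction
#'
#' @param aln Alignment `data.frame`.
#' @param sample_id,fraction Labels (`fraction` is `"viral"` or
#'   `"cellular"`).
#' @param total_reads Sample total reads (default: number of distinct
#'   mapped read ids, i.e. every read mapped).
#' @param subsample_n,seed Optional read subsampling before counting.
#' @return List with `sample_id`, `fraction`, `total_reads`, `counts`,
#'   `percent` (named vectors) and `shannon`.
#' @export
abundance_profile <- function(aln, sample_id, fraction,
                              total_reads = NULL, subsample_n = NULL,
                              seed = 1L) {
  if (!is.null(subsample_n)) aln <- subsample_reads(aln, subsample_n, seed)
  counts <- count_mapped_reads(aln)
  if (is.null(total_reads)) total_reads <- sum(counts)
  pct <- relative_abundance(counts, total_reads)
  list(sample_id = sample_id, fraction = fraction,
       total_reads = total_reads, counts = counts, percent = pct,
       shannon = shannon_index(counts))
}

#' Cellular:viral abundance ratios per scaffold
#'
#' `ratio_i = cellular%_i / viral%_i` over the shared scaffold universe.
#' Scaffolds absent (zero) in the viral fraction are excluded and counted.
#'
#' @param cellular,viral Named numeric vectors of per-scaffold
#'   percentages.
#' @return List with `ratios` (named vector), `n_excluded`, and `summary`
#'   (median and quartiles).
#' @export
fraction_ratio <- function(cellular, viral) {
  ids <- union(names(cellular), names(viral))
  cel <- ifelse(ids %in% names(cellular), cellular[ids], 0)
  vir <- ifelse(ids %in% names(viral), viral[ids], 0)
  excl <- vir == 0
  if (any(excl)) {
    vm_message(sum(excl), " scaffold(s) absent from viral fraction excluded")
  }
  ratios <- setNames(cel[!excl] / vir[!excl], ids[!excl])
  list(ratios = ratios, n_excluded = sum(excl),
       summary = if (length(ratios)) {
         quantile(ratios, c(0.25, 0.5, 0.75))
       } else setNames(rep(NA_real_, 3), c("25%", "50%", "75%")))
}
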