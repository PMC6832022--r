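# Closest-relative taxonomy, functional-category assignment, and virus-host
# prediction from three sequence signals (genomic homology, CRISPR spacers,
# shared tRNAs) with a strict consensus rule: a scaffold predicted to infect
# more than one taxon at the requested rank gets no host.

parse_taxonomy <- function(x, rank = c("family", "genus", "species")) {
  rank <- match.arg(rank)
  i <- match(rank, c("family", "genus", "species"))
  parts <- strsplit(x, ";", fixed = TRUE)
  out <- vapply(parts, function(p) if (length(p) >= i) p[[i]] else NA_character_,
                character(1))
  out[!is.na(out) & !nzchar(out)] <- NA_character_
  out
}

#' Closest-relative taxonomic affiliation of a scaffold
#'
#' Per ORF, takes the best passing hit (lowest e-value; ties by higher
#' bitscore then lexicographic subject) among reference hits filtered on
#' identity, bitscore, alignment length and e-value; tallies the taxa of
#' those best hits at the requested rank; the majority taxon wins. Ties
#' (multiple taxa matched by the same number of ORFs) are broken in favour
#' of the taxon with the highest mean identity among its matched ORFs. No
#' passing hits, or hits lacking taxonomy at the rank, give no call.
#'
#' @param genes Gene table of one scaffold (or several; calls are per
#'   scaffold).
#' @param hits Reference hit table with a `subject_taxonomy` column
#'   (`family;genus;species`).
#' @param rank `"family"`, `"genus"` or `"species"`.
#' @param min_identity,min_bitscore,min_aln_len,max_evalue Hit filters
#'   (defaults 30, 50, 30, 1e-5).
#' @return `data.frame`, one row per scaffold: `scaffold_id`, `rank`,
#'   `taxon` (`NA` for no call), `n_orfs_matched`, `mean_identity`,
#'   `tie_broken`.
#' @export
closest_relative <- function(genes, hits, rank = "family",
                             min_identity = 30, min_bitscore = 50,
                             min_aln_len = 30, max_evalue = 1e-5) {
  stopifnot("subject_taxonomy" %in% names(hits) || nrow(hits) == 0)
  if (nrow(hits)) {
    keep <- hits$percent_identity >= min_identity &
            hits$bitscore >= min_bitscore &
            hits$aln_length >= min_aln_len &
            hits$evalue <= max_evalue
    hits <- hits[keep & hits$query_gene_id %in% genes$gene_id, , drop = FALSE]
  }
  scaffs <- unique(genes$scaffold_id)
  no_call <- function(sc) data.frame(
    scaffold_id = sc, rank = rank, taxon = NA_character_,
    n_orfs_matched = 0L, mean_identity = NA_real_, tie_broken = FALSE,
    stringsAsFactors = FALSE)
  if (!nrow(hits)) {
    return(do.call(rbind, lapply(scaffs, no_call)))
  }
  ord <- order(hits$query_gene_id, hits$evalue, -hits$bitscore,
               hits$subject_id)
  best <- hits[ord, , drop = FALSE]
  best <- best[!duplicated(best$query_gene_id), , drop = FALSE]
  best$taxon <- parse_taxonomy(best$subject_taxonomy, rank)
  best <- best[!is.na(best$taxon), , drop = FALSE]
  gene_scaffold <- setNames(genes$scaffold_id, genes$gene_id)
  best$scaffold_id <- unname(gene_scaffold[best$query_gene_id])
  rows <- lapply(scaffs, function(sc) {
    b <- best[best$scaffold_id == sc, , drop = FALSE]
    if (!nrow(b)) return(no_call(sc))
    counts <- table(b$taxon)
    top <- names(counts)[counts == max(counts)]
    tie <- length(top) > 1
    mean_id <- tapply(b$percent_identity, b$taxon, mean)
    win <- if (tie) {
      top[order(-mean_id[top], top)][[1]]
    } else top
    data.frame(scaffold_id = sc, rank = rank, taxon = win,
               n_orfs_matched = as.integer(counts[[win]]),
               mean_identity = unname(mean_id[[win]]), tie_broken = tie,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Assign functional categories from product strings
#'
#' Case-insensitive fixed-substring matching against a prioritised keyword
#' table; the first matching row wins. Products with no match are
#' `(unknown, unknown)`.
#'
#' @param products Character vector of protein product descriptions.
#' @param keywords Keyword table (`keyword`, `broad`, `specific`), ordered
#'   by priority; default table via [default_keyword_table()].
#' @return `data.frame` with `category_broad` and `category_specific`.
#' @export
#' @examples
#' assign_category("putative tail fiber protein")
assign_category <- function(products, keywords = default_keyword_table()) {
  prods <- tolower(ifelse(is.na(products), "", products))
  broad <- rep("unknown", length(prods))
  specific <- rep("unknown", length(prods))
  undone <- rep(TRUE, length(prods))
  for (i in seq_len(nrow(keywords))) {
    hit <- undone & grepl(tolower(keywords$keyword[[i]]), prods, fixed = TRUE)
    broad[hit] <- keywords$broad[[i]]
    specific[hit] <- keywords$specific[[i]]
    undone <- undone & !hit
  }
  data.frame(category_broad = broad, category_specific = specific,
             stringsAsFactors = FALSE)
}

#' Default functional keyword table
#'
#' Maps product-description substrings to broad categories (replication,
#' structural, metabolism, regulation) and specific categories (e.g.
#' `tail_fiber`, `capsid`, `dna_polymerase`). Shipped as a TSV in
#' `inst/extdata` and loadable from any path with the same layout.
#'
#' @param path Optional path to an alternative keyword TSV
#'   (`keyword`, `broad`, `specific` columns, priority order).
#' @return `data.frame` with columns `keyword`, `broad`, `specific`.
#' @export
default_keyword_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "functional_keywords.tsv",
                        package = "viromicro")
  }
  read.delim(path, stringsAsFactors = FALSE)
}

# Longest shared segment between two sequences on a k-mer-seeded diagonal.
best_shared_segment <- function(a, b, k = 21L) {
  la <- nchar(a); lb <- nchar(b)
  if (la < k || lb < k) return(NULL)
  ka <- substring(a, 1:(la - k + 1L), k:la)
  kb <- substring(b, 1:(lb - k + 1L), k:lb)
  pos_b <- split(seq_along(kb), kb)
  hit <- which(ka %in% names(pos_b))
  if (!length(hit)) return(NULL)
  pairs <- do.call(rbind, lapply(hit, function(i)
    cbind(i, pos_b[[ka[[i]]]])))
  diags <- pairs[, 2] - pairs[, 1]
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  best <- NULL
  for (d in unique(diags)) {
    p <- pairs[diags == d, 1]
    lo <- min(p); hi <- max(p) + k - 1L
    idx <- lo:hi
    ident <- mean(ca[idx] == cb[idx + d])
    seg <- list(a_start = lo, a_end = hi, b_start = lo + d,
                length = hi - lo + 1L, identity = ident)
    if (is.null(best) || seg$length * seg$identity >
          best$length * best$identity) best <- seg
  }
  best
}

#' Detect a genomic homology host signal
#'
#' Looks for a long, high-identity shared segment between a viral scaffold
#' and a candidate host genome (k-mer-seeded, ungapped). A signal is
#' emitted iff the best segment is at least `min_len` bp at `min_identity`
#' percent identity.
#'
#' @param viral_seq,host_seq Sequence strings.
#' @param min_len Minimum segment length in bp (default 1000).
#' @param min_identity Minimum percent identity (default 90).
#' @param k Seed k-mer length.
#' @return One-row `data.frame` (`signal`, `score` = segment length,
#'   `identity`) or `NULL`.
#' @export
detect_homology <- function(viral_seq, host_seq, min_len = 1000,
                            min_identity = 90, k = 21L) {
  seg <- best_shared_segment(viral_seq, host_seq, k)
  if (is.null(seg)) return(NULL)
  if (seg$length >= min_len && seg$identity * 100 >= min_identity) {
    return(data.frame(signal = "homology", score = seg$length,
                      identity = seg$identity * 100,
                      stringsAsFactors = FALSE))
  }
  NULL
}

#' Match CRISPR spacers against a viral scaffold
#'
#' Each spacer is searched on both strands; a signal is emitted for every
#' spacer with an occurrence at no more than `max_mismatches` mismatches
#' (Biostrings pattern matching).
#'
#' @param spacers Named character vector of spacer sequences (>= 20 bp).
#' @param scaffold_seq Scaffold sequence string.
#' @param max_mismatches Allowed mismatches per occurrence (default 1).
#' @return `data.frame` with `spacer_id`, `signal`, `score` (spacer
#'   length), `strand`; zero rows when nothing matches.
#' @export
match_spacers <- function(spacers, scaffold_seq, max_mismatches = 1) {
  subj <- Biostrings::DNAString(scaffold_seq)
  rows <- lapply(seq_along(spacers), function(i) {
    sp <- spacers[[i]]
    if (nchar(sp) < 20) return(NULL)
    fwd <- Biostrings::matchPattern(Biostrings::DNAString(sp), subj,
                                    max.mismatch = max_mismatches)
    rev <- Biostrings::matchPattern(
      Biostrings::reverseComplement(Biostrings::DNAString(sp)), subj,
      max.mismatch = max_mismatches)
    strand <- if (length(fwd)) "+" else if (length(rev)) "-" else NA
    if (is.na(strand)) return(NULL)
    data.frame(spacer_id = names(spacers)[[i]], signal = "crispr",
               score = nchar(sp), strand = strand, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(spacer_id = character(0), signal = character(0),
                      score = numeric(0), strand = character(0))
  }
  out
}

#' Shared tRNA host signal
#'
#' A signal is emitted for every viral/host tRNA pair with exact
#' full-length nucleotide identity.
#'
#' @param viral_trnas,host_trnas Named character vectors of tRNA
#'   sequences.
#' @return `data.frame` with `viral_trna`, `host_trna`, `signal`, `score`
#'   (tRNA length); zero rows when none shared.
#' @export
shared_trnas <- function(viral_trnas, host_trnas) {
  rows <- list()
  for (i in seq_along(viral_trnas)) {
    hit <- which(host_trnas == viral_trnas[[i]])
    for (j in hit) {
      rows[[length(rows) + 1L]] <- data.frame(
        viral_trna = names(viral_trnas)[[i]],
        host_trna = names(host_trnas)[[j]], signal = "trna",
        score = nchar(viral_trnas[[i]]), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(viral_trna = character(0), host_trna = character(0),
                      signal = character(0), score = numeric(0))
  }
  out
}

#' Consensus host call from signals
#'
#' All signals for a scaffold must agree on the host taxon at the
#' requested rank; disagreement (an ambiguous prediction) or absence of
#' signals yields no call.
#'
#' @param signals `data.frame` with a `host_taxonomy` column
#'   (`phylum;genus` or deeper path) or a pre-extracted `host_taxon`
#'   column.
#' @param rank Index into the taxonomy path (1 = first/highest rank) used
#'   when `host_taxonomy` paths are supplied.
#' @return Host taxon string, or `NA_character_` (none/ambiguous).
#' @export
consensus_host <- function(signals, rank = 1L) {
  if (is.null(signals) || !nrow(signals)) return(NA_character_)
  taxa <- if ("host_taxon" %in% names(signals)) signals$host_taxon
          else vapply(strsplit(signals$host_taxonomy, ";", fixed = TRUE),
                      function(p) if (length(p) >= rank) p[[rank]]
                                  else NA_character_, character(1))
  taxa <- unique(taxa[!is.na(taxa)])
  if (length(taxa) == 1) taxa else NA_character_
}

#' Predict hosts for viral scaffolds from all three signals
#'
#' Runs homology detection against every host genome, spacer matching and
#' tRNA sharing for each viral scaffold, attaches the host taxonomy to
#' every signal and applies the consensus rule at the requested rank.
#'
#' @param viral_seqs Named character vector of viral scaffold sequences.
#' @param host_genomes Named character vector of host genome sequences.
#' @param host_taxonomy Named character vector mapping host id to a
#'   taxonomy path (e.g. `"Proteobacteria;Pelagibacter"`).
#' @param spacers Named character vector of spacers; names must be
#'   `<host_id>|<anything>`.
#' @param viral_trnas,host_trnas Named character vectors; tRNA names must
#'   be `<scaffold_or_host_id>|<anything>`.
#' @param rank Taxonomy path index for the consensus (1 = phylum by the
#'   shipped fixtures' convention).
#' @param config Configuration list (host thresholds).
#' @return `data.frame`, one row per viral scaffold: `scaffold_id`,
#'   `host_taxon`, `n_signals`, `signals` (comma-joined kinds).
#' @export
predict_hosts <- function(viral_seqs, host_genomes, host_taxonomy,
                          spacers = character(0),
                          viral_trnas = character(0),
                          host_trnas = character(0), rank = 1L,
                          config = viromicro_config()) {
  hostcfg <- config$host
  owner <- function(x) sub("\\|.*$", "", x)
  rows <- lapply(names(viral_seqs), function(vid) {
    sigs <- list()
    for (hid in names(host_genomes)) {
      hom <- detect_homology(viral_seqs[[vid]], host_genomes[[hid]],
                             hostcfg$homology_min_len,
                             hostcfg$homology_min_identity)
      if (!is.null(hom)) {
        hom$host_id <- hid
        sigs[[length(sigs) + 1L]] <- hom[, c("signal", "score", "host_id")]
      }
    }
    if (length(spacers)) {
      sp <- match_spacers(spacers, viral_seqs[[vid]],
                          hostcfg$spacer_max_mismatches)
      if (nrow(sp)) {
        sp$host_id <- owner(sp$spacer_id)
        sigs[[length(sigs) + 1L]] <- sp[, c("signal", "score", "host_id")]
      }
    }
    vt <- viral_trnas[owner(names(viral_trnas)) == vid]
    if (length(vt) && length(host_trnas)) {
      tr <- shared_trnas(vt, host_trnas)
      if (nrow(tr)) {
        tr$host_id <- owner(tr$host_trna)
        sigs[[length(sigs) + 1L]] <- tr[, c("signal", "score", "host_id")]
      }
    }
    sigs <- do.call(rbind, sigs)
    if (is.null(sigs) || !nrow(sigs)) {
      return(data.frame(scaffold_id = vid, host_taxon = NA_character_,
                        n_signals = 0L, signals = "",
                        stringsAsFactors = FALSE))
    }
    sigs$host_taxonomy <- unname(host_taxonomy[sigs$host_id])
    data.frame(scaffold_id = vid,
               host_taxon = consensus_host(sigs, rank),
               n_signals = nrow(sigs),
               signals = paste(sort(unique(sigs$signal)), collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
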