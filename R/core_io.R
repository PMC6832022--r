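# Readers and writers for the standard formats the pipeline consumes:
# FASTA, outfmt6-style hit tables, GFF3 gene coordinates and SAM alignments.
# All coordinates are 1-based inclusive (GFF3/SAM convention).

#' Read a FASTA file into a named character vector
#'
#' Sequences are upper-cased, whitespace inside sequence lines is stripped,
#' and any character outside `{A,C,G,T,N}` is replaced by `N` with a
#' warning. Record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences (names are the full header
#'   text after `>`); empty vector for an empty file.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(setNames(character(0), character(0)))
  if (!startsWith(lines[[1]], ">")) {
    stop("malformed FASTA: line 1 does not start with '>'")
  }
  hdr <- startsWith(lines, ">")
  rec <- cumsum(hdr)
  ids <- sub("^>", "", trimws(lines[hdr]))
  seqs <- vapply(split(lines[!hdr], rec[!hdr]),
                 function(x) paste(x, collapse = ""), character(1))
  # records with no sequence lines yield empty strings
  out <- setNames(rep("", length(ids)), ids)
  out[as.integer(names(seqs))] <- seqs
  out <- gsub("[ \t]", "", out)
  out <- toupper(out)
  bad <- grepl("[^ACGTN]", out)
  if (any(bad)) {
    warning(sprintf("%d sequence(s) contained non-ACGTN characters; mapped to N",
                    sum(bad)))
    out <- gsub("[^ACGTN]", "N", out)
  }
  names(out) <- ids
  out
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    if (nchar(s)) {
      starts <- seq(1, nchar(s), width)
      writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
    }
  }
  invisible(path)
}

hit_table_cols <- c("query_gene_id", "subject_id", "percent_identity",
                    "aln_length", "mismatches", "gaps", "qstart", "qend",
                    "sstart", "send", "evalue", "bitscore")

#' Read a tabular homology hit table (BLAST/DIAMOND outfmt 6 layout)
#'
#' Expects 12 tab-separated columns (query, subject, identity, alignment
#' length, mismatches, gaps, qstart, qend, sstart, send, evalue, bitscore).
#' An optional 13th column carrying the subject taxonomy path
#' (`family;genus;species`) is accepted for reference hits.
#'
#' @param path Path to the table.
#' @return `data.frame` with columns named after the outfmt6 fields and,
#'   when present, `subject_taxonomy`. Empty file gives zero rows.
#' @export
read_hits_table <- function(path) {
  stopifnot(file.exists(path))
  empty <- stats::setNames(
    as.data.frame(c(rep(list(character(0)), 2), rep(list(numeric(0)), 10))),
    hit_table_cols)
  if (file.size(path) == 0) return(empty)
  nf <- count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (is.null(nf) || !length(nf)) return(empty)
  bad <- which(!nf %in% c(12L, 13L))
  if (length(bad)) {
    stop(sprintf("hit table %s: line %d has %d columns (expected 12)",
                 path, bad[[1]], nf[bad[[1]]]))
  }
  d <- read.delim(path, header = FALSE, sep = "\t", quote = "",
                  colClasses = "character", comment.char = "")
  names(d)[1:12] <- hit_table_cols
  if (ncol(d) == 13) names(d)[13] <- "subject_taxonomy"
  for (col in hit_table_cols[3:12]) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    if (anyNA(v)) {
      stop(sprintf("hit table %s: line %d: cannot parse '%s' as numeric in %s",
                   path, which(is.na(v))[[1]], d[[col]][which(is.na(v))[[1]]],
                   col))
    }
    d[[col]] <- v
  }
  d
}

#' Write a hit table in outfmt6 layout
#'
#' @param hits `data.frame` as returned by [read_hits_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_table <- function(hits, path) {
  cols <- c(hit_table_cols,
            intersect("subject_taxonomy", names(hits)))
  write.table(hits[, cols, drop = FALSE], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a SAM alignment file
#'
#' Parses plain-text SAM. Unmapped records (FLAG bit 0x4) are skipped.
#' Aligned blocks are built from `M`/`=`/`X` CIGAR runs only; insertions and
#' soft/hard clips consume no reference, deletions consume no read. Each
#' block is a `(read_offset, ref_pos, length)` triple, both 1-based.
#'
#' @param path Path to a SAM file with a header.
#' @param sample_id,fraction Optional labels attached to every alignment
#'   (sample depth label and size fraction, `"viral"` or `"cellular"`).
#' @return `data.frame` with columns `read_id`, `scaffold_id`, `pos`,
#'   `cigar`, `seq`, `sample_id`, `fraction` and a list-column `blocks`
#'   (integer matrices with columns `read_off`, `ref_pos`, `len`).
#' @export
read_sam <- function(path, sample_id = NA_character_,
                     fraction = NA_character_) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "@")]
  refs <- sub("\tLN:.*$", "", sub("^@SQ\tSN:", "", hdr[startsWith(hdr, "@SQ")]))
  body <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (!length(body)) {
    return(data.frame(read_id = character(0), scaffold_id = character(0),
                      pos = integer(0), cigar = character(0),
                      seq = character(0), sample_id = character(0),
                      fraction = character(0),
                      blocks = I(list())))
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  flag <- vapply(f, function(x) as.integer(x[[2]]), integer(1))
  keep <- bitwAnd(flag, 4L) == 0L
  f <- f[keep]
  rname <- vapply(f, `[[`, character(1), 3)
  unknown <- setdiff(unique(rname), refs)
  if (length(unknown)) {
    stop("SAM reference(s) absent from header: ",
         paste(unknown, collapse = ", "))
  }
  pos <- vapply(f, function(x) as.integer(x[[4]]), integer(1))
  cigar <- vapply(f, `[[`, character(1), 6)
  out <- data.frame(
    read_id = vapply(f, `[[`, character(1), 1),
    scaffold_id = rname,
    pos = pos,
    cigar = cigar,
    seq = vapply(f, `[[`, character(1), 10),
    sample_id = sample_id,
    fraction = fraction,
    stringsAsFactors = FALSE)
  out$blocks <- I(mapply(cigar_blocks, cigar, pos, SIMPLIFY = FALSE,
                         USE.NAMES = FALSE))
  out
}

# Decompose a CIGAR string into matched reference blocks.
# Returns an integer matrix (read_off, ref_pos, len), 1-based.
cigar_blocks <- function(cigar, pos) {
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[A-Z=]", cigar))[[1]]
  bad <- setdiff(ops, c("M", "=", "X", "I", "D", "S", "H"))
  if (length(bad)) stop("unsupported CIGAR op(s): ", paste(bad, collapse = ""))
  read_off <- 1L
  ref_pos <- pos
  blocks <- list()
  for (i in seq_along(ops)) {
    op <- ops[[i]]; n <- lens[[i]]
    if (op %in% c("M", "=", "X")) {
      blocks[[length(blocks) + 1L]] <- c(read_off, ref_pos, n)
      read_off <- read_off + n
      ref_pos <- ref_pos + n
    } else if (op %in% c("I", "S")) {
      read_off <- read_off + n
    } else if (op == "D") {
      ref_pos <- ref_pos + n
    } # H consumes nothing
  }
  m <- do.call(rbind, blocks)
  if (is.null(m)) m <- matrix(integer(0), 0, 3)
  colnames(m) <- c("read_off", "ref_pos", "len")
  m
}

#' Write alignments as SAM text
#'
#' @param aln Alignment `data.frame` (needs `read_id`, `scaffold_id`, `pos`,
#'   `cigar`, `seq`).
#' @param ref_lengths Named integer vector of reference scaffold lengths for
#'   the `@SQ` header lines.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, ref_lengths, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths),
                   as.integer(ref_lengths)))
  qual <- strrep("I", nchar(aln$seq))
  body <- sprintf("%s\t0\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s",
                  aln$read_id, aln$scaffold_id, as.integer(aln$pos),
                  aln$cigar, aln$seq, qual)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read gene coordinates from GFF3
#'
#' Reads CDS-style rows; attributes must carry `ID=` and may carry
#' `product=`.
#'
#' @param path Path to a GFF3 file.
#' @return `data.frame` with `gene_id`, `scaffold_id`, `start`, `end`,
#'   `strand`, `product`.
#' @export
read_genes_gff <- function(path) {
  stopifnot(file.exists(path))
  d <- read.delim(path, header = FALSE, comment.char = "#", quote = "",
                  col.names = c("seqid", "source", "type", "start", "end",
                                "score", "strand", "phase", "attributes"),
                  colClasses = c("character", "character", "character",
                                 "integer", "integer", "character",
                                 "character", "character", "character"))
  get_attr <- function(attrs, key) {
    m <- regmatches(attrs, regexpr(paste0("(^|;)", key, "=[^;]*"), attrs))
    out <- rep(NA_character_, length(attrs))
    hit <- vapply(regexpr(paste0("(^|;)", key, "=[^;]*"), attrs), `>`,
                  logical(1), 0)
    out[hit] <- sub(paste0("^;?", key, "="), "", m)
    out
  }
  data.frame(
    gene_id = get_attr(d$attributes, "ID"),
    scaffold_id = d$seqid,
    start = d$start,
    end = d$end,
    strand = d$strand,
    product = get_attr(d$attributes, "product"),
    stringsAsFactors = FALSE)
}

#' Write gene coordinates as GFF3
#'
#' @param genes Gene `data.frame` (`gene_id`, `scaffold_id`, `start`, `end`,
#'   `strand`, optional `product`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genes_gff <- function(genes, path) {
  prod <- if ("product" %in% names(genes)) genes$product else NA
  attrs <- ifelse(is.na(prod),
                  paste0("ID=", genes$gene_id),
                  paste0("ID=", genes$gene_id, ";product=", prod))
  lines <- sprintf("%s\tviromicro\tCDS\t%d\t%d\t.\t%s\t0\t%s",
                   genes$scaffold_id, as.integer(genes$start),
                   as.integer(genes$end), genes$strand, attrs)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Default analysis configuration
#'
#' All pipeline thresholds in one namespace. Values are the study defaults:
#' minimum scaffold length 5000 bp; AVQ round (10% of ORFs with hits, AVQ
#' >= 2, E <= 1e-5); baiting round (identity >= 30, bitscore >= 50,
#' alignment >= 30 aa, E <= 1e-5, >= 20% of ORFs and >= 3 matches to a
#' single bait scaffold); SNP validity (count >= 4, frequency >= 1%, codon
#' coverage >= 5); population clustering (ANI >= 95 over >= 80% of the
#' shorter scaffold).
#'
#' @param path Optional YAML file whose entries override the defaults.
#' @param quiet If `FALSE`, echo every threshold to the message stream.
#' @return Nested list of settings.
#' @export
viromicro_config <- function(path = NULL, quiet = TRUE) {
  cfg <- list(
    min_scaffold_length = 5000,
    avq = list(min_percent = 10, min_avq = 2, max_evalue = 1e-5),
    bait = list(min_percent = 20, min_matches = 3, min_identity = 30,
                min_bitscore = 50, min_aln_len = 30, max_evalue = 1e-5),
    taxonomy = list(min_identity = 30, min_bitscore = 50, min_aln_len = 30,
                    max_evalue = 1e-5),
    host = list(homology_min_len = 1000, homology_min_identity = 90,
                spacer_max_mismatches = 1),
    snp = list(min_count = 4, min_freq = 0.01, min_cov = 5),
    medians = list(min_genes = 3),
    population = list(ani = 95, cov = 80),
    concordance = list(virsorter_ok = 1:6, virfinder_score = 0.7,
                       virfinder_p = 0.05),
    subsample = list(n = NULL))
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, user)
  }
  if (!quiet) {
    flat <- unlist(cfg)
    for (k in names(flat)) vm_message(k, " = ", flat[[k]])
  }
  cfg
}
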