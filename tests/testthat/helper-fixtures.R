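# Fixture builders shared across tests. Everything is generated in code;
# no binary files.

# write a small FASTA and return its path
tmp_fasta <- function(seqs, envir = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".fasta", .local_envir = envir)
  writeLines(unlist(lapply(seq_along(seqs), function(i)
    c(paste0(">", names(seqs)[i]), seqs[[i]]))), path)
  path
}

# write SAM text with a proper header
tmp_sam <- function(records, refs, envir = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".sam", .local_envir = envir)
  hdr <- c("@HD\tVN:1.6",
           sprintf("@SQ\tSN:%s\tLN:%d", names(refs), as.integer(refs)))
  writeLines(c(hdr, records), path)
  path
}

sam_record <- function(qname, rname, pos, cigar, seq, flag = 0L) {
  sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s",
          qname, flag, rname, pos, cigar, seq, strrep("I", nchar(seq)))
}

# a minimal single-gene scaffold: 10 bp pad + cds + 10 bp pad, + strand
simple_gene <- function(cds, id = "g1", scaffold_id = "sc1") {
  data.frame(gene_id = id, scaffold_id = scaffold_id,
             start = 11L, end = 10L + nchar(cds), strand = "+",
             stringsAsFactors = FALSE)
}

simple_scaffold <- function(cds, pad = strrep("A", 10)) {
  paste0(pad, cds, pad)
}

# construct an alignment data.frame directly (bypassing SAM round trip)
make_aln <- function(read_id, scaffold_id, pos, seq) {
  rl <- nchar(seq)
  out <- data.frame(read_id = read_id, scaffold_id = scaffold_id,
                    pos = pos, cigar = paste0(rl, "M"), seq = seq,
                    sample_id = NA_character_, fraction = NA_character_,
                    stringsAsFactors = FALSE)
  out$blocks <- I(mapply(function(p, l) {
    m <- matrix(c(1L, as.integer(p), as.integer(l)), 1, 3)
    colnames(m) <- c("read_off", "ref_pos", "len")
    m
  }, pos, rl, SIMPLIFY = FALSE))
  out
}

# a pileup data.frame for one codon column
make_pileup <- function(ref_codon, variant_codon, var_count, coverage,
                        gene_id = "g1", codon_index = 0L) {
  data.frame(gene_id = gene_id, codon_index = codon_index,
             ref_codon = ref_codon,
             codon = c(ref_codon, variant_codon),
             count = c(coverage - var_count, var_count),
             stringsAsFactors = FALSE)
}

# independent translation oracle (seqinr), for codon-spectrum tests
oracle_translate <- function(codon) {
  seqinr::translate(strsplit(tolower(codon), "")[[1]])
}

# independent enumeration of a codon's 9 neighbors
oracle_spectrum <- function(codon) {
  bases <- c("A", "C", "G", "T")
  aa0 <- oracle_translate(codon)
  n_syn <- 0L
  for (i in 1:3) for (b in setdiff(bases, substr(codon, i, i))) {
    mut <- codon
    substr(mut, i, i) <- b
    if (oracle_translate(mut) == aa0) n_syn <- n_syn + 1L
  }
  c(n_syn = n_syn, n_nonsyn = 9L - n_syn)
}

# 12-column outfmt6 hit row builder
hit_row <- function(query, subject, identity = 50, aln_len = 100,
                    evalue = 1e-10, bitscore = 100, taxonomy = NULL) {
  d <- data.frame(query_gene_id = query, subject_id = subject,
                  percent_identity = identity, aln_length = aln_len,
                  mismatches = 0, gaps = 0, qstart = 1, qend = aln_len,
                  sstart = 1, send = aln_len, evalue = evalue,
                  bitscore = bitscore, stringsAsFactors = FALSE)
  if (!is.null(taxonomy)) d$subject_taxonomy <- taxonomy
  d
}

# mutate a fraction of positions of a sequence (never to the same base)
mutate_seq <- function(seq, positions) {
  chars <- strsplit(seq, "")[[1]]
  for (p in positions) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  paste(chars, collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
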