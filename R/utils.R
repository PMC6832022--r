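# Shared low-level helpers: seeded RNG streams, sequence arithmetic and the
# standard genetic code. Coordinates are 1-based inclusive throughout.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded helpers never perturb the
#' caller's RNG stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

#' Stable string hash for per-scaffold RNG streams
#'
#' Polynomial rolling hash modulo 2^31 - 1. Used to derive independent,
#' order-insensitive RNG streams from a top-level seed and an identifier, so
#' adding a scaffold to a community never perturbs the sequences of others.
#'
#' @param x Character scalar.
#' @return Integer in `[0, 2^31 - 2]`.
#' @keywords internal
stable_hash <- function(x) {
  h <- 0
  for (c in utf8ToInt(x)) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

# Derived stream seed: combine top-level seed with an id hash, kept below
# 2^31 so set.seed() always accepts it.
stream_seed <- function(seed, id) {
  as.integer((as.numeric(seed) * 48271 + stable_hash(id)) %% 2147483647)
}

#' Reverse complement of plain DNA strings
#'
#' @param x Character vector over `{A,C,G,T,N}`.
#' @return Character vector of reverse complements.
#' @keywords internal
revcomp <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

# The standard genetic code as a named vector codon -> amino acid ("*" stop).
genetic_code <- function() Biostrings::GENETIC_CODE

#' Translate codon strings under the standard genetic code
#'
#' @param codons Character vector of 3-letter codons. Codons containing
#'   characters outside `{A,C,G,T}` translate to `NA`.
#' @return Character vector of amino acids, `"*"` for stop.
#' @export
#' @examples
#' translate_codons(c("ATG", "TTT", "TAA"))
translate_codons <- function(codons) {
  unname(genetic_code()[codons])
}

# Translate a full in-frame coding sequence (gene orientation) to protein,
# trimming a single terminal stop if present.
translate_cds <- function(seq, trim_stop = TRUE) {
  n <- nchar(seq)
  stopifnot(n %% 3 == 0)
  codons <- substring(seq, seq(1, n, 3), seq(3, n, 3))
  aa <- translate_codons(codons)
  if (trim_stop && length(aa) && !is.na(aa[length(aa)]) &&
      aa[length(aa)] == "*") {
    aa <- aa[-length(aa)]
  }
  paste(aa, collapse = "")
}

# Split a gene-oriented CDS into codon strings.
split_codons <- function(seq) {
  n <- nchar(seq)
  stopifnot(n %% 3 == 0)
  substring(seq, seq(1, n, 3), seq(3, n, 3))
}

# Extract the gene-oriented coding sequence of a gene from its scaffold
# sequence (reverse complement for '-' strand genes).
gene_cds <- function(scaffold_seq, start, end, strand) {
  s <- substr(scaffold_seq, start, end)
  if (strand == "-") revcomp(s) else s
}

# fast reverse complement for many 3-mers: complement via chartr, reverse
# by re-slicing (avoids per-element strsplit)
revcomp_fast <- function(x) {
  n <- nchar(x)
  if (!length(x)) return(x)
  if (all(n == 3L)) {
    y <- chartr("ACGTN", "TGCAN", x)
    paste0(substr(y, 3, 3), substr(y, 2, 2), substr(y, 1, 1))
  } else revcomp(x)
}

vm_message <- function(...) message("[viromicro] ", ...)
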