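---
title: "Methods: viral scaffold classification and codon-level microdiversity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: viral scaffold classification and codon-level microdiversity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viromicro)
```

# Scope and data model

`viromicro` takes the standard products of a virome assembly workflow —
scaffold FASTA, gene coordinates (GFF3) with protein translations,
tabular homology hits (outfmt-6 layout), and read alignments (SAM) — and
produces viral classifications, annotations, abundance profiles, and
codon-resolved microdiversity summaries. Coordinates are 1-based inclusive
throughout (the GFF3/SAM convention); conversions happen only at array
boundaries. Reverse-strand genes are handled by taking the reverse
complement of the scaffold segment, and all codon indices are expressed in
gene orientation. `N` is never counted as a variant base, so ambiguous
sequence cannot inflate polymorphism. Scaffolds shorter than 5,000 bp are
outside the intended scale of the pipeline (the generator never produces
them and the default configuration records the floor).

# Viral classification

**Round 1 (AVQ).** For each ORF the best orthologous-group hit is the one
with the lowest e-value among hits with E ≤ 1e−5; ties are broken by
higher bitscore, then lexicographic subject id — fixed tie-breaks chosen
purely for determinism. The scaffold's added viral quotient (AVQ) is the
sum of best-hit viral quotients, and a scaffold is classified viral when
at least 10% of its ORFs have hits **and** AVQ ≥ 2, both bounds
inclusive. Adding a hit can only increase both statistics, so
classification is monotone in the evidence.

**Round 2 (baiting).** Unclassified scaffolds are compared ORF-by-ORF
against round-1 ORFs. A hit qualifies only if it passes all four filters
(identity ≥ 30%, bitscore ≥ 50, alignment ≥ 30 aa, E ≤ 1e−5). The match
count is then the number of *distinct* candidate ORFs with at least one
qualifying hit to a *single* bait scaffold — counts are never pooled
across bait scaffolds, the strictest consistent reading of a
singular-target recruitment rule. Recruitment requires the maximum
per-bait count to reach three matches and 20% of the candidate's ORFs.
Any qualifying hit counts (not only each ORF's best hit); this is an open
design choice and is deliberately the permissive reading, since the
filters are already strict. Baiting is a single pass: recruits are never
re-used as bait, so the procedure cannot cascade.

**Round 3 (curation)** simply promotes listed, still-unclassified
scaffolds; already-viral entries produce a warning and are left alone.

**Concordance** against external classifier labels counts a scaffold
discordant when *neither* rule flags it: category within 1–6, or score
≥ 0.7 with p ≤ 0.05 (boundaries inclusive). Scaffolds with no label row
are counted discordant with a warning, the conservative choice.

**Population clustering** links two scaffolds when their best shared
diagonal (seeded by exact 15-mers, compared ungapped) shows ≥ 95%
identity over ≥ 80% of the shorter sequence; populations are connected
components. The 95/80 thresholds follow the community-standard viral
population definition and are configurable. The ungapped estimator is
intentionally simple: it is exact for the identical-or-point-mutated
scaffolds the generator produces, and deliberately conservative (an
indel-rich pair will not be linked). It is not a replacement for a
gapped whole-genome aligner on real data.

# Annotation

Taxonomy is called per rank (family, genus, species) independently, so a
scaffold may carry a family but no genus. Per ORF the best qualifying
reference hit votes for its taxon; the majority wins, and ties go to the
taxon with the highest mean percent identity among its matched ORFs.
Functional categories come from a prioritised, case-insensitive substring
table over product strings (first match wins; no match is
`unknown`/`unknown`). The shipped table covers the broad triad
replication / structural / metabolism plus regulation.

Host prediction uses three sequence signals with artifact-chosen,
configurable thresholds: genomic homology (shared segment ≥ 1 kb at
≥ 90% identity, found by seeded ungapped extension), CRISPR spacers
(forward or reverse-complement occurrence with ≤ 1 mismatch), and shared
tRNAs (exact full-length identity). The consensus rule is strict: all
signals for a scaffold must agree at the requested rank, otherwise the
prediction is ambiguous and dropped. Only these three automated signals
are implemented; manual assignment from gene content and synteny is not
algorithmically specified and is out of scope.

# Abundance

A read counts once, to its best alignment (most aligned reference bases;
ties broken lexicographically by scaffold id — read mappers do not expose
a canonical choice, so determinism wins). Relative abundance is
100·count/total sample reads; aggregation by family or host phylum sums
member percentages and conserves the grand total to floating tolerance.
The Shannon index uses the natural logarithm — the base is an explicit
package convention, logged here because downstream comparisons of
absolute H values depend on it. Subsampling to a fixed read number is a
seeded uniform draw without replacement over read ids.

# Codon microdiversity

**Pileups.** A read contributes to a codon only when a single aligned
block covers all three bases; reads ending mid-codon or with an indel
inside the codon are excluded from that codon, and read codons containing
`N` are ignored.

**Variant validity.** A variant codon is valid iff count ≥ 4, frequency
≥ 1% of the reads covering that codon, and codon coverage ≥ 5×, all
inclusive. The frequency denominator is per-codon coverage — the only
reading consistent with a per-codon coverage floor in the same rule.
Boundary behaviour is pinned by tests on constructed pileups around each
threshold.

**Counting unit.** By default each distinct valid variant codon at a site
counts once toward the observed totals (SNP-style counting);
read-weighted counting is available via `count_mode = "reads"`. The
distinct-allele mode is the default because it makes the truth/estimate
mapping of the simulator unambiguous.

**Neutral expectation.** For every sense codon the nine single-nucleotide
substitutions are enumerated under the standard genetic code; stop gains
count as nonsynonymous, reference stop codons are excluded everywhere,
and no transition/transversion weighting is applied (no mutation-rate
matrix is assumed). Gene fractions f_S and f_N are opportunity-weighted
averages over included codons, and

pN = N/((N+S)·f_N), pS = S/((N+S)·f_S), so pN/pS = (N/S)·(f_S/f_N),
reported as undefined when S = 0 or no valid variants exist.

**Percent polymorphic sites** uses assayable codons (coverage ≥ 5×) as
the denominator: sites below the validity floor cannot be polymorphic by
definition, so including them would understate polymorphism at low
coverage. The gene-length denominator is available by flag.

**Group medians** include a gene in pN/pS medians only when pN > 0 and
pS > 0, it has at least one polymorphic site, and at least 1% of its
sites are polymorphic; groups with fewer than three qualifying genes
report no value. Percent-polymorphic medians are computed over all genes
with at least one assayable codon.

# The synthetic-data generator

The generator emulates the features downstream stages actually consume:
multi-ORF scaffolds with strand-mixed, internally-stop-free genes;
orthologous-group hits whose density and quotients make the round-1 share
pass the AVQ thresholds by construction; bait hit tables concentrating on
a single round-1 scaffold for planted round-2 recruits; taxonomy
reference hits with a majority planted family (plus one minority hit so
majority voting is actually exercised); host fixtures embedding exactly
one verbatim signal per planted pair; and 150 bp single-end reads tiling
genes with uniform placement (pairing adds nothing to pileup logic, so
mates are not modelled).

Determinism: one top-level seed, with per-scaffold streams derived by a
stable string hash of ids, so adding a scaffold never perturbs the
others. All derived seeds stay below 2³¹.

**Selection construction.** Variant sites are planted by proposing a
(site, neighbour) pair uniformly — the site from the unplanted codons,
the variant from that codon's nine single-nucleotide neighbours —
accepting synonymous proposals always and nonsynonymous ones with
probability α, and redrawing the *whole pair* on rejection. Redrawing the
pair rather than only the variant matters: per-site redraw renormalises
acceptance within each codon, so codons with few or no synonymous
neighbours (ATG, TGG) would always plant a nonsynonymous variant and the
expected pN/pS of the planted set would be α plus a usage-dependent
offset (≈ +0.03 under uniform codon usage — a 33% relative error at
α = 0.1). With pair redraw the accepted syn:nonsyn ratio across the gene
is f_S : α·f_N exactly, so the expected planted pN/pS equals α and the
simulator is a calibrated instrument for recovery tests. Each read fully
covering a planted site then carries the variant independently with the
planted frequency.

What the generator does **not** model: sequencing error, quality strings
(constant high quality), GC and amplification bias, multi-allelic sites
(a caller can still plant two variants at one site manually), genuine
strain mixtures, and gapped divergence between scaffolds. Passing
recovery tests therefore demonstrates correctness of the estimators under
clean mapping, not robustness to mapper artefacts or error-rich reads on
real data.

# Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| AVQ percent / AVQ | 10 / 2 | % ORFs, quotient sum | classification round 1, inclusive |
| bait percent / matches | 20 / 3 | % ORFs, count | recruitment to a single bait scaffold |
| hit filters | 30 / 50 / 30 / 1e−5 | %, bits, aa, E | shared by baiting and taxonomy |
| SNP validity | 4 / 0.01 / 5 | count, fraction, × | inclusive variant filters |
| population | 95 / 80 | % ANI, % coverage | species-like viral population definition |
| host signals | 1000 bp / 90% / 1 mm / exact | — | homology, spacer, tRNA thresholds |
| read length | 150 | bp | matches short-read virome sequencing |
| simulation | 50 genes × 300 codons, 50×, 200 sites at 5–50% | — | recovery-experiment scale |

The recovery-experiment sizes (50 genes of 300 codons per selection
factor at 50× coverage) were chosen as the smallest design in which the
median pN/pS over genes is a stable estimator (per-gene relative spread
≈ 15% with ~170 detected variants; the median of 50 genes pins the
recovery to a few percent) while a full run of all three selection
factors completes in about a minute on one CPU.

# Degenerate inputs and numerical choices

Zero-coverage genes report zero observed variants and undefined pN/pS;
empty hit tables classify nothing; all-zero abundance vectors are an
error (Shannon is undefined); Pearson correlations with fewer than three
defined pairs or zero variance report `NA`. Variant-frequency thresholds
are compared with `>=` on exact ratios (no rounding). Consensus
amino-acid ties resolve in favour of the reference amino acid, matching
how a reference-anchored profile is read.

# Known limitations

The ungapped identity estimators (population clustering, homology
detection) under-link diverged or indel-rich pairs. pN/pS here is a
population-level polymorphism ratio, not a phylogenetic dN/dS, and at low
coverage the validity filters censor low-frequency variants of both
classes — symmetrically, so ratios remain unbiased, but absolute
percent-polymorphic values drop. Multi-mapped reads are resolved
deterministically rather than probabilistically. These are deliberate
simplicity/correctness trade-offs at desk scale.
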