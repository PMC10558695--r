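---
title: "Methods: catalog construction and population genomics in skincat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: catalog construction and population genomics in skincat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and procedures implemented in skincat,
the parameter defaults and why they were chosen, what the synthetic
generator does and does not emulate, and the numerical conventions used
throughout. All quantitative behavior claimed here is exercised by the test
suite (`tests/testthat/`) and by `scripts/acceptance.R`; nothing beyond what
those compute is asserted.

## Sequence primitives

All comparisons rest on one seeded pairwise aligner (`align_pair`). Query
and subject must share an exact k-mer (k = 15 for DNA, 5 for protein) to be
considered at all; absence of a shared seed is the package's model of "no
detectable homology" and is returned as `NULL`. The most-supported seed
diagonal anchors a banded window (half-width 32) of the subject, inside
which Biostrings performs affine-gap dynamic programming. DNA scores are
match 2 / mismatch −3 with gap open 5 and extension 2; proteins use BLOSUM62
with gap 11/1 — conventional scales whose absolute values do not matter
because every downstream decision is a threshold on identity, coverage, or
score. Two numerical conventions deserve note:

* a gap of length L costs `open + L × extension` (the Biostrings
  convention), and the test oracles implement the same convention
  independently;
* percent identity is matches over aligned columns, where equal *ambiguity*
  characters (N–N, X–X) do not count as matches, mirroring the substitution
  matrices in which only unambiguous characters score positively;
* when periodic sequences tie several seed diagonals at equal support, the
  tie breaks toward the diagonal whose band window is largest, so tandem
  repeats are not truncated at a window edge.

Translation uses the bacterial genetic code (table 11) via Biostrings;
codons containing ambiguity codes translate to `X`.

## Genome quality and tiers

Completeness is the fraction of the expected single-copy marker set observed
at least once; contamination is the number of *extra* marker copies over the
set size. Tiers follow the community definitions, inclusive at both
boundaries: HQ requires completeness ≥ 0.90 and contamination ≤ 0.05, MQ
requires ≥ 0.50 and ≤ 0.10, everything else fails. The inclusive boundaries
are asserted on an exact grid in the tests.

## Fragment ANI and dereplication

`compute_ani` cuts the *smaller* genome into non-overlapping 1 kb fragments
(per contig; a trailing sub-kilobase remainder donates no fragment) and maps
each fragment glocally (query global, subject local) against the other
genome's contigs concatenated with N spacers — ambiguity k-mers never seed,
so no fragment is anchored across a contig junction. Fragments count as
mapped when identity ≥ 0.8 and query coverage ≥ 0.9; ANI is the mean mapped
identity and the alignment fraction (AF) is mapped length over the smaller
genome. Using the smaller genome as the fragment donor makes the statistic
symmetric, which the tests verify.

Clustering is greedy at ANI ≥ 0.95 and AF ≥ 0.30: bins are ranked by
(contamination ascending, completeness descending, genome length descending,
identifier ascending), the best unassigned bin seeds a cluster and absorbs
everything within the thresholds, and the seed is the cluster
representative. The same lexicographic rule drives
`select_representative`. The 1 kb / 0.95 / 0.30 values are the catalog
defaults exposed in `default_config()`.

## Abundance

Per-contig depths are normalized within each sample; species abundance is
the **median** of its contigs' normalized depths (robust to a single
aberrant contig), optionally renormalized. Read classification is k = 31
containment against the representative genomes, indexed on both strands; a
read is classified when ≥ 60% of its k-mers are contained.

## Functional profiling

Protein families are built greedily from longest to shortest: a protein
joins the first existing representative with alignment identity ≥ 0.5
covering ≥ 90% of the shorter sequence, else founds a family. KEGG module
definitions are parsed into the grammar of space-separated steps, commas
(OR), plus (complex AND) and parentheses, with `-K…` components optional and
ignored; completeness is the mean of satisfied top-level steps. The parser
is validated against randomly generated expression *trees* that are
serialized and evaluated independently of it.

## SNV calling and selection pressure

For each pileup site the majority alternative allele is tested against a
binomial sequencing-error null (error rate 0.001, split evenly over the
three alternatives), with Benjamini–Hochberg correction across all nonzero
(site, alternative) tests. Emitted SNVs must satisfy depth ≥ 5, allele
frequency ≥ 0.05 and q ≤ 1e-6; the tests construct pileups violating each
filter singly and require exactly zero calls at those sites.

Classification is strand-resolved codon substitution; the test oracle
instead re-translates the whole mutated gene, so the two routes share no
code. Synonymous and nonsynonymous *site* counts follow Nei–Gojobori
counting (each position contributes its three possible substitutions, ÷3).
`selection_pressure` computes, per sample, depth-normalized counts of each
class divided by the corresponding site counts, and reports `ka_ks` as the
mean over samples with at least one synonymous observation (excluded samples
are counted and reported); a pooled estimator is also available. Under the
generator's acceptance model (nonsynonymous proposals accepted with
probability *a*, synonymous always), the expected site-normalized ratio
equals *a*, which is how the neutral (= 1) and purifying regimes are
validated.

## Horizontal gene transfer

Genes are compared across top-level taxon groups (phyla by default) at the
DNA level. A gene is a candidate when its best cross-group hit has identity
≥ 0.9 *and* exceeds its best within-group hit — vertically inherited
families with intact within-group support are thereby excluded, which the
tests verify with a counterexample. Reciprocal candidates merge into one
event; orientation resolves toward the side with closer within-group
support. Divergence (1 − identity) below a strict 1% threshold marks an
event "recent". Validation builds a neighbor-joining species tree from
(1 − ANI) distances and a gene tree from protein distances and compares
unit-edge cophenetic topologies; DNA identity is used for detection because
recency at the 1% scale is a nucleotide-level signal that protein identity
would compress.

## BGC networks

Two clusters share a gene when some protein's best hit in the other cluster
has identity **strictly greater than** 0.50 over **at least** 50% of the
shorter protein. The asymmetric strict/inclusive pair is deliberate and is
pinned by constructed boundary cases: an alignment with identity exactly
0.50 does not connect, while one covering exactly half the protein at full
identity does. Networks connect clusters sharing ≥ 1 gene; connected
components are the candidate families.

## The synthetic generator

The generator *is* the study design: defaults in `default_config()` (4
species in 2 phyla, 2 bins per species at 97% within-species ANI, lognormal
coverage noise with CV 0.1, 300 planted SNVs, transfers at 0.5% and 5%
divergence, a 2-family BGC set) define the conditions under which every
claim is tested. It emulates:

* genomes as genes (uniform 300–1500 nt, both strands) separated by random
  spacers across several contigs, with single-copy markers and KO/COG
  labels;
* divergence by *exact* substitution counts (`round((1 − ANI) × L)`
  positions, each to a different base), so planted ANI is exact by
  construction;
* bin quality by deleting gene-containing segments (completeness) and
  appending foreign contigs (contamination), again exactly;
* coverage as unit-mean lognormal noise around abundance × depth;
* pileups with binomial sequencing error and planted alternative alleles at
  controlled frequencies;
* selection as acceptance-weighted sampling over all possible coding
  substitutions;
* transfers as gene insertions into intergenic gaps with coordinate
  shifting.

It does **not** emulate assembly or binning error beyond these controls: no
chimeric contigs, strain mixtures within a sample, read-level sequencing,
indels, rearrangements, or reference bias. Claims validated on it are claims
about the *analysis* chain, not about upstream assembly.

## Determinism

Every stochastic routine takes an explicit seed; the pipeline derives
per-stage seeds from the master seed, and the CLI (`skincat run`) is
byte-deterministic: reruns with the same seed produce identical outputs,
which both the tests and the acceptance script check by file checksums.

## Limitations

* ANI is estimated from 1 kb fragments of the smaller genome; genomes
  shorter than 1 kb per contig contribute nothing, and AF resolution is one
  fragment.
* The aligner requires an exact seed k-mer; homologs below ~80% DNA identity
  routinely lack a shared 15-mer and are invisible, which is intended for
  the ≥ 90% decisions made here but unsuitable for remote homology.
* ka/ks from planted pileups inherits a small upward bias at low acceptance
  because each genomic position hosts at most one planted variant; the
  tolerance in the tests (±0.05 around 0.2) absorbs it.
* KEGG module evaluation treats `+` (complex) and space (step sequence)
  inside a parenthesized group identically as AND, and does not model
  partial complex credit.
* Phylogenetic validation requires ≥ 4 genomes carrying the family;
  otherwise events remain "unvalidated".
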