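---
title: "From somatic variant calls to long vaccine peptides: methods and design choices"
author: "neovax"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From somatic variant calls to long vaccine peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neovax)
```

# The problem

Personalized cancer vaccines against low mutational load tumors such as
pancreatic ductal adenocarcinoma rely almost entirely on *in silico*
prioritization: with a few dozen somatic mutations per patient and limited
immunopeptidomics depth, direct mass-spectrometric detection of neoantigens
usually fails, and the vaccine payload — a set of ten long synthetic
peptides — must be chosen from predicted HLA ligands. `neovax` implements
that decision pipeline end to end: from three per-caller somatic VCFs to a
ranked table of optimally designed long peptides, plus the proteogenomics
side products (a mutation-annotated protein database and flags for
MS-identified mutant peptides).

# The procedure, stage by stage

## Consensus variant calls

The three callers (a haplotype-assembly caller, a Bayesian somatic caller,
and a hard-filtering caller — consumed only as VCFs) are merged into a
non-redundant union keyed on `(chrom, pos, ref, alt)` after left
normalization and multi-allelic splitting. When callers disagree at a
genomic coordinate, the variant supported by a strict majority of the
callers reporting at that coordinate is kept; with no strict majority the
coordinate is rejected outright. One deliberate generalization: a single
caller reporting a heterozygous-alternate site contributes two variants at
one coordinate, each supported by every caller that reported it — both
survive, because the majority denominator counts *callers*, not calls.

A variant present in tumor and matched normal is a germline SNP; present
only in tumor, somatic. Presence disagreements resolve conservatively:
germline evidence from any caller wins. Germline-only calls are dropped
with a warning.

High confidence means: somatic and (detected by the Bayesian somatic caller
alone, or by at least two of the three callers). Germline SNPs are retained
only when phase-linked to a retained somatic variant — they inherit
retention and the support rule is *not* applied to them independently,
since their evidence profile (present in both samples, often deeply
covered) is not comparable to a somatic call's. Linkage requires a shared
phase set *and* the same haplotype side in the phased tumor genotype;
unphased variants are never linked.

## Mutant contexts

Each retained somatic missense variant is mapped onto the canonical
transcript of its gene — the longest complete CDS, ties broken by
transcript identifier — and expanded into a mutant context: the novel
residue at the centre of a 31-mer (15 reference residues each side,
truncated and never padded at the protein termini), with every
non-synonymous linked-SNP edit falling inside the window applied to both
the sequence and the mutation label. Synonymous and stop-gained effects are
excluded. One context per mutation; when isoforms disagree the canonical
transcript decides.

Frameshift indels can optionally contribute a context consisting of the 24
unaltered residues upstream of the first altered residue followed by the
novel open-reading-frame translation up to (not including) the first stop.
The option is off by default, matching the intended clinical configuration,
and an immediate stop leaves a flagged upstream-only context.

## Candidate epitopes and scoring

From each context, all windows of 9–12 residues (HLA class I) and 12–19
residues (HLA class II) whose span covers the mutated residue are
enumerated. Note the geometry: a window of length $k$ through centre
position 16 of a 31-mer has $\min(k, 32-k)$ placements, so a full context
yields 42 class I and 112 class II candidates. Windows covering only a
linked-SNP edit but not the somatic residue are excluded by default.

Scoring is pluggable. The built-in scorer is a per-allele position weight
matrix: class I peptides score the sum of position weights under the matrix
of their length; class II peptides score their best 9-mer core under a
single core matrix. A percentile rank calibrates each score against
`decoyN` random peptides per length (default 100{,}000, drawn i.i.d. from
background amino-acid frequencies under a fixed seed):
$\%\mathrm{Rank} = 100 \cdot \Pr(\text{decoy} \ge \text{score})$, and the
reported p-value is $\%\mathrm{Rank}/100$. That identification keeps one
degree of freedom and reproduces the printed pairing of sub-5% ranks with
p-values like 0.002; it is a stand-in, since the published predictors do
not document the exact relation. An adapter ingests external score tables
(`peptide`, `allele`, `score`, `percent_rank`[, `p_value`]) so published
predictor output can replace the built-in scorer; candidates missing from
the table are flagged unscored and excluded from binder calls.

A candidate is a predicted binder when its best per-allele rank is strictly
below the cutoff (default 5; printed formulations differ between strict and
non-strict, so a switch exists and the Methods-style strict `<` is the
default) **or** when the wild-type form of the window is an exact ligand
database match.

## Exclusion filters and hotspot overlap

Four filters, all order-independent (their commutativity is a tested
property):

* **Expression** — a mutation is dropped when its gene's 90th-percentile
  TPM in the target tissue is below 1 (strict; exactly 1 is retained). The
  percentile uses linear interpolation between order statistics (the
  default type-7 convention; samples 1..10 give 9.1), fixed here because
  the upstream expression resource does not document its method. Genes
  missing from the table are retained with a flag — absence of evidence is
  not evidence of absence.
* **Wild-type identity** — a mutant peptide whose exact sequence occurs
  anywhere in a reference proteome is dropped; the wild-type counterpart
  being present is irrelevant.
* **Hypermutated genes** — genes with more than `k = 3` somatic mutations
  lose all their mutations (likely false-positive havens). The source text
  quantifies neither this nor underrepresentation, so both defaults are
  explicit placeholders.
* **Underrepresentation** — a mutation whose source protein has ligand
  database coverage below a threshold is dropped; the default threshold 0
  leaves the filter inert until a user supplies a number.

Per HLA class, the overlap of a mutation's wild-type candidate forms with
the ligand database is classified EXACT (equal to a ligand) > INCLUDED
(proper substring relation in either direction) > PARTIAL (overlap of at
least 5 residues with a ligand mapped to the same protein) > NONE. The
containment and 5-residue operationalizations of the middle categories are
this package's own, documented and configurable; exact wild-type matches
additionally act as a ranking tie-break (a prioritization nudge, not a
filter).

## Long peptide design and ranking

For each surviving mutation with at least one binder, the design is the
contiguous context window maximizing the number of *fully contained*
binders; among maxima the shortest; among those the leftmost. All
$O(L^2)$ windows are enumerated (contexts are at most 31 residues for
SNVs, so exhaustive search is exact and cheap; a tested brute-force oracle
confirms equivalence). There is no length cap beyond the context itself by
default — within a 31-mer the whole context always contains every binder,
so the optimum is the tight hull of the binder spans — but an optional
`maxLength` cap exists for long open-reading-frame contexts, where two
distant binder clusters may not fit one window and the larger cluster wins.

Designs are ranked by: minimum class I binder p-value ascending (designs
with no class I binder last); total binder count descending; distinct
class I + class II alleles descending; exact hotspot match first; genomic
coordinate ascending as the final deterministic tie-break (a total order —
re-running the pipeline reproduces the report byte for byte). The top 10
designs form the report, one row per mutation, with fourteen columns
mirroring the clinical summary table (rank, position, gene, expression,
mutation, driver status, sequence, hotspot categories, lowest p-values per
class, binder and allele counts). "Predicted peptides" counts unique binder
sequences contained in the design, classes pooled — the alternative
reading (peptide–allele pairs) is available from the binder table.

## Proteogenomics

The customized database contains every reference protein once plus, per
affected transcript, one mutant entry with all retained substitutions
applied and a header suffix listing the edits
(`transcript|gene|p.Ala2Val;...`). The pipe-delimited convention is this
package's own. With zero variants the output is byte-identical to the
reference proteome (a tested invariant). Post-search, an identified
peptide is flagged `mutant` only when it occurs in a mutant entry, spans an
edited residue and is absent from the entire reference proteome; the
intended downstream search settings (unspecific digestion, 8–25 aa, 5%
peptide FDR) are recorded here as metadata and not executed.

# The synthetic cohort and what it shows

`generateCohort()` writes a fully self-consistent toy cohort: a
single-chromosome genome of one-exon, plus-strand genes (multi-exon and
minus-strand mapping is exercised by dedicated unit tests instead, keeping
fixture coordinates readable); three caller VCFs with planted supporter
profiles, a 1-vs-1 conflict, a multi-allelic site, phased linked and
opposite-haplotype SNPs, and a germline-only call; an expression table; a
ligand database; PWM motif files; driver and identified-peptide lists; and
a `truth.json` with the expected outcome of every planted variant.

The default emulates one study patient: 23 non-synonymous somatic
mutations (the cohort's patients carried 60, 39 and 23 — the smallest was
chosen as the representative low-burden case), 14 genes of 120–260
residues, ten expression samples per gene, uniform background amino-acid
frequencies (the simplest null for decoy calibration), and 100,000 decoys
per length.

The planted-truth trick: background proteins avoid tryptophan and
methionine (apart from start codons), and the fixture PWMs are
anchor-indicator matrices — weight 6 on W at fixed class I anchor
positions, on M for the class II core, zero elsewhere. Planted mutations
then fall into exact score tiers (0, 2 or 3 anchors), whose percentile
ranks concentrate far from the 5% cutoff
($\approx 100\%$, $\approx 0.7\%$, $\approx 0.01\%$), so binder status,
design spans, binder counts and the identity of the rank-1 mutation are
known by construction for *any* seed. One gene each plants: the engineered
best mutation (three class I anchors, a class II core, exact database
matches in both classes), a driver-gene binder seen by the somatic caller
alone, a binder in a sub-threshold-expression gene, a hypermutated gene, a
wild-type-identity trap (its best 9-mer duplicated into another reference
protein), a binder whose second anchor arrives via a phased linked SNP
(with an opposite-haplotype decoy that must *not* be applied), and a
non-binder rescued only by an exact wild-type database match.

What passing the fixture suite does **not** show: performance on real
motifs (real PWMs are dense and peptide ranks crowd the cutoff), real
linkage structure (real phase sets span many variants), indel-rich tumors
(the fixture plants substitutions), isoform complexity, or the behaviour
of the published predictors the adapter can ingest. The fixture
demonstrates that the *plumbing and decision rules* are implemented as
specified, not that the predictions are accurate.

# Numerical choices and degenerate inputs

* Percentile ranks use a weak inequality ($\ge$) against decoys, so a
  score above every decoy gives rank 0 and the rank is monotone
  non-increasing in score (tested property).
* Decoy generation restores the caller's RNG state; two models built with
  the same matrices and seed are bit-identical.
* Contexts shorter than a class's minimum window length yield no
  candidates, with a warning. Peptides containing non-standard residues
  are dropped from scoring and flagged `unmapped` in observed-peptide
  classification.
* Designs without class I binders rank after all designs with one (their
  missing p-value sorts as just above 1).
* Transcripts with CDS length not divisible by three are loaded but
  flagged and excluded from annotation; a reference-allele mismatch
  between VCF and transcript sequence skips the variant with a warning.
* Test problem sizes: the consensus oracle sweep uses 1,000 random
  three-caller instances, the optimizer oracle sweep 1,000 random contexts
  with up to 40 binder spans, and the end-to-end checks run two cohorts
  (one at the default 100,000 decoys, one at 20,000).

# Known limitations

Effect annotation is deliberately minimal (substitutions and indel frame
logic on canonical transcripts; no splice-site, UTR or regulatory calls).
The built-in scorer is a transparent stand-in, not a reimplementation of
the published mixture-model predictors; real deployments should feed the
external-score adapter. Phasing is consumed, never computed. The ligand
"hotspot" categories reduce a density notion to three set relations; a
fraction-of-overlap definition would be a reasonable alternative and the
thresholds are exposed. Ranking beyond the explicit keys has no biological
tie-break — the genomic-coordinate key exists purely to make reports
reproducible.
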