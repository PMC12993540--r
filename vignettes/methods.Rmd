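---
title: "Methods: marker-based phage-family discovery and tracking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: marker-based phage-family discovery and tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of what it computes and why the
defaults are set the way they are. It states no empirical result that the
test suite and `scripts/acceptance.R` do not themselves compute.

## The analysis model

The package operates on *translated* assembled metagenomes: each contig is
one amino-acid ORF fragment. All identity thresholds throughout the
pipeline are amino-acid identities, because marker discovery at 20-40%
nucleotide-level divergence is only tractable on protein alignments.

### Alignment contract

Every module consumes one alignment contract: exact Smith–Waterman local
alignment under BLOSUM62 with affine gaps (open 11, extend 1) — the scoring
system of default `blastp`. `X` scores 0 against every residue. Percent
identity is `100 * identities / aligned columns` (the blastp convention).
Significance uses the Karlin–Altschul formula
`E = K·m′·n′·exp(−λ·S)` with the published gapped-BLOSUM62/11/1 parameters
λ = 0.267, K = 0.041, H = 0.14. The effective lengths `m′`, `n′` apply the
standard edge-length correction: the adjustment `l` is the fixed point of
`l = ln(K·(m−l)·(n−N·l))/H`, iterated with damping, clamped so neither
effective length collapses below one residue per sequence. Consequences
worth knowing:

* E is exactly linear in database size only with the correction off
  (`length_correct = FALSE`); with it on, E is monotone but slightly
  sublinear. The tests exercise both regimes.
* The cutoff E < 0.001 (the signature rule) corresponds, for a ~550-aa
  reference against a ~0.5-Mres metagenome, to a raw score around 77 —
  comfortably above the maximal scores (~70) that uniform-composition
  background contigs attain by chance, which is what makes background
  false positives rare rather than impossible.

`compute_signatures()` uses a two-stage search: contigs sharing no exact
amino-acid 5-mer with the reference are skipped before Smith–Waterman.
This is a seeded heuristic in the BLAST mold, and it is applied by default
because the sensitivity cost is negligible in the regime the pipeline
targets: at 30% divergence the chance that a ≥50-aa homologous fragment
contains no conserved 5-mer window is well under 0.1%, while ~98% of
unrelated contigs are skipped. `prefilter = FALSE` restores the exhaustive
search; the oracle-equivalence tests run on the exhaustive path.

### Signature clustering

A reference's *signature* is the set of contigs with E < 0.001 against it.
Two references overlap *stringently* when shared contigs exceed 50% of
**either** signature — operationally, of the smaller one. This reading
maximises de-duplication: a small signature nested inside a larger one
counts as overlapping. Greedy clustering repeatedly retains the unprocessed
reference with the largest signature and eclipses everything overlapping it
above threshold. The greedy key (signature size desc, then best E asc,
then lexical reference id) is a package choice: signature size is the one
signature-level quantity the downstream gates also use, and the two
tie-breaks make the procedure fully deterministic and input-order
invariant. One pass over the sorted list is a fixed point of the rule, so
convergence is immediate; provenance records which reference eclipsed
which, so alternative keys can be audited.

### Discovery cascade

The gates are applied in their natural order and each output is a subset of
its input: annotation match (case-insensitive regular expression,
default `"terminase"`), signature size ≥ 5, identity to the representative
contig ≥ 10%, cross-dataset conservation ≥ 75%, redundancy removal at
E ≤ 0.001 (one survivor per connected homology component; largest
signature, then lexical id). One deliberate tightening: the cross-dataset
screen requires the qualifying alignment to *also* pass E ≤ 0.001, because
a bare identity threshold can be met by chance on very short local
alignments; homology search tools impose significance implicitly and this
package does so explicitly.

Full-length selection collects, from every supplied database, sequences at
≥ 70% identity to the candidate fragment, aligns the collected set
(center-star, see below), and scores each sequence `s` as the
equal-database-weighted mean of its column identities to every other
sequence, where a column in which either sequence of the pair has a gap can
only count against, never for (`100 · #identical non-gap columns / #columns
where either is non-gap`). End gaps from short sequences therefore act as
mismatches, which is precisely the "penalise shorter sequences" intent.
Databases are weighted equally so a large database cannot dominate the
mean. Ties go to the longer sequence, then lexical id. The expected
full-length band (400-800 aa, around the ~550 aa typical of TerL genes) is
recorded as an `in_band` flag rather than enforced, so an out-of-band
arg-max is visible rather than silently discarded.

### Multiple alignment

`center_star_msa()` is a progressive center-star alignment over pairwise
global (Needleman–Wunsch) alignments against the longest sequence (ties:
lexical id). It is not guaranteed optimal, and does not need to be: every
quantity computed *on* an alignment (full-length scores, conservation
profiles, matrix exports) is computed on the alignment actually built, and
the test oracles rescore the same alignment. An external aligner can be
substituted upstream wherever a function accepts a prebuilt alignment
matrix.

### Presence, prevalence, temporal statistics

The three-state presence call is intentionally asymmetric: *present*
requires a ≥150-aa alignment above 70% identity; *absent* requires that
**no** ≥75-aa alignment exceeds 40% identity. The permissive absence rule
exists to avoid mistaking low coverage (or a short remote homolog) for true
absence; everything between the rules is *indeterminate*. Only the 150-aa
and 75-aa span values appear as defaults because they are the spans the
statistic definitions use; both are configurable per dataset
(`presence_thresholds()`), and the span actually used is recorded in the
prevalence-matrix metadata.

Prevalence aggregates by maximum over a group's metagenomes (a subject is
positive if any of its samples is), so adding a metagenome can never lower
a cell. Indeterminate calls count as not-positive for prevalence, but
*exclude the subject entirely* (numerator and denominator) for `f_switch` —
a flip into or out of an indeterminate state is evidence about coverage,
not about colonisation. "Two consecutive visits" means the subject's first
two visits with data; with several metagenomes per cell the lexically first
is used, a deterministic stand-in for "one metagenome per habitat".
Oral aggregation is any-present / all-absent per visit; because the
exclusion rule then acts on different subject sets per habitat, the
aggregate `f_switch` is *not* bounded by the per-habitat values, and the
test suite pins that down with a constructed counterexample.

### Degenerate primers

Anchor columns are those whose information content
(`log2 20 + Σ p log2 p`, equal-weighted residue frequencies across
datasets) reaches 3.5 bits within regions spanned by all datasets. An
information-content score is used for anchoring because it measures exactly
what a position-specific profile search measures — positional conservation
— without requiring an external domain database; the cutoff is exposed as
configuration, and a profile-database scorer can be plugged in by
supplying a different profile.

The 3′ core covers 3-4 codons of anchor-region residues, every core column
at ≥ 90% equal-weighted consensus identity. Per column the package selects
the **largest exact codon box**: a cartesian product of per-position
nucleotide sets that contains only codons of the allowed residues while
covering every allowed residue. The naive IUPAC union is *not* exact
(Leu's union YTN also encodes Phe), so exactness is enforced by exhaustive
search over per-position base subsets (≤ 15³ boxes; microseconds). The
3′-terminal codon is restricted to G/C-ending codons (G/C-starting for
reverse primers), so the GC clamp holds by construction; every amino acid
has a G/C-ending codon, but ten lack G/C-starting ones, so reverse anchors
are only feasible on the other ten. Degeneracy-cap enforcement order:
shorten the core (4 → 3 codons), then drop residues rarer than 5% in the
profile, then reject with the failed constraint named — never silently.

The 5′ clamp is non-degenerate consensus sequence, one preferred codon per
consensus residue. The inputs are protein alignments, so true codon-bias
matching is impossible without nucleotide data; the default is a standard
bacterial preferred-codon table, and `codon_usage=` accepts a caller's
table derived from nucleotide alignments. Clamp length is chosen to bring
the melting temperature to 60 ± 2 °C, where Tm is the midpoint of the
nearest-neighbor range (SantaLucia 1998 unified parameters,
`ΔS + 0.368·N·ln[Na+]` salt correction, 500 nM primer, 50 mM Na⁺) over the
least- and most-stable degenerate expansions. Hairpin and primer-dimer
risks are screened as longest (3′-anchored) complementary runs over IUPAC
sets — a deliberate proxy: it is monotone in the true thermodynamic risk,
costs nothing, and has no hidden parameters.

### Amplicon QC

The read model is the strictest one compatible with paired 2×300
sequencing of short amplicons: the mates overlap over the entire fragment,
any mismatch rejects the pair, joined quality is the per-base maximum.
Quality filtering keeps reads whose interior bases (first/last two exempt,
as read ends are systematically low quality) are all ≥ Q30. Barcodes are
matched exactly; the barcode table is validated to be error-detecting
(pairwise Hamming ≥ 2), so any single substitution is caught rather than
mis-assigned. Primers are matched with zero mismatches under IUPAC
degeneracy. Every discard is logged with stage and reason, and
`reads_in = reads_binned + Σ discards` holds exactly. OTU clustering is
greedy abundance-sorted centroid clustering (ties: lexically smaller
sequence; representative id: lexically first member), with identity from
an end-gap-free global alignment — chosen because it is reproducible and
order-invariant, which reference OTU pickers often are not.

### Phylogenetic preparation

Isolate homologs require ≥ 70% identity across ≥ 90% of the marker length.
Consolidation clusters *within* species × body-region × health-status
groups only (health status is curated input, never inferred), single
linkage at ≤ 3% amino-acid distance counting only pairs whose alignment
spans ≥ 98% of the marker; the representative is the longest sequence,
then lexical id. Matrices include rows at ≥ 70% identity over ≥ 400
alignment columns; fewer than four qualifying taxa refuses the matrix
(network and tree tools need ≥ 4 leaves) rather than erroring. Exports are
aligned FASTA, relaxed PHYLIP, and NEXUS with per-taxon provenance carried
as taxa-block comments; all three round-trip losslessly, and network/tree
estimation itself is deliberately out of scope — external tools consume
the exports.

## The synthetic study system

The generators emulate the statistical structure the analysis assumes, not
any particular sequencing platform:

* **Reference library** — independent uniform-random ancestor proteins,
  one per family; family members are per-site substitution mutants (rate =
  `family_divergence`, substitutions uniform over the 19 other residues, so
  configured rate = expected observed divergence). Genes average 550 ± 60
  aa, the size of a typical TerL gene (~1650 nt).
* **Metagenomes** — planted fragments with truncated-normal lengths
  (default 112 ± 56 aa, floor 50 aa: plaque-metagenome-like contigs of
  ~336 ± 167 nt with a 300-bp assembly minimum; cohort analyses in the
  tests use 200 ± 20 aa, matching longer gut/oral assembly contigs, so
  that ≥150-aa presence spans exist), uniform start positions, and
  uniform-composition background contigs.
* **Cohorts** — per subject × habitat, presence at visit 1 is
  Bernoulli(`presence_prob`); each later visit flips state with
  `switch_prob`. Both accept per-family × habitat matrices.
* **Amplicon runs** — reads are barcode + primer + insert +
  reverse-complemented primer with full-overlap mates, iid per-base
  substitution errors on each mate, and Phred 35-40 qualities.

Every generator draws from its own RNG stream, derived from the master
seed and a stable label (`stream_seed()`), so outputs are byte-identical
under a fixed seed and adding a generator never perturbs another.

What the generators do **not** emulate — and hence what green tests do not
establish about real data: realistic amino-acid composition (uniform
background makes chance high-identity alignments rarer than in real
low-complexity regions), indels (substitution-only mutation keeps percent
identity the single currency; an indel-capable model is the natural next
step), platform-specific error and quality profiles, chimeras, assembly
artefacts, and within-metagenome abundance structure. Detection
sensitivities measured here are therefore upper bounds on real-data
performance; threshold *semantics* (what passes which gate) transfer
directly.

## Numerical and design choices

* Coordinates are 0-based half-open internally; exported tables are
  documented per column.
* Ties everywhere break deterministically (documented per function):
  lexical ids after the scientifically meaningful keys.
* Degenerate inputs: empty planting, empty signatures, constant rank
  vectors (Spearman reported `NA`), singleton databases (score defined
  100), no qualifying full-length sequence or < 4 matrix taxa (reported,
  not raised), no eligible `f_switch` subjects (`NA`).
* The pipeline driver (`run_pipeline()`) is a plain R function rather than
  a shell tool: its users drive it from R, and the JSON manifest (seed,
  thresholds, stage summaries, output list — no timestamps) makes runs
  byte-comparable.
* Problem sizes in the test suite are chosen to exercise each estimator's
  statistical claim at meaningful power while staying desk-scale: the
  clustering sensitivity benchmark uses 10 replicates of 20 families ×
  5 fragments among 4,000 background contigs; parameter-recovery checks
  use 100-200 subjects; oracle-equivalence checks use ≤ 30-element
  instances where brute force is exact.

## Known limitations

* Substitution-only evolution: no indels, no recombination, no selection.
* The conservation-profile anchor score is a proxy for profile-database
  bit scores; the 3.5-bit cutoff was adopted for cutoff-semantics
  compatibility, not re-derived.
* The clamp codon table is a global bacterial preference, not the codon
  bias of the actual target community, unless the caller supplies one.
* `call_presence()` evaluates the single best-scoring local alignment per
  contig; a secondary, higher-identity-but-shorter alignment on the same
  contig is not considered separately (multiple-HSP support would refine
  borderline indeterminate calls).
* Smith–Waterman against every contig is exact but quadratic; the 5-mer
  prefilter keeps cohort-scale runs tractable, and swapping in an
  accelerated exact backend is supported as long as it reproduces scores.
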