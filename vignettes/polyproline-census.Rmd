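---
title: "The polyproline census: model, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The polyproline census: model, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyproscan)
```

## Why count polyproline

Consecutive prolines are the hardest peptide bonds a ribosome forms;
EF-P (bacteria) and eIF5A (eukaryotes) exist to relieve the stall, and the
Pro-Pro-Gly tripeptide is among the strongest stalling contexts. The
comparative question — how much polyproline and PPG a proteome carries, and
whether that content concentrates in evolutionarily young proteins — reduces
to a small set of well-defined counting problems. This vignette records how
`polyproscan` defines each of them, the parameters that matter, and the
design choices made where more than one convention was defensible.

## The counting model

**Maximal runs.** A repeat is a maximal run: n consecutive identical
residues whose flanking positions hold a different letter or fall outside
the sequence. Sequence boundaries are treated as non-matching flanks, so a
protein that begins or ends with `PPP` contributes a run. The alternative —
requiring a literal non-matching residue on both sides — would silently
discard every terminal run; we reject it because terminal polyproline
stalls ribosomes exactly as internal polyproline does.

**The triplet unit rule.** A run of length n contributes `floor(n / 3)`
repeat units: runs of 3–5 are one unit, 6–8 two units, and so on, uncapped.
This equals the greedy count of disjoint `PPP` trigrams inside the run (a
property the test suite verifies by brute force for all n up to 1000), so a
"unit" can be read as "one ribosome-stalling triplet's worth of proline".

**PPG.** PPG is counted by an independent left-to-right scan of the full
sequence. Because P≠G, two PPG matches can never overlap, so the greedy
non-overlapping count equals the total number of match positions — a small
theorem the property tests confirm on random strings. PPP and PPG counts
are deliberately independent: `PPPPG` contributes one PPP unit *and* one
PPG. No exclusion rule is applied, because the two motifs answer different
questions (repeat content vs stalling-context content) and any exclusion
would make their totals non-additive across proteins. Users who need the
exclusive count can subtract PPG occurrences whose proline pair lies inside
a recorded run, which the per-protein run lists make possible.

**Ambiguity letters.** X, B, Z, J, U and O are retained in sequences and
count toward protein length — frequencies are calibrated against *total*
residue counts — but they never match a repeat residue: `PPXPP` holds two
runs of length 2 and zero units.

**Triplet census for all residues.** The same maximal-run/`floor(n/3)`
machinery applies to each of the twenty amino acids, giving the
tandem-repeat census (`aa_composition()`); the proline column of that
census equals the PPP unit count by construction, and the tests assert it.

## From proteins to proteomes

Per-protein profiles are summed into integer totals and converted to
calibrated frequencies: units per 10,000 amino acids, proline usage in per
cent. Full precision is carried internally; report tables round half away
from zero at the conventional printed precision (frequencies two decimals,
percentages one), because half-to-even rounding — R's default — disagrees
with how such tables are conventionally printed on .5 boundary values.

The run-length distribution table buckets maximal proline-run lengths into
3…10 and ">10" (lengths ≥ 11). The exact lengths in the overflow bucket are
preserved alongside the table: without them the bucketed counts alone
under-determine the unit total, and the conservation identity

> units recomputed from the distribution table = unit total from the
> per-protein scan

must hold exactly for every proteome (it is tested on random proteomes).
On a repeat-free input the triple-proline share is reported as 0 with an
explicit `pct_3p_defined = FALSE` flag rather than an error, so batch runs
over repeat-free species do not abort.

Protein-length box statistics use linear interpolation between order
statistics (`stats::quantile` type 7). Box-plot percentile estimators vary
across software and the choice is rarely material at proteome scale, so we
take R's default, expose `quantile_type`, and record it in the result.

## Dataset preparation conventions

Proteomes arrive as protein FASTA with one of three header schemas (plain
ids, Ensembl-style `gene:`/`transcript:` tags, or `key=value` pairs).
A transcript-level proteome is reduced to one longest protein per gene;
ties on length break to the lexicographically smallest protein id, which
makes the selection a pure function of the record set rather than of input
order. A single trailing `*` stop symbol is stripped; an *internal* stop or
gap character is treated as pseudogene leakage and rejected loudly, not
trimmed. When an Ensembl-style header exposes a biotype tag naming a
pseudogene or transposable element, the entry is dropped; with plain
headers no filtering occurs. Proteins with no gene assignment keep
`gene_id = protein_id`, so they survive isoform selection as singletons.

## Ortholog pools

Pairwise InParanoid-style tables are filtered to inparalog score exactly
1.0 — the cluster seeds — on the focal species' side, and a pool is the
intersection of the focal-side seed sets across the pool's comparator
species. With nested comparator sets the pools nest (more comparators can
only shrink the intersection): pool 1, shared across all species, holds the
oldest proteins; pool 4, shared with only the closest comparator, the
newest. Score comparison is exact by default because the tables are written
with exact decimals; a tolerance exists for tables with floating-point
artifacts and its use is logged. A gene seeded in several clusters counts
once. The filter is applied to the focal side only; whether both sides
should be filtered is genuinely open, and `filter_seed_orthologs()` returns
both species' sets so either construction is available. Pool members
lacking a motif profile are a hard error listing the missing genes —
identifier-namespace mismatches must be fixed with a gene map, never
silently dropped, because a silent drop biases pool frequencies downward.

## The synthetic generator

`generate_proteome()` emulates exactly the features the scanner measures:
background residues drawn iid from a configurable composition, plus planted
maximal runs and PPG trigrams. Defaults are chosen once to resemble real
proteomes: proline probability 0.05 (observed proline usage across the
proteomes the census targets spans roughly 4.3–6.3%), remaining mass
uniform over the other nineteen residues, and a log-normal length sampler
(meanlog 5.8, sdlog 0.55; median ≈ 330 aa with a long right tail). Plant
placement reserves a one-residue pad around each site, redraws a flanking
residue whenever the background would extend a plant (for proline runs a
right-flank G is also excluded, so a planted run never manufactures an
unplanned PPG), and rejects colliding positions with a retry cap of 500
before declaring the spec infeasible. Per-protein draws come from a stream
seeded by (seed, protein index), making every record reproducible
independently of generation order.

What the generator does *not* emulate: residue autocorrelation, domain
structure, low-complexity regions other than the planted ones, and any
evolutionary dynamics of repeat expansion. Passing recovery tests therefore
show that the scanner measures what was planted under iid background — they
do not validate biological conclusions drawn from real proteomes.

`expected_frequencies()` gives the closed-form expectation of the
background contribution: the expected number of maximal runs of length n in
an iid sequence of length L with residue probability p is
`2 p^n (1-p) + (L-n-1) p^n (1-p)^2` for n < L (boundary starts need one
non-matching flank, interior starts two) and `p^L` for n = L. Expectations
are computed conditional on realized protein lengths with planted
footprints excised; flank-redraw edge effects at plant boundaries are
ignored, which is why statistical recovery tests compare a 20-seed mean to
the expectation using the empirical standard error rather than an exact
variance.

The ortholog-table generator plants a nested membership design (pool sizes
non-decreasing from the all-species pool to the closest-comparator pool,
infeasible nesting is an error), assigns score 1.0 to designed members and
sub-1.0 scores to decoy clusters, and the round-trip through parsing,
seed filtering and intersection must recover the design exactly.

## Problem sizes and numerical choices

The test suite runs entirely on generated data: the oracle-equivalence
check uses 10,000 random sequences of 10–60 residues against brute-force
window-scanning oracles; statistical recovery uses 20 seeds of a
50-protein × 400-residue proteome; pool round-trips use five-species
instances of 100 genes. These sizes make the full suite complete in a few
minutes on one CPU while keeping every stochastic check's power: the 5σ
band on a 20-seed mean, binomial 5σ bands on composition, exact identity
everywhere determinism allows. All counting is integer arithmetic;
frequencies are the only reals, derived from stored integer totals so that
recomputing them reproduces the stored values exactly.

## Known limitations

* Only exact homopolymer runs and the exact PPG trigram are detected; no
  PSSM or fuzzy matching, and no non-consecutive proline-rich patterns
  (PxxP and the like).
* Ortholog pools consume precomputed pairwise tables; no homology inference
  is performed and no transitive closure across species is taken.
* The generator's iid background understates the clustering of prolines in
  real low-complexity regions, so background unit expectations on real
  proteomes will exceed the iid closed form.
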