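# polyproscan

Polyproline and amino-acid tandem-repeat census of proteomes.

Ribosomes stall when translating consecutive prolines, and dedicated
translation factors — EF-P in bacteria, eIF5A (with its unique hypusine
residue) in eukaryotes, aIF5A in archaea — exist to rescue that stalling.
How much polyproline a proteome carries, and where it sits in old versus
newly evolved proteins, is therefore a comparative question about
translation itself. `polyproscan` is for bioinformaticians who want to run
that census on local protein FASTA files: bacterial, fungal, plant or
animal proteomes, or synthetic ones with planted ground truth.

## What it computes

For every protein the scanner finds **maximal homopolymer runs**: stretches
of n identical residues flanked by a different residue or the sequence
boundary (the `XPnX` convention, with boundaries counting as non-matching
flanks). Each run is converted to repeat units by the triplet rule

    units(n) = floor(n / 3)

so runs of 3–5 prolines are one PPP unit, 6–8 prolines two units, and so
on, with no upper cap. Independently of the run scan, the exact tripeptide
**Pro-Pro-Gly (PPG)** — the strongest stalling motif — is counted as
non-overlapping occurrences (PPG cannot overlap itself, so the left-to-right
count equals the number of all match positions). Per-proteome aggregation
yields:

* run-length distribution tables (buckets 3P…10P and >10P, with the
  triple-proline share of all runs);
* unit totals and calibrated frequencies — units per 10,000 amino acids,
  proline usage in per cent;
* gene groups at unit thresholds (≥1, ≥2, ≥3 PPP or PPG);
* protein-length box-plot statistics (quartiles by linear interpolation);
* the same triplet-unit census for all twenty amino acids.

InParanoid-style pairwise ortholog tables can be intersected (after keeping
only inparalog-score-1.0 seed orthologs) into nested **ortholog pools** —
pool 1 shared across all species (the oldest proteins) through pool 4
shared with only the closest comparator (the newest) — and every statistic
above can be restricted to a pool, exposing how repeat content varies with
protein age.

A synthetic-proteome generator plants homopolymer runs and PPG trigrams
with enforced maximal flanks, and a synthetic ortholog-table generator
plants nested pool memberships, so the whole pipeline can be validated
against exact ground truth.

## Worked example

```r
library(polyproscan)
fa <- system.file("extdata", "demo_proteome.fasta", package = "polyproscan")
prot <- read_proteome_fasta(fa, "ensembl")   # drops the pseudogene entry
prot <- select_longest_per_gene(prot)        # one isoform per gene
profiles <- scan_proteome(prot)
profiles[, c("protein_id", "gene_id", "length", "ppp_units",
             "ppg_count", "proline_count")]
#>   protein_id gene_id length ppp_units ppg_count proline_count
#> 1      sp001      gA     50         4         2            18
#> 2      sp002      gB     35         0         0             0
#> 3      sp004      gC     28         0         3             6

summarize_proteome(profiles, "demo")
#> Proteome summary: demo
#>   ORFs 3 | aa 113 | PPP units 4 | PPG 5 | Pro 24
#>   PPP 353.98 /10^4 aa | PPG 442.48 /10^4 aa | Pro 21.24%

format_table1(list(demo = run_length_table(profiles)))
#>   species 3P 4P 5P 6P 7P 8P 9P 10P >10P total pct_3p
#> 1    demo  1  0  1  0  0  1  0   0    0     3   33.3
```

`sp001` carries maximal proline runs of 5, 3 and 8 residues — 1 + 1 + 2 = 4
PPP units — plus two PPG motifs (one of them at the end of the 8-proline
run, which the independent PPG scan counts even though the prolines also
belong to a run). The summary line calibrates those totals against the 113
residues of this toy proteome; on real proteomes the same numbers land in
the units-per-10,000-aa range.

From a shell, the same pipeline runs via the bundled wrapper:

```sh
Rscript inst/cli/polyproscan.R scan --fasta proteome.fasta --species Sc \
    --header-schema ensembl --out reports/
Rscript inst/cli/polyproscan.R simulate --seed 7 --out sim_reports/
```

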