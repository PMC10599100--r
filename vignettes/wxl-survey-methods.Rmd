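---
title: "Methods: detecting WxL gene clusters in annotated genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting WxL gene clusters in annotated genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wxlsurvey)
```

## The problem

WxL proteins are peptidoglycan-anchored surface proteins of
Lactobacillales and Bacillales. The WxL domain is 160–190 residues long
and carries two conserved Trp-x-Leu motifs; small WxL proteins are
little more than a signal peptide plus this domain, while large WxL
proteins carry it at the C-terminus behind host-interaction domains.
Their genes co-occur in loci with a partner protein, here called WxLIP,
composed of a peptidoglycan-binding domain (PGBD; Pfam DUF916), a
host-binding domain (HBD; DUF3324) and a C-terminal transmembrane helix
(TMH), in that order. `wxlsurvey` turns the genome survey of these loci
into a reusable pipeline: find the proteins, classify their domain
architecture, chain the genes into clusters, type the clusters, and
compute the accompanying conservation and physicochemical statistics.

## Domain evidence

Evidence comes from one of two routes, both normalized into the same
hit table (`protein_id`, `domain`, 0-based half-open envelope
coordinates, E-value, source):

* **HMMER route.** `parse_domtblout()` reads `hmmsearch --domtblout`
  output for the three Pfam models (PF13731 → WXL, PF06040 → PGBD,
  PF11797 → HBD; the name map is configurable) and keeps rows with
  full-sequence E-value strictly below `1e-10`. The per-domain
  conditional E-value is ignored by default because hmmsearch ranks
  sequences by the full-sequence statistic; `use_domain_evalue = TRUE`
  switches to the independent per-domain E-value for users who prefer
  the stricter reading.
* **Motif route** (`motif_only` mode). `scan_wxl_motifs()` enumerates
  Trp-x-Leu offset pairs `(i, j)` with `j − i ≥ 40` and
  `j + 3 − i ≤ 190`; `scan_pgbd_anchor()` matches the conserved PGBD
  N-terminal anchor `NQIDKxxxYFDLK` with exactly three free positions.
  Motif evidence is assigned a pseudo-E-value of `1e-12` so it flows
  through the same filter and merge pathway. No sequence motif exists
  for HBD, so this mode cannot distinguish a full WxLIP from an
  isolated PGBD protein — it is a lower-fidelity fallback for running
  without any external tool, not a replacement for profile HMMs.

The minimum motif separation of 40 residues is a package choice: the
domain-length envelope alone admits adjacent spurious pairs, and 40
keeps the two motifs in separate halves of even the shortest WxL
domain. It is exposed as an argument.

`merge_hits()` collapses same-domain hits on one protein that overlap
by more than half of the shorter interval, keeping the lowest E-value
(ties: longer, then more N-terminal). Different domains never merge.
The survivor set is the fixed point "a hit survives iff no
better-ranked survivor overlaps it", which the tests verify against an
exhaustive subset search.

### Hydropathy detectors

`detect_tmh()` slides a 19-residue Kyte–Doolittle window; window starts
with mean ≥ 1.6 are merged into maximal residue-space spans, and only
spans starting within the final 60 residues are reported, because the
WxLIP TMH is C-terminal. The 19/1.6 defaults are standard hydropathy
practice for single-span helices; the reported `hydropathy` is the peak
window mean inside the span, so every reported span satisfies the
threshold by construction even after merging. Note that poly-alanine
tracts (Kyte–Doolittle 1.8) score above the default threshold; the
detector is meant for sequences with hydrophilic background, which is
what real loop regions and the synthetic generator provide.

`detect_signal_peptide()` is a deliberately light heuristic — a
positive residue among the first 10 (n-region) and an 8-residue window
of mean hydropathy ≥ 1.5 inside residues 5–30 (h-region). It is
advisory metadata only: the survey classified proteins from domain
content alone, so no classification decision ever depends on this
call.

## Architecture grammar

`classify_architecture()` applies, per protein:

1. PGBD and HBD both present, PGBD first → `WXLIP_FULL` (the two
   domains always occur in this order in full-length WxLIP; the reverse
   order is classed `OTHER` with an `order_violation` flag);
2. exactly one of PGBD/HBD → `PGBD_ONLY` / `HBD_ONLY`;
3. otherwise, with WxL evidence: `WXL_SMALL` when the longest WxL hit
   covers ≥ 60% of the mature length (sequence minus a nominal
   25-residue signal peptide), else `WXL_LARGE` when the most
   C-terminal WxL hit ends within 15 residues of the C-terminus, else
   `OTHER`;
4. no relevant evidence → `OTHER`.

A protein carrying both PGBD/HBD and WxL evidence takes the PGBD/HBD
branch: the survey treats WxLIP and WxL proteins as disjoint sets and
none of its proteins carried both. The 60% coverage cutoff and
15-residue tolerance quantify a qualitative small/large dichotomy and
are configurable. When several WxL hits survive merging, the coverage
test uses the longest hit and the C-terminal test the most C-terminal
one — the two tests ask different questions of the evidence.

One documented edge: an anomalously short WxLIP that has lost its HBD
and TMH (such cases exist in real genomes) classes as `PGBD_ONLY` under
this grammar. We record the literal class rather than special-casing;
the buttressing-insert call below still identifies its in-cluster PGBD.

`detect_buttressing_insert()` flags PGBD hits of length ≥ 140 residues
as carrying the ~20-residue buttressing loop that distinguishes
in-cluster PGBDs (~148 aa) from Pfam's DUF916 definition (~125 aa);
140 is the midpoint discriminator and uses the hit length directly
rather than an alignment to a reference, since the insert manifests as
total domain length.

## The adjacency rule

Gene ordinals are ranks in start-coordinate order along a replicon,
strand ignored, counting annotated CDS only (pseudogenes and RNA genes
are excluded; this is a documented choice, since "annotated genes"
is ambiguous between CDS-only and all features). Internal coordinates
are 0-based half-open, converted once at the GenBank parser boundary.

Two relevant genes join the same cluster candidate when at most 4
annotated genes intervene (ordinal difference ≤ 5), applied
transitively — single linkage. Transitive chaining is the natural
reading given that real loci contain up to nine WxL genes, which no
pairwise-only rule could span. Candidates partition the relevant genes
(singletons included); genes on different replicons never chain, and
adjacency does not wrap around the origin of circular replicons
(GenBank ordinals are linear; a wrap-around option would need the
replicon's topology, which annotation rarely states reliably).

A candidate **qualifies** as a WxL cluster with ≥ 1 `WXLIP_FULL` and
≥ 2 WxL members (small + large pooled — the definition says "two WxL
proteins" without distinguishing); it is **simple** with exactly 1 + 2.
Isolated PGBD/HBD members co-occur but count toward neither tally. A
genome is **sparse** when it has only one or two relevant proteins in
total and no qualifying cluster.

## Conservation statistic

`column_conservation()` computes, per alignment column, the most
frequent non-gap residue (ties broken alphabetically for determinism)
and flags the column conserved when the count reaches the threshold —
by default the absolute count 60 used on the 175-sequence PGBD and HBD
alignments. "Invariant" is strict identity; conservative substitutions
do not count, matching the definition used for the alignment figures.
For other alignment depths `threshold_frac` scales the cutoff
(60/175 ≈ 0.343). `map_to_reference()` translates conserved columns to
1-based ungapped positions of a chosen reference row, reporting
separately the conserved columns where the reference is gapped.

## Physicochemical properties

Average (isotope-weighted) residue masses plus one water give the
molecular weight; `X` contributes the mean residue mass. The net charge
at a given pH is the Henderson–Hasselbalch sum over the N-terminus and
K/R/H (positive) and the C-terminus and D/E/C/Y (negative); it is
strictly decreasing in pH, so the pI — its unique zero in (0, 14) — is
found by bisection to |charge| < 1e-4. The default pKa set is the
EMBOSS table (N-term 8.6, C-term 3.6, D 3.9, E 4.1, C 8.5, Y 10.1,
H 6.5, K 10.8, R 12.5); the table is pluggable because prediction
servers differ in their internal sets, and agreement with ProtParam
values is expected within about ±0.5 pH rather than asserted. A
numerical note: at pH 14 arginine (pKa 12.5) still retains ≈ +0.03
charge per residue, so the "fully deprotonated" closed form
−(1 + nD + nE + nC + nY) is exact only for arginine-free sequences;
tests use that restriction where they assert the limit to 0.01.
Acidity bands (acidic < 6.5 < neutral < 7.5 < basic) reproduce the
qualitative basic-versus-acidic split of WxLIP pIs across genera and
are configurable. The property table reports both full-length and
mature (first 25 residues clipped) values, since published tables do
not always state whether the signal peptide is included.

## Synthetic data: what it emulates, and what it does not

`generate_genome()` emits a GenBank file, a domtblout table and a truth
manifest from a single seed. Background residues are uniform over the
19 standard residues excluding tryptophan, so Trp-x-Leu pairs exist
only where planted; decoy genes (100–300 aa) are scrubbed the same way.
Planted proteins carry their class's diagnostic features: WxL proteins
two motifs spaced within the domain envelope (C-terminal placement for
the large class), WxLIP a signal-like N-terminus, a 148-residue PGBD
with the NQIDK anchor, a 112-residue HBD and a 22-residue L/I/V/F
C-terminal tract, with total length drawn from 337–365. True-domain
domtblout rows get E-values log-uniform in [1e-50, 1e-11] (below the
cutoff); spurious rows get [1e-9, 1] (above it) and must never change a
call. Cluster plants are placed with at least `max_gap + 3` decoys
between blocks so distinct plants cannot chain; the truth manifest's
qualifies/simple flags are computed directly from the definitional rule
on the planted gap lists, independent of the detection code.

What passing on this generator shows: the filtering, grammar, chaining
and typing rules are implemented exactly, since the rules are
deterministic and the generator covers compositions and gap values
spanning the rule boundaries. What it does not show: behaviour on real
annotation noise — miscalled gene boundaries, partial domains, Pfam
model drift, atypical E-value distributions, compositional bias — none
of which the generator imitates (nor codon usage, GC content, or
phylogenetic correlation between sequences). Real-genome use should
treat the HMMER route as authoritative and the motif route as triage.

`generate_msa()` plants columns where exactly the threshold count of
rows share a residue while balanced assignment keeps every other count
strictly below threshold, making the planted set the unique correct
answer; infeasible depth/threshold combinations are refused rather than
silently degraded.

## Numerical and degenerate-input choices

* GenBank CDS without `/translation` are translated from the nucleotide
  span under genetic code table 11; CDS with neither are skipped with a
  warning, as are `/pseudo` features. Ambiguity codes map to `X` with a
  warning. Internal stop symbols also become `X`.
* Sequences shorter than a scanner's window return empty results rather
  than erroring; the signal heuristic returns `present = FALSE` below
  25 residues.
* All tie-breaks (majority residue, hit ranking) are deterministic, so
  identical inputs always give identical outputs; reruns of
  `run_survey()` on fixed inputs produce identical tables.
* Problem sizes in the test-suite and acceptance panel (52 genomes of
  ~20–40 genes, 175 × 30 alignments, 100-sequence pI comparisons
  against a 1e-4-step grid) were chosen so that the full suite
  completes in about a minute on a laptop while still crossing every
  rule boundary; they are package choices, not statistical necessities.

## Interfaces

Every user-facing function takes a data frame first and returns a
tibble, so stages chain with the pipe; `run_survey()` drives the whole
pipeline from a `pipeline_config()` (or a flat `key = value` file) and
writes TSV tables mirroring the survey's per-protein, per-cluster and
per-genome inventories. `tidy()`/`glance()` expose results in
broom style and `autoplot()` draws the conservation profile and the
gene-ordinal cluster map. A thin Rscript wrapper
(`inst/scripts/wxl-survey.R`) provides `survey`, `synth`, `props`,
`conserve` and `validate` subcommands for shell use.

## Known limitations

* The headline counts of the original 5482-genome survey depend on a
  GenBank snapshot that is not versioned or deposited, so they cannot
  be reproduced here; the package instead guarantees the rules that
  produced them, verified against planted ground truth and independent
  oracles.
* No profile-HMM scoring engine is included: HMMER output (or the
  motif fallback) supplies the evidence.
* The signal-peptide and TMH detectors are single-heuristic stand-ins
  for dedicated predictors and are not suitable for proteome-wide
  topology annotation.
* Large-WxL internal domain content (mucin-binding repeats and the
  like) is not sub-annotated; the survey only needs the WxL call.
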