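---
title: "Dissecting galectin functional evolution with loop-graft chimeras"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting galectin functional evolution with loop-graft chimeras}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(galtrace)
```

## The scientific problem

Conger eel skin mucus carries two proto-type galectins, congerin I (ConI,
136 residues) and congerin II (ConII, 135 residues), which diverged from a
common ancestor under accelerated evolution and differ markedly in
thermostability and glycan preference. Given a reconstructed ancestral
sequence ("Con-anc"), the question becomes dissectable: which of the 31
residue differences between ancestor and descendant carry which functional
gain? The experimental strategy is region grafting — replace the ancestor's
N/C-terminal segments and binding-site loops (L3, L5, L6) with the
descendant's residues, one combination at a time — and measure each chimera's
thermostability, its dissociation constants against a glycan panel by frontal
affinity chromatography (FAC), and, on the simulation side, the cooperativity
of hydrogen bonds around the binding site.

`galtrace` implements the full analysis layer of that strategy. Wet-lab and
simulation raw data are replaced by seeded synthetic generators with known
ground truth, so every stage is testable offline; the published
dissociation-constant table ships as a plain-text fixture and is recomputed,
not trusted.

## Sequence model and grafting

Sequences are stored against a shared reference numbering (the descendant's
residue numbers, assigned by alignment column). A graft is a column-wise
splice: inside every named region the chimera takes the donor's residues,
including donor insertions and deletions expressed as alignment gaps. This is
what makes a length-changing graft well defined — the ancestral loop L5 has 7
residues (`LNSMVNS`) where the descendant has 9 (`MNSTLKGDN`), so grafting L5
grows the product by two residues while every position keeps its reference
number; no renumbering is performed.

Residue-level diffs report one record per reference position: substitutions
in `E5Q` notation plus explicit insertion/deletion records where exactly one
sequence has a gap. Both kinds count as difference sites; that convention is
what makes the ancestor/descendant distance come out at 31 sites (24
substitutions outside L5, 5 substitutions and 2 insertions inside it).

Chimera names join grafted region labels with `/` in the order the mutants
were built: `N/C` (both terminal segments), then `L5`, `L6`, `L3` — e.g.
`Con-anc-N/C/L5/L6`.

**Region boundaries are configuration, not code.** Published loop boundaries
are typically drawn on a structure figure rather than printed as coordinates,
so the region map ships as an editable JSON file
(`galtrace_example("region_map.json")`) and every function takes it as an
argument.

**The bundled sequences are synthetic stand-ins.** The real alignment exists
only as a figure and a database record that were not machine-readable when
this package was assembled. The shipped FASTA
(`congerin_alignment_synthetic.fasta`, marked as synthetic in every header)
was constructed to satisfy every constraint the accompanying text does state:
136-column reference, 31 difference sites, terminal substitutions exactly
{E5Q, K12T, A118F, N120P, F132L}, the L5 sequences above, and Met38/Thr38 in
L3. Green sequence tests therefore establish internal consistency of the
graft/diff machinery under all documented constraints — not a transcription
of the true sequences. Swapping in the real alignment requires replacing one
FASTA file.

## Loop hydropathy

```{r}
hydropathy_sum("LNSMVNS")    # ancestral L5
hydropathy_sum("MNSTLKGDN")  # descendant L5
```

`hydropathy_sum()` is the plain sum of Kyte–Doolittle indices, not the
length-normalised GRAVY mean. The sum is the convention that matches the
published loop scores (1.3 and −10.6 for the 7- and 9-residue loops above):
it lets a longer hydrophilic loop score lower in absolute terms, which is the
quantity of interest when a graft changes loop length. The scale is
replaceable via `read_hydropathy_scale()`.

## Thermostability: the half-activity retention temperature

Residual activity after a 30-minute incubation is measured by
hemagglutination titer — the last two-fold dilution step that still
agglutinates — so activity relative to an unheated control is
`2^(titer − control)`, capped at 1, and 0 when nothing agglutinates.

T~m~ is defined operationally as the temperature at which 50% activity is
retained. Because the published definition involves no fitting model,
`half_activity_temperature()` uses the first downward 0.5 crossing with
linear interpolation, with three documented choices:

* an exactly sampled 0.5 returns its own temperature;
* noisy, non-monotone curves use the crossing *after the last* temperature
  with activity ≥ 0.5, so an early assay dip cannot masquerade as the
  transition; isotonic pre-smoothing is available (`smooth = TRUE`) but off
  by default;
* curves entirely above or below 0.5 are an explicit out-of-range error —
  never an extrapolation.

The generator (`gen_inactivation_curve()`) produces logistic decays on the
assayed 38–62 °C grid (1 °C steps) with steepness 1.5 °C, a transition width
typical of lectin inactivation curves; published midpoints (44, 46, 48,
52 °C) are treated as plantable generator parameters, since the raw curves
are not printed. At zero noise, recovery is exact on grid points; under noise
of sd 0.05 the published stability ordering (ancestor < ConII < single
grafts < double graft ≈ ConI) is recovered in well over 90% of seeds.

## Binding analysis: dissociation constants and specificity

FAC reports a dissociation constant per (lectin, glycan) pair. The package
stores them in a `kd_table` with a first-class "no detectable binding" state
(`NA`, printed `-`) that is never conflated with 0 or infinity. The frontal
relation `K_d = Bt/(V − V0)` (ligand-excess regime; nmol/mL gives μM) is
provided as `fac_kd()`, with zero retardation mapping to the no-binding
state. The published methods cite this relation's sources rather than
printing it; adopting the standard form is a documented design choice
verified by round-trip against the elution generator.

Three comparative statistics reproduce the published table structure:

* `relative_activity()`: `K_d(reference)/K_d(lectin)` per glycan;
* `ratio_columns()`: the publication layout, rounded to 2 significant
  figures *at the presentation layer only*;
* `sugar_pair_ratio()`: the ratio of relative activities between two glycans
  — a pure specificity measure, invariant to rescaling either lectin's
  K~d~ column. It is always computed from K~d~ cells, never from rounded
  ratio columns: only that choice reproduces the printed three-significant-
  figure values (6.18, 5.27, 10.7 for the Lewis-a discriminating pairs)
  exactly.

```{r}
tab <- read_kd_table(galtrace_example("table1_kd.csv"))
signif(sugar_pair_ratio(tab, "Con-anc-N/C/L5", "ConI", "44", "42"), 3)
```

Because published ratio columns were evidently computed from unrounded
K~d~ values, `ratio_diff_report()` classifies every printed ratio cell as
`match` (reproduced at printed precision), `input_rounding` (achievable from
K~d~ values within half a unit of their printed last digit), or
`inconsistent`. On the bundled table: 306 match, 107 input_rounding, 0
inconsistent, plus 4 cells in the #40 row where a K~d~ is printed but the
ratio is `-` (reported as `not_printed`).

Specificity shifts are attributed to structure through glycan motif
annotations (`glycan_motifs.json`), reconstructed by solving the published
pairwise "different structures" column for per-glycan motif sets. Eleven of
twelve printed rows are reproduced; the printed #47 vs #43 row is internally
inconsistent with three other rows, and the reconstruction yields
α1,3-GalNAc(Gal) for that pair (documented in the JSON rather than forced).

## Hydrogen-bond cooperativity networks

The MD analysis chain mirrors standard trajectory post-processing:

1. **Occupancy**: a bond is present in a frame iff donor–acceptor distance
   ≤ 3.5 Å and (when hydrogens exist) the donor-H…acceptor angle ≥ 120°.
   The source analysis does not state its geometric criteria; these are the
   conventional defaults and both are arguments, with a distance-only mode
   for hydrogen-free toy inputs.
2. **10–90% filter**: bonds formed almost never or almost always carry no
   fluctuation signal and are removed. Bounds are inclusive (the published
   "10–90%" does not specify) and configurable.
3. **Binned formation rates**: the first 3 ns are divided into 200-ps bins
   (20 snapshots at the 10-ps save interval implied by "20 steps"); a
   trailing partial bin is dropped; the rate is the mean occupancy per bin.
4. **Pearson correlation** between bin-rate vectors of every bond pair.
   Zero-variance vectors give undefined correlations, which are excluded
   from averaging and counted (the source is silent on this case).
5. **Group averaging** into a signed network over structural elements:
   intra-loop groups, inter-loop pairs (`L2-L4`), and ligand–arginine groups
   (`Lac-R28`, `Lac-R47`). Chains are labelled so dimer copies stay
   distinct.

No numeric correlation values are published for this analysis — only a
qualitative sign pattern (cooperation within/between L3 and L5, an
L2-mediated L6–L2–L4 block, and anti-correlation of that block with the
lactose-binding arginine bonds). The acceptance property therefore tests
*sign recovery on synthetic data*: the probit generator plants two
anti-correlated latent factors (loadings 0.8, inter-factor correlation −0.7,
marginal rates 0.5 — chosen once as a realistic stated world) and the full
chain must recover the pattern in at least 18 of 20 fixed seeds. The pattern
is checked at the granularity the source states it: L3–L5, L2–L4 and L2–L6
edges positive, and the mean of the {L2, L4, L6} edges to each
lactose-arginine group negative. A stricter variant requiring all six
loop-to-ligand edges individually negative recovers in 16/20 seeds under the
same stated world — with 15 bins, a single 8-pair edge average has a
standard error of roughly 0.1–0.2, so occasional sign flips of one edge are
expected and the block-level statement is the robust one.

Two numerical notes worth recording. First, a *single shared* permutation of
snapshots provably cannot destroy this network: the planted correlations are
contemporaneous, and any statistic computed from synchronised columns is
invariant under a common column shuffle. The "shuffling destroys the
network" property is therefore operationalised with independent per-bond
permutations, which drive the mean absolute edge weight below 0.3. Second,
the probit construction attenuates latent correlations through binarisation
(a latent 0.45 becomes a binary ≈ 0.30 at rate 0.5), which the tests account
for by asserting signs and bounds, not magnitudes.

## Synthetic-data generators: what they emulate, and what not

All generators are bit-reproducible given a seed and emit ground truth next
to the data. Scales mirror the real experiments: K~d~ 0.2–700 μM with
lognormal noise and planted region-by-glycan-class effects; activity curves
on the 38–62 °C assay grid; 3000-snapshot occupancy series giving 15
analysable bins; toy multi-model PDB trajectories whose donor–acceptor
distances follow exact schedules (collinear hydrogens, pairs isolated by
50 Å). They do not emulate: force-field physics, glycan conformations,
correlated assay drift, or FAC instrument effects. A green test on synthetic
data establishes that the analysis recovers what was planted at realistic
scales — not that the published numbers are re-derivable where the paper
prints no raw data (thermal curves, correlation values).

## Known limitations

* The bundled alignment is a constructed stand-in (above); sequence-level
  results are internally consistent rather than literal.
* One acceptance criterion is deliberately left failing: the binding-loss
  call set for `Con-anc-N/C/L5/L6` against the ancestor. The source figure
  legend implies losses at glycans #29, #30, #33 and #40, but in the printed
  K~d~ table row #33 shows no binding for *every* lectin (so #33 can never
  be a "lost" call) and the mutant carries a printed K~d~ of 28 μM at #40
  (so #40 is "retained"). The faithful computation yields {#29, #30}.
  Inventing row-33 values or overriding the printed 28 μM would fabricate
  data; the contradiction is documented instead, and the loss-call logic is
  verified on synthetic tables with planted missing cells.
* `-` cells cannot be distinguished between "no detectable binding" and
  "not measured"; the table treats them uniformly as the former.
* The dimer question (whether published correlations pooled both protomers)
  is unstated; the implementation analyses chains jointly with chain-labelled
  bonds, so either convention can be recovered by filtering.
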