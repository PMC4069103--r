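---
title: "Methods: trajectory comparison, interaction networks and kinetics in phstab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trajectory comparison, interaction networks and kinetics in phstab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phstab)
```

`phstab` packages the statistics used to dissect pH-dependent stability of
a multidomain enzyme: per-domain trajectory statistics, a dynamic-time-warping
comparison of RMSD series, geometric hydrogen-bond and near-attack analysis,
pKa-threshold protonation, subfamily-specific-position ranking, and
inactivation / Michaelis–Menten kinetics. This vignette explains the models
behind each stage, the tunable parameters and their defaults, the numerical
choices, and what the synthetic-data generators do and do not emulate.

## Trajectories, domains and RMSD/RMSF

A trajectory is a fixed atom topology plus an ordered stack of coordinate
frames (Å) at a constant `frame_interval` (ps; default 5 ps, the usual MD
snapshot spacing, so 2000 frames span 10 ns). Domains are named lists of
inclusive per-chain residue ranges and may be discontinuous: the catalytic
αββα-core of penicillin acylase is assembled from three separate β-chain
stretches (β1–72, β146–290, β452–536, totalling 302 residues). The built-in
`ecpa_domains()` partition carries an explicit `Total` entry covering the
whole heterodimer (209 + 557 = 766 residues), because the customary "Total"
row of a per-domain stability table refers to the complete protein, not the
union of the named domains (which covers 713 residues).

RMSD is computed per frame after a least-squares rigid superposition
(Kabsch, via SVD, reflections excluded). Two superposition policies exist
and matter:

* `fit = "local"` (default in `rmsd_series()` when `fit` is omitted): the
  measured selection is also the fitted selection. This isolates a domain's
  *internal* deformation and is the conservative reading of per-domain RMSD.
* `fit = "global"`: the whole structure is fitted, the domain measured.
  This additionally captures rigid displacement of the domain relative to
  the rest — which is precisely the signature of a domain detaching from
  its anchoring interactions.

Whether a published per-domain RMSD used a global or local fit is usually
unstated; both are provided and the pipeline's `run_stability()` exposes the
switch. "Backbone" means {N, CA, C, O} — whether the carbonyl oxygen is
included is a convention; including it is the common choice and changes
nothing qualitatively. RMSF is computed against the time-average structure
over a trailing window (default 2000 frames) after aligning each frame to
the window's first frame on the same selection.

## The Δ~RMSD~ / f trajectory-comparison statistic

Two RMSD series (each truncated to the trailing `expected_length` = 2000
frames) are first smoothed by a centred moving average of 10 frames. The
window is truncated at the series edges so the output keeps its length and
constant series pass through unchanged; this keeps the 2000-frame
bookkeeping intact. The series are then aligned by dynamic time warping:
minimal total cost under local cost |a~i~ − b~j~|, symmetric unit-weight
steps {(1,0), (0,1), (1,1)}, fixed endpoints, and a Sakoe–Chiba band
|i − j| ≤ w. Window sizes {0, 100, 250, 500, 750, 900, 1000} are examined;
reported statistics use w = 500. w = 0 means no DTW: the identity pairing of
equal-length series, which reduces the comparison to a difference of means.
Ties in the traceback break deterministically (diagonal first, then
advancing along the first series), so alignments are reproducible
bit-for-bit. The DP kernel is C++ (Rcpp): a banded 2000×2000 table is the
hot loop of the whole package and this is where the field's time-series
packages also compile.

Along the alignment path,

* Δ~RMSD~ = mean(b~j~ − a~i~) over path elements (signed; positive when the
  second model runs higher), and
* f = fraction of path elements with a~i~ ≥ b~j~ (non-strict, so
  self-comparison gives f = 1 exactly).

Averaging is over *path elements*; when the path repeats a frame the frame
is counted each time it appears. (The alternative — collapsing repeats to
original frame indices — differs only at warping excursions and is not what
the aligned-frame definition of f suggests.) Replicate sets are compared
over all |set1|×|set2| ordered pairs, reporting the mean ± sample SD of
Δ~RMSD~ and the mean f. f ≤ 0.05 is labelled significant, consistent with
the convention that f in the 0.003–0.004 range marks a clearly destabilised
domain; the threshold is configurable.

## The planted-drift experiment

The synthetic two-model experiment behind the package's acceptance checks
emulates a destabilised domain with known ground truth: four pseudo-domains
(60/10/65/65 CA atoms), per-coordinate fluctuation σ = 0.5 Å, three
replicates per model, 3000 frames of which the last 2000 are analysed, and
in model 2 a coherent +x translation of the small domain at 0.001 Å/frame.
Drift is modelled as rigid translation rather than per-atom diffusion
because it reproduces the "ascending RMSD trend" of a detaching domain with
an analytically known magnitude (RMSD = rate × frame under an external
fit). Two consequences shaped the design:

* A *local* fit removes a rigid translation entirely, so drift detection
  must use the global fit.
* Under a global fit the drifting atoms pull on the superposition: a
  fraction ρ (their share of fitted atoms) of the offset leaks into every
  stationary domain's RMSD. Keeping the drifting domain small
  (ρ ≈ 0.05) keeps the leak below the noise floor of the stationary
  domains, so they are not spuriously flagged — mirroring the real
  situation where one domain is a minority of the fitted backbone.

With these conditions the drifting domain shows Δ~RMSD~ ≈ 0.9–1.0 Å and
f ≤ 0.01 at every window 100–1000, while stationary domains keep
f ≈ 0.25–0.45; the experiment scale (6 × 3000 frames, ~200 atoms) runs in
about a minute on one CPU.

## Hydrogen bonds and interaction networks

A donor–H–acceptor triple is accepted when the donor–acceptor distance is
≤ 3.5 Å and the donor–H–acceptor angle is within 145–180°. "Within" is read
as boundary-inclusive on both criteria. The chemistry roster is fixed and
deliberately simple: N and O heavy atoms accept; an N or O with a
covalently attached hydrogen (≤ 1.25 Å in the frame, nearest-atom
assignment) donates; water oxygens do both; sulfur, π-systems and C–H···O
contacts are out of scope. When the topology carries no hydrogens —
crystal structures before protonation — strict mode refuses, and a
heavy-atom fallback accepts on the distance criterion alone, flagging its
output; that is the right screen for comparing homolog structures.

A residue pair counts as bonded in a frame if *any* qualifying atom triple
exists between the two residues; persistence is the mean of this per-frame
indicator, reported per run and pooled (whether a published persistence
range is per-trajectory or pooled is typically unstated — both are cheap).
Networks are extracted around seed residues: all bonds incident to a seed,
plus, for bridging waters bonded to a seed, the water's remaining bonds one
hop out — this is how a buried water mediating three interactions between
two β-sheets becomes visible as a degree-3 node. Network differences are
set differences on unordered residue-pair keys.

## Near-attack conformations

A substrate pose is productive when three distances are simultaneously
≤ 3.5 Å (inclusive — "did not exceed"): catalytic Ser Oγ to the substrate
carbonyl carbon, and the substrate carbonyl oxygen to the backbone amide N
and the side-chain amide N of the oxyanion hole. Residues are fixed by the
enzyme (Serβ1 OG, Alaβ69 N, Asnβ241 ND2 in penicillin acylase); substrate
atom names vary by compound and are supplied in the criteria. The NAC
percentage is evaluated over the trailing 1000 frames (5 ns) by default,
and replicate summaries use the sample (n − 1) SD, matching the mean ± SD
presentation of replicate MD tables.

## Protonation assignment

Fixed-protonation MD freezes each titratable group at the start: protonated
iff pKa > target pH, strictly — equality deprotonates, because the rule is
"higher than". Overrides take precedence and are logged with their source;
the classic cases are a buried carboxylate in a carboxyl–carboxylate pair
(predicted pKa ~13.8 yet deliberately ionised at pH 10 to model the
alkaline state) and a catalytic N-terminal amine kept neutral at all pH.
Neutral His is NE2-protonated by default; doubly protonated only when its
pKa exceeds the pH. The package does not predict pKa values: they arrive as
a four-column text table from any predictor, with a textbook model-value
fallback (Asp 3.8, Glu 4.2, His 6.0, Lys 10.5, Arg 12.5, Cys 8.3, Tyr 10.1,
N-term 8.0, C-term 3.5) when none is supplied.

## Subfamily-specific positions

Candidate alignments are first cleaned: sequences sharing strictly less
than 0.25 bits per column with the template are discarded (global BLOSUM62
alignment, gap open 11 / extend 1, raw score converted to bits with the
standard gapped Karlin–Altschul constants λ = 0.267, K = 0.041), and
clusters above 95 % pairwise identity (greedy single linkage) are collapsed
to one representative — the first in input order, except the template,
which is always retained. The bits filter is applied before the redundancy
filter; the order is configurable and rarely matters.

The specificity score of a column is the mutual information (bits) between
residue identity and subfamily label over the column's non-gap entries,
with the Miller–Madow small-sample correction applied to each entropy term
and the result clamped at zero. The published statistic this stands in for
is defined in separate cited work; the printed scores of that method
(1.894, 1.885, 1.582 for the three headline positions) are therefore
reference output, not targets this package reproduces. The corrected MI is
a documented, testable surrogate with the same qualitative behaviour:
maximal for columns conserved within and distinct between subfamilies, zero
for label-independent columns. The trivially checkable identities (exactly
1 bit for two equal subfamilies with two fixed residues; exactly 0 for
identical distributions) hold for the *uncorrected* estimate, so
`specificity_score()` exposes `correction = "none"` alongside the default.

Significance comes from a permutation null: labels are shuffled across
sequences (one shuffle shared by all columns per permutation, seeded,
mandatory seed), p = (1 + #{null ≥ observed}) / (1 + n~perm~), plus a
Z-score against the null mean/SD. Columns with more than 50 % gaps are
skipped and flagged. Positions are reported by template residue number
(non-gap count up to the column) with per-subfamily frequency strings
formatted as `N(50%) D(50%)` at integer rounding.

The alignment generator plants specificity columns on a conserved
background: four subfamilies of 20/10/10/4 sequences (the sizes of the four
penicillin-acylase subfamilies), 60 columns, 3 planted columns with
distinct per-subfamily consensus residues, background consensus retention
0.9 and planted-column substitution noise 0.1. At these conditions the
planted columns outrank every background column in effectively all seeded
runs. What the generator does *not* emulate: gaps, phylogenetic
correlation between sequences (draws are i.i.d. given the consensus), and
realistic amino-acid substitution preferences — so passing recovery tests
demonstrates the ranking machinery, not robustness to tree-correlated
noise.

## Kinetics

Inactivation follows A~t~ = A₀·exp(−k~in~·t); the fit is
Levenberg–Marquardt least squares (via minpack.lm) with initial guesses
from a log-linear regression on the positive activities, two perturbed
restarts, k~in~ bounded at 0, and convergence tolerances of 1e−12 on the
objective. Constant data converge immediately to k~in~ = 0.
Michaelis–Menten rates v = k~cat~·E₀·S/(K~M~ + S) are fitted the same way
(guesses K~M~ = median S, V~max~ = max v); a warning is raised when the
fitted K~M~ lands far outside the sampled substrate range, the signature of
a grid with no curvature. Reported errors are standard errors of the fit
(not replicate SDs), and catalytic efficiency k~cat~/K~M~ is conventionally
rounded to 2 significant figures in reports. The stabilisation fold is the
plain ratio of reference to variant inactivation constants.

The kinetics generators add Gaussian noise: homoscedastic at a fraction of
A₀ for decay curves, and proportional to the per-point signal for
initial-rate data (relative error is how such assays behave). At 2 % noise
the median relative recovery error is ≈1–2 % for k~in~ and ≈2–3 % for
k~cat~/K~M~ over 100 seeded datasets; the substrate grid (12 points,
0.5–50 µM around K~M~ = 25 µM) matches the assayed range.

## Determinism, degenerate inputs and limitations

Every generator is a pure function of its configuration and a mandatory
seed (RNG state is restored afterwards); identical configuration and seed
give byte-identical outputs end to end. Degenerate inputs fail loudly and
early: mismatched atom rosters between PDB models name the first offending
model, unparseable coordinates name the line, collinear geometry aborts the
superposition, window-0 DTW refuses unequal lengths, a band narrower than
the length difference refuses alignment, overrides naming absent residues
abort, and single-replicate summaries refuse an undefined SD.

Known limitations: the synthetic trajectories contain no solvent and no
force-field realism — they emulate the *statistical* signatures
(stationary fluctuation, coherent drift, Bernoulli-bonded triads) that the
statistics are designed to detect, so green tests certify the statistics,
not MD itself. The H-bond module scores geometry only (no energetics), the
MSA module takes subfamily labels as input (no automatic subfamily
detection), and pKa prediction, docking scores and secondary-structure
timelines are upstream of or outside the package.
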