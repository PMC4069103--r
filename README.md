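# phstab

Tools for dissecting the pH-dependent stability of multidomain enzymes —
penicillin acylase from *Escherichia coli* being the motivating case — from
molecular-dynamics trajectories, labelled sequence alignments and kinetic
assays.

Penicillin acylase (EC 3.5.1.11) is a heterodimeric Ntn-hydrolase whose
catalytic αββα-core domain is held together by a buried hydrogen-bond
network anchored on a carboxyl–carboxylate pair (Gluβ482–Aspβ484). At
neutral pH one carboxyl is protonated and the pair shares a hydrogen bond;
at alkaline pH both ionise, the network collapses and the enzyme
inactivates. `phstab` implements the computational pipeline by which this
mechanism is established and a stabilising mutation predicted:

- **Trajectory statistics** — multi-model PDB I/O, Kabsch superposition,
  per-domain backbone RMSD series and Cα RMSF profiles over discontinuous
  domain partitions.
- **Trajectory comparison** — the Δ<sub>RMSD</sub>/f statistic: two RMSD
  series are smoothed by a 10-frame moving average, aligned by dynamic
  time warping under a Sakoe–Chiba band (default 500 frames), and
  summarised as Δ<sub>RMSD</sub> = mean(RMSD<sub>MD2</sub> −
  RMSD<sub>MD1</sub>) over the alignment and f = the frequency of aligned
  frames with RMSD<sub>MD1</sub> ≥ RMSD<sub>MD2</sub>. Replicate sets are
  compared over all ordered pairs; f ≤ 0.05 flags a significant
  stability difference.
- **Hydrogen bonds** — geometric detection (donor–acceptor ≤ 3.5 Å,
  donor–H–acceptor 145–180°), per-pair persistence across frames,
  seed-residue network extraction with bridging waters, and network
  differencing.
- **Near-attack conformations** — the three active-site distance criteria
  (Ser Oγ ↔ substrate carbonyl C; carbonyl O ↔ the two oxyanion-hole
  amide nitrogens, all ≤ 3.5 Å) and productive-frame percentages.
- **Protonation assignment** — the fixed-protonation rule (protonated iff
  pKa > target pH) with logged manual overrides.
- **Subfamily-specific positions** — redundancy (>95 % identity) and
  relatedness (≥0.25 bits/column) filters, per-column specificity scoring
  by corrected mutual information with a permutation null, ranking and
  Table-style per-subfamily frequency strings.
- **Kinetics** — first-order inactivation fits
  (A<sub>t</sub> = A₀·e<sup>−k_in·t</sup>), Michaelis–Menten fits
  (v = k<sub>cat</sub>·E₀·S/(K<sub>M</sub> + S)), catalytic efficiency
  and stabilisation fold-change.
- **Synthetic data** — seeded generators for every input class
  (fluctuating/drifting trajectories, planted-column alignments, decay and
  rate data, bonded/unbonded H-bond triads) so each statistic is testable
  against known ground truth.

Everything is tidyverse-shaped: functions take data frames and return
tibbles, results chain with the pipe, fitted objects have `tidy()` /
`glance()` methods and `autoplot()` views.

## Worked example

A two-model experiment: three stationary replicates against three in which
one small domain drifts away from its reference, exactly the signature of
a pH-destabilised domain.

```r
library(phstab)

doms_stable <- list(
  A1 = list(n_atoms = 60, sigma = 0.5, drift = 0),
  B1 = list(n_atoms = 10, sigma = 0.5, drift = 0),
  B2 = list(n_atoms = 65, sigma = 0.5, drift = 0),
  B3 = list(n_atoms = 65, sigma = 0.5, drift = 0)
)
doms_drift <- doms_stable
doms_drift$B1$drift <- 0.001  # Å per frame, coherent translation

m1 <- lapply(101:103, function(s) gen_trajectory(doms_stable, n_frames = 3000, seed = s))
m2 <- lapply(201:203, function(s) gen_trajectory(doms_drift,  n_frames = 3000, seed = s))

run_stability(m1, m2, attr(m1[[1]], "domains"),
              atoms = "CA", fit = "global",
              model_names = c("neutral", "alkaline"))
#>   domain n_res rmsd_1 rmsd_1_sd rmsd_2 rmsd_2_sd delta_rmsd delta_sd      f significant
#> 1 A1        60   1.17    0.0552   1.22    0.0642     0.0206   0.0260 0.261        FALSE
#> 2 B1        10   1.22    0.142    2.22    0.471      0.963    0.146  0      TRUE
#> 3 B2        65   1.21    0.0567   1.25    0.0670     0.0282   0.0458 0.294        FALSE
#> 4 B3        65   1.20    0.0541   1.24    0.0610     0.0108   0.0146 0.317        FALSE
```

The drifting domain is the only one flagged: its RMSD runs ~1 Å above the
stable model's throughout the DTW alignment (Δ<sub>RMSD</sub> ≈ 0.96 Å)
and essentially no aligned frame has model 1 ≥ model 2 (f = 0), while the
stationary domains keep f ≈ 0.26–0.32.

Kinetics, at the wild-type/variant constants:

```r
fit <- fit_michaelis_menten(gen_mm(k_cat = 19.5, K_M = 14.8, noise_sd = 0.02, seed = 1))
signif(catalytic_efficiency(fit), 2)
#> [1] 1.3
stabilization_fold(0.0026, 0.00029)
#> [1] 8.965517   # the "9-fold" stabilisation at integer rounding
```

The published domain boundaries are built in:

```r
domain_residue_count(ecpa_domains(), "B1")
#> [1] 302
```

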