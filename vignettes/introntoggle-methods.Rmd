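---
title: "Methods: active-site toggling geometry, path collective variables and splicing kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: active-site toggling geometry, path collective variables and splicing kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(introntoggle)
```

## The system and the questions

Group II introns are self-splicing ribozymes that excise themselves in two
sequential phosphotransfer steps. Between the two steps, the active site is
thought to *toggle*: the catalytic triple helix formed by the J2/3 junction
(A287-G288-C289) and the D5 catalytic triad (C358-G359-C360, with C358
Watson-Crick paired to G385) transiently disengages, the active-site
potassium ion K1 leaves, and the site rearranges before re-forming the
catalytic configuration for the second step. `introntoggle` implements the
quantitative layer needed to study this process on structures, trajectories,
biased-sampling outputs and splicing assays:

1. geometric descriptors of the active site and a two-descriptor state
   classifier;
2. ion-release event detection on descriptor time series;
3. discretized reference paths between conformers and the path collective
   variables $(S, Z)$;
4. adaptive-width metadynamics hill logs, free-energy-surface
   reconstruction, and basin/barrier analysis, with a toy Langevin sampler
   to validate the whole chain on analytic landscapes;
5. sequential two-step splicing kinetics and the Eyring-Polanyi bridge from
   rate constants to activation free energies.

Residue numbering throughout follows the *Oceanobacillus iheyensis* group II
intron convention.

## Geometric descriptors and state classification

The two state-defining descriptors are

* $d_{289\text{-}358}$: the distance between O2 of C289 and N4 of C358
  (heavy-atom hydrogen-bond proxy for the junction-triad base triple), and
* $\alpha$: the angle between the nucleobase planes of C358 and its
  Watson-Crick partner G385.

A frame is classified `TRIPLE_HELIX` iff $d \le 3\,\text{Å}$ **and**
$\alpha \le 0.35$ rad, with both boundaries inclusive; otherwise
`DISRUPTED`. Base planes are least-squares planes through the ring atoms
(nine for purines, six for pyrimidines) obtained from the smallest-variance
principal direction; the angle is folded to $[0, \pi/2]$ via
$\alpha = \arccos |n_a \cdot n_b|$ so the arbitrary sign of a plane normal
cannot matter. For mutant constructs whose substituted bases lack O2/N4,
the descriptor catalog accepts any atom pair (the natural choice is the
closest WC-face donor-acceptor pair), and records the choice used.

Supporting descriptors are plain atom-pair distances: the K1 contact
$d_{\mathrm{K1\text{-}N7^{G288}}}$, the catalytic-metal separations
$d_{\mathrm{M1\text{-}M2}}$ and $d_{\mathrm{M2\text{-}O6}}$, the
scissile-phosphate contact $d_{\mathrm{SP\text{-}M2}}$, and a coordination
count (non-hydrogen atoms within 3.5 Å). Deposited structure files do not
label which potassium is K1 or which magnesiums are M1/M2, so ion roles are
always user-supplied atom serials; `suggest_ion_roles()` proposes candidates
by proximity to O5′ of G359 (K1) and to the triad phosphates (M1/M2), but
the suggestions are advisory.

Trajectory statistics are reported as mean ± sample s.d. after discarding
the first 25 ns of each trajectory (the equilibration window used for all
summaries; configurable via `discard`).

**Ion release.** A release event is declared at the first time the ion
contact exceeds the released cutoff (default 6 Å) and stays above it for a
full dwell window (default 1 ns), provided the ion was previously bound
(below 3.5 Å). The cutoffs and dwell are package defaults, not literature
values, and are exposed in the configuration; re-binding may start a new
event. The dwell requirement makes the detector robust to single-frame
excursions at the cost of a detection latency bounded by the dwell.

## Reference paths and the collective variables S and Z

A reference path between the triple-helix and toggled endpoint
conformations is built from the heavy atoms of nucleotides 285-290:

1. the end conformation is rigid-body superposed onto the start (Kabsch,
   unweighted), then 30 interior linear Cartesian interpolants are placed
   between them;
2. the chain of frames is re-parameterized by arc length (cumulative
   adjacent RMSD) and resampled to 16 nodes at equal spacing (equal within
   5%, verified);
3. $\lambda$ is set by the standard overlap prescription
   $\lambda = 2.3/\bar{d}^2$ for mean node spacing $\bar d$, so that
   $\lambda \bar d^2 = 2.3$ identically; a mean spacing of ~0.31 Å gives
   $\lambda \approx 23.7\ \text{Å}^{-2}$.

For a conformation $x$ with per-node aligned RMSDs $d_i$,
$$S = \frac{\sum_{i=1}^{P} i\, e^{-\lambda d_i^2}}{\sum_{i=1}^{P} e^{-\lambda d_i^2}},
\qquad
Z = -\frac{1}{\lambda}\ln \sum_{i=1}^{P} e^{-\lambda d_i^2},$$
evaluated with a log-sum-exp shift so that large $\lambda d^2$ cannot
underflow. $S$ is reported on the node-index scale $1..P$ (a convention; it
is recorded in output metadata), and $Z$ carries units of Å² because the
exponent uses squared RMSD with $\lambda$ in Å⁻².

Design notes. The original path construction energy-minimized each morph
intermediate; this package deliberately substitutes pure linear Cartesian
morphing (minimization of RNA fragments requires a force field and is out
of scope), which leaves bond geometry approximate but preserves the only
property the CVs need: an ordered, equally spaced node set. Each node
distance is computed after per-node optimal superposition, and hydrogens
are excluded. At the standard overlap ($\lambda \bar d^2 = 2.3$) the
*interior* nodes satisfy $S(\text{node}_i) = i$ exactly by symmetry, but
the two *endpoint* nodes deviate by $\approx e^{-2.3} \approx 0.09$ because
they have a neighbor on one side only; the exact node-index identity holds
in the well-separated-node limit (inter-node distances ≥ 3 Gaussian length
scales), which is how the identity is exercised in the tests.

## Metadynamics: hills, reconstruction, barriers

Hill logs store Gaussians with per-coordinate widths; deposition follows
the adaptive-width protocol: widths are the sample standard deviations of
$(S, Z)$ over the trailing 1 ps window, clipped from below at 0.03 (in each
coordinate's own unit), with height 0.3 kJ/mol deposited every 1 ps.
Internally all energies are kcal/mol (0.3 kJ/mol = 0.0717 kcal/mol);
conversions happen only at the I/O boundary, and the plain-text hill-log
dialect (`time S Z sigma_S sigma_Z height`, kJ/mol, `#` comments) keeps
heights in kJ/mol for interchange with common biased-MD tooling.

The free-energy estimate is the negated bias sum,
$F(p) = -\sum_k h_k \exp(-\tfrac{(S-S_k)^2}{2\sigma_{S,k}^2}
-\tfrac{(Z-Z_k)^2}{2\sigma_{Z,k}^2})$, shifted so the grid minimum is
exactly zero. This is non-well-tempered metadynamics, so after the
landscape is filled the bias keeps rising roughly uniformly; convergence is
therefore assessed by averaging reconstructions over the final 20% of the
deposition time (`average_fes()`, 5 checkpoints by default).

**Barriers.** A single $\Delta G^{\ddagger}$ per landscape is reported via
the minimax path: the smallest level $m$ such that the two basins connect
through grid cells (8-connectivity) with $F \le m$; then
$\Delta G^{\ddagger} = m - F(\text{basin A})$. This is computed by a
union-find sweep over cells in ascending energy order (the standard
Kruskal-style construction) and verified in the tests against an exhaustive
flood-fill oracle on coarse grids. Basins are minima inside caller-hinted
regions; a hinted region without an interior local minimum is an error
rather than a silent boundary artifact.

**What is, and is not, validated.** The published full-RNA landscapes
(barriers of ~25 kcal/mol for the non-protonated and ~20 kcal/mol for the
protonated transition, with the toggled state ~+5 kcal/mol above the
deepest minimum) require hundreds of nanoseconds of biased all-atom MD and
are not desk-reproducible. What this package validates is the identical
analysis machinery on analytic landscapes with known answers: an
overdamped-Langevin toy sampler (friction 1, Euler-Maruyama, seeded and
bit-reproducible) deposits adaptive-width hills on a double well with a
3 kcal/mol barrier, and the reconstruction recovers that barrier within
20%; a "three-state" preset mirrors the published landscape topology with
a +5 kcal/mol final-basin offset by construction. During sampling the bias
force is interpolated from an internal grid for speed, but the exact hill
log is kept and all reconstructions use the exact Gaussian sum; the two
are cross-checked in the tests.

## Splicing kinetics and the Eyring-Polanyi bridge

Band-fraction time courses follow sequential first-order kinetics
(precursor $\to$ intermediate $\to$ excised intron):
$$f_P = e^{-k_1 t},\quad
f_I = \frac{k_1}{k_2 - k_1}\left(e^{-k_1 t} - e^{-k_2 t}\right),\quad
f_E = 1 - f_P - f_I,$$
with the degenerate case $k_1 = k_2$ handled by the limit
$f_I = k_1 t e^{-k_1 t}$ (an `expm1` form keeps the crossover continuous
to ~1e-9 relative). Fits are simultaneous weighted least squares over all
three series by Levenberg-Marquardt on log-rates with multi-start
(log-spaced starts anchored to the data time span; best residual wins).
Weights are inverse variance when per-point s.e.m. columns are present —
floored at the per-species median, because an s.e.m. estimated from three
replicates is a very noisy scale estimate and raw inverse-variance weights
would let near-zero estimates dominate the fit. Standard errors come from
the covariance at the optimum or, optionally, from a case bootstrap over
time points, which additionally captures the cross-species error coupling
that per-time renormalization introduces (the three fractions at one time
sum to one, so their errors are negatively correlated) and the
heteroscedasticity near the 0/1 boundaries.

Activation free energies use the Eyring-Polanyi equation with transmission
coefficient 1:
$$k = \frac{k_B T}{h}\, e^{-\Delta G^{\ddagger}/RT}.$$
The default temperature is **310 K**. The assays were run at 37 °C
(310.15 K), but the reference barrier values (0.031 min⁻¹ → 22.8 kcal/mol;
0.026 min⁻¹ → 22.9 kcal/mol) are jointly reproducible only with the rounded
310 K: at 310.15 K the second conversion gives 22.95 kcal/mol, outside the
printed value by more than its printed precision. The 0.15 K difference is
0.01 kcal/mol on the barrier — irrelevant for any scientific conclusion —
and the temperature is an explicit argument everywhere.

## The synthetic-data generators

The generators define the conditions under which the analysis layer is
tested; they are first-class, seeded, deterministic code.

**Active-site fragments** (`gen_active_site_frame`) place idealized planar
base templates so that the three core descriptors hit requested targets
exactly (then optionally add Gaussian coordinate noise). They contain the
residues the descriptor layer needs (G288, C289, C358, G385, one K⁺) and
nothing else — they are geometric fixtures, not physical RNA models.

**Two-state toggling series** (`gen_toggling_series`) simulate a
continuous-time two-state Markov chain (exact Gillespie path, then frame
sampling) with Gaussian per-state emissions for
$(d_{289\text{-}358}, \alpha, d_{\mathrm{K1}})$. Emission *means* mirror
the reference values: triple helix at (2.7 Å, 0.17 rad, 2.98 Å) versus
toggled at (4.88 Å, 0.63 rad, ~9 Å). Emission *widths* are a design
choice: the literature spreads (e.g. ±1.05 Å on the toggled distance) are
trajectory-wide numbers that include slow inter-state drift, and used as
per-state widths they would put a substantial fraction of each state's
emissions on the wrong side of the classification thresholds — no
threshold classifier could then agree with the truth at the documented
level. Per-state widths are therefore set once so that each state sits at
least four standard deviations clear of its thresholds (d: 0.07/0.45 Å;
α: 0.04/0.07 rad; K1 bound keeps the literature 0.27 Å, released uses
1.0 Å), the regime the classifier is specified for. K1 release is coupled
one-way to the first toggling event by default (release follows the first
triple-helix disruption and is not reversed), mirroring the observed
ordering; a reversible mode is available by flag.

**Band time courses** (`gen_band_timecourse`) add truncated (censored at
[0, 1]) Gaussian noise per replicate to the closed-form fractions,
renormalize each time point to sum to one, and average replicates,
populating s.e.m. columns. One consequence, measured and documented here
because it bounds what coverage tests can show: censoring at the
boundaries (the t = 0 precursor point and the late near-zero fractions)
biases the *data*, and hence any least-squares rate estimate, by roughly
0.17 standard errors under the default conditions (sd 0.02, 12 points,
3 replicates). Intervals that are perfectly calibrated for sampling noise
therefore cover the true pair of rates jointly in only ~87% of runs, not
the nominal ~90%; per-rate coverage is ~93%. The case-bootstrap intervals
come closest to this ceiling. Point estimates remain unbiased well within
5% of the true rates.

**Toy landscapes** (`gen_toy_landscape`): `"double-well"` is
$V = b(s^2-1)^2 + \tfrac{1}{2}k_z z^2$ with saddle exactly $b$;
`"three-state"` is three Gaussian wells along $s$ in a weak confining bowl,
with the final well offset exactly `offset` above the first (the bowl term
is absorbed into the well depths so basin values are exact to ~1e-3).
Both provide analytic gradients, verified against finite differences.

## Structure and trajectory I/O

PDB parsing and writing delegate to `bio3d` behind the package's own atom
table; HETATM ions (K, NA, MG, CA) are kept as ordinary atoms so selections
can reach them. Alternate locations keep the highest-occupancy conformer
(ties prefer altloc A). Multi-model files serve as both multi-state
containers and trajectories; a plain frame format (`t=<ns>` header plus
`name x y z` lines) covers trajectory exchange when engine-native formats
are unavailable. Coordinates are Å and times ns throughout; there is no
unit autodetection. Superposition is unweighted Kabsch via SVD (weights
optional), with a rank warning and best-effort transform for degenerate
(collinear) inputs.

Selections are conjunctions of simple clauses (`resnum 285-290`,
`name N7`, `elem K`, `chain A`, `heavy`, each negatable with `not`) —
deliberately small, order-preserving, and sufficient for every descriptor
in the catalog.

## Numerical and testing choices

* Log-sum-exp for the path CVs; exact Gaussian sums for FES reconstruction.
* Union-find minimax barriers; exhaustive flood-fill oracle in tests
  (grids ≤ 20×20).
* Kabsch superposition cross-checked against an independent numerical
  minimization over Euler angles and against `bio3d::fit.xyz`.
* The sequential model is cross-checked against `deSolve::lsoda` at 1e-8.
* Every generator is seed-deterministic; every stochastic test fixes seeds.
* Problem sizes in the default test run are chosen for a laptop-scale run:
  the toy metadynamics validation uses 2×10⁵ steps (4000 hills), the
  coverage and classifier studies use 40-100 seeded replicates of
  moderate-size series (2000-4000 frames), and the equipartition check
  uses 4×10⁵ unbiased steps.

## Limitations

* No mmCIF or binary trajectory formats; no hydrogen placement; no
  symmetry records.
* Path intermediates are linear Cartesian morphs, not minimized structures.
* Non-well-tempered metadynamics only; no reweighting estimators or
  multiple walkers; the toy sampler is a validation device, not an MD
  engine.
* The published full-RNA free-energy barriers (~20 vs ~25 kcal/mol) and
  the +5 kcal/mol toggled offset are not recomputed — the machinery that
  would analyze such runs is validated on analytic landscapes instead.
* Crystal-structure validation values are shipped as a reference table
  (`crystal_reference_values()`); the deposited coordinate files
  themselves must be downloaded by the user (PDB ids 4FAQ, 4FAR, 6T3K,
  6T3R) and placed under `inst/extdata/reference_structures/` for the
  corresponding checks to run.
* Datasets with identically zero intermediate and product (no forward
  flux) are rejected by the fitter rather than fitted.
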