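---
title: "Methods: SAXS-oriented ensemble refinement and the surrounding analytics"
author: "saxser"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SAXS-oriented ensemble refinement and the surrounding analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Tandem RNA-binding domains joined by flexible linkers — such as the paired
K-homology (KH) domains of MEX3-family proteins — do not adopt a single
solution conformation. Small-angle X-ray scattering (SAXS) reports on the
whole conformational ensemble at once: the measured intensity is a
population-weighted average over every species in the beam. Recovering an
ensemble consistent with a SAXS curve therefore couples two tasks: *sampling*
plausible conformers, and *selecting* a sub-ensemble whose averaged profile
matches the data. `saxser` implements this loop, with the calorimetric (ITC),
NMR chemical-shift-perturbation (CSP) and RNA-motif analytics that surround
such a study, and a synthetic-data module that generates every input the
pipeline needs so that all stages are testable end to end without external
data.

## Scattering model

Profiles are back-calculated with the Debye formula over bead models with
constant per-bead form factors $f_i$ (default 1, one bead per residue):

$$I(q) = \sum_i \sum_j f_i f_j \,\frac{\sin(q d_{ij})}{q d_{ij}},
  \qquad I(0) = \Big(\sum_i f_i\Big)^2 .$$

No hydration shell or excluded-volume correction is applied. This is a
deliberate reduction: the synthetic "experimental" curves are generated by
the same physics, so the refinement machinery is exercised under a
self-consistent forward model. The cost of the double sum
($O(N^2 K)$ for $N$ beads and $K$ grid points) is paid once per conformer in
a small compiled kernel and cached per pool.

An ensemble's profile is the uniform average
$I(q) = \frac{1}{N}\sum_{n=1}^{N} I_n(q)$ over its $N$ members, and agreement
with an experimental curve of $K$ points is scored as

$$\chi^2 = \frac{1}{K-1}\sum_{i=1}^{K}
  \left[\frac{\mu I(q_i) - I_{\mathrm{exp}}(q_i)}{\sigma(q_i)}\right]^2,$$

with the scale factor $\mu$ set to its analytic least-squares optimum
$\mu = \sum_k I_k I_{\mathrm{exp},k}/\sigma_k^2 \big/ \sum_k I_k^2/\sigma_k^2$
unless fixed by the caller. Internally, residuals are stored with the
$(\mu I_{\mathrm{calc}} - I_{\mathrm{exp}})/\sigma$ sign of the statistic's
numerator; `residual_plot_data()` exposes the conventional
experiment-minus-model sign for plots, along with a lag-1 autocorrelation of
the residuals as a flatness summary. $\chi^2$ is invariant to either choice.

## Ensemble selection

`select_ensemble_exhaustive()` enumerates all distinct-index subsets of a
given size and is the exact reference implementation; it is used
automatically whenever the subset count is at most $10^4$. Larger pools use
a seeded genetic algorithm (`select_ensemble_ga()`): chromosomes are
distinct-index subsets, fitness is $-\chi^2$ with $\mu$ optimized
analytically inside the evaluation, parents are chosen by binary tournament,
crossover samples the child from the union of its parents (repaired to
distinctness), mutation replaces genes with unused indices, and elitism
makes the best fitness non-decreasing across generations. Defaults
(population 100, generations 200, crossover 0.5, mutation 0.1 per gene,
elite 10) are sized so the GA matches the exhaustive optimum on 12-member
pools in nearly every seed. Ensembles are *sets* — members are not repeated;
published ensemble-optimization software permits repeats as implicit
weighting, but uniform weights over distinct representative conformations
are used here. Ties in $\chi^2$ break toward the lexicographically smallest
sorted index list, making every selection deterministic.

## The refinement loop

`run_refinement()` iterates sampling and selection:

1. a preliminary burst from the initial structure seeds the conformer pool
   (run proportionally longer than the per-cycle bursts so the pool starts
   at least $2 N_{es}$ deep);
2. each cycle selects the best-fitting $N_{es}$-member ensemble from the
   pool;
3. one independent short burst is restarted from each selected conformer —
   many short simulations sample better than one long one — and the
   snapshots join the pool;
4. repeat for the configured number of cycles.

The pool **accumulates** by default: selection at cycle $c$ sees every
structure generated so far. Because the feasible set only grows, the best
$\chi^2$ is monotone non-increasing — and to keep this exact under the
stochastic GA, the previous cycle's winning ensemble is injected into the GA
population as a warm start. A `replace` mode (selection sees only the latest
bursts) is provided for fidelity experiments; it forfeits the monotonicity
guarantee. Seeds for every burst and every GA call are derived from the root
seed with a counter scheme, so a run is bit-reproducible from its
configuration.

The per-cycle records (best $\chi^2$, scale, member indices, member Rg
values) feed the standard diagnostics: $\chi^2$-versus-cycle convergence
traces, the pooled Rg histogram of the trailing cycles
(`rg_distribution()`, default last 10 cycles, 0.5 Å bins), and smoothed
peak-finding on that histogram (`find_rg_peaks()`; the smoothing window
trades resolution for noise rejection — sub-bin-scale doublets are resolved
only with the window at 1 bin).

## Accelerated-MD boost mathematics

The sampler acceleration used in this class of refinement is the dual-boost
accelerated-MD bias. Below a threshold $E$ the potential is raised by

$$\Delta V = \frac{(E_p - V)^2}{\alpha_p + E_p - V}
           + \frac{(E_d - V_d)^2}{\alpha_d + E_d - V_d},$$

one term for the total potential and one for the dihedral (torsion)
potential. The two terms are gated independently (each applies only when its
energy is below its threshold): with a single shared gate the dihedral
denominator could turn negative for states far above the dihedral threshold.
The bias is non-negative, vanishes continuously at the thresholds, and
compresses slopes by $(\alpha/(\alpha + E - V))^2 \in (0, 1]$ below them —
the landscape flattens but minima never reorder (`flattening_check()`
verifies this numerically on a grid).

`estimate_amd_parameters()` implements the standard dual-boost recipe from a
conventional-MD energy trace: $E_p = \langle V\rangle + 0.16\,n_{\mathrm{atoms}}$,
$\alpha_p = 0.16\,n_{\mathrm{atoms}}$,
$E_d = \langle V_d\rangle + 4\,n_{\mathrm{res}}$,
$\alpha_d = 4\,n_{\mathrm{res}}/5$ (kcal/mol). For a 175-residue construct
the recipe gives $\alpha_d = 140$ kcal/mol. Published parameter sets can
also be supplied verbatim through `amd_parameters()`. No canonical
reweighting of boosted ensembles is implemented; the refinement uses the
boost only to accelerate exploration, with the SAXS selection — not the
sampler's equilibrium distribution — determining the reported ensemble.

## The synthetic-data module

`two_domain_spec()` describes a coarse two-domain architecture: 89 + 75
beads (one per residue, packed on a 3.8 Å lattice into compact globules)
joined by an 11-bead linker, spanning residues 56–230 — the shape of a
tandem-KH construct with its inter-domain linker. Linker geometry is a
vector of per-bond bend/azimuth angles expressed in a frame transported
along the chain, so conformers depend smoothly on the angles; all bends zero
gives the fully extended, maximally separated arrangement.

The two regimes set the study conditions:

* **apo** — bends drawn uniformly on $[0, 0.85]$ rad with uniform azimuths:
  an extended, heterogeneous ensemble (mean Rg ≈ 26 Å, SD ≈ 3.6 Å for the
  default spec);
* **bound** — a tight Gaussian (SD 0.06/0.12 rad) about a fixed compact
  reference geometry with Rg = 21.8 Å, found once by constrained
  optimization of the generator's own construction and frozen as a package
  constant: a compact, homogeneous ensemble (mean Rg ≈ 21.7 Å, SD ≈ 1.3 Å).

This reproduces the statistical structure the SAXS analysis assumes — a
ligand-induced compaction of roughly 4–5 Å in mean Rg with a simultaneous
narrowing of the distribution — in the numeric range where the real
diagnostics operate, without claiming structural fidelity.

`simulate_saxs_experiment()` adds independent Gaussian noise with
$\sigma(q) = \max(0.02\,I(q), \mathrm{floor})$ and stores the exact
generating $\sigma$, so the generating ensemble itself scores
$\chi^2 \approx 1$ — the calibration that makes "converges to about 1"
meaningful on synthetic data. Real beamline errors are neither independent
nor exactly known; passing these tests demonstrates the machinery, not
detector physics.

`toy_sampler()` is a Metropolis walk over linker angles with soft-sphere
cross-domain repulsion plus a weak harmonic bend term standing in for the
torsion potential; it honours the refinement loop's sampler contract
(deterministic under seed, point-count preserving) and can run with the
dual-boost bias applied to its energy, which measurably broadens the sampled
Rg distribution. It is a stand-in for a molecular-dynamics engine, not a
physical model: moves are single-bond, the domains are rigid, and the energy
has no attractive term.

## ITC model

`simulate_titration()` and `fit_single_site()` share one exact forward
model. After each injection the cell contents are diluted by
$(1 - dV/V_0)$ (the displaced volume leaves the active cell), titrant is
added at the syringe concentration, the bound-titrant concentration is the
physical root of the single-site quadratic, and the measured heat is the
increment of $Q = [B] V_0 \Delta H$ corrected for the displaced volume,
$\Delta Q_i = Q_i - Q_{i-1} + \frac{dV_i}{V_0}\frac{Q_i + Q_{i-1}}{2}$.
Dilution tracking matters at these volumes: the default schedule (one 1 µl
priming injection, then 18 × 2 µl) injects 37 µl into a 200 µl cell.
Fitting is Levenberg–Marquardt on $(N, \log_{10} K_d, \Delta H)$,
multi-started over a $K_d$ grid spanning $10^{-9}$–$10^{-3}$ M, with the
priming injection down-weighted (weight 0.01) in keeping with the
discard-first convention. A saturated-from-start titration (no curvature)
raises an identifiability error rather than returning an arbitrary $K_d$.

`simulate_two_site_titration()` provides an independent forward route for a
cell species carrying two identical, independent sites, solving the
free-ligand conservation equation directly. Because such a system is
algebraically a single-site system of stoichiometry 2, analyzing its data
with the single-site model returns exactly $N = 2$ at the per-site $K_d$ —
the mechanism by which a 2:1 protein-per-RNA stoichiometry appears in a
single-site fit.

On estimator precision: with Gaussian noise at 2% of the maximum injection
heat, the Cramér–Rao bound for this 19-injection schedule puts the relative
standard error of $K_d$ near 12% at $c = 50$ (and near 10% even at
$c = 5$–10). The package's calibration test therefore checks that the
fitted-$K_d$ spread *matches* this bound (an efficient, unbiased estimator
with nominal 2σ coverage) rather than asserting a precision the experiment
cannot carry.

## CSP and assignment arithmetic

Combined amide perturbations use the standard $^1$H/$^{15}$N weighting
$\mathrm{CSP} = \sqrt{\Delta\delta_H^2 + (\Delta\delta_N/5)^2}$ (the
nitrogen weight is configurable). Residues present in the free state but
absent after binding are reported separately as candidate
exchange-broadened peaks. The default selection rule flags residues with
CSP above mean + 1 SD; this is a field convention, not a derived threshold,
and both the multiplier and an absolute cutoff are exposed. Assignment
completeness divides assigned amides by observable residues — prolines,
which lack a backbone amide proton, are excluded from the denominator — so
79 of 89 residues with 5 prolines gives 94.0%, and 62 of 75 with 5 prolines
gives 88.6%.

## Motif scanning

The degenerate elements are written as a head, one variable-length spacer
`N<a>-<b>`, and a tail, with parenthesized alternatives, e.g.
`(A/G/U)(G/U)AGN0-8U(U/A/C)UA`. `scan_sequence()` enumerates **every**
(start, gap-length) combination on the given strand — overlapping registers
and multiple gap lengths at one start are all reported, because that
multiplicity is precisely what creates ambiguous binding modes in longer
substrate fragments. Coordinates are 1-based inclusive in reports (0-based
half-open internally); no reverse-complement scanning is performed since the
substrates are single-stranded mRNA. Scanning is direction-dependent by
construction: reversing a sequence does not conserve its matches, mirroring
the orientation dependence of tandem-domain recognition.

## Numerical choices and degenerate inputs

* Guinier fits restrict to $q R_g \le 1.3$ (community standard; iterated
  twice to self-consistency) and flag non-globular curves (non-negative
  slope) instead of returning an imaginary $R_g$.
* PDDF uses 100 bins over $[0, D_{max}]$ by default; densities are
  normalized to unit trapezoid integral and vanish beyond $D_{max}$.
* The NSD superposition searches principal-axes alignments, their four
  proper flips and both enantiomers, then polishes with Nelder–Mead over
  rotation and translation; the value is symmetrized over argument order so
  `align_and_nsd(a, b)` equals `align_and_nsd(b, a)` exactly. Collinear or
  sub-2-point models raise geometry errors.
* Coordinates are Å throughout and $q$ is Å⁻¹; an explicit unit flag on the
  SAXS reader converts nm⁻¹ grids rather than guessing.
* Steric rejection in the conformer generator resamples rather than
  returning clashed geometry; an excessive rejection rate errors out.

## Study conditions and problem sizes

Where the underlying study leaves a quantity unstated, the package fixes one
value and uses it consistently: ensemble size $N_{es} = 10$ and 15 cycles
for the convergence analyses (the convergence claim concerns cycles 5
onward, and the Rg analyses pool trailing cycles); a 150-point $q$ grid on
0.01–0.30 Å⁻¹; 2% relative noise; 5-member ground-truth ensembles; bursts of
30 Metropolis sweeps yielding 5 snapshots. The ITC acceptance setups fix
plausible concentrations (20 µM cell / 300 µM syringe for the round trip;
10 µM / 400 µM for the two-site read-out) since the main text does not print
them. These sizes keep a full three-seed convergence analysis to a few
minutes on one CPU while leaving every qualitative behaviour — fast early
decay of $\chi^2$, convergence near 1, compaction recovery — intact.

## Known limitations

The scattering model has no hydration layer, excluded volume, or atomic
form factors, so absolute profiles are not comparable to beamline data; the
toy sampler explores linker geometry only (rigid domains); aMD ensembles are
used unreweighted; the single-site ITC model does not cover sequential or
cooperative multi-site binding; and P(r) is computed from models, not
estimated from experimental curves by indirect Fourier transform. These are
scope boundaries, not approximations hidden in results: every number the
package reports is produced under the reduced models described here.
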