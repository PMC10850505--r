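# saxser

Ensemble modelling of flexible two-domain RNA-binding proteins against
small-angle X-ray scattering (SAXS) data, with the binding analytics that
surround such a study.

Proteins built from tandem domains on a flexible linker — the paired
K-homology (KH) domains of MEX3-family RNA-binding proteins are the
motivating case — exist in solution as conformational ensembles. A SAXS
curve averages over that ensemble, so a single best-fit structure is the
wrong deliverable: the task is to find a *set* of conformers whose averaged
profile matches the data. `saxser` implements this as an iterative
sampling/selection loop (SAXS-oriented ensemble refinement) and packages the
surrounding analyses: scattering diagnostics, isothermal titration
calorimetry (ITC) simulation and fitting, NMR chemical-shift-perturbation
mapping, and degenerate RNA-motif scanning. A synthetic-data module
generates every input the pipeline needs, so the whole analysis runs and is
tested end to end without external data.

## The model in brief

* **Profiles** — Debye formula over bead models,
  `I(q) = Σᵢ Σⱼ fᵢ fⱼ sin(q dᵢⱼ)/(q dᵢⱼ)`, one bead per residue.
* **Ensemble score** — the uniform average `I(q) = (1/N) Σₙ Iₙ(q)` is fitted
  to the experimental curve by
  `χ² = (1/(K−1)) Σᵢ [(μ I(qᵢ) − I_exp(qᵢ))/σ(qᵢ)]²`, with the scale factor
  μ at its analytic least-squares optimum.
* **Selection** — exhaustive subset search when cheap, otherwise a seeded
  genetic algorithm over distinct-index subsets (fitness −χ², elitism,
  deterministic tie-breaks).
* **Refinement loop** — a preliminary sampler burst seeds a conformer pool;
  each cycle selects the best N_es-member ensemble and restarts one short
  burst from every selected conformer; with the default accumulating pool
  the best χ² is monotone non-increasing and typically settles near 1 on
  noise-calibrated data after about five cycles.
* **Sampler acceleration** — the dual-boost accelerated-MD bias
  ΔV = (E_p−V)²/(α_p+E_p−V) + (E_d−V_d)²/(α_d+E_d−V_d) is implemented with
  per-term gating, together with the standard parameter recipe from a
  conventional-MD energy trace.
* **ITC** — exact single-site forward model (binding quadratic, dilution
  tracking, displaced-volume correction) shared between the simulator and
  the Levenberg–Marquardt fitter; a two-identical-site species analyzed with
  the single-site model reads out N = 2 at the per-site Kd.
* **CSP** — combined amide shifts `√(ΔδH² + (ΔδN/5)²)`, mean + k·SD
  selection, exchange-broadened peaks reported; assignment completeness
  excludes prolines from the denominator.
* **Motifs** — degenerate gapped elements such as
  `(A/G/U)(G/U)AGN0-8U(U/A/C)UA`, scanned exhaustively over every start and
  gap length on the given strand.

The methods vignette
(`vignettes/ensemble-refinement-methods.Rmd`) documents the model choices,
calibrations, tolerances and limitations in full.

## Worked example

```r
library(saxser)

# --- ITC: round trip at the weakened, switched-orientation RNA Kd ---
prot <- itc_protocol(cell_volume_ul = 200, cell_conc = 20e-6,
                     syringe_conc = 300e-6)
expt <- simulate_titration(n = 1, kd = 1.11e-6, dh = -10, protocol = prot)
fit_single_site(expt)
#> <binding_fit: N = 1.000, Kd = 1.11e-06 M (1.110 uM), dH = -10.000 kcal/mol>

# --- motif scanning: the 12-nt substrate has exactly one register ---
els <- mex3_recognition_elements()
scan_sequence(rna_sequence("CUGAGCUGUAAC"), els$hs_element)
#>   start gap_len end matched_text
#> 1     2       2  11   UGAGCUGUAA

# --- SAXS refinement against a synthetic compact-state curve ---
spec_bound <- two_domain_spec(mode = "bound")   # 89 + 11 + 75 beads
spec_apo   <- two_domain_spec(mode = "apo")
truth <- make_pool(spec_bound, 5, seed = 101)$members
curve <- simulate_saxs_experiment(truth, noise = noise_model(seed = 202))
init  <- make_two_domain_conformer(spec_apo, linker_state_extended(spec_apo))
state <- run_refinement(init, curve, toy_sampler(spec_apo),
                        refinement_config(n_es = 10, n_cycles = 15, seed = 301))
round(state$chi2_by_cycle, 3)
#>  [1] 1.956 0.985 0.941 0.937 0.937 0.930 0.928 0.927 0.927 0.927 0.927 0.926
#> [13] 0.926 0.925 0.925
mean(vapply(truth, rg_from_coords, numeric(1)))   # ground-truth mean Rg
#> [1] 21.42009
mean(state$rg_samples_by_cycle[[15]])             # recovered from refinement
#> [1] 21.33719
```

Starting from a fully extended conformer, the loop drops below χ² ≈ 1 within
two cycles (the noise model is calibrated so the generating ensemble itself
scores χ² ≈ 1 — fitting much below 1 is not possible without overfitting the
10-member ensemble) and recovers the compact truth's mean radius of gyration
to better than half a percent.

The `analysis/` directory holds the same workflow as numbered narrative
scripts (`01_simulate_inputs.R` … `05_motif_scan.R`), each writing its
tables under `results/`.

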