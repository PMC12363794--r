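# plastichrom

Tools for the computational stages that link EZH2-driven chromatin-state
dynamics to cell-state programs and drug-combination synergy in
lineage-plastic prostate cancer models. The package is aimed at
epigenomics and regulatory-genomics analysts working with paired
H3K4me3/H3K27me3 ChIP-seq, single-cell expression, dose–response plates
and RIME interaction proteomics, and at anyone who wants those stages as
tested, reusable functions rather than one-off notebook code.

Four analysis engines, plus a synthetic-data module that generates every
input with planted ground truth:

* **Chromatin states** (`assign_mark_presence`, `call_states`,
  `transition_matrix`, `integrate_with_de`) — classify each promoter per
  condition into one of four states from two-mark peak presence in a
  TSS ± w window,

  | H3K4me3 | H3K27me3 | state |
  |---|---|---|
  | + | − | Active |
  | − | + | Repressed |
  | + | + | Bivalent |
  | − | − | Unmarked |

  tabulate condition-to-condition transitions, and rank transition
  classes by hypergeometric enrichment of differentially expressed genes.
* **Cell programs** (`normalize_log`, `score_signature`,
  `assign_subtype`, `mrtf_modules`, `pseudotime_profile`, `de_rank`,
  `gsea_preranked`) — per-cell gene-program scores as means of per-gene
  z-scores, epithelial subtype and master-regulator TF module assignment
  (module 0 = NEPC, 1 = transition, 2 = adenocarcinoma), smoothing-spline
  trajectories along pseudotime, Wilcoxon differential rankings, and
  pre-ranked GSEA with gene-label permutations: ES is the weighted
  running-sum deviation, NES = ES / mean |permutation ES| of matching
  sign, FDR q from the standard NES-ratio estimator.
* **Synergy** (`normalize_plate`, `bliss_expected`, `synergy_surface`) —
  control-well plate normalization and Bliss-independence landscapes:
  expected combination inhibition `E_a + E_b − E_a·E_b`, per-well
  δ = 100 × (observed − expected) in percentage points, and a landscape
  summary equal to the mean δ over combination wells.
* **RIME filtering** (`nominate_venn`, `nominate_fdr`,
  `compare_conditions`) — interactor nomination either by the ≥ 5
  spectral counts-in-every-replicate rule with IgG exclusion, or by an
  FDR-controlled (q ≤ 0.1, BH) one-sided Poisson rate-ratio test with a
  ≥ 2-of-4-samples detection requirement.

`sim_config()` + `simulate_all()` generate a full synthetic study —
promoters with planted states and a planted transition kernel,
negative-binomial single-cell counts with planted programs and an
EZH2i response planted in bivalent promoters, Bliss surfaces with a
planted interaction, Poisson spectral counts with planted enrichment —
so every claim the package makes is testable without external data.

## Worked example

The `analysis/` directory holds the numbered study drivers
(`01_simulate.R` … `05_rime.R`); running them in order writes all tables
under `results/`. Highlights, as printed by the scripts on the default
configuration (`sim_config(seed = 1)`; 10,000 promoters, 2,000 cells):

```
Transition matrix (rows = condition 1, columns = condition 2):
          Active Repressed Bivalent Unmarked
Active      3829        87      421      123
Repressed     69      1157      149       80
Bivalent     141       162     1149       70
Unmarked     120       113      250     2080

Net bivalency change between genotypes: +447 promoters
```

The planted kernel leaks Active and Unmarked promoters into the Bivalent
state in condition 2, and the called transitions recover that net
bivalency gain. Because the simulated EZH2i response is planted in
bivalent-condition-2 promoters, integrating the transitions with the
EZH2i-vs-vehicle differential ranking puts the Bivalent class first by a
wide margin:

```
        level     class n_genes n_de             p         p_adj
1 cond2_state  Bivalent    1969  170 3.400131e-121 1.360052e-120
2 cond2_state    Active    4159    1  1.000000e+00  1.000000e+00
```

The synergy stage recovers the +10-point planted interaction from three
noisy replicate plates:

```
Bliss synergy summary: 11.37 points over 16 combination wells
  replicate summaries: 10.24, 12.27, 11.60 (SD 1.04)
```

and the RIME stage finds exactly the planted interactors:

```
fdr mode: 20 hits (planted 20; sensitivity 1.00, precision 1.00)
```

A single-command end-to-end run of the same pipeline is
`run_all(system.file("extdata", "demo_config.yaml", package = "plastichrom"), "out")`,
which writes per-stage outputs plus a `report.json` carrying parameters,
headline tables and an MD5 manifest of every file.

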