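# cisrange

How far do transcription factors act? `cisrange` is an R package for
quantifying the genomic distance over which a TF regulates its target
genes, from TF ChIP-seq peaks, gene annotation, TAD intervals, and
either perturbation differential-expression tables or expression
cohorts. It is aimed at regulatory genomicists who want a tested,
scriptable reimplementation of the regulatory-potential framework and
its TAD-level companion analyses, exercisable end-to-end on synthetic
data with planted ground truth.

## The model

The regulatory potential of TF *i* on gene *j* sums the TF's binding
sites in the gene's TAD, weighted by an exponentially decaying function
of the peak-to-TSS distance *x*:

    R_ij(Δ) = Σ_k 2^(−x_ijk / Δ)

Δ, the *decay distance*, is the distance at which a site's modeled
effect is halved (a power-law kernel Σ max(x,1)^λ is available for
comparison with Hi-C contact decay). The TF-specific Δ\* is the grid
value (33 geometric points, 100 bp – 4,000 kb) that best matches an
independent readout of regulation:

- **perturbation route** — Δ\* maximizes the Kolmogorov–Smirnov
  separation between DE-gene RP scores and all other genes';
- **expression-cohort route** — per-gene TF–gene expression
  correlations γ̂ (the MLE of the regulatory effect under a
  standardized linear model) are compared against R(Δ) columns; Δ\*
  maximizes |Pearson ρ| or the distance correlation.

TFs are classified short-range (Δ\* ≤ 3 kb) or long-range (> 3 kb).
Around this core the package provides TAD chromatin-state calls from
H3K27ac (A-type/B-type), TF–TAD relative-occupancy z-scores and
target-TAD calling, TAD-type-restricted Δ estimates, a
pioneer-factor-like logistic test, eQTL–TSS distance contrasts, Hi-C
contact-decay power-law fits, and cosine-similarity GWAS TF
prioritization with permutation significance.

## A worked example

```r
library(cisrange)

lay  <- make_genome(seed = 1)                       # 50 TADs, 600 genes
ps   <- make_peaks(lay, delta_true = 1e4, seed = 2) # planted Δ = 10 kb
tfg  <- lay$genes$gene_id[1]
expr <- make_expression(lay, ps, 1e4, tfg, seed = 3)
prof <- correlation_profile(normalize_expression(expr), tfg)
curve <- delta_grid_search(ps, lay, prof, default_grid(33), "linear")
curve
#> decay_curve (expr-linear): 33 grid points, delta* = 10310 bp, max stat = 0.3787
classify_range(curve$delta_star)
#> [1] "long-range"
```

The inferred decay distance (10,313 bp, the grid point nearest the
planted 10 kb) says that for this TF, binding sites ~10 kb from a TSS
still carry half-weight — a long-range regulator. The concordance
maximum 0.38 is the Pearson correlation between the per-gene expression
effects and the RP scores at Δ\*, matching the generator's calibrated
signal strength.

The full pipeline (simulation → RP → Δ inference → TAD classification →
occupancy → eQTL/Hi-C/GWAS) runs from a config:

```r
run_pipeline(sim_config(seed = 1), "outdir")
```

or from the shell via the thin wrapper
`Rscript inst/scripts/cisrange run --seed 1 --out outdir`.

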