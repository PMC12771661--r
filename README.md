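# raopart

Diversity partitioning for managed grassland communities under an
expansive-species cover gradient.

When mowing stops, expansive clonal grasses (e.g. *Brachypodium*-type
tussock grasses) spread and filter subordinate species out of the sward.
`raopart` implements the analysis chain needed to quantify that biotic
filter and how management modulates it, from a plot x species cover table,
plot metadata (management type, expansive-species cover) and a rooted
phylogeny:

1. **Alpha diversity** per plot as Rao's quadratic entropy
   `Q = Σ_ij d_ij p_i p_j`, in a *taxonomic* facet (`d_ij = 1` for `i ≠ j`,
   so `Q = 1 − Σ p_i²`, Gini–Simpson) and a *phylogenetic* facet (`d_ij` =
   cophenetic tree distance, rescaled once to `[0, 1]`).
2. **Pairwise beta diversity** by additive partitioning `γ = mean α + β`
   per plot pair, with the Jost equivalent-number correction
   `1/(1−α)`, `1/(1−γ)`; the normalized `β_add / γ_eq ∈ [0, 1)` is the
   default plot-pairwise dissimilarity.
3. **Group dispersion**: principal-coordinate embedding of the beta matrix
   (negative-eigenvalue block retained) and each plot's distance to its
   management group's centroid (or spatial median) — a plot-level beta
   response.
4. **Indicator species analysis**: IndVal `= sqrt(A·B)` with a 999-run
   permutation test and the conservative `A ≥ 0.6`, `B ≥ 0.25`, `p < 0.05`
   filter.
5. **Inference**: OLS of each diversity response on
   `cover * management` (reference: abandoned), hierarchical partitioning
   of `R²` into independent/joint predictor contributions, and unpaired
   t-tests of environmental covariates (aspect folded to a 0–180
   north–south scale).
6. **Synthetic data**: a generator emulating 31 mown + 30 abandoned
   0.5 × 0.5 m quadrats from 60/50-species pools, with subordinate
   richness declining more steeply with expansive cover under mowing —
   ground truth for end-to-end parameter-recovery experiments.

See `vignette("diversity-partitioning")` for the methods account and every
defaulted decision.

## Worked example

The `analysis/` directory chains the stages as numbered scripts
(`01_simulate.R` … `06_recovery.R`), writing tables under `results/`.
Running them in order on the packaged synthetic design prints, among other
things:

```
$ Rscript analysis/01_simulate.R
study design: 61 plots x 81 species; 31 mown, 30 abandoned
expansive cover range: 5.2-69.6%

$ Rscript analysis/02_diversity.R
taxonomic    alpha: mown 0.724, abandoned 0.698; mean pairwise beta 0.286
phylogenetic alpha: mown 0.615, abandoned 0.543; mean pairwise beta 0.162
phylogenetic alpha never exceeds taxonomic alpha: TRUE

$ Rscript analysis/05_models.R
== interaction models (coefficients with stars; reference = abandoned)
 index facet expansive_cover management_mown    interaction adj_R2_pct  AIC
 alpha    TD      -0.0042***        0.1087**    -0.002308**      72*** -151
 alpha    PD    -0.004884***         0.1023* -0.0008152n.s.      58*** -110
  beta    TD    -0.004236***    -0.01655n.s.  0.0003383n.s.      83*** -221
  beta    PD     -0.001568**   -0.006525n.s.  0.0003301n.s.       18** -175
```

Read the alpha-TD row as: each percent of expansive cover costs 0.0042
units of Rao Q in abandoned plots; mown plots start 0.109 units more
diverse at zero cover; and mowing steepens the per-percent decline by a
further 0.0023 (the management-modulated biotic filter), with 72% of
variance explained. `06_recovery.R` repeats the whole analysis on 200
replicate datasets — the interaction sign is recovered in 98% of them —
and on 500 fully null replicates, where its rejection rate stays at the
nominal 5% (0.040).

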