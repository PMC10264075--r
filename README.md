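# osteomorph

High-density 3D geometric morphometrics for detecting **size-independent
shape dimorphism** in long-bone populations.

Morphological sexual dimorphism in skeletal samples is often not a size
difference but a subtle, localized shape contrast — e.g. a laterally
bowed vs straight femoral shaft coupled with a narrower vs wider distal
epiphysis.  `osteomorph` implements the full analysis chain used to
detect such structure in dense landmark data, for morphometricians and
paleobiologists working with complete or fragmented limb bones:

1. **Landmarking model** — anatomical landmarks plus sliding
   semilandmarks on curves and surfaces (TPS text and flat-table readers;
   PLY/OBJ/STL mesh I/O).
2. **Semilandmark relaxation** — template surface-patch projection, then
   sliding that minimizes the thin-plate-spline bending energy
   (3D kernel U(r) = r), 5 iterations against the template and 2 against
   the partial-Procrustes consensus; anatomical landmarks never move.
3. **Superimposition and ordination** — partial generalized Procrustes
   analysis (unit centroid size CS = sqrt(Σ‖xᵢ − x̄‖²), proper rotations
   only, canonical output frame) and PCA of the aligned coordinates.
4. **Dimorphism scan** — per-axis univariate Gaussian mixtures fitted by
   EM (equal- and free-variance, G = 1..9) selected by maximized
   BIC = 2·logL − k·log n, gated by a Pearson allometry test of the scores
   against log CS.  An axis is *dimorphic, size-independent* iff G = 2 and
   the allometry p-value exceeds 0.05.
5. **Accounting** — per-cluster mean-shape reconstruction with mesh
   warping, fragment (proximal/distal epiphysis) re-analysis with
   cluster-consistency counts, repeatability (operator-noise)
   quantification, and MNE/MNI element bookkeeping with staged filter
   ledgers.
6. **Synthetic data** — a parametric femur template (default census
   25 anatomical / 99 curve / 495 surface landmarks = 619 points) and a
   two-morph population generator with a near-1:1 mixing ratio, landmark
   noise, and log-normal size decoupled from morph, used to validate the
   whole pipeline end to end.

## Worked example

Simulate a dimorphic femur population, relax, superimpose, and scan:

```r
library(osteomorph)

tpl  <- build_ideal_femur(c(15, 30, 120), with_mesh = FALSE)  # small census
pop  <- generate_population(population_spec(n = 24, seed = 2), tpl)
r1   <- relax_to_template(pop$specimens, tpl, n_iter = 5)
r2   <- relax_to_consensus(r1$configs, tpl, n_iter = 2)
g    <- gpa(r2$configs)
p    <- shape_pca(g)
scan <- dimorphism_scan(p, g, axes = 1:3)
print(scan)
```

```
<dimorphism_scan>
    axis variance_fraction selected_G          model allometry_r allometry_p dimorphic
PC1    1            0.4672          2 equal_variance      -0.142       0.507      TRUE
PC2    2            0.0912          1 equal_variance      -0.118       0.584     FALSE
PC3    3            0.0386          1 equal_variance       0.130       0.545     FALSE
dimorphic, size-independent axes: PC1
```

PC1 carries 46.7% of the shape variance, splits into exactly two Gaussian
components (the two morphs; comparing assignments against the generator's
hidden labels gives 100% recovery here), and shows no correlation with
log centroid size (p = 0.51) — a size-independent dimorphism.  The other
axes are unimodal.  `cluster_mean_shapes()` reconstructs the two group
mean shapes along PC1, and `run_pipeline()` wires all stages (including
fragment extraction and cluster-consistency counts) into one call with a
JSON/CSV report.

Element accounting reproduces published-style MNI bookkeeping:

```r
inv <- angeac_inventory()
compute_mni(inv, "femur")   # 46
compute_mni(inv, "tibia")   # 61
```

A thin CLI over the same functions lives at `inst/cli/osteomorph.R`
(subcommands `simulate`, `slide`, `gpa`, `pca`, `dimorph`, `consistency`,
`run`).

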