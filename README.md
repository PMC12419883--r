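# pemretro

Phylogenetic eigenvector map (PEM) regression for retrodicting red blood
cell (RBC) size in fossil tetrapods from bone histometrics and phylogeny.

## The problem

RBC size constrains gas diffusion and hence aerobic capacity, but cells do
not fossilize. Bone does — and the vascular canals and osteocyte lacunae
preserved in cortical bone scale with the capillaries and cells that
occupied them. Given blood-smear RBC measurements for extant species, bone
histometric proxies for extant *and* extinct species, and a phylogeny over
all of them, the RBC dimensions of the extinct species can be retrodicted:
predicted by a model fitted on the modern data and projected to fossil
positions on the tree.

`pemretro` implements that workflow for comparative biologists:

1. **Influence matrix.** A rooted tree with branch lengths φ is converted
   to a binary tips × edges matrix **B**, with B(t, e) = 1 iff edge e lies
   on the root-to-tip path of t.
2. **PEM basis.** Columns are weighted by w(φ) = √ψ · φ^((1−a)/2)
   (steepness a ∈ [0, 1]: a = 0 is the Brownian-motion limit, a = 1 makes
   influence length-independent), centered on their training-tip means,
   and decomposed by SVD into orthonormal eigenvectors **U** — descriptors
   of phylogenetic structure usable as regression covariates.
3. **Candidate models.** For a response y (ln RBC width/area/length), four
   models are fitted: each single log-transformed histometric co-predictor
   (osteocyte lacuna volume, canal harmonic-mean diameter, canal minimum
   calibre) plus forward-selected eigenvectors, and eigenvectors alone.
   Forward selection adds the eigenvector with the lowest resulting AICc
   and stops when AICc no longer improves (an R²-maximizing mode is also
   available). Models are ranked by R²; overall-F p-values are reported
   raw and with a step-down Holm–Šidák adjustment across the grid.
4. **Retrodiction.** Each held-out tip (fossil, or extant with a missing
   response) is located on the training tree (attachment edge + traversed
   length), scored against the basis as
   (row − means) · **V** · diag(1/d), fed through the best model, and
   back-transformed by exp to original units (µm, µm²).

A seeded synthetic-data generator (pure-birth tree, Brownian trait, noisy
linear proxies, fossil masking) makes every stage testable with no data
downloads.

## Worked example

```r
library(pemretro)

cfg  <- sim_config(n_tips = 40, fossil_fraction = 0.5, seed = 42)
sim  <- simulate_dataset(cfg)                 # tree + trait table + truth
paths <- write_fixture(sim$tree, sim$table, "data")
res  <- run_pipeline(run_config(paths[["tree"]], paths[["characters"]],
                                out_dir = "out"))
print(res$comparisons$RBC_area)
```

```
Model comparison for RBC_area
                      model r_squared      p_value   p_adjusted      aicc  best
 lnOsteo_volume + phylogeny 0.9584749 3.586027e-09 1.434411e-08 -51.90157  TRUE
  lnCan_harmean + phylogeny 0.9496397 1.367132e-08 4.101396e-08 -48.04348 FALSE
      lnCan_min + phylogeny 0.8567876 5.518371e-07 1.103674e-06 -36.18857 FALSE
                  phylogeny 0.8651972 5.479243e-05 5.479243e-05 -22.59369 FALSE
```

Each row is one candidate: its R² on the 20 training (extant) taxa, the
overall F-test p-value (raw and Holm–Šidák-adjusted across the four
models) and AICc; the `best` flag marks the highest R², which is the model
used for prediction. The retrodictions for the 20 masked "fossil" tips:

```r
head(res$retrodictions[, 1:4], 5)
#   taxon response ln_prediction prediction
# 1   t03 RBC_area      4.430004   83.93174
# 2   t05 RBC_area      4.450621   85.68014
# 3   t07 RBC_area      4.806137  122.25839
# 4   t08 RBC_area      4.245824   69.81325
# 5   t11 RBC_area      4.535604   93.27987
```

`prediction` is in µm² (exp of the ln-scale prediction). Against the
generator's withheld truth these predictions have a median absolute
ln-error of 0.065, i.e. about 7% in cell area. `run_pipeline()` also
writes `model_table.csv`, `retrodictions.csv` and a `provenance.json`
recording input hashes and every setting; reruns are byte-identical.

The same pipeline runs from the shell (`inst/exec/pemretro`):

```sh
pemretro simulate --n-tips 40 --seed 42 --out-dir data
pemretro reproduce --tree data/tree.nwk --matrix data/characters.csv --out-dir out
```

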