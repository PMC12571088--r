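# toothspace

Landmark-based tooth morphospace analysis and extinction simulation for
sharks (and other dentally tractable vertebrates).

A large fraction of requiem shark (*Carcharhinus*) species is threatened
with extinction, and their teeth — easy to sample, tightly linked to
feeding — are a practical window on the genus's functional diversity.
`toothspace` quantifies tooth-crown shape from 2D landmark configurations
and asks what happens to the occupied shape space, and to dietary
diversity, if species disappear in order of IUCN threat status rather than
at random.

The pipeline:

- **Input**: TPS landmark files (3 fixed landmarks + two semilandmark
  curves, 160 points per tooth), a species trait table (IUCN status,
  body-size class, habitat, depth, length), a proportional diet matrix,
  and a phylogeny (newick).
- **Shape**: equidistant curve resampling; generalized Procrustes
  superimposition with bending-energy sliding semilandmarks; species mean
  shapes; PCA ordination with a deterministic axis-sign rule.
- **Erosion**: threat-ordered extinction scenarios (CR → CR+EN →
  CR+EN+VU → CR+EN+VU+NT) tracked in a fixed baseline ordination —
  convex-hull area loss, centroid displacement, survivor depth range —
  against Monte Carlo random-extinction nulls with 95% envelopes.
- **Disparity**: the average pairwise Procrustes distance,
  APPD = 2/(n(n−1)) · Σ_{i<j} d_ij, plus per-group Procrustes variance.
- **Inference**: residual-randomization permutation ANOVA (Goodall-style,
  full coordinate space), pairwise group contrasts, and a multivariate
  Blomberg-type phylogenetic signal statistic K (expectation 1 under
  Brownian motion) with permutation p and effect size Z.
- **Ecology**: centered log-ratio diet analysis, ordinated dietary niche
  breadth (ODB) via principal coordinates of prey incidence profiles,
  multivariate dispersion homogeneity, and scenario-wise dispersion
  contraction.
- **Synthetic data**: a generator producing full datasets (pure-birth
  tree, Brownian crown parameters through a smooth tooth template, noisy
  specimens with jaw dimorphism, morphology-selective threat statuses,
  Dirichlet diets) so the whole pipeline is testable and parameter
  recovery is measurable.

See the methods vignette (`vignettes/morphospace-erosion.Rmd`) for the
models, assumptions, defaults and design choices.

## Worked example

```r
library(toothspace)

bundle <- simulate_dataset(n_species = 30, seed = 7)   # synthetic study
paths  <- write_bundle(bundle, "bundle")               # TPS + CSV + newick
ds     <- load_dataset(paths["tps"], paths["traits"],
                       paths["diets"], paths["tree"])
ds
#> Tooth shape dataset: 1311 specimens, 30 species
#>   IUCN: CR=4 EN=8 VU=10 NT=4 LC=4
#>   diet coverage: 27/30 species; tree: 30 tips

gpa <- superimpose(ds$configs, slide = TRUE)
gpa
#> Generalized Procrustes superimposition
#>   1311 configurations of 160 landmarks; sliding semilandmarks: bending energy
#>   7 iteration(s), converged (tol 1e-08)

ord <- ordinate(species_mean_shapes(gpa))
ord
#> Shape PCA of 30 entities, 29 axes
#>   % variance: PC1 76.16%, PC2 19.29%, PC3 3.77%, PC4 0.11%, PC5 0.08%

ext <- run_extinction_analysis(ord, ds$traits,
                               shapes = species_mean_shapes(gpa),
                               n_reps = 100, seed = 7)
ext
#> Baseline: hull area 0.01241, APPD 0.07477
#>     scenario  k hull_area pct_area_loss centroid_shift    appd  ...
#>           CR  4  0.010307         16.94       0.009498 0.06928  ...
#>        CR+EN 12  0.005152         58.48       0.002220 0.06113  ...
#>     CR+EN+VU 22  0.002999         75.83       0.015440 0.05784  ...
#>  CR+EN+VU+NT 26  0.001914         84.57       0.015255 0.06183  ...
```

Reading the output: the first axis is an obliquity continuum carrying
~76% of shape variance. Removing only the four critically endangered
species already erases ~17% of the occupied PC1–PC2 hull and pushes the
survivors' disparity (APPD 0.0693 vs baseline 0.0748) below the 95%
envelope of 100 random 4-species removals (`class_appd = "below"`), i.e.
threat-ordered extinction homogenizes tooth shape faster than chance.
`plot(ext)`, `plot(ord)` and `plot(gpa)` give the standard graphics.

Statistical tests follow the same grammar:

```r
means <- species_mean_shapes(gpa)
iucn  <- factor(setNames(ds$traits$iucn, ds$traits$species_id)[rownames(means)])
perm_anova(means ~ iucn, n_perm = 999, seed = 1)     # shape ~ status (RRPP)
phylo_signal(means, ds$tree)                          # multivariate K
clr <- clr_transform(ds$diets)
group_dispersion(clr, iucn[rownames(clr)])            # diet dispersion
```

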