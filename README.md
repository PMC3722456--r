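# plaqcluster

Quantification and spatial-clustering analysis of amyloid plaques in
two/three-channel fluorescence images.

## The problem

In amyloid-depositing mouse models, plaques present at a reference time
point can be labelled in vivo with a long-lived dense-core dye (channel
"MX"), while a pan-amyloid antibody at sacrifice labels all deposits
(channel "AB"). A deposit that is antibody positive but core-label negative
is a **new** plaque. This package asks, for users quantifying such images:
do new plaques deposit **near pre-existing plaques more often than chance**
— i.e. does plaque growth proceed partly by clustering of deposits?

The pipeline:

* **detection** — per channel, threshold at the background mean + 9
  background SDs (background estimated from a plaque-free region or a
  deterministic fallback), 8-connected components, minimum area 20 px
  (30 px for the size-distribution analysis);
* **classification** — pair dense cores to antibody plaques by centroid
  containment; flag *new* plaques (`n_cores == 0`), *new-in-vicinity*
  (centre-to-centre distance to the nearest pre-existing plaque < 40 µm,
  strict), *flower* clusters (≥ 2 new plaques around one pre-existing
  plaque), *multicore* plaques (≥ 2 separate cores in one antibody
  boundary; merged/separate fate from an optional dense-core counterstain
  "TR"), *large* plaques (> 300 µm²);
* **null model** — per image, the observed number of new plaques is placed
  uniformly at random (1,000 iterations); the chance in-vicinity proportion
  is compared to the observed one per animal with a two-sided Wilcoxon
  matched-pairs signed-rank test;
* **group statistics** — D'Agostino–Pearson K2 normality gate, then
  Kruskal–Wallis + Dunn's post hoc (or ANOVA + Tukey), core-count-vs-size
  regression, and per-animal mean ± SEM summary proportions.

Because no real images ship with the package, a **synthetic scene
generator** (`generate_scene()` / `render_scene()`) produces ground-truth
plaque configurations and noisy rendered channels; every stage is validated
against it. See `vignettes/plaque-clustering-methods.Rmd` for the model,
parameter rationale and limitations.

## Worked example

```r
library(plaqcluster)

cfg <- scene_config(seed = 42)       # 688 x 512 um field, 12 pre / 10 new
sc  <- generate_scene(cfg)
sc
#> plaque_scene: 12 pre-existing (0 multicore), 10 new (3 clustered)
#>   field 688 x 512 um @ 0.43 um/px; truth vicinity fraction 0.300

ren <- render_scene(sc)              # noisy MX / AB / TR channels
ab  <- ren$img[, , "AB"]
bg  <- estimate_background(ab)       # mean 99.95, sd 5.00
det_ab <- detect_plaques(ab, bg, pixel_size_um = 0.43)
det_ab
#> plaque_regions: 22 regions, threshold 144.99, 0.43 um/px

mx <- ren$img[, , "MX"]
cls <- classify_image(det_ab,
                      detect_plaques(mx, estimate_background(mx), 0.43))
rec <- cls$records
sum(rec$is_new)                      # 10 of 22 plaques are new
sum(rec$in_vicinity)                 # 3 of the 10 new are within 40 um

sim <- simulate_random_placement(cls$pre_centers, n_new = 10, seed = 42,
                                 image_id = "demo",
                                 observed_vicinity_prop = 0.3)
sim
#> nullsim_result [demo]: n_new = 10, observed = 0.300,
#>   chance mean = 0.1434 (1000 iterations)
```

All 22 planted plaques are recovered; the observed in-vicinity proportion
(0.300) exceeds the random-placement chance level for this layout (0.143)
— on a whole study, `paired_comparison()` turns the per-animal pairs of
such numbers into the Wilcoxon matched-pairs test.

## Analysis workflow

The `analysis/` scripts run a full synthetic study (three groups with
increasing new-plaque load, six animals each) and write their tables under
`results/`:

```sh
Rscript analysis/01_simulate_study.R    # design + ground truth scenes
Rscript analysis/02_detect_classify.R   # rendered-image pipeline subset
Rscript analysis/03_null_simulation.R   # observed vs chance per animal
Rscript analysis/04_group_statistics.R  # group tests + summary proportions
```

On the committed configuration, stage 3 prints

```
observed vicinity 0.241 vs chance 0.150 across 18 animals;
Wilcoxon matched-pairs signed-rank, exact: V = 155, p = 0.00129
```

— the clustered deposition planted by the generator (10 % clustered
mechanism on top of a ~0.15 chance level) is detected as an excess of
observed over chance vicinity proportions.

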