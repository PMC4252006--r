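# ihcscore

Quantification of DAB immunohistochemistry (IHC) in brightfield images, and
a statistical conversion of continuous staining intensity into the
categorical scores pathologists use.

Digital image analysis of IHC returns continuous DAB intensities, but
clinical reporting — HER2 above all — happens on an ordinal 0/1+/2+/3+
scale. `ihcscore` bridges the two for any DAB-stained marker, nuclear or
membranous:

1. **Stain separation.** RGB tiles are unmixed by optical-density color
   deconvolution, `M c = −log10(I/I0)`, with configurable unit stain
   vectors (published H-DAB triplets by default). Each stain is expressed
   as *white pixel intensity* w = 255·10^(−c) on 0–255, where 255 = no
   stain.
2. **Background cutoff t0** by Otsu's global histogram threshold (maximal
   between-class variance, smallest-threshold tie rule), or a fixed
   override such as the conventional 230.
3. **Categorization.** Positive intensities (≤ t0) are fitted with a
   3-component Gaussian mixture f(x) = Σ π_s N(x; μ_s, σ_s) by EM
   (deterministic quantile-seeded k-means initialization); the category
   thresholds t1 (strong/moderate) and t2 (moderate/weak) are the
   intersections of adjacent weighted component densities, solved in
   closed form.
4. **Scoring.** Nuclei are segmented on the hematoxylin channel; a cell is
   positive when its mean DAB white intensity is ≤ t0; region scores are
   the fraction-weighted sum `score = 1·f_weak + 2·f_moderate +
   3·f_strong ∈ [0, 3]`.
5. **Decalcification statistics.** The full battery for time-course studies
   (ANOVA + Welch-on-ranks + Tukey; Kruskal–Wallis + pairwise Wilcoxon at
   the Bonferroni level 0.05/6 = 0.0083 for four time points), applied to
   baseline-normalized field measurements.
6. **Scanner comparison.** Normalized channel histograms, category-zone
   areas and pixelwise intensity correspondence between co-registered
   images.

Because no public data exist for this workflow, the package includes a
fully ground-truthed synthetic H-DAB field and time-course generator
(`generate_ihc_image()`, `generate_timecourse()`); every pipeline stage is
tested against it.

## Worked example

```r
library(ihcscore)

spec <- synthetic_image_spec(n_cells = 250, seed = 7)   # 35% DAB-positive field
field <- generate_ihc_image(spec)
channels <- separate_stains(field$image, spec$vectors)

intens <- round(generate_mixture_sample(field$model, 1e4, seed = 7))
th <- derive_thresholds(intens, t0 = 230)
th
#> thresholds: t1 = 75.43 (strong/moderate), t2 = 180.07 (moderate/weak), t0 = 230.00 (background)
attr(th, "model")
#> Gaussian mixture, k = 3
#>   weight   mean    sd
#> 1 0.3025  40.66 15.30
#> 2 0.4013 130.85 25.55
#> 3 0.2962 204.58 11.25
#> log-likelihood -52510.004 after 36 iterations

score_regions(channels, th)
#>   region n_cells n_negative n_weak n_moderate n_strong frac_weak frac_moderate
#> 1      1     250        162     31         34       23    0.3523        0.3864
#>   frac_strong pct_positive mean_intensity score
#> 1      0.2614         35.2          130.6 1.909
```

The fitted mixture recovers the generating components (true means 40, 130,
205), the thresholds land at the density crossings, 35.2 % of cells are
called positive against a ground truth of 35.2 %, and the region's
fraction-weighted score is 1.91 on the 0–3 scale.

The decalcification battery on a synthetic ER time course (9 cases,
5 fields, 0/1/6/24 h, 15 % loss after 1 h then plateau):

```r
decal_battery(generate_timecourse(seed = 7))$pairwise
#>   pair  tukey_p_adj significant   wilcoxon_p
#> 1  1-0 3.408385e-14        TRUE 3.877499e-16
#> 2 24-0 3.408385e-14        TRUE 3.173685e-16
#> 3 24-1 2.340884e-05        TRUE 4.000037e-05
#> 4 24-6 9.984646e-01       FALSE 7.044830e-01
#> 5  6-0 3.408385e-14        TRUE 3.627302e-16
#> 6  6-1 4.721528e-05        TRUE 1.038031e-04
```

The 1-hour drop is detected and the 6-to-24-hour pair is correctly flat.

## Command line

A thin CLI wraps the same functions (installed under the package's `exec/`
directory):

```sh
ihc-catscore simulate image --out sim/ --seed 3 --cells 250
ihc-catscore calibrate sim/image.png --t0 230 --out thresholds.json
ihc-catscore score sim/image.png --thresholds thresholds.json --out measurements.csv
ihc-catscore simulate timecourse --out tc.csv --seed 5
ihc-catscore decal-stats tc.csv --out stats.json
ihc-catscore compare-scanners a.png b.png --thresholds thresholds.json --out cmp.json
```

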