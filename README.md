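# edgecooc

Sparse edge extraction and edge co-occurrence statistics for rapid scene
categorization.

Early visual cortex represents an image as a set of oriented edges, and in
natural scenes those edges are not independent: collinear and co-circular
arrangements are far more common than chance. `edgecooc` asks how much
*category* information this second-order structure carries. It decomposes
grayscale images into discrete oriented edges with an over-complete
log-Gabor dictionary and matching pursuit, accumulates the relative
geometry of every edge pair into the four-dimensional "association field"
histogram `p(d, psi, theta, sigma)` (distance, symmetrized angle,
orientation difference, log scale ratio; `psi = 0` marks co-circular
pairs), compares histograms with Kullback–Leibler and Jensen–Shannon
divergences, and classifies images from histogram features with a
cross-validated linear SVM scored by the binary F1 measure
(`2TP / (2TP + FP + FN)`; 50% is chance for balanced classes). A synthetic
contour generator with controlled curvature statistics makes every stage
testable without any external image database: classes with curved contours
("animal-like" statistics) separate from classes with straight contours
("man-made-like" statistics) on these features alone.

The package is aimed at computational-neuroscience and computer-vision
researchers studying natural scene statistics, association fields, and
low-level routes to categorization.

## A worked example

```r
library(edgecooc)

# a 64x64 dictionary: 8 orientations x 5 scales, octave-spaced
bank <- build_filterbank(filter_params(image_shape = c(64L, 64L)))

# a synthetic image: 3 smooth contours of Gabor strokes + 1/f background
g <- generate_contour_image(fixture_spec(curvature_mean = 0.05, seed = 5))

# sparse-code it: greedy pursuit down to 5% residual energy
fit <- extract_edges(g$image, bank, n_edges = 256)
fit
#> sparse log-Gabor edge decomposition
#>   33 edges extracted (budget 256), residual energy 4.96%

# the association field and its angular (chevron-map) marginal
h <- cooc_histogram(fit$edges)
h
#> edge co-occurrence histogram p(d, psi, theta, sigma)
#>   bins 6 x 12 x 12 x 5, 292 pairs binned (114 dropped), amplitude-weighted
plot(chevron_map(h))
```

The decomposition reaches the 5% residual-energy criterion after 33 edges;
the histogram then summarizes all 292 masked edge pairs. At the benchmark
scale — 100 images per class — a straight-contour class and a
curved-contour class separate almost perfectly:

```r
ds <- generate_dataset(list(straight = fixture_spec(),
                            curved = fixture_spec(curvature_mean = 0.05)),
                       n_per_class = 100, seed = 7)
edges <- lapply(names(ds$images), function(id)
  extract_edges(ds$images[[id]], bank, n_edges = 256, source_id = id)$edges)
x <- make_features(edges, mode = "SO")     # full 4-D histogram features
crossval_f1(x, ds$manifest$label, n_resamples = 20, seed = 1)
#> SVM cross-validation (curved vs straight, SO features)
#>   mean F1 = 99.2%  (SD 1.2, range 97.4-100.0 over 20 resamples)
```

while two classes drawn from the *same* specification score at chance
(mean F1 near 50%). The ratio chevron map of curved against straight
classes shows the characteristic signature: co-circular cells
(`psi ~ 0`, `theta != 0`) enriched, the collinear cell depleted.

A command-line driver is installed as `exec/edgecooc` with subcommands
`synth`, `extract`, `stats`, `classify` and `compare`; see
`edgecooc --help` and the methods vignette
(`vignettes/edge-cooccurrence.Rmd`) for conventions and parameter
documentation.

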