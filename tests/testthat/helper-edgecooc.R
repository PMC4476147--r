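# shared fixtures, built lazily and memoized across test files
.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, expr, envir = .cache)
  get(key, envir = .cache)
}

bank64 <- function() memo("bank64", build_filterbank(
  filter_params(image_shape = c(64L, 64L))))

bank128 <- function() memo("bank128", build_filterbank(
  filter_params(image_shape = c(128L, 128L))))

bank256 <- function() memo("bank256", build_filterbank(filter_params()))

# edges placed along a straight line, identical orientation
collinear_edges <- function(n = 10, theta = pi / 4, shape = c(64L, 64L)) {
  t0 <- seq(-18, 18, length.out = n)
  as_edge_list(data.frame(
    x = (shape[2] - 1) / 2 + t0 * cos(theta),
    y = (shape[1] - 1) / 2 + t0 * sin(theta),
    theta = theta, scale_index = 2, amplitude = 1, phase = 0),
    image_shape = shape)
}

# edges tangent to a circle of given radius at equally spaced polar angles
circle_tangent_edges <- function(n = 12, radius = 20, shape = c(64L, 64L)) {
  alpha <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  as_edge_list(data.frame(
    x = (shape[2] - 1) / 2 + radius * cos(alpha),
    y = (shape[1] - 1) / 2 + radius * sin(alpha),
    theta = (alpha + pi / 2) %% pi, scale_index = 2, amplitude = 1,
    phase = 0), image_shape = shape)
}

random_edges <- function(n = 60, shape = c(64L, 64L), seed = 1,
                         scales = 1:5) {
  set.seed(seed)
  as_edge_list(data.frame(
    x = runif(n, 2, shape[2] - 3), y = runif(n, 2, shape[1] - 3),
    theta = runif(n, 0, pi),
    scale_index = scales[sample.int(length(scales), n, replace = TRUE)],
    amplitude = runif(n, 0.2, 1), phase = runif(n, -pi, pi)),
    image_shape = shape)
}

random_prob <- function(dims, seed) {
  set.seed(seed)
  w <- array(rexp(prod(dims)), dims)
  w / sum(w)
}

# the straight-vs-curved and identical-spec benchmarks used by the
# acceptance tests (shared across criteria; memoized)
bench_edges <- function(spec_a, spec_b, seed, n_per_class = 100) {
  ds <- generate_dataset(list(a = spec_a, b = spec_b),
                         n_per_class = n_per_class, seed = seed)
  list(edges = lapply(names(ds$images), function(id) {
    fit <- extract_edges(ds$images[[id]], bank64(), n_edges = 256,
                         source_id = id)
    fit$edges
  }), labels = ds$manifest$label)
}

bench_chance <- function() memo("bench_chance",
  bench_edges(fixture_spec(), fixture_spec(), seed = 1))

bench_separable <- function() memo("bench_separable",
  bench_edges(fixture_spec(curvature_mean = 0),
              fixture_spec(curvature_mean = 0.05), seed = 7))
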