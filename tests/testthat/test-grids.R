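make_dist <- function(values, ncol = NULL) {
  n <- length(values)
  if (is.null(ncol)) ncol <- n
  m <- matrix(values, ncol = ncol,
              dimnames = list(paste0("r", seq_len(n / ncol)),
                              paste0("c", seq_len(ncol))))
  extract_distribution(as_clag_matrix(m))
}

test_that("distribution extraction sorts, keeps multiplicity, drops the
           diagonal in square mode", {
  v <- matrix(c(0.1, 0.2, 0.3, 0.4), 2, 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  m <- as_clag_matrix(v)
  d <- extract_distribution(m, symmetric_mode = FALSE)
  expect_equal(d$sorted_entries, c(0.1, 0.2, 0.3, 0.4))
  expect_equal(d$T, 4L)
  dsq <- extract_distribution(m, symmetric_mode = TRUE)
  expect_equal(dsq$sorted_entries, c(0.2, 0.3))
  expect_equal(dsq$T, 2L)

  d3 <- make_dist(c(0.5, 0.5, 0.5, 0.1), ncol = 2)
  expect_equal(d3$sorted_entries, c(0.1, 0.5, 0.5, 0.5))
})

test_that("delta-quantile ranges follow ceil(delta*T) with tail truncation", {
  d100 <- make_dist(seq(0.005, 0.995, length.out = 100), ncol = 20)
  expect_equal(delta_quantile(1L, d100, 0.20), c(1L, 20L))
  expect_equal(delta_quantile(50L, d100, 0.05), c(50L, 54L))
  d10 <- make_dist(seq(0.05, 0.95, length.out = 10), ncol = 5)
  expect_equal(delta_quantile(8L, d10, 0.5), c(8L, 10L))
  expect_error(delta_quantile(11L, d10, 0.5))
})

test_that("0-grid and 1-grid interval counts match the quantile layout", {
  d100 <- make_dist(seq(0.005, 0.995, length.out = 100), ncol = 20)
  g0 <- build_grid(d100, 0.2, 0L)
  expect_equal(g0$ends - g0$starts + 1L, rep(20L, 5))
  g1 <- build_grid(d100, 0.2, 1L)
  expect_equal(g1$ends - g1$starts + 1L, c(10L, 20L, 20L, 20L, 20L, 10L))
  d7 <- make_dist(seq(0.1, 0.7, by = 0.1), ncol = 7)
  g <- build_grid(d7, 0.5, 0L)
  expect_equal(g$ends - g$starts + 1L, c(4L, 3L))
})

test_that("heterogeneity uses the strict mu + sigma rule", {
  # interval value-lengths (.1, .1, .1, .7): mu = .25, sigma ~ .2598
  d <- make_dist(c(0, 0.1, 0.1, 0.2, 0.2, 0.3, 0.3, 1.0), ncol = 4)
  g <- build_grid(d, 0.25, 0L)
  expect_equal(g$lengths, c(0.1, 0.1, 0.1, 0.7))
  expect_equal(g$mu, 0.25)
  expect_equal(g$sigma, sqrt(mean((c(.1, .1, .1, .7) - .25)^2)))
  expect_true(is_heterogeneous(g))

  # equal lengths: sigma = 0 and no length exceeds mu strictly
  dhom <- make_dist(seq(0.005, 0.995, length.out = 100), ncol = 20)
  expect_false(is_heterogeneous(build_grid(dhom, 0.2, 0L)))
  # single interval: length equals mu, sigma 0
  expect_false(is_heterogeneous(build_grid(make_dist(c(0.1, 0.9), 2),
                                           0.9, 0L)))
})

test_that("refinement splits only offending intervals at the value midpoint", {
  d <- make_dist(c(0, 0.1, 0.1, 0.2, 0.2, 0.3, 0.3, 1.0), ncol = 4)
  g <- build_grid(d, 0.25, 0L)
  r <- refine_grid(g, d)
  expect_true(r$refined)
  expect_length(r$starts, 5L)
  # the split interval [.3, 1.0] cuts at .65: member .3 left, 1.0 right
  expect_equal(r$lo, c(0, 0.1, 0.2, 0.3, 1.0))
  expect_equal(r$hi, c(0.1, 0.2, 0.3, 0.3, 1.0))
  # homogeneous grids come back unchanged
  dhom <- make_dist(seq(0.005, 0.995, length.out = 100), ncol = 20)
  ghom <- build_grid(dhom, 0.2, 0L)
  expect_identical(refine_grid(ghom, dhom), ghom)
})

test_that("every rank lies in exactly one interval, before and after
           refinement", {
  set.seed(101)
  for (i in 1:20) {
    Tn <- sample(10:60, 1)
    vals <- sort(round(runif(Tn), 3))  # duplicates likely
    d <- make_dist(vals, ncol = Tn)
    for (off in c(0L, 1L)) {
      g <- build_grid(d, sample(c(0.1, 0.2, 0.25), 1), off)
      expect_equal(unname(tabulate(g$interval_of, length(g$starts))),
                   unname(g$ends - g$starts + 1L))
      expect_length(g$interval_of, d$T)
      r <- refine_grid(g, d)
      expect_length(r$interval_of, d$T)
      expect_equal(sum(r$ends - r$starts + 1L), d$T)
    }
  }
})

test_that("are_close agrees with the brute-force oracle on random
           distributions", {
  set.seed(202)
  for (i in 1:100) {
    Tn <- sample(8:40, 1)
    delta <- sample(c(0.1, 0.15, 0.2, 0.25), 1)
    vals <- round(runif(Tn), sample(1:3, 1))  # ties common
    d <- make_dist(vals, ncol = Tn)
    g <- suppressWarnings(build_grids(d, delta))
    og <- oracle_grids(d$sorted_entries, delta)
    pairs <- utils::combn(d$T, 2L)
    got <- are_close(pairs[1L, ], pairs[2L, ], g)
    want <- mapply(function(a, b) oracle_close(a, b, og),
                   pairs[1L, ], pairs[2L, ])
    expect_equal(got, unname(want),
                 info = sprintf("iter %d T=%d delta=%g", i, Tn, delta))
  }
})

test_that("closeness is reflexive at equal ranks and fails across the
           distribution", {
  d <- make_dist(seq(0.005, 0.995, length.out = 100), ncol = 20)
  g <- build_grids(d, 0.2)
  expect_true(are_close(37L, 37L, g))
  expect_true(are_close(37L, 38L, g))
  expect_false(are_close(1L, 100L, g))
  # symmetric under argument order
  expect_identical(are_close(15L, 42L, g), are_close(42L, 15L, g))
})

test_that("non-multiple-of-0.05 delta warns but still builds", {
  d <- make_dist(seq(0.005, 0.995, length.out = 100), ncol = 20)
  expect_warning(build_grids(d, 0.17), "multiple of 0.05")
  expect_silent(build_grids(d, 0.25))
})
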