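test_that("sample_volume draws from the requested family", {
  set.seed(101)
  ln <- volume_spec("lognormal", mu = 6.04, sigma = 0.394)
  v <- sample_volume(ln, 2e5)
  # closed-form log-normal median e^mu = 419.9
  expect_equal(median(v), exp(6.04), tolerance = 0.01)

  un <- volume_spec("uniform", vmin = 160, vmax = 1000)
  u <- sample_volume(un, 1e4)
  expect_true(all(u >= 160 & u <= 1000))

  tiny <- sample_volume(volume_spec("lognormal", mu = 6.04, sigma = 1e-12),
                        100)
  expect_equal(tiny, rep(exp(6.04), 100), tolerance = 1e-9)

  expect_error(volume_spec("lognormal", mu = 6, sigma = 0),
               class = "xtalgen_config_error")
  expect_error(volume_spec("uniform", vmin = 10, vmax = 5),
               class = "xtalgen_config_error")
})

test_that("analytic volume pdf: support, normalization, MC agreement", {
  expect_equal(pdf_volume_uniform_cells(0.5 * 4^3, 4, 10), 0)
  expect_equal(pdf_volume_uniform_cells(1001, 4, 10), 0)
  expect_error(pdf_volume_uniform_cells(100, 10, 4),
               class = "xtalgen_domain_error")

  # normalization to 1e-6 for several (l, u) pairs
  for (lu in list(c(4, 10), c(4, 50), c(2, 7))) {
    nrm <- integrate(function(v) pdf_volume_uniform_cells(v, lu[1], lu[2]),
                     lu[1]^3, lu[2]^3, subdivisions = 2000L,
                     rel.tol = 1e-9)$value
    expect_equal(nrm, 1, tolerance = 1e-6)
  }

  # KS against brute-force Monte-Carlo products of three uniforms
  set.seed(202)
  for (lu in list(c(4, 10), c(4, 50), c(2, 7))) {
    mc <- oracle_mc_products(2e5, lu[1], lu[2])
    cdf <- cdf_volume_uniform_cells(lu[1], lu[2])
    expect_lt(ks_distance(mc, cdf), 0.005)
  }
})

test_that("cell_from_volume honors volume, bounds and adjacent ratios", {
  b <- cell_bounds(4, 10, 3)
  set.seed(303)
  expect_equal(cell_from_volume(1000, b), c(10, 10, 10), tolerance = 1e-9)
  expect_equal(cell_from_volume(64, b), c(4, 4, 4), tolerance = 1e-9)
  expect_error(cell_from_volume(63, b), class = "xtalgen_domain_error")
  expect_error(cell_from_volume(1001, b), class = "xtalgen_domain_error")

  # property check over random feasible (volume, bounds) configurations
  set.seed(304)
  for (i in 1:2000) {
    lmin <- runif(1, 2, 6); lmax <- lmin + runif(1, 1, 10)
    r <- runif(1, 1.2, 4)
    bb <- cell_bounds(lmin, lmax, r)
    v <- runif(1, lmin^3, lmax^3)
    a <- cell_from_volume(v, bb)
    expect_true(all(diff(a) >= -1e-12))
    expect_lt(abs(prod(a) / v - 1), 1e-8)
    expect_true(all(a >= lmin - 1e-9 & a <= lmax + 1e-9))
    expect_lte(a[2] / a[1], r + 1e-9)
    expect_lte(a[3] / a[2], r + 1e-9)
  }
})

test_that("permute_lengths preserves the multiset and is uniform", {
  set.seed(405)
  expect_equal(sort(permute_lengths(c(4, 7, 10))), c(4, 7, 10))
  expect_equal(permute_lengths(c(5, 5, 5)), c(5, 5, 5))

  n <- 6e4
  perms <- replicate(n, paste(permute_lengths(c(1, 2, 3)), collapse = ""))
  freq <- table(perms)
  expect_length(freq, 6)
  # binomial 3 sigma around 1/6
  sd3 <- 3 * sqrt((1 / 6) * (5 / 6) / n)
  expect_true(all(abs(freq / n - 1 / 6) < sd3 + 1e-3))
})

test_that("sample_cell_uniform is three independent uniforms", {
  set.seed(506)
  draws <- t(replicate(2e5, sample_cell_uniform(cell_bounds(4, 10))))
  expect_true(all(draws >= 4 & draws <= 10))
  vols <- draws[, 1] * draws[, 2] * draws[, 3]
  expect_equal(mean(vols), 343, tolerance = 0.01)   # E(A)^3 = 7^3
  # product distribution matches the analytic pdf
  cdf <- cdf_volume_uniform_cells(4, 10)
  expect_lt(ks_distance(vols, cdf), 0.005)
})

test_that("fit_lognormal recovers parameters and validates input", {
  set.seed(607)
  v <- sample_volume(volume_spec("lognormal", mu = 6.04, sigma = 0.394), 1e5)
  fit <- fit_lognormal(v)
  expect_equal(fit$mu, 6.04, tolerance = 0.01 / 6.04)
  expect_equal(fit$sigma, 0.394, tolerance = 0.005 / 0.394)

  cfit <- fit_lognormal(c(100, 100, 100))
  expect_equal(cfit$mu, log(100))
  expect_equal(cfit$sigma, 0)

  expect_error(fit_lognormal(c(100, 0, 50)), class = "xtalgen_domain_error")
  expect_error(fit_lognormal(c(5)), class = "xtalgen_domain_error")

  # plain-text one-volume-per-line interface
  tf <- withr::local_tempfile(fileext = ".txt")
  writeLines(as.character(v[1:1000]), tf)
  ffit <- fit_lognormal(tf)
  expect_equal(ffit$mu, mean(log(v[1:1000])), tolerance = 1e-6)
})

test_that("feasible-volume resampling truncates to the bounds", {
  set.seed(708)
  b <- cell_bounds(4, 10)
  spec <- volume_spec("lognormal", mu = 6.04, sigma = 0.394)
  vv <- replicate(500, sample_volume_feasible(spec, b))
  expect_true(all(vv >= 64 & vv <= 1000))
  narrow <- volume_spec("uniform", vmin = 2000, vmax = 3000)
  expect_error(sample_volume_feasible(narrow, b, max_tries = 50),
               class = "xtalgen_domain_error")
})

test_that("sampling is bit-reproducible under a fixed seed", {
  spec <- volume_spec("lognormal", mu = 6.04, sigma = 0.394)
  b <- cell_bounds(4, 10, 3)
  set.seed(99); a1 <- sample_volume(spec, 10); c1 <- cell_from_volume(500, b)
  set.seed(99); a2 <- sample_volume(spec, 10); c2 <- cell_from_volume(500, b)
  expect_identical(a1, a2)
  expect_identical(c1, c2)
})
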