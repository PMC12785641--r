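test_that("reflection enumeration: cutoff, Friedel reduction, index cap", {
  cube <- diag(c(10, 10, 10))
  refl <- reflection_list(cube, diffraction_config(d_min = 1.0))
  expect_true(all(refl$d >= 1.0))
  expect_false(any(refl$h == 0 & refl$k == 0 & refl$l == 0))
  # (10, 0, 0) has d = a/h = 1.0 exactly
  expect_true(any(refl$h == 10 & refl$k == 0 & refl$l == 0))
  expect_equal(max(abs(as.matrix(refl[, 1:3]))), 10)
  # one Friedel representative per pair
  key <- paste(refl$h, refl$k, refl$l)
  mate <- paste(-refl$h, -refl$k, -refl$l)
  expect_length(intersect(key, mate), 0)
})

test_that("scattering factors: f(0) = Z, monotone decrease", {
  tab <- form_factor_table()
  expect_equal(scattering_factor("C", 0), 6, tolerance = 0.1 / 6)
  expect_equal(scattering_factor("H", 0), 1, tolerance = 0.05)
  zs <- c(H = 1, C = 6, N = 7, O = 8, F = 9, Si = 14, P = 15, S = 16,
          Cl = 17, Br = 35, Sc = 21, Ti = 22, V = 23, Cr = 24, Mn = 25,
          Fe = 26, Co = 27, Ni = 28, Cu = 29, Zn = 30)
  s <- seq(0, 0.5, by = 0.01)
  for (el in rownames(tab)) {
    f <- scattering_factor(el, s)
    expect_equal(f[1], zs[[el]], tolerance = 0.1)
    expect_true(all(diff(f) <= 1e-12))
  }
  expect_error(scattering_factor("Xx", 0), class = "xtalgen_config_error")
})

test_that("Debye-Waller attenuation", {
  expect_equal(debye_waller(0, 1.3), 1)
  expect_equal(debye_waller(0.05, 1), exp(-0.1 * pi^2))
  u <- seq(0, 0.2, by = 0.01)
  expect_true(all(diff(debye_waller(u, 1.5)) < 0))
})

test_that("structure factors: one-atom case and s->0 electron count", {
  sg <- space_group("P-1")
  st <- structure(list(
    vectors = diag(c(6, 6, 6)),
    parameters = parameters_from_vectors(diag(c(6, 6, 6))),
    group = sg,
    atoms = data.frame(element = "C", x = 0, y = 0, z = 0, u_iso = 1e-12,
                       site = "special", special_index = 1L)),
    class = "crystal_structure")
  refs <- structure_factors(st, config = diffraction_config(d_min = 1.2))
  f_expected <- scattering_factor("C", 1 / (2 * refs$d))
  expect_equal(refs$amplitude, f_expected, tolerance = 1e-9)
  expect_true(all(refs$phase == 0))

  # extrapolated F(000) equals the full-cell electron count
  set.seed(10)
  r <- make_batch("molecules", 1, seed = 914)[[1]]
  at <- r$structure$atoms
  zs <- c(H = 1, C = 6, N = 7, O = 8, F = 9, Si = 14, P = 15, S = 16,
          Cl = 17, Br = 35, Sc = 21, Ti = 22, V = 23, Cr = 24, Mn = 25,
          Fe = 26, Co = 27, Ni = 28, Cu = 29, Zn = 30)
  mult <- ifelse(at$site == "special", 1, 2)
  n_el <- sum(mult * zs[at$element])
  st0 <- r$structure
  st0$atoms$u_iso <- 0
  f000 <- oracle_cosine_sf(st0, data.frame(h = 0, k = 0, l = 0, d = Inf))
  expect_equal(f000, n_el, tolerance = 0.02 * n_el)  # 4-Gaussian f(0) error
})

test_that("complex and cosine-route structure factors agree; phases binary", {
  set.seed(11)
  batch <- make_batch("molecules", 10, seed = 915)
  for (r in batch) {
    refs <- r$reflections
    expect_true(all(refs$phase %in% c(0, pi)))
    fc <- oracle_cosine_sf(r$structure, refs)
    signed <- refs$amplitude * cos(refs$phase)
    expect_equal(signed, fc, tolerance = 1e-8)
    # Friedel mates have equal amplitude
    mates <- refs[1:20, ]
    mates[, 1:3] <- -mates[, 1:3]
    fm <- abs(oracle_cosine_sf(r$structure, mates))
    expect_equal(fm, refs$amplitude[1:20], tolerance = 1e-10)
  }
})

test_that("lattice translation leaves F unchanged", {
  set.seed(12)
  r <- make_batch("molecules", 1, seed = 916)[[1]]
  st <- r$structure
  shifted <- st
  shifted$atoms$x <- st$atoms$x + 1   # full lattice vector
  refl <- reflection_list(st$vectors)
  f1 <- oracle_cosine_sf(st, refl)
  f2 <- oracle_cosine_sf(shifted, refl)
  expect_equal(f1, f2, tolerance = 1e-10)
})

test_that("completeness thinning", {
  set.seed(13)
  r <- make_batch("uniform", 1, seed = 917)[[1]]
  refs <- r$reflections
  expect_identical(apply_completeness(refs, 1), refs)
  thin <- apply_completeness(refs, 0.85)
  expect_equal(nrow(thin), round(0.85 * nrow(refs)))
  key <- function(x) paste(x$h, x$k, x$l)
  expect_true(all(key(thin) %in% key(refs)))
  expect_error(apply_completeness(refs, 1.2), class = "xtalgen_config_error")
})

test_that("grid packing round-trips and counts nonzeros", {
  cfg <- diffraction_config(index_cap = 10)
  empty <- data.frame(h = integer(0), k = integer(0), l = integer(0),
                      d = numeric(0), amplitude = numeric(0),
                      phase = numeric(0))
  g0 <- to_grid(empty, cfg)
  expect_true(all(g0$amplitude == 0) && all(g0$phase == 0))
  expect_equal(dim(g0$amplitude), c(11, 21, 21))

  set.seed(14)
  r <- make_batch("uniform", 1, seed = 918)[[1]]
  refs <- r$reflections
  g <- to_grid(refs, cfg)
  expect_equal(sum(g$amplitude != 0), nrow(refs))
  back <- from_grid(g, cfg)
  ord <- order(refs$h, refs$k, refs$l)
  expect_equal(back$amplitude, refs$amplitude[ord])
  expect_equal(back$phase, refs$phase[ord])
  expect_equal(back[, c("h", "k", "l")], refs[ord, c("h", "k", "l")],
               ignore_attr = TRUE)

  over <- refs
  over$h[1] <- 99
  expect_error(to_grid(over, cfg), class = "xtalgen_domain_error")
})

test_that("sampled resolution and completeness stay in their ranges", {
  cfg <- generator_config(
    placement_mode = "uniform",
    diffraction = diffraction_config(sample_resolution = TRUE,
                                     sample_completeness = TRUE),
    seed = 919)
  for (i in 1:5) {
    r <- generate_structure(cfg, i)
    expect_gte(min(r$reflections$d), 1.0)
  }
})
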