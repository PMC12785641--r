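test_that("content budget follows the stated formulas", {
  sg <- space_group("P-1")
  set.seed(1)
  # forced v_atom = 10: n_nonh = round(800 / (2 * 10)) = 40
  b <- sample_budget(800, sg, v_atom_range = c(10, 10),
                     x_h_range = c(0.5, 0.5))
  expect_equal(b$n_nonh, 40L)
  expect_equal(b$n_h, 40L)                       # x/(1-x) = 1 at x = 0.5
  b0 <- sample_budget(800, sg, v_atom_range = c(10, 10),
                      x_h_range = c(1e-12, 1e-12))
  expect_equal(b0$n_h, 0L)
  # floor at 1
  b1 <- sample_budget(5, sg, v_atom_range = c(22, 22))
  expect_equal(b1$n_nonh, 1L)
})

test_that("sample_sphere_point is on the sphere and uniform", {
  set.seed(2)
  p <- t(replicate(200, sample_sphere_point(c(1, 2, 3), 1.5)))
  off <- sweep(p, 2, c(1, 2, 3))
  expect_equal(sqrt(rowSums(off^2)), rep(1.5, 200), tolerance = 1e-12)

  n <- 2e5
  off <- t(replicate(n, sample_sphere_point(radius = 1)))
  expect_true(all(abs(colMeans(off)) < 3 / sqrt(3 * n) * 3))
  # Archimedes hat-box: z uniform on [-1, 1]
  expect_lt(ks_distance(off[, 3], function(z) punif(z, -1, 1)), 0.005)
})

test_that("ADP assignment: shared U, deviations, clamping", {
  st <- list(atoms = data.frame(element = rep("C", 50),
                                x = runif(50), y = runif(50), z = runif(50),
                                u_iso = NA_real_, site = "general",
                                special_index = NA_integer_))
  class(st) <- "crystal_structure"
  set.seed(3)
  same <- assign_adps(st, dev_range = c(0, 0))
  expect_equal(length(unique(same$atoms$u_iso)), 1L)

  def <- assign_adps(st)
  expect_true(all(def$atoms$u_iso >= 0.005 & def$atoms$u_iso <= 0.105))

  clamped <- assign_adps(st, u_range = c(0.001, 0.001),
                         dev_range = c(-0.005, -0.005))
  expect_equal(unique(clamped$atoms$u_iso), 0.001)
})

test_that("uniform placement respects d_min everywhere (brute force)", {
  rules <- placement_rules()
  set.seed(4)
  batch <- make_batch("uniform", 40, seed = 910)
  for (r in batch) {
    expect_identical(oracle_contact_audit(r$structure, "uniform", rules), 0L)
  }
  # element frequencies of general non-H atoms converge to the table
  tab <- element_table("general")
  elems <- unlist(lapply(batch, function(r) {
    a <- r$structure$atoms
    a$element[a$site == "general" & a$element != "H"]
  }))
  obs <- table(factor(elems, levels = tab$elements))
  common <- tab$probs > 0.02          # rare elements pooled out of the test
  chi <- suppressWarnings(chisq.test(
    c(obs[common], sum(obs[!common])),
    p = c(tab$probs[common], sum(tab$probs[!common]))))
  expect_gt(chi$p.value, 0.01)
})

test_that("uniform placement degenerate cases", {
  sg <- space_group("P-1")
  vec <- diag(c(5, 5, 5))
  # impossible d_min: at most one atom placed, with a warning
  rules_big <- placement_rules(d_min_contact = 20)
  set.seed(5)
  budget <- sample_budget(125, sg, v_atom_range = c(10, 10),
                          x_h_range = c(0.3, 0.3))
  expect_warning(
    st <- place_uniform(vec, sg, budget, rules_big),
    "discarded")
  expect_lte(nrow(st$atoms), 1)

  # budget floored at 1 places exactly one non-H atom
  b1 <- sample_budget(1, sg, v_atom_range = c(22, 22),
                      x_h_range = c(1e-12, 1e-12))
  st1 <- place_uniform(vec, sg, b1, placement_rules())
  expect_equal(nrow(st1$atoms), 1L)
  expect_false(st1$atoms$element == "H")
})

test_that("molecule growth: bonds, dichotomy and connectivity (brute force)", {
  rules <- placement_rules()
  radii <- covalent_radii()
  # C-C bond window from Cordero radius 0.76
  expect_equal(0.9 * 2 * radii[["C"]], 1.368)
  expect_equal(1.1 * 2 * radii[["C"]], 1.672)

  set.seed(6)
  batch <- make_batch("molecules", 40, seed = 911)
  for (r in batch) {
    expect_identical(oracle_contact_audit(r$structure, "molecule", rules), 0L)
    expect_true(oracle_connectivity(r$structure, rules))
  }
  # hydrogen count matches the budget when no shortfall occurred
  clean <- Filter(function(r) r$structure$shortfall == 0, batch)
  expect_gt(length(clean), 0)
  for (r in clean) {
    b <- r$structure$budget
    expect_equal(sum(r$structure$atoms$element == "H"), b$n_h)
    expect_equal(sum(r$structure$atoms$element != "H"), b$n_nonh)
  }
})

test_that("equal-atom conversion is geometry-preserving and idempotent", {
  set.seed(7)
  r <- make_batch("molecules", 1, seed = 912)[[1]]
  eq <- make_equal_atom(r$structure)
  expect_true(all(eq$atoms$element == "C"))
  expect_equal(eq$atoms[, c("x", "y", "z", "u_iso")],
               r$structure$atoms[, c("x", "y", "z", "u_iso")])
  expect_identical(make_equal_atom(eq), eq)
})

test_that("special positions count against the heavy-atom budget", {
  set.seed(8)
  cfg <- generator_config(placement_mode = "molecules", special_p = 1,
                          seed = 913)
  r <- generate_structure(cfg, 1)
  sp <- sum(r$structure$atoms$site == "special")
  expect_gt(sp, 0)
  expect_true(all(r$structure$atoms$element[
    r$structure$atoms$site == "special"] != "H"))
  if (r$structure$shortfall == 0) {
    expect_equal(sum(r$structure$atoms$element != "H"),
                 r$structure$budget$n_nonh)
  }
  # structure remains clash-free under the full audit
  expect_identical(
    oracle_contact_audit(r$structure, "molecule", cfg$rules), 0L)
})
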