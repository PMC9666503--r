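test_that("fraction abundance scales reads proportionally to qPCR totals", {
  expect_equal(fraction_absolute_abundance(c(10, 30), 8e6), c(2e6, 6e6))
  expect_equal(fraction_absolute_abundance(c(3, 5, 2), 1e7),
               c(3e6, 5e6, 2e6))
  # empty-fraction convention: no reads -> no attributable copies
  expect_equal(fraction_absolute_abundance(c(0, 0), 5e6), c(0, 0))
  expect_error(fraction_absolute_abundance(c(-1, 2), 1e6), "non-negative")
  expect_error(fraction_absolute_abundance(c(1, 2), -5), "non-negative")
})

test_that("weighted-average density is the copy-weighted mean", {
  expect_equal(weighted_average_density(c(0, 5, 0), c(1.68, 1.700, 1.72)),
               1.700)
  expect_equal(weighted_average_density(c(1, 3), c(1.70, 1.72)), 1.715)
  # uniform copies -> arithmetic mean of densities
  d <- c(1.68, 1.69, 1.70, 1.71)
  expect_equal(weighted_average_density(rep(2, 4), d), mean(d))
  expect_true(is.na(weighted_average_density(c(0, 0), c(1.7, 1.71))))
  expect_error(weighted_average_density(c(1, 2), 1.7), "aligned")
})

test_that("WAD is translation-equivariant in density", {
  set.seed(1)
  for (i in 1:20) {
    cp <- rgamma(6, 1); d <- sort(runif(6, 1.66, 1.74)); delta <- runif(1, -0.02, 0.02)
    expect_equal(weighted_average_density(cp, d + delta),
                 weighted_average_density(cp, d) + delta)
  }
})

test_that("GC calibration inverts at its anchor points", {
  expect_equal(gc_from_unlabeled_density(1.646057), 0)
  expect_equal(gc_from_unlabeled_density(1.646057 + 0.083506), 1)
  expect_equal(gc_from_unlabeled_density(1.700), 0.645977534548414,
               tolerance = 1e-12)
  expect_warning(gc_from_unlabeled_density(1.60), "outside")
})

test_that("atom fraction excess follows the molecular-weight chain", {
  # no density shift -> zero excess
  expect_equal(atom_fraction_excess_18O(1.700, 1.700), 0)
  # frozen from the independent arithmetic chain:
  # G = 0.6459775, M_light = 308.0114049, M_lab = M_light * 1705/1700
  expect_equal(atom_fraction_excess_18O(1.705, 1.700), 0.0748586977411204,
               tolerance = 1e-12)
  # saturation: a shift of delta_mw_max in molecular weight gives
  # A = 1 - natural abundance
  k <- qsip_constants()
  m_light <- molecular_weight_light(gc_from_unlabeled_density(1.700, k), k)
  w_sat <- 1.700 * (1 + k$delta_mw_max_18O / m_light)
  expect_equal(atom_fraction_excess_18O(w_sat, 1.700, k),
               1 - k$natural_abundance_18O)
  # negative shifts give negative excess, retained
  expect_lt(atom_fraction_excess_18O(1.698, 1.700), 0)
})

test_that("atom fraction excess is strictly increasing in the labeled WAD", {
  w_lab <- seq(1.695, 1.76, by = 0.002)
  a <- atom_fraction_excess_18O(w_lab, 1.700)
  expect_true(all(diff(a) > 0))
})

test_that("wad_shift_for_afe is the exact inverse of the excess equation", {
  for (a in c(0, 0.01, 0.0748587, 0.3, 0.785, 0.998)) {
    w <- wad_shift_for_afe(a, 1.6923)
    expect_equal(atom_fraction_excess_18O(w, 1.6923), a, tolerance = 1e-12)
  }
})

test_that("growth potential implements linear growth", {
  # A = 0: nothing new
  g0 <- growth_potential(5e8, 0)
  expect_equal(g0$b, 0)
  expect_equal(g0$n_light, 5e8)
  # A = A_sat: the whole pool is new
  gs <- growth_potential(5e8, 0.7856, a_sat = 0.7856, t = 7)
  expect_equal(gs$b, 5e8 / 7)
  expect_equal(gs$n_light, 0)
  # frozen worked example (copies_per_cell = 6)
  g <- growth_potential(6e8, 0.0748586977411204, a_sat = 0.7856, t = 7)
  expect_equal(g$p_new, 0.0952885663710799, tolerance = 1e-10)
  expect_equal(g$b, 8167591.40323542, tolerance = 1e-10)
  expect_equal(g$cells_b, g$b / 6)
  # negative excess propagates, not clamped
  expect_lt(growth_potential(1e8, -0.01)$b, 0)
  expect_warning(growth_potential(1e8, 0.9, a_sat = 0.7856),
                 "super-saturated")
  expect_error(growth_potential(1e8, 0.1, t = 0), "positive")
})

test_that("growth is zero when labeled equals unlabeled density", {
  for (w in c(1.66, 1.70, 1.73)) {
    a <- atom_fraction_excess_18O(w, w)
    expect_equal(growth_potential(3e8, a)$b, 0)
  }
})

test_that("per-tube profiles match brute-force recomputation on a hand table", {
  b <- minimal_bundle()
  prof <- tube_taxon_profiles(b)
  cnt16 <- rbind(c(10, 40, 5), c(30, 40, 15))   # asv x fraction
  cnt18 <- rbind(c(30, 40, 15), c(10, 40, 5))
  dens <- c(1.72, 1.70, 1.68); tot <- c(2e6, 8e6, 1e6)
  oracle <- brute_force_chain(cnt16, cnt18, dens, dens, tot, tot)
  p16 <- prof[prof$tube_id == "tube16", ]
  p18 <- prof[prof$tube_id == "tube18", ]
  expect_equal(p16$wad[match(c("a1", "a2"), p16$asv_id)], oracle$w16,
               tolerance = 1e-12)
  expect_equal(p18$wad[match(c("a1", "a2"), p18$asv_id)], oracle$w18,
               tolerance = 1e-12)
  expect_equal(sum(p16$n_total), sum(tot))
})

test_that("full estimator chain matches brute force on a 5-taxon table", {
  set.seed(42)
  n_taxa <- 5; n_frac <- 5
  dens <- seq(1.74, 1.66, length.out = n_frac)
  cnt16 <- matrix(rpois(n_taxa * n_frac, 20), n_taxa)
  cnt18 <- matrix(rpois(n_taxa * n_frac, 20), n_taxa)
  # shift taxon mass heavier in the labeled tube
  cnt18[, 1:2] <- cnt18[, 1:2] + matrix(rpois(n_taxa * 2, 30), n_taxa)
  tot16 <- runif(n_frac, 1e6, 9e6); tot18 <- runif(n_frac, 1e6, 9e6)
  oracle <- brute_force_chain(cnt16, cnt18, dens, dens, tot16, tot18)

  copies16 <- vapply(seq_len(n_frac), function(f)
    fraction_absolute_abundance(cnt16[, f], tot16[f]), numeric(n_taxa))
  copies18 <- vapply(seq_len(n_frac), function(f)
    fraction_absolute_abundance(cnt18[, f], tot18[f]), numeric(n_taxa))
  w16 <- apply(copies16, 1, weighted_average_density, densities = dens)
  w18 <- apply(copies18, 1, weighted_average_density, densities = dens)
  a <- atom_fraction_excess_18O(w18, w16)
  b <- growth_potential(rowSums(copies18), a, a_sat = 0.7876 - 0.002000429,
                        t = 7)$b
  expect_equal(w16, oracle$w16, tolerance = 1e-10)
  expect_equal(w18, oracle$w18, tolerance = 1e-10)
  expect_equal(gc_from_unlabeled_density(w16), oracle$gc, tolerance = 1e-10)
  expect_equal(molecular_weight_light(gc_from_unlabeled_density(w16)),
               oracle$m_light, tolerance = 1e-10)
  expect_equal(a, oracle$a, tolerance = 1e-10)
  expect_equal(b, oracle$b, tolerance = 1e-10)
})
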