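test_that("the default design reproduces the experiment layout", {
  sim <- generate_experiment(qsip_design(n_taxa = 20), seed = 1)
  m <- sim$bundle$meta
  expect_equal(nrow(m), 54)
  expect_equal(length(unique(m$treatment)), 6)
  expect_equal(sort(unique(table(m$treatment, m$replicate))), 3)
  # per replicate: T0 16O, T7 16O, T7 18O
  key <- table(paste(m$timepoint, m$isotope))
  expect_equal(as.vector(key[c("T0 16O", "T7 16O", "T7 18O")]),
               c(18, 18, 18))
  expect_equal(as.vector(table(sim$bundle$fractions$tube_id)), rep(22L, 54))
  # reduced design arithmetic
  sim2 <- generate_experiment(
    qsip_design(fungal = "uninoculated", moisture = "replete",
                n_replicates = 2, n_taxa = 5), seed = 1)
  expect_equal(nrow(sim2$bundle$meta), 6)
})

test_that("truth generation is reproducible and respects the mixture", {
  d <- qsip_design(n_taxa = 40)
  t1 <- make_taxa(40, d, seed = 5)
  t2 <- make_taxa(40, d, seed = 5)
  expect_identical(t1, t2)
  expect_true(all(t1$taxa$gc >= 0.3 & t1$taxa$gc <= 0.7))
  expect_true(all(t1$ape >= 0 & t1$ape <= d$ape_max))
  expect_equal(colSums(t1$abund), rep(1, 6), ignore_attr = TRUE)
  # all-inactive design has exactly zero APE
  t0 <- make_taxa(10, qsip_design(n_taxa = 10, active_prob = 0), seed = 1)
  expect_true(all(t0$ape == 0))
  expect_error(qsip_design(active_prob = 1.5), class = "qsip_config_error")
})

test_that("simulated tubes conserve DNA mass before noise", {
  g <- gradient_config(noise = FALSE, conc_cutoff = 0)
  d <- qsip_design(fungal = "u", moisture = "w", n_taxa = 15, gradient = g)
  truth <- make_taxa(15, d, seed = 3)
  tube <- simulate_tube(truth, "u_w", "18O", g, seed = 1, replicate = 2)
  expected <- sum(g$tube_total_16s * truth$abund[, "u_w"] *
                    truth$rep_effects[, "u_w", 2])
  expect_equal(sum(tube$fractions$total_16s_copies), expected,
               tolerance = 1e-9)
  expect_equal(nrow(tube$fractions), 22)
})

test_that("without noise the forward model inverts to the exact truth", {
  g <- gradient_config(noise = FALSE, conc_cutoff = 0)
  cfg <- qsip_config()
  d <- qsip_design(fungal = "u", moisture = "w", n_taxa = 4, gradient = g)
  truth <- make_taxa(4, d, seed = 2)
  truth$ape[, 1] <- c(0, 7.49, 30, 64.2)
  t16 <- simulate_tube(truth, "u_w", "16O", g, seed = 1, config = cfg)
  t18 <- simulate_tube(truth, "u_w", "18O", g, seed = 1, config = cfg)
  b <- as_qsip_bundle(
    rbind(t16$fractions, transform(t18$fractions, tube_id = "t18")),
    data.frame(tube_id = c("u_w_16O", "t18"), microcosm_id = "m",
               fungal = "u", moisture = "w", isotope = c("16O", "18O"),
               timepoint = "T7", replicate = 1),
    rbind(t16$counts, transform(t18$counts, tube_id = "t18")),
    data.frame(asv_id = truth$taxa$asv_id, phylum = truth$taxa$phylum),
    data.frame(treatment = "u_w", replicate = 1, co2_efflux = 10),
    qsip_config(cutoff_ng_ul = 0))
  prof <- tube_taxon_profiles(b)
  w16 <- prof$wad[prof$tube_id == "u_w_16O"]
  w18 <- prof$wad[prof$tube_id == "t18"]
  ord <- match(truth$taxa$asv_id, prof$asv_id[prof$tube_id == "u_w_16O"])
  ape_hat <- 100 * atom_fraction_excess_18O(w18[ord], w16[ord])
  expect_equal(ape_hat, unname(truth$ape[, 1]), tolerance = 0.01)
  # the unlabeled tube also recovers each taxon's GC-determined density
  k <- qsip_constants()
  expect_equal(sort(w16), sort(k$gc_intercept + k$gc_slope * truth$taxa$gc),
               tolerance = 1e-4)
})

test_that("a band outside the collected gradient is truncated with a warning", {
  g <- gradient_config(density_min = 1.66, density_max = 1.70,
                       noise = FALSE, conc_cutoff = 0)
  d <- qsip_design(fungal = "u", moisture = "w", n_taxa = 3, gradient = g)
  truth <- make_taxa(3, d, seed = 4)
  truth$taxa$gc[] <- 0.69           # density ~1.704, above density_max
  expect_warning(simulate_tube(truth, "u_w", "16O", g, seed = 1),
                 "truncated")
})

test_that("estimator error grows with band spread and qPCR noise", {
  # the sequencing window is held fixed (cutoff 0) so the grid varies
  # only the noise mechanism, not which fractions are observed; with the
  # cutoff active, narrower bands also shrink the observed window and
  # truncation bias can dominate the comparison
  err_at <- function(band_sd, qpcr_cv, seed) {
    g <- gradient_config(band_sd = band_sd, qpcr_cv = qpcr_cv,
                         conc_cutoff = 0)
    sim <- suppressWarnings(generate_experiment(
      qsip_design(fungal = "uninoculated", moisture = "replete",
                  n_taxa = 60, gradient = g), seed = seed))
    fit <- suppressWarnings(qsip(sim$bundle, n_boot = 200, seed = seed))
    rec <- truth_recovery_report(sim$truth, fit)
    median(abs(rec$detail$ape_error))
  }
  avg <- function(band_sd, qpcr_cv)
    mean(vapply(c(17, 31, 53), function(s)
      err_at(band_sd, qpcr_cv, s), numeric(1)))
  r_band <- vapply(c(0.003, 0.006, 0.012), avg, numeric(1),
                   qpcr_cv = 0.15)
  r_cv <- vapply(c(0.05, 0.15, 0.45), function(cv)
    avg(0.006, cv), numeric(1))
  expect_true(all(diff(r_band) > 0))
  expect_true(all(diff(r_cv) > 0))
})

test_that("truth recovery joins on ids and flags strangers", {
  sim <- small_sim(seed = 19, n_taxa = 20)
  fit <- qsip(sim$bundle, n_boot = 150, seed = 19)
  rec <- truth_recovery_report(sim$truth, fit)
  expect_s3_class(rec, "qsip_recovery")
  expect_equal(rec$n, sum(!is.na(fit$enrichment$ape_median)))
  bad <- fit
  bad$enrichment$asv_id[1] <- "ASV9999"
  expect_error(truth_recovery_report(sim$truth, bad),
               class = "qsip_referential_error")
})
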