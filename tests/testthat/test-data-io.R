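test_that("a hand-written fixture round-trips through read_experiment", {
  dir <- write_minimal_dir()
  b <- read_experiment(dir, quiet = TRUE)
  expect_s3_class(b, "qsip_bundle")
  expect_equal(nrow(b$meta), 2)
  expect_equal(nrow(b$fractions), 6)
  expect_setequal(unique(b$counts$asv_id), c("a1", "a2"))
  expect_equal(b$meta$treatment, rep("uninoculated_replete", 2))
  # cutoff 1.0 ng/uL: all three fractions exceed it
  expect_true(all(b$fractions$sequenced))
})

test_that("sequencing flag derives from the concentration cutoff", {
  tb <- minimal_tables()
  cfg <- qsip_config(cutoff_ng_ul = 1.8)
  tb$counts <- tb$counts[tb$counts$fraction_index != 3, ]
  b <- as_qsip_bundle(tb$fractions, tb$samples, tb$counts, tb$taxonomy,
                      tb$co2, cfg)
  expect_equal(b$fractions$sequenced, rep(c(TRUE, TRUE, FALSE), 2))
  # explicit sequenced column wins and permits missing concentrations
  tb$fractions$sequenced <- TRUE
  tb$fractions$dna_conc_ng_ul <- NULL
  tb$counts <- minimal_tables()$counts
  b2 <- as_qsip_bundle(tb$fractions, tb$samples, tb$counts, tb$taxonomy,
                       tb$co2, cfg)
  expect_true(all(b2$fractions$sequenced))
})

test_that("validation rejects malformed inputs with typed errors", {
  tb <- minimal_tables()
  # missing column named in the message
  expect_error(as_qsip_bundle(tb$fractions[-3], tb$samples, tb$counts,
                              tb$taxonomy, tb$co2),
               class = "qsip_schema_error")
  expect_error(as_qsip_bundle(tb$fractions[-3], tb$samples, tb$counts,
                              tb$taxonomy, tb$co2),
               "density_g_ml")
  # count on an unsequenced fraction names tube and fraction
  tb2 <- minimal_tables()
  tb2$fractions$dna_conc_ng_ul[3] <- 0.2   # tube16 fraction 3
  err <- tryCatch(as_qsip_bundle(tb2$fractions, tb2$samples, tb2$counts,
                                 tb2$taxonomy, tb2$co2),
                  error = identity)
  expect_s3_class(err, "qsip_referential_error")
  expect_match(conditionMessage(err), "tube16/fraction 3")
  # tube in counts absent from samples
  tb3 <- minimal_tables()
  tb3$samples <- tb3$samples[1, , drop = FALSE]
  expect_error(as_qsip_bundle(tb3$fractions, tb3$samples, tb3$counts,
                              tb3$taxonomy, tb3$co2),
               class = "qsip_referential_error")
  # taxonomy must cover every counted ASV
  tb4 <- minimal_tables()
  tb4$taxonomy <- tb4$taxonomy[1, , drop = FALSE]
  expect_error(as_qsip_bundle(tb4$fractions, tb4$samples, tb4$counts,
                              tb4$taxonomy, tb4$co2),
               class = "qsip_referential_error")
  # physical density range
  tb5 <- minimal_tables()
  tb5$fractions$density_g_ml[1] <- 1.90
  expect_error(as_qsip_bundle(tb5$fractions, tb5$samples, tb5$counts,
                              tb5$taxonomy, tb5$co2),
               class = "qsip_schema_error")
  # T0 tubes must be unlabeled
  tb6 <- minimal_tables()
  tb6$samples$timepoint <- c("T0", "T7")
  tb6$samples$isotope <- c("18O", "18O")
  expect_error(as_qsip_bundle(tb6$fractions, tb6$samples, tb6$counts,
                              tb6$taxonomy, tb6$co2),
               class = "qsip_schema_error")
  # labeled tube without an unlabeled partner
  tb7 <- minimal_tables()
  tb7$samples$isotope <- c("18O", "18O")
  expect_error(as_qsip_bundle(tb7$fractions, tb7$samples, tb7$counts,
                              tb7$taxonomy, tb7$co2),
               class = "qsip_referential_error")
})

test_that("non-monotone density warns and re-sorts without breaking references", {
  tb <- minimal_tables()
  tb$fractions$density_g_ml[1:3] <- c(1.70, 1.72, 1.68)  # out of order
  expect_warning(
    b <- as_qsip_bundle(tb$fractions, tb$samples, tb$counts, tb$taxonomy,
                        tb$co2),
    "not monotone")
  f <- b$fractions[b$fractions$tube_id == "tube16", ]
  expect_equal(f$density_g_ml, c(1.72, 1.70, 1.68))
  expect_equal(f$fraction_index, c(2L, 1L, 3L))  # indices kept
})

test_that("result tables round-trip through write/read at full precision", {
  dir <- withr::local_tempdir()
  set.seed(9)
  enr <- data.frame(asv_id = sprintf("a%02d", 1:7),
                    treatment = "x_y",
                    ape_median = rnorm(7) * 10,
                    ci_low = runif(7, -1, 0) * 1e-4,
                    ci_high = runif(7, 1e6, 1e9),
                    active = c(TRUE, FALSE)[c(1, 2, 1, 2, 1, 1, 2)])
  man <- write_results(list(enrichment = enr), dir, seed = 9)
  expect_equal(man$n_rows, 7)
  back <- read_results(dir)$enrichment
  expect_equal(back$ape_median, enr$ape_median, tolerance = 1e-12)
  expect_equal(back$ci_low, enr$ci_low, tolerance = 1e-12)
  expect_equal(back$ci_high, enr$ci_high, tolerance = 1e-12)
  expect_identical(back$active, enr$active)
  expect_identical(names(back), names(enr))
  # empty table: header only, manifest count 0
  man2 <- write_results(list(empty = enr[0, ]), dir)
  expect_equal(man2$n_rows[man2$file == "empty.tsv"], 0)
  expect_equal(nrow(read_results(dir)$empty), 0)
})

test_that("BIOM count tables are accepted", {
  skip_if_not_installed("biomformat")
  dir <- write_minimal_dir()
  tb <- minimal_tables()
  m <- matrix(0, 2, 6, dimnames = list(
    c("a1", "a2"),
    paste(rep(c("tube16", "tube18"), each = 3), rep(1:3, 2), sep = ":")))
  for (i in seq_len(nrow(tb$counts)))
    m[tb$counts$asv_id[i],
      paste(tb$counts$tube_id[i], tb$counts$fraction_index[i], sep = ":")] <-
      tb$counts$count[i]
  biom_path <- file.path(dir, "counts.biom")
  biomformat::write_biom(biomformat::make_biom(m), biom_path)
  file.remove(file.path(dir, "counts.tsv"))
  b <- read_experiment(dir, quiet = TRUE)
  ref <- minimal_bundle()
  key <- function(d) d[order(d$tube_id, d$fraction_index, d$asv_id), ]
  expect_equal(key(b$counts)$count, key(ref$counts)$count)
})

test_that("the default synthetic experiment loads as a 54-tube bundle", {
  sim <- generate_experiment(qsip_design(n_taxa = 25), seed = 2)
  expect_equal(nrow(sim$bundle$meta), 54)
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  b <- read_experiment(list(fractions = file.path(dir, "fractions.tsv"),
                            samples = file.path(dir, "samples.tsv"),
                            counts = file.path(dir, "counts.tsv"),
                            taxonomy = file.path(dir, "taxonomy.tsv"),
                            co2 = file.path(dir, "co2.tsv")),
                       quiet = TRUE)
  expect_equal(nrow(b$meta), 54)
  expect_equal(sort(b$fractions$density_g_ml),
               sort(sim$bundle$fractions$density_g_ml), tolerance = 1e-12)
  expect_equal(sum(b$counts$count), sum(sim$bundle$counts$count))
})
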