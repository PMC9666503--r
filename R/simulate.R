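#' Gradient and measurement settings for the simulator
#'
#' Physical and measurement parameters of one simulated CsCl gradient
#' tube. Defaults emulate the assay design: 22 collected fractions,
#' ~5 ug DNA loaded per tube, per-fraction concentrations measured on
#' the 40 uL post-cleanup resuspension, sequencing only of fractions
#' above 1.0 ng uL^-1 (which under these defaults passes about 6-11 of
#' the 22 fractions), and multiplicative qPCR / concentration noise.
#'
#' @param n_fractions Number of collected fractions per tube.
#' @param band_sd Gaussian spread (g mL^-1) of a taxon's DNA band around
#'   its equilibrium density (centrifugation equilibrium plus diffusion
#'   broadening).
#' @param density_min,density_max Density range (g mL^-1) spanned by the
#'   collected gradient; fractions partition it into equal bins.
#' @param read_depth Sequencing reads per sequenced fraction.
#' @param qpcr_cv Coefficient of variation of the lognormal noise on
#'   per-fraction qPCR totals.
#' @param conc_cv CV of the lognormal noise on per-fraction DNA
#'   concentration.
#' @param conc_cutoff Sequencing concentration cutoff, ng uL^-1.
#' @param tube_dna_ng Total DNA loaded per tube, ng.
#' @param fraction_vol_ul Volume in which each fraction's DNA is
#'   resuspended for quantification, uL.
#' @param tube_total_16s Total 16S rRNA gene copies per tube (per g dry
#'   soil basis).
#' @param noise Logical; `FALSE` switches every stochastic measurement
#'   layer off (exact qPCR totals, exact concentrations, counts
#'   proportional to true copies) for forward-inverse identity checks.
#' @return A named list of class `gradient_config`.
#' @export
gradient_config <- function(n_fractions = 22, band_sd = 0.006,
                            density_min = 1.610, density_max = 1.810,
                            read_depth = 10000, qpcr_cv = 0.15,
                            conc_cv = 0.10, conc_cutoff = 1.0,
                            tube_dna_ng = 5000, fraction_vol_ul = 40,
                            tube_total_16s = 3e9, noise = TRUE) {
  if (n_fractions < 3) stop("n_fractions must be >= 3")
  if (band_sd <= 0) stop("band_sd must be positive")
  if (density_max <= density_min) stop("density_max must exceed density_min")
  structure(list(n_fractions = n_fractions, band_sd = band_sd,
                 density_min = density_min, density_max = density_max,
                 read_depth = read_depth, qpcr_cv = qpcr_cv,
                 conc_cv = conc_cv, conc_cutoff = conc_cutoff,
                 tube_dna_ng = tube_dna_ng,
                 fraction_vol_ul = fraction_vol_ul,
                 tube_total_16s = tube_total_16s, noise = noise),
            class = "gradient_config")
}

#' Experimental design for the simulator
#'
#' Defaults mirror the study layout: three fungal inoculum conditions
#' crossed with two moisture regimes, three replicate microcosms each,
#' and per replicate three gradient tubes (T0 16O, T7 16O, T7 18O) - 54
#' tubes in all. True per-treatment atom percent excess follows a
#' mixture of a point mass at zero (inactive taxa) and a uniform draw on
#' (0, `ape_max`), covering the observed field range.
#'
#' @param fungal,moisture Factor levels; their crossing defines the
#'   treatments.
#' @param n_replicates Replicate microcosms per treatment.
#' @param n_taxa Number of simulated ASVs.
#' @param active_prob Probability that a taxon is active (APE > 0) in a
#'   given treatment.
#' @param ape_max Upper bound of the uniform true-APE draw, points.
#' @param abund_alpha Dirichlet concentration for true relative
#'   abundances (small values give realistic skew).
#' @param rep_sdlog sdlog of the per-(taxon, treatment, replicate)
#'   lognormal abundance multipliers.
#' @param co2_mean Mean CO2 efflux per treatment (ug CO2 mg^-1 soil C
#'   over the assay); scalar or named by treatment.
#' @param co2_cv CV of the lognormal CO2 replicate noise.
#' @param gradient A [gradient_config()].
#' @return A named list of class `qsip_design`.
#' @export
qsip_design <- function(fungal = c("uninoculated", "R_irregularis", "S_bescii"),
                        moisture = c("replete", "limited"),
                        n_replicates = 3, n_taxa = 300,
                        active_prob = 0.4, ape_max = 65,
                        abund_alpha = 0.3, rep_sdlog = 0.3,
                        co2_mean = 30, co2_cv = 0.2,
                        gradient = gradient_config()) {
  if (active_prob < 0 || active_prob > 1)
    qsip_error("qsip_config_error",
               "active_prob must lie in [0, 1] (mixture weight)")
  if (n_taxa < 1) qsip_error("qsip_config_error", "n_taxa must be >= 1")
  if (ape_max <= 0) qsip_error("qsip_config_error", "ape_max must be positive")
  structure(list(fungal = fungal, moisture = moisture,
                 n_replicates = n_replicates, n_taxa = n_taxa,
                 active_prob = active_prob, ape_max = ape_max,
                 abund_alpha = abund_alpha, rep_sdlog = rep_sdlog,
                 co2_mean = co2_mean, co2_cv = co2_cv,
                 gradient = gradient),
            class = "qsip_design")
}

design_treatments <- function(design)
  as.vector(outer(design$fungal, design$moisture, paste, sep = "_"))

# mean-1 multiplicative lognormal noise
rlnorm_cv <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

# 12 soil phyla, roughly rank-abundance ordered; the tail two keep the
# "ten most abundant" reporting filter non-trivial.
.sim_phyla <- c("Proteobacteria", "Actinobacteria", "Acidobacteria",
                "Bacteroidetes", "Chloroflexi", "Verrucomicrobia",
                "Planctomycetes", "Gemmatimonadetes", "Firmicutes",
                "Armatimonadetes", "Nitrospirae", "Elusimicrobia")

#' Draw ground-truth taxa
#'
#' @param n_taxa Number of ASVs.
#' @param design A [qsip_design()].
#' @param seed Integer seed.
#' @return A `qsip_truth` list: `taxa` (asv_id, gc, lineage), `ape`
#'   (taxa x treatments matrix, points), `abund` (taxa x treatments,
#'   columns sum to 1), `rep_effects` (taxa x treatments x replicates),
#'   `treatments`, `design`, `seed`.
#' @export
make_taxa <- function(n_taxa = design$n_taxa, design = qsip_design(),
                      seed = 1) {
  set.seed(substream_seed(seed, "taxa"))
  trts <- design_treatments(design)
  asv_id <- sprintf("ASV%04d", seq_len(n_taxa))
  gc <- stats::runif(n_taxa, 0.3, 0.7)
  phy <- sample(.sim_phyla, n_taxa, replace = TRUE,
                prob = 0.55^seq_along(.sim_phyla))
  taxa <- data.frame(asv_id = asv_id, gc = gc, domain = "Bacteria",
                     phylum = phy,
                     class = paste0(phy, "_c1"),
                     order = paste0(phy, "_o1"),
                     family = paste0(phy, "_f1"),
                     genus = paste0("g_", asv_id),
                     stringsAsFactors = FALSE)
  ape <- matrix(0, n_taxa, length(trts), dimnames = list(asv_id, trts))
  abund <- matrix(0, n_taxa, length(trts), dimnames = list(asv_id, trts))
  for (tr in trts) {
    act <- stats::runif(n_taxa) < design$active_prob
    ape[act, tr] <- stats::runif(sum(act), 0, design$ape_max)
    a <- stats::rgamma(n_taxa, shape = design$abund_alpha)
    abund[, tr] <- a / sum(a)
  }
  rep_effects <- array(
    rlnorm_cv(n_taxa * length(trts) * design$n_replicates,
              sqrt(exp(design$rep_sdlog^2) - 1)),
    dim = c(n_taxa, length(trts), design$n_replicates),
    dimnames = list(asv_id, trts, NULL))
  structure(list(taxa = taxa, ape = ape, abund = abund,
                 rep_effects = rep_effects, treatments = trts,
                 design = design, seed = seed),
            class = "qsip_truth")
}

#' Simulate one gradient tube
#'
#' Forward model of density fractionation. Each taxon's DNA is a
#' two-component Gaussian band: pre-existing (unlabeled) DNA centred at
#' the GC-determined density, and DNA synthesised during the assay
#' centred at the fully 18O-labeled density (new DNA carries the soil
#' water's 18O atom fraction). The mass fraction of new DNA is
#' p_new = APE / (100 A_sat), so the taxon's mean density reproduces its
#' true APE exactly under the analytical model. Mass is integrated over
#' equal-width density bins (the fractions); per-fraction qPCR totals,
#' DNA concentrations, the concentration cutoff and multinomial read
#' counts are then layered on top.
#'
#' @param truth A [make_taxa()] truth object.
#' @param treatment One of `truth$treatments`.
#' @param isotope `"16O"` or `"18O"`.
#' @param gradient A [gradient_config()].
#' @param seed Integer seed for this tube's substream.
#' @param replicate Replicate index (selects the abundance multipliers).
#' @param timepoint `"T0"` or `"T7"`; labeling applies only at T7 with
#'   18O water.
#' @param tube_id Identifier stamped on the output rows.
#' @param config A [qsip_config()] (constants and A_sat).
#' @return A list with `fractions` and `counts` data.frames in the
#'   [read_experiment()] schemas.
#' @export
simulate_tube <- function(truth, treatment, isotope = c("16O", "18O"),
                          gradient = gradient_config(), seed = 1,
                          replicate = 1, timepoint = "T7",
                          tube_id = paste(treatment, isotope, sep = "_"),
                          config = qsip_config()) {
  isotope <- match.arg(isotope)
  if (!treatment %in% truth$treatments)
    qsip_error("qsip_config_error",
               paste("unknown treatment:", treatment))
  set.seed(seed)
  g <- gradient
  k <- config$constants
  n_taxa <- nrow(truth$taxa)

  copies <- g$tube_total_16s * truth$abund[, treatment] *
    truth$rep_effects[, treatment, replicate]
  p_new <- if (isotope == "18O" && timepoint == "T7")
    (truth$ape[, treatment] / 100) / config$a_sat else rep(0, n_taxa)

  w_light <- k$gc_intercept + k$gc_slope * truth$taxa$gc
  w_heavy <- wad_shift_for_afe(config$a_sat, w_light, k)

  edges <- seq(g$density_min, g$density_max, length.out = g$n_fractions + 1)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  bin_mass <- function(mu) {       # taxa x bins band integrals
    p <- outer(mu, edges, function(m, e) stats::pnorm(e, m, g$band_sd))
    p[, -1, drop = FALSE] - p[, -ncol(p), drop = FALSE]
  }
  share <- (1 - p_new) * bin_mass(w_light) + p_new * bin_mass(w_heavy)
  lost <- 1 - rowSums(share)
  if (any(lost > 1e-6))
    warning(sum(lost > 1e-6), " taxon band(s) extend beyond the collected ",
            "gradient in tube ", tube_id, "; mass truncated")
  M <- copies * share                       # taxa x bins, gene copies

  # collection order: fraction 1 = densest bin
  ord <- if (config$density_orientation == "heavy_first")
    rev(seq_len(g$n_fractions)) else seq_len(g$n_fractions)
  M <- M[, ord, drop = FALSE]
  dens <- centers[ord]

  tot_true <- colSums(M)
  mass_share <- if (sum(tot_true) > 0) tot_true / sum(tot_true) else tot_true
  if (g$noise) {
    tot <- tot_true * rlnorm_cv(g$n_fractions, g$qpcr_cv)
    conc <- g$tube_dna_ng * mass_share / g$fraction_vol_ul *
      rlnorm_cv(g$n_fractions, g$conc_cv)
  } else {
    tot <- tot_true
    conc <- g$tube_dna_ng * mass_share / g$fraction_vol_ul
  }
  sequenced <- conc > g$conc_cutoff

  fractions <- data.frame(tube_id = tube_id,
                          fraction_index = seq_len(g$n_fractions),
                          density_g_ml = dens, dna_conc_ng_ul = conc,
                          total_16s_copies = tot, sequenced = sequenced,
                          stringsAsFactors = FALSE)

  cl <- vector("list", g$n_fractions)
  for (f in which(sequenced)) {
    if (sum(M[, f]) <= 0) next
    cnt <- if (g$noise)
      as.numeric(stats::rmultinom(1, g$read_depth, M[, f]))
    else round(M[, f])
    keep <- cnt > 0
    if (!any(keep)) next
    cl[[f]] <- data.frame(tube_id = tube_id, fraction_index = f,
                          asv_id = truth$taxa$asv_id[keep],
                          count = cnt[keep], stringsAsFactors = FALSE)
  }
  counts <- do.call(rbind, cl[!vapply(cl, is.null, logical(1))])
  if (is.null(counts))
    counts <- data.frame(tube_id = character(), fraction_index = integer(),
                         asv_id = character(), count = numeric())
  list(fractions = fractions, counts = counts)
}

#' Simulate the full experiment
#'
#' Generates every tube of the design (per treatment and replicate: a T0
#' 16O tube, a T7 16O tube and a T7 18O tube), per-treatment CO2 efflux,
#' and assembles a validated bundle together with the ground-truth
#' ledger. All randomness descends from `seed` through named substreams
#' (one per tube), so any subset of tubes is reproducible.
#'
#' @param design A [qsip_design()].
#' @param seed Integer master seed.
#' @param config A [qsip_config()].
#' @param truth Optional pre-built [make_taxa()] truth (e.g. with
#'   hand-set APE values); defaults to drawing one from `design`.
#' @return A list of class `qsip_sim`: `bundle` (a `qsip_bundle`) and
#'   `truth` (a `qsip_truth`).
#' @examples
#' sim <- generate_experiment(qsip_design(n_taxa = 40), seed = 1)
#' nrow(sim$bundle$meta)  # 54 tubes under the default design
#' @export
generate_experiment <- function(design = qsip_design(), seed = 1,
                                config = qsip_config(), truth = NULL) {
  truth <- truth %||% make_taxa(design$n_taxa, design, seed)
  trts <- truth$treatments
  layout <- expand.grid(replicate = seq_len(design$n_replicates),
                        moisture = design$moisture, fungal = design$fungal,
                        stringsAsFactors = FALSE)
  sub <- data.frame(timepoint = c("T0", "T7", "T7"),
                    isotope = c("16O", "16O", "18O"))
  fr_l <- list(); ct_l <- list(); meta_l <- list()
  for (i in seq_len(nrow(layout))) {
    tr <- paste(layout$fungal[i], layout$moisture[i], sep = "_")
    r <- layout$replicate[i]
    for (j in seq_len(nrow(sub))) {
      tube_id <- sprintf("%s_r%d_%s_%s", tr, r, sub$timepoint[j],
                         sub$isotope[j])
      tube <- simulate_tube(truth, tr, sub$isotope[j], design$gradient,
                            seed = substream_seed(seed, tube_id),
                            replicate = r, timepoint = sub$timepoint[j],
                            tube_id = tube_id, config = config)
      fr_l[[tube_id]] <- tube$fractions
      ct_l[[tube_id]] <- tube$counts
      meta_l[[tube_id]] <- data.frame(
        tube_id = tube_id, microcosm_id = sprintf("%s_r%d", tr, r),
        fungal = layout$fungal[i], moisture = layout$moisture[i],
        isotope = sub$isotope[j], timepoint = sub$timepoint[j],
        replicate = r, stringsAsFactors = FALSE)
    }
  }
  set.seed(substream_seed(seed, "co2"))
  mu <- design$co2_mean
  if (is.null(names(mu))) mu <- stats::setNames(rep(mu, length(trts))[seq_along(trts)], trts)
  co2 <- do.call(rbind, lapply(trts, function(tr)
    data.frame(treatment = tr, replicate = seq_len(design$n_replicates),
               co2_efflux = mu[[tr]] *
                 rlnorm_cv(design$n_replicates, design$co2_cv),
               stringsAsFactors = FALSE)))
  taxonomy <- truth$taxa[, c("asv_id", "domain", "phylum", "class",
                             "order", "family", "genus")]
  cfg <- config
  cfg$cutoff_ng_ul <- design$gradient$conc_cutoff
  bundle <- as_qsip_bundle(do.call(rbind, fr_l), do.call(rbind, meta_l),
                           do.call(rbind, ct_l), taxonomy, co2, cfg)
  structure(list(bundle = bundle, truth = truth, seed = seed),
            class = "qsip_sim")
}

#' Write a simulated experiment to disk
#'
#' Writes the five input tables of [read_experiment()] plus the
#' ground-truth ledger (`truth.tsv`, one row per ASV x treatment).
#'
#' @param sim A [generate_experiment()] result.
#' @param out_dir Output directory.
#' @return File manifest, invisibly.
#' @export
write_simulation <- function(sim, out_dir) {
  b <- sim$bundle
  truth_long <- do.call(rbind, lapply(sim$truth$treatments, function(tr)
    data.frame(asv_id = rownames(sim$truth$ape), treatment = tr,
               gc = sim$truth$taxa$gc, true_ape = sim$truth$ape[, tr],
               true_abund = sim$truth$abund[, tr],
               stringsAsFactors = FALSE)))
  write_results(list(fractions = b$fractions,
                     samples = b$meta[setdiff(names(b$meta), "treatment")],
                     counts = b$counts, taxonomy = b$taxonomy,
                     co2 = b$co2, truth = truth_long),
                out_dir, seed = sim$seed)
}

#' Compare pipeline estimates with simulator ground truth
#'
#' @param truth A `qsip_truth`.
#' @param fit A [qsip()] fit run on the matching simulated bundle.
#' @return A list of class `qsip_recovery`: the per-estimate join
#'   (`detail`) and summary metrics - median absolute APE error among
#'   truly active taxa, empirical coverage of the nominal CIs,
#'   active-classification confusion matrix and false-positive rate,
#'   and median relative growth-rate error among truly active taxa.
#' @export
truth_recovery_report <- function(truth, fit) {
  est <- fit$enrichment
  est <- est[!is.na(est$ape_median), ]
  if (!all(est$asv_id %in% rownames(truth$ape)))
    qsip_error("qsip_referential_error",
               "fit contains ASV ids absent from the truth ledger")
  if (!all(est$treatment %in% truth$treatments))
    qsip_error("qsip_referential_error",
               "fit contains treatments absent from the truth ledger")
  ij <- cbind(match(est$asv_id, rownames(truth$ape)),
              match(est$treatment, truth$treatments))
  true_ape <- truth$ape[ij]
  d <- data.frame(est[c("asv_id", "treatment", "ape_median",
                        "ci_low", "ci_high", "active")],
                  true_ape = true_ape,
                  ape_error = est$ape_median - true_ape,
                  covered = est$ci_low <= true_ape & true_ape <= est$ci_high,
                  true_active = true_ape > 0)
  # truth-side growth rate: expected T7 totals from the design constants
  g <- truth$design$gradient
  n_true <- g$tube_total_16s * truth$abund[ij] *
    apply(truth$rep_effects, c(1, 2), mean)[ij]
  b_true <- n_true * (true_ape / 100) / fit$config$a_sat / fit$config$t
  gr <- merge(d, fit$growth[c("asv_id", "treatment", "b")],
              by = c("asv_id", "treatment"))
  gr$b_true <- b_true[match(paste(gr$asv_id, gr$treatment),
                            paste(d$asv_id, d$treatment))]
  act <- d$true_active
  conf <- table(factor(d$true_active, c(FALSE, TRUE), c("inactive", "active")),
                factor(d$active, c(FALSE, TRUE), c("called_inactive", "called_active")))
  res <- list(
    detail = d,
    n = nrow(d),
    median_abs_ape_error_active = stats::median(abs(d$ape_error[act])),
    coverage = mean(d$covered),
    coverage_active = mean(d$covered[act]),
    confusion = conf,
    false_positive_rate = if (any(!act)) mean(d$active[!act]) else NA_real_,
    sensitivity = if (any(act)) mean(d$active[act]) else NA_real_,
    median_rel_b_error_active =
      stats::median(abs(gr$b - gr$b_true)[gr$true_active] /
                      abs(gr$b_true)[gr$true_active]))
  class(res) <- "qsip_recovery"
  res
}

#' @export
print.qsip_recovery <- function(x, ...) {
  cat("qSIP truth-recovery report (", x$n, " ASV x treatment estimates)\n",
      sep = "")
  cat(sprintf("  median |APE error| (active taxa): %.3f points\n",
              x$median_abs_ape_error_active))
  cat(sprintf("  90%% CI coverage: %.1f%% (active: %.1f%%)\n",
              100 * x$coverage, 100 * x$coverage_active))
  cat(sprintf("  false-positive rate: %s, sensitivity: %s\n",
              format(x$false_positive_rate), format(x$sensitivity)))
  print(x$confusion)
  invisible(x)
}
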