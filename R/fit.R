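#' Fit the qSIP growth model to an experiment
#'
#' The package's central estimator. For every treatment with labeled
#' (18O) tubes it:
#' \enumerate{
#'   \item applies the replicate-presence filter
#'     ([filter_replicate_presence()]);
#'   \item computes per-tube taxon profiles (WAD and total gene copies,
#'     [tube_taxon_profiles()]);
#'   \item bootstrap-estimates each retained ASV's 18O atom percent
#'     excess with a replicate-level percentile interval
#'     ([bootstrap_ape()]);
#'   \item classifies actively growing ASVs (lower CI bound > 0,
#'     [classify_active()]);
#'   \item converts APE and T7 abundance to linear growth potential
#'     ([growth_potential()]).
#' }
#'
#' @param bundle A `qsip_bundle` from [read_experiment()] or
#'   [generate_experiment()].
#' @param n_boot Bootstrap iterations per estimate.
#' @param ci_level Bootstrap confidence level.
#' @param seed Integer seed; the whole fit is deterministic given it.
#' @param light_tubes `"T7"` (default): unlabeled WADs from the T7 16O
#'   tubes, one per replicate; `"all16O"`: include the T0 tubes in the
#'   unlabeled baseline as well.
#' @param include_t0_presence Count T0 tubes in the replicate-presence
#'   filter.
#' @param config Overrides the bundle's [qsip_config()].
#' @return An object of class `qsip_fit` with components `enrichment`
#'   (per ASV x treatment: `ape_median`, `ci_low`, `ci_high`, `n_boot`,
#'   `active`, replicate counts, skip code), `growth` (per ASV x
#'   treatment: `ape`, `n_total`, `n_light`, `b`, `cells_b`, `p_new`,
#'   `t`, `n_t0`), `whitelist`, `wads`, `config`, `seed`, `call`.
#' @examples
#' sim <- generate_experiment(qsip_design(
#'   fungal = "uninoculated", moisture = "replete", n_taxa = 30), seed = 1)
#' fit <- qsip(sim$bundle, n_boot = 200, seed = 1)
#' fit
#' @export
qsip <- function(bundle, n_boot = 1000, ci_level = 0.90, seed = 1,
                 light_tubes = c("T7", "all16O"),
                 include_t0_presence = FALSE, config = NULL) {
  stopifnot(inherits(bundle, "qsip_bundle"))
  light_tubes <- match.arg(light_tubes)
  config <- config %||% bundle$config
  k <- config$constants
  meta <- bundle$meta
  trts <- sort(unique(meta$treatment[meta$timepoint == "T7" &
                                       meta$isotope == "18O"]))
  if (length(trts) == 0)
    qsip_error("qsip_data_error", "no T7 18O tubes: nothing to estimate")

  whitelist <- filter_replicate_presence(bundle, include_t0_presence)
  profiles <- tube_taxon_profiles(bundle)
  pkey <- paste(profiles$tube_id, profiles$asv_id)

  look <- function(tubes, asvs, what) {
    m <- matrix(NA_real_, length(asvs), length(tubes),
                dimnames = list(asvs, tubes))
    for (j in seq_along(tubes)) {
      idx <- match(paste(tubes[j], asvs), pkey)
      m[, j] <- profiles[[what]][idx]
    }
    if (what == "n_total") m[is.na(m)] <- 0   # absent taxon = 0 copies
    m
  }

  set.seed(substream_seed(seed, "bootstrap"))
  enr_l <- list(); grw_l <- list(); wads <- list()
  for (tr in trts) {
    sub <- meta[meta$treatment == tr, ]
    ord <- order(sub$replicate)
    lab_tubes <- sub$tube_id[sub$timepoint == "T7" & sub$isotope == "18O"][
      order(sub$replicate[sub$timepoint == "T7" & sub$isotope == "18O"])]
    light_sel <- sub$isotope == "16O" &
      (sub$timepoint == "T7" | light_tubes == "all16O")
    light_tubes_id <- sub$tube_id[light_sel][order(sub$replicate[light_sel])]
    t7_tubes <- sub$tube_id[sub$timepoint == "T7"]
    t0_tubes <- sub$tube_id[sub$timepoint == "T0"]
    asvs <- whitelist[[tr]]
    if (length(asvs) == 0) next
    wl <- look(light_tubes_id, asvs, "wad")
    wh <- look(lab_tubes, asvs, "wad")
    n7 <- look(t7_tubes, asvs, "n_total")
    n0 <- if (length(t0_tubes)) look(t0_tubes, asvs, "n_total") else
      matrix(NA_real_, length(asvs), 0)
    wads[[tr]] <- list(asv_id = asvs, light = wl, labeled = wh)
    est <- do.call(rbind, lapply(seq_along(asvs), function(i)
      bootstrap_ape(wl[i, ], wh[i, ], k, n_iter = n_boot,
                    ci_level = ci_level)))
    est <- data.frame(asv_id = asvs, treatment = tr, est,
                      stringsAsFactors = FALSE)
    est$active <- classify_active(est)
    enr_l[[tr]] <- est

    n_total <- rowMeans(n7)
    gp <- growth_potential(n_total, est$ape_median / 100,
                           a_sat = config$a_sat, t = config$t,
                           copies_per_cell = config$copies_per_cell)
    grw_l[[tr]] <- data.frame(asv_id = asvs, treatment = tr,
                              ape = est$ape_median, gp,
                              n_t0 = if (ncol(n0)) rowMeans(n0) else NA_real_,
                              stringsAsFactors = FALSE)
  }
  fit <- structure(list(enrichment = do.call(rbind, c(enr_l, make.row.names = FALSE)),
                        growth = do.call(rbind, c(grw_l, make.row.names = FALSE)),
                        whitelist = whitelist, wads = wads,
                        config = config, n_boot = n_boot,
                        ci_level = ci_level, seed = seed,
                        light_tubes = light_tubes,
                        call = match.call()),
                   class = "qsip_fit")
  fit
}

#' @export
print.qsip_fit <- function(x, ...) {
  e <- x$enrichment
  cat("qSIP growth-potential fit\n")
  cat(sprintf("  %d ASV x treatment estimates across %d treatment(s)\n",
              nrow(e), length(unique(e$treatment))))
  cat(sprintf("  bootstrap: %d iterations, %.0f%% percentile CI, seed %d\n",
              x$n_boot, 100 * x$ci_level, x$seed))
  ok <- !is.na(e$ape_median)
  cat(sprintf("  active: %d / %d estimated (%.1f%%)\n",
              sum(e$active[ok]), sum(ok), 100 * mean(e$active[ok])))
  invisible(x)
}

#' @export
summary.qsip_fit <- function(object, ...) {
  e <- object$enrichment
  sp <- split(e, e$treatment)
  tab <- do.call(rbind, lapply(names(sp), function(tr) {
    s <- sp[[tr]]; ok <- !is.na(s$ape_median)
    act <- ok & s$active
    data.frame(treatment = tr, n_retained = nrow(s), n_estimated = sum(ok),
               n_active = sum(act),
               median_ape_active = if (any(act))
                 stats::median(s$ape_median[act]) else NA_real_,
               max_ape = if (any(ok)) max(s$ape_median[ok]) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  structure(list(table = tab, n_boot = object$n_boot,
                 ci_level = object$ci_level), class = "summary.qsip_fit")
}

#' @export
print.summary.qsip_fit <- function(x, ...) {
  cat(sprintf("qSIP fit summary (%d bootstrap iterations, %.0f%% CI)\n",
              x$n_boot, 100 * x$ci_level))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.qsip_fit <- function(object, ...) {
  e <- object$enrichment
  asv <- sort(unique(e$asv_id)); tr <- sort(unique(e$treatment))
  m <- matrix(NA_real_, length(asv), length(tr), dimnames = list(asv, tr))
  m[cbind(match(e$asv_id, asv), match(e$treatment, tr))] <- e$ape_median
  m
}

#' @export
plot.qsip_fit <- function(x, active_only = TRUE, ...) {
  e <- x$enrichment[!is.na(x$enrichment$ape_median), ]
  if (active_only) e <- e[e$active, ]
  if (nrow(e) == 0) {
    warning("nothing to plot")
    return(invisible(x))
  }
  op <- graphics::par(mar = c(9, 4, 2, 1)); on.exit(graphics::par(op))
  graphics::boxplot(ape_median ~ treatment, data = e, las = 2,
                    ylab = expression({}^18 * "O atom percent excess"),
                    xlab = "", main = "Taxon growth potential", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

default_comparisons <- function(treatments) {
  cmp <- list()
  fung <- unique(sub("_(replete|limited)$", "", treatments))
  for (f in fung) {
    a <- paste0(f, "_limited"); b <- paste0(f, "_replete")
    if (all(c(a, b) %in% treatments))
      cmp[[paste0(f, ":limited_vs_replete")]] <- c(a, b)
  }
  for (f in setdiff(fung, "uninoculated")) {
    a <- paste0(f, "_limited"); b <- "uninoculated_limited"
    if (all(c(a, b) %in% treatments))
      cmp[[paste0(f, "_vs_uninoculated:limited")]] <- c(a, b)
  }
  cmp
}

#' Run the full analysis pipeline
#'
#' simulate/read -> fit -> compare -> summarise, writing every result
#' table and a manifest. Comparisons default to water-limited vs
#' water-replete within each fungal condition plus each fungal inoculum
#' vs uninoculated within water-limited soil.
#'
#' @param bundle A `qsip_bundle`.
#' @param out_dir Output directory for [write_results()].
#' @param seed Seed passed to [qsip()].
#' @param n_boot Bootstrap iterations.
#' @param comparisons Named list of `c(treatment_a, treatment_b)` pairs;
#'   `NULL` for the defaults.
#' @param n_top_phyla Reporting filter for phylum-level tables.
#' @param ... Passed on to [qsip()].
#' @return A list of class `qsip_run`: `fit`, `tables`, `manifest`,
#'   `out_dir`.
#' @export
run_pipeline <- function(bundle, out_dir, seed = 1, n_boot = 1000,
                         comparisons = NULL, n_top_phyla = 10, ...) {
  fit <- qsip(bundle, n_boot = n_boot, seed = seed, ...)
  est <- fit$enrichment
  trts <- unique(est$treatment)
  comparisons <- comparisons %||% default_comparisons(trts)
  phyla <- top_phyla(bundle, n_top_phyla)

  ratios_asv <- list(); ratios_phylum <- list()
  for (nm in names(comparisons)) {
    cmp <- comparisons[[nm]]
    rt <- ape_ratio_table(fit, cmp[1], cmp[2])
    if (nrow(rt)) {
      ratios_asv[[nm]] <- data.frame(comparison = nm, rt,
                                     stringsAsFactors = FALSE)
      pt <- phylum_ratio_test(rt, bundle$taxonomy, phyla = phyla)
      if (nrow(pt))
        ratios_phylum[[nm]] <- data.frame(comparison = nm, pt,
                                          stringsAsFactors = FALSE)
    }
  }
  act_growth <- fit$growth[
    fit$growth$asv_id %in% est$asv_id[!is.na(est$active) & est$active] &
      paste(fit$growth$asv_id, fit$growth$treatment) %in%
        paste(est$asv_id, est$treatment)[!is.na(est$active) & est$active], ]
  by_phy <- gross_growth_by_group(act_growth, bundle$taxonomy, "phylum",
                                  t = fit$config$t, groups = phyla)
  gross <- stats::aggregate(gross_growth ~ treatment,
                            gross_growth_by_group(act_growth,
                                                  bundle$taxonomy, "phylum",
                                                  t = fit$config$t), sum)
  eff <- growth_efficiency(gross, bundle$co2)
  tables <- list(
    enrichment = est,
    growth = fit$growth,
    median_ape = treatment_median_ape(fit),
    ratios_asv = if (length(ratios_asv)) do.call(rbind, c(ratios_asv, make.row.names = FALSE)) else
      data.frame(comparison = character(), asv_id = character(),
                 ape_a = numeric(), ape_b = numeric(), ratio = numeric()),
    ratios_phylum = if (length(ratios_phylum)) do.call(rbind, c(ratios_phylum, make.row.names = FALSE)) else
      data.frame(comparison = character(), phylum = character(),
                 mean_ratio = numeric(), se = numeric(),
                 n_asvs = integer(), p_raw = numeric(), p_adj = numeric(),
                 significant = logical()),
    growth_by_phylum = by_phy,
    diversity = diversity_table(fit, bundle),
    efficiency = eff)
  manifest <- write_results(tables, out_dir, seed = seed)
  structure(list(fit = fit, tables = tables, manifest = manifest,
                 out_dir = out_dir), class = "qsip_run")
}

#' @export
print.qsip_run <- function(x, ...) {
  cat("qSIP pipeline run ->", x$out_dir, "\n")
  print(x$manifest, row.names = FALSE)
  invisible(x)
}

#' Render a plain-text (and HTML) summary of a pipeline run
#'
#' Re-reads the result tables written by [run_pipeline()] and writes
#' `report.txt` and `report.html` into the run directory. Regeneration
#' is idempotent.
#'
#' @param run_dir Directory written by [run_pipeline()].
#' @return Path of the text report, invisibly.
#' @export
report <- function(run_dir) {
  tb <- read_results(run_dir)
  need <- c("enrichment", "median_ape", "growth_by_phylum",
            "ratios_phylum", "diversity", "efficiency")
  miss <- setdiff(need, names(tb))
  if (length(miss))
    qsip_error("qsip_io_error",
               paste("run directory lacks table(s):",
                     paste(miss, collapse = ", ")))
  out <- character()
  put <- function(...) out <<- c(out, sprintf(...))
  put("qSIP analysis report")
  put("====================")
  e <- tb$enrichment
  ok <- !is.na(e$ape_median)
  put("Estimates: %d ASV x treatment (%d active)", nrow(e),
      sum(e$active[ok], na.rm = TRUE))
  put("")
  put("Median APE by treatment (pooled over active ASVs):")
  mp <- tb$median_ape[tb$median_ape$replicate == "pooled", ]
  if (nrow(mp) == 0 || all(is.na(mp$median_ape))) {
    put("  no active taxa in any treatment")
  } else {
    for (i in seq_len(nrow(mp)))
      put("  %-40s %8.2f APE  (n = %d)", mp$treatment[i],
          mp$median_ape[i], mp$n_asvs[i])
  }
  put("")
  put("Gross growth by phylum (top phyla, copies g-1 over assay):")
  if (nrow(tb$growth_by_phylum) == 0) {
    put("  no active taxa")
  } else {
    g <- tb$growth_by_phylum
    for (tr in unique(g$treatment)) {
      put("  %s:", tr)
      s <- g[g$treatment == tr, ]
      s <- s[order(-s$gross_growth), ]
      for (i in seq_len(nrow(s)))
        put("    %-22s %12.4g (%d ASVs)", s$phylum[i], s$gross_growth[i],
            s$n_asvs[i])
    }
  }
  put("")
  put("Phylum-level APE ratio tests:")
  r <- tb$ratios_phylum
  if (nrow(r) == 0) {
    put("  no comparable active taxa")
  } else {
    for (cm in unique(r$comparison)) {
      s <- r[r$comparison == cm, ]
      put("  %s (%d phyla):", cm, nrow(s))
      for (i in seq_len(nrow(s)))
        put("    %-22s mean ratio %6.3f  p_adj %7.4f%s", s$phylum[i],
            s$mean_ratio[i], s$p_adj[i],
            if (isTRUE(s$significant[i])) " *" else "")
    }
  }
  put("")
  put("Inverse Simpson diversity (mean over tubes):")
  d <- stats::aggregate(inverse_simpson ~ treatment + mode, tb$diversity,
                        mean, na.rm = TRUE)
  for (i in seq_len(nrow(d)))
    put("  %-40s %-7s %8.2f", d$treatment[i], d$mode[i],
        d$inverse_simpson[i])
  put("")
  put("Growth efficiency (gross growth / CO2 efflux):")
  f <- tb$efficiency
  for (i in seq_len(nrow(f)))
    put("  %-40s %12.4g", f$treatment[i], f$efficiency[i])
  txt <- file.path(run_dir, "report.txt")
  writeLines(out, txt)
  writeLines(c("<html><body><pre>",
               gsub("<", "&lt;", out, fixed = TRUE),
               "</pre></body></html>"),
             file.path(run_dir, "report.html"))
  invisible(txt)
}
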