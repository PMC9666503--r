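#' qSIP-filtered community view
#'
#' Restricts a community profile to its actively growing members (or
#' returns the total view) and renormalises relative abundances.
#'
#' @param abund Named numeric vector of (relative or absolute)
#'   abundances per ASV.
#' @param active Character vector of active ASV ids (used only for
#'   `mode = "active"`).
#' @param mode `"total"` or `"active"`.
#' @return Named numeric vector of relative abundances summing to 1; a
#'   zero-length vector (with a warning) when no active member remains.
#' @export
qsip_filter_community <- function(abund, active = character(),
                                  mode = c("total", "active")) {
  mode <- match.arg(mode)
  if (any(abund < 0)) stop("abundances must be non-negative")
  if (mode == "active") abund <- abund[names(abund) %in% active]
  abund <- abund[abund > 0]
  if (length(abund) == 0 || sum(abund) == 0) {
    warning("no ", mode, " taxa with positive abundance; empty view")
    return(stats::setNames(numeric(0), character(0)))
  }
  abund / sum(abund)
}

#' Inverse Simpson diversity
#'
#' D = 1 / sum(p_i^2) on renormalised relative abundances; ranges from 1
#' (single taxon) to the richness (uniform community).
#'
#' @param rel_abundances Non-negative abundances (renormalised
#'   internally).
#' @return The index, or `NA` (with a warning) for an empty community.
#' @examples
#' inverse_simpson(c(0.5, 0.3, 0.2))  # 1 / 0.38
#' @export
inverse_simpson <- function(rel_abundances) {
  if (any(rel_abundances < 0)) stop("abundances must be non-negative")
  if (length(rel_abundances) == 0 || sum(rel_abundances) == 0) {
    warning("empty community; inverse Simpson undefined")
    return(NA_real_)
  }
  as.numeric(vegan::diversity(rel_abundances, index = "invsimpson"))
}

#' Per-sample diversity of total and qSIP-filtered communities
#'
#' For every T7 tube, pools copy-number-scaled ASV abundances over its
#' sequenced fractions and computes the Inverse Simpson index of the
#' total community and of the actively growing subset (ASVs classified
#' active in the tube's treatment, renormalised).
#'
#' @param fit A [qsip()] fit.
#' @param bundle The bundle the fit was computed from.
#' @param modes Subset of `c("total", "active")`.
#' @return data.frame: `tube_id`, `treatment`, `mode`,
#'   `inverse_simpson`, `richness`.
#' @export
diversity_table <- function(fit, bundle, modes = c("total", "active")) {
  prof <- tube_taxon_profiles(bundle)
  meta <- bundle$meta
  t7 <- meta[meta$timepoint == "T7", ]
  est <- fit$enrichment
  out <- list()
  for (i in seq_len(nrow(t7))) {
    tube <- t7$tube_id[i]; tr <- t7$treatment[i]
    p <- prof[prof$tube_id == tube & prof$n_total > 0, ]
    ab <- stats::setNames(p$n_total, p$asv_id)
    act <- est$asv_id[est$treatment == tr & !is.na(est$active) & est$active]
    for (m in modes) {
      v <- suppressWarnings(qsip_filter_community(ab, act, m))
      out[[paste(tube, m)]] <- data.frame(
        tube_id = tube, treatment = tr, mode = m,
        inverse_simpson = if (length(v)) inverse_simpson(v) else NA_real_,
        richness = length(v), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Gross growth aggregated by taxonomic group
#'
#' New gene copies synthesised over the assay (b_i * t, the linear-growth
#' convention) summed over the member ASVs of each group.
#'
#' @param growth The `growth` table of a [qsip()] fit, usually
#'   restricted to active ASVs.
#' @param taxonomy Taxonomy table (`asv_id` plus rank columns).
#' @param level Rank column to group by.
#' @param t Assay duration, days.
#' @param groups Optional restriction (e.g. [top_phyla()]).
#' @return data.frame: `treatment`, group column, `gross_growth`
#'   (copies g^-1 over the assay), `n_asvs`.
#' @export
gross_growth_by_group <- function(growth, taxonomy, level = "phylum",
                                  t = 7, groups = NULL) {
  if (!level %in% names(taxonomy))
    stop("taxonomy has no rank column '", level, "'")
  grp <- taxonomy[[level]][match(growth$asv_id, taxonomy$asv_id)]
  grp[is.na(grp) | grp == ""] <- "unclassified"
  d <- data.frame(treatment = growth$treatment, group = grp,
                  new_copies = growth$b * t, stringsAsFactors = FALSE)
  if (!is.null(groups)) d <- d[d$group %in% groups, , drop = FALSE]
  agg <- stats::aggregate(new_copies ~ treatment + group, d, sum)
  n <- stats::aggregate(new_copies ~ treatment + group, d, length)
  out <- data.frame(treatment = agg$treatment, group = agg$group,
                    gross_growth = agg$new_copies, n_asvs = n$new_copies,
                    stringsAsFactors = FALSE)
  names(out)[2] <- level
  out[order(out$treatment, out[[level]]), , drop = FALSE]
}

#' Growth efficiency per treatment
#'
#' The proxy metric: gross bacterial growth (new 16S rRNA gene copies
#' g^-1 over the assay, summed over active taxa) divided by CO2 efflux.
#' The composite unit string is carried, never converted.
#'
#' @param gross_growth data.frame with `treatment` and `gross_growth`
#'   (total new copies g^-1 per treatment).
#' @param co2 CO2 table (`treatment`, `co2_efflux`, one row per
#'   replicate); replicates are averaged per treatment.
#' @return data.frame: `treatment`, `gross_growth`, `co2`, `efficiency`,
#'   `unit`. Treatments with non-positive CO2 get `NA` efficiency and a
#'   warning.
#' @export
growth_efficiency <- function(gross_growth, co2) {
  co2m <- stats::aggregate(co2_efflux ~ treatment, co2, mean)
  m <- merge(gross_growth, co2m, by = "treatment", all.x = TRUE)
  bad <- is.na(m$co2_efflux) | m$co2_efflux <= 0
  if (any(bad))
    warning("non-positive or missing CO2 for treatment(s): ",
            paste(m$treatment[bad], collapse = ", "),
            "; efficiency undefined")
  eff <- ifelse(bad, NA_real_, m$gross_growth / m$co2_efflux)
  data.frame(treatment = m$treatment, gross_growth = m$gross_growth,
             co2 = m$co2_efflux, efficiency = eff,
             unit = "copies g-1 per (ug CO2 mg-1 soil C)",
             stringsAsFactors = FALSE)
}

#' Percent change in growth efficiency between paired treatments
#'
#' @param efficiency Output of [growth_efficiency()].
#' @param treatment_ref Reference treatment (e.g. the water-replete
#'   member of a pair).
#' @param treatment_cmp Comparison treatment (e.g. water-limited).
#' @return Percent reduction, `100 * (1 - eff_cmp / eff_ref)`; negative
#'   values mean an increase.
#' @export
efficiency_reduction <- function(efficiency, treatment_ref, treatment_cmp) {
  e <- stats::setNames(efficiency$efficiency, efficiency$treatment)
  if (!treatment_ref %in% names(e) || !treatment_cmp %in% names(e))
    stop("treatment not present in the efficiency table")
  100 * (1 - e[[treatment_cmp]] / e[[treatment_ref]])
}
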