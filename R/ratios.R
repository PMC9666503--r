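#' Pairwise APE ratio
#'
#' Ratio of a taxon's atom percent excess under one treatment to its APE
#' under another; values above 1 mean higher growth potential under the
#' first condition. Defined only for taxa actively growing under both
#' conditions, which guarantees positive denominators.
#'
#' @param ape_a,ape_b APE values (points) under the two conditions.
#' @return `ape_a / ape_b`, vectorised.
#' @export
ape_ratio <- function(ape_a, ape_b) {
  if (any(ape_b <= 0, na.rm = TRUE) || any(ape_a <= 0, na.rm = TRUE))
    stop("ape_ratio is defined only for positive APE ",
         "(both taxa must be actively growing)")
  ape_a / ape_b
}

#' ASV-level APE ratio table for one treatment comparison
#'
#' Joins the fitted enrichment estimates of two treatments, keeps the
#' ASVs classified active under **both**, and forms the per-ASV ratio
#' `ape(treatment_a) / ape(treatment_b)`.
#'
#' @param fit A [qsip()] fit.
#' @param treatment_a,treatment_b Treatment labels as in
#'   `fit$enrichment$treatment` (numerator, denominator).
#' @return data.frame: `asv_id`, `ape_a`, `ape_b`, `ratio`.
#' @export
ape_ratio_table <- function(fit, treatment_a, treatment_b) {
  est <- fit$enrichment
  est <- est[!is.na(est$active) & est$active, ]
  a <- est[est$treatment == treatment_a, c("asv_id", "ape_median")]
  b <- est[est$treatment == treatment_b, c("asv_id", "ape_median")]
  m <- merge(a, b, by = "asv_id", suffixes = c("_a", "_b"))
  if (nrow(m) == 0)
    return(data.frame(asv_id = character(), ape_a = numeric(),
                      ape_b = numeric(), ratio = numeric()))
  data.frame(asv_id = m$asv_id, ape_a = m$ape_median_a,
             ape_b = m$ape_median_b,
             ratio = ape_ratio(m$ape_median_a, m$ape_median_b),
             stringsAsFactors = FALSE)
}

#' Most abundant phyla
#'
#' Ranks phyla by total read count across the experiment (the reporting
#' filter used for phylum-level panels).
#'
#' @param bundle A `qsip_bundle`.
#' @param n Number of phyla to keep.
#' @return Character vector of phylum names, most abundant first.
#' @export
top_phyla <- function(bundle, n = 10) {
  phy <- bundle$taxonomy$phylum[match(bundle$counts$asv_id,
                                      bundle$taxonomy$asv_id)]
  phy[is.na(phy) | phy == ""] <- "unclassified"
  tot <- sort(tapply(bundle$counts$count, phy, sum), decreasing = TRUE)
  utils::head(names(tot), n)
}

#' Phylum-level ratio test
#'
#' Averages the ASV-level APE ratios within each phylum and tests, per
#' phylum, whether the ratios differ from 1 with a two-sided Wilcoxon
#' signed-rank test (exact null distribution for fewer than 25 untied
#' ratios, normal approximation otherwise; ratios exactly 1 drop out as
#' zero differences). P-values are Benjamini-Hochberg adjusted across
#' the phyla of this one comparison.
#'
#' @param ratio_tbl Output of [ape_ratio_table()].
#' @param taxonomy Taxonomy table (`asv_id`, `phylum`).
#' @param phyla Optional restriction (e.g. [top_phyla()]); phyla not
#'   listed are dropped before testing.
#' @param alpha Significance threshold on the adjusted p-value.
#' @return data.frame: `phylum`, `mean_ratio`, `se`, `n_asvs`, `p_raw`,
#'   `p_adj`, `significant`, ordered by phylum.
#' @export
phylum_ratio_test <- function(ratio_tbl, taxonomy, phyla = NULL,
                              alpha = 0.05) {
  phy <- taxonomy$phylum[match(ratio_tbl$asv_id, taxonomy$asv_id)]
  phy[is.na(phy) | phy == ""] <- "unclassified"
  d <- data.frame(ratio = ratio_tbl$ratio, phylum = phy,
                  stringsAsFactors = FALSE)
  if (!is.null(phyla)) d <- d[d$phylum %in% phyla, , drop = FALSE]
  if (nrow(d) == 0)
    return(data.frame(phylum = character(), mean_ratio = numeric(),
                      se = numeric(), n_asvs = integer(),
                      p_raw = numeric(), p_adj = numeric(),
                      significant = logical()))
  res <- lapply(split(d$ratio, d$phylum), function(r) {
    nz <- r[r != 1]                       # zero differences drop out
    p <- if (length(nz) == 0) 1 else {
      exact <- length(nz) < 25 && !anyDuplicated(abs(nz - 1))
      suppressWarnings(
        stats::wilcox.test(nz, mu = 1, exact = exact)$p.value)
    }
    c(mean_ratio = mean(r),
      se = if (length(r) > 1) stats::sd(r) / sqrt(length(r)) else NA_real_,
      n_asvs = length(r), p_raw = p)
  })
  out <- data.frame(phylum = names(res),
                    do.call(rbind, res), row.names = NULL,
                    stringsAsFactors = FALSE)
  out$n_asvs <- as.integer(out$n_asvs)
  out$p_adj <- stats::p.adjust(out$p_raw, method = "BH")
  out$significant <- out$p_adj < alpha
  out[order(out$phylum), , drop = FALSE]
}
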