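#' Replicate-presence filter
#'
#' Keeps, per treatment, only ASVs recovered (at least one read in any
#' sequenced fraction of any tube of the treatment's qSIP set) in
#' **every** replicate. This is the stringent pre-filter applied before
#' any enrichment estimate, ensuring estimates rest on all independent
#' biological replicates.
#'
#' @param bundle A `qsip_bundle`.
#' @param include_t0 Count T0 tubes towards presence (default: the qSIP
#'   set is the T7 tubes of both isotopes).
#' @return Named list, one character vector of ASV ids per treatment.
#' @export
filter_replicate_presence <- function(bundle, include_t0 = FALSE) {
  meta <- bundle$meta
  qset <- meta[meta$timepoint == "T7" | include_t0, , drop = FALSE]
  counts <- bundle$counts[bundle$counts$count > 0, ]
  trts <- unique(qset$treatment)
  out <- vector("list", length(trts)); names(out) <- trts
  for (tr in trts) {
    sub <- qset[qset$treatment == tr, ]
    reps <- unique(sub$replicate)
    if (length(reps) == 0)
      qsip_error("qsip_data_error",
                 paste("treatment", tr, "has no replicates"))
    per_rep <- lapply(reps, function(r) {
      tubes <- sub$tube_id[sub$replicate == r]
      unique(counts$asv_id[counts$tube_id %in% tubes])
    })
    out[[tr]] <- sort(Reduce(intersect, per_rep))
  }
  out
}

#' Bootstrap confidence interval for a taxon's 18O atom percent excess
#'
#' Resamples the replicate-level weighted-average densities with
#' replacement, independently on the unlabeled (16O) and labeled (18O)
#' sides, averages each side, and converts the pair of mean densities to
#' an atom fraction excess. The point estimate is the median of the
#' bootstrap draws (in APE points) and the confidence bounds are the
#' percentile bounds on the same draws, so `ci_low <= ape_median <=
#' ci_high` by construction.
#'
#' @param wad_light Per-replicate WADs from 16O tubes (NAs dropped).
#' @param wad_labeled Per-replicate WADs from 18O tubes (NAs dropped).
#' @param constants A [qsip_constants()].
#' @param n_iter Bootstrap iterations.
#' @param ci_level Confidence level (0.90 gives the 5th/95th
#'   percentiles).
#' @param seed Optional seed; when `NULL` the current RNG stream is
#'   used (callers seed once for a whole run).
#' @return A one-row data.frame: `ape_median`, `ci_low`, `ci_high`,
#'   `n_boot`, `n_light_reps`, `n_lab_reps`, `skip` (NA when estimated;
#'   otherwise a reason code and all numerics NA).
#' @export
bootstrap_ape <- function(wad_light, wad_labeled,
                          constants = qsip_constants(),
                          n_iter = 1000, ci_level = 0.90, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  wl <- wad_light[!is.na(wad_light)]
  wh <- wad_labeled[!is.na(wad_labeled)]
  skip <- if (length(wl) == 0) "missing_16O_side"
          else if (length(wh) == 0) "missing_18O_side" else NA_character_
  if (!is.na(skip))
    return(data.frame(ape_median = NA_real_, ci_low = NA_real_,
                      ci_high = NA_real_, n_boot = n_iter,
                      n_light_reps = length(wl), n_lab_reps = length(wh),
                      skip = skip, stringsAsFactors = FALSE))
  nl <- length(wl); nh <- length(wh)
  ml <- rowMeans(matrix(wl[sample.int(nl, nl * n_iter, replace = TRUE)],
                        n_iter, nl))
  mh <- rowMeans(matrix(wh[sample.int(nh, nh * n_iter, replace = TRUE)],
                        n_iter, nh))
  draws <- 100 * atom_fraction_excess_18O(mh, ml, constants)
  a <- (1 - ci_level) / 2
  q <- stats::quantile(draws, c(a, 1 - a), names = FALSE)
  data.frame(ape_median = stats::median(draws), ci_low = q[1],
             ci_high = q[2], n_boot = n_iter, n_light_reps = nl,
             n_lab_reps = nh, skip = NA_character_,
             stringsAsFactors = FALSE)
}

#' Exhaustive resampling distribution for small replicate sets
#'
#' Enumerates every equally likely with-replacement resample of the two
#' sides (n^n each, e.g. 27 x 27 for 3 + 3 replicates) and returns all
#' side-mean APE combinations. The population this enumerates is exactly
#' what [bootstrap_ape()] samples from, so its percentiles are the
#' infinite-iteration limit of the bootstrap.
#'
#' @inheritParams bootstrap_ape
#' @return Numeric vector of APE values, one per resample pair.
#' @export
enumerate_ape_resamples <- function(wad_light, wad_labeled,
                                    constants = qsip_constants()) {
  wl <- wad_light[!is.na(wad_light)]
  wh <- wad_labeled[!is.na(wad_labeled)]
  side_means <- function(w) {
    n <- length(w)
    idx <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
    rowMeans(matrix(w[idx], nrow(idx), n))
  }
  ml <- side_means(wl); mh <- side_means(wh)
  as.vector(100 * outer(mh, ml, function(h, l)
    atom_fraction_excess_18O(h, l, constants)))
}

#' Activity classification
#'
#' A taxon is actively growing in a treatment when the lower bound of
#' its 90% bootstrap confidence interval on APE exceeds zero (strictly:
#' a bound exactly at zero is not active).
#'
#' @param estimate A data.frame with a `ci_low` column (e.g. rows of
#'   [bootstrap_ape()] output), or a numeric vector of lower bounds.
#' @return Logical vector; `NA` where the estimate was skipped.
#' @export
classify_active <- function(estimate) {
  ci_low <- if (is.data.frame(estimate)) estimate$ci_low else estimate
  ci_low > 0
}

#' Treatment-level median APE
#'
#' The per-treatment summary of growth potential: the median of
#' ASV-level median APE values over retained (by default, actively
#' growing) taxa. Also reports per-replicate medians, where replicate r
#' pairs that replicate's labeled WAD with the mean unlabeled WAD.
#'
#' @param fit A [qsip()] fit.
#' @param treatments Treatments to report (default all fitted).
#' @param active_only Restrict to active ASVs.
#' @return data.frame: `treatment`, `replicate` (`"pooled"` or the
#'   replicate index), `median_ape`, `n_asvs`.
#' @export
treatment_median_ape <- function(fit, treatments = NULL,
                                 active_only = TRUE) {
  est <- fit$enrichment
  if (active_only) est <- est[!is.na(est$active) & est$active, ]
  trts <- treatments %||% sort(unique(fit$enrichment$treatment))
  out <- list()
  for (tr in trts) {
    e <- est[est$treatment == tr, ]
    if (nrow(e) == 0) {
      warning("no ", if (active_only) "active " else "", "ASVs in treatment ",
              tr, "; median APE undefined")
      out[[tr]] <- data.frame(treatment = tr, replicate = "pooled",
                              median_ape = NA_real_, n_asvs = 0L)
      next
    }
    rows <- data.frame(treatment = tr, replicate = "pooled",
                       median_ape = stats::median(e$ape_median),
                       n_asvs = nrow(e))
    w <- fit$wads[[tr]]
    if (!is.null(w)) {
      keep <- match(e$asv_id, w$asv_id)
      n_rep <- ncol(w$labeled)
      for (r in seq_len(n_rep)) {
        wl_bar <- rowMeans(w$light[keep, , drop = FALSE], na.rm = TRUE)
        ape_r <- 100 * atom_fraction_excess_18O(
          w$labeled[keep, r], wl_bar, fit$config$constants)
        rows <- rbind(rows, data.frame(
          treatment = tr, replicate = as.character(r),
          median_ape = stats::median(ape_r, na.rm = TRUE),
          n_asvs = sum(!is.na(ape_r))))
      }
    }
    out[[tr]] <- rows
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}
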