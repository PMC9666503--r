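#' Absolute ASV abundance within one gradient fraction
#'
#' Scales the relative read abundance of each ASV in a sequenced fraction
#' by the total 16S rRNA gene copy number measured in that fraction by
#' qPCR, giving per-ASV gene copies on the basis of the qPCR totals.
#'
#' @param counts Non-negative read counts, one per ASV (names kept).
#' @param total_16s_copies Total 16S rRNA gene copies in the fraction.
#' @return Numeric vector of gene copies per ASV, summing to
#'   `total_16s_copies` (all zero when no reads were observed).
#' @examples
#' fraction_absolute_abundance(c(a = 10, b = 30), 8e6)
#' @export
fraction_absolute_abundance <- function(counts, total_16s_copies) {
  if (any(counts < 0) || total_16s_copies < 0)
    stop("counts and total_16s_copies must be non-negative")
  s <- sum(counts)
  if (s == 0) return(counts * 0)
  counts / s * total_16s_copies
}

#' Weighted-average buoyant density (WAD) of a taxon in one tube
#'
#' The abundance-weighted mean of fraction densities, the taxon's mean
#' equilibrium position in the CsCl gradient.
#'
#' @param copies_per_fraction Gene copies of the taxon in each sequenced
#'   fraction.
#' @param densities Fraction buoyant densities (g mL^-1), aligned with
#'   `copies_per_fraction`.
#' @return The WAD (g mL^-1), or `NA_real_` when the taxon has zero
#'   copies in the tube (its WAD is undefined).
#' @examples
#' weighted_average_density(c(1, 3), c(1.70, 1.72))  # 1.715
#' @export
weighted_average_density <- function(copies_per_fraction, densities) {
  if (length(copies_per_fraction) != length(densities))
    stop("copies_per_fraction and densities must be aligned")
  if (any(copies_per_fraction < 0)) stop("copies must be non-negative")
  s <- sum(copies_per_fraction)
  if (s == 0) return(NA_real_)
  sum(densities * copies_per_fraction) / s
}

#' GC content from unlabeled buoyant density
#'
#' Inverts the linear density-GC calibration: DNA density varies with GC
#' content even without isotope incorporation, so the unlabeled WAD fixes
#' each taxon's GC fraction and thereby its unlabeled molecular weight.
#'
#' @param w_light Unlabeled (16O) WAD, g mL^-1. Vectorised.
#' @param constants A [qsip_constants()] object.
#' @return GC fraction; values outside [0, 1] are kept but trigger a
#'   warning (they indicate densities outside the calibration range).
#' @export
gc_from_unlabeled_density <- function(w_light, constants = qsip_constants()) {
  g <- (w_light - constants$gc_intercept) / constants$gc_slope
  out <- !is.na(g) & (g < -1e-9 | g > 1 + 1e-9)
  if (any(out))
    warning(sum(out), " GC estimate(s) outside [0, 1]; ",
            "unlabeled density outside the calibration range")
  g
}

#' Mean nucleotide molecular weight of unlabeled DNA
#'
#' @param gc GC fraction. Vectorised.
#' @param constants A [qsip_constants()] object.
#' @return Molecular weight, g mol^-1.
#' @export
molecular_weight_light <- function(gc, constants = qsip_constants()) {
  constants$mw_gc_slope * gc + constants$mw_intercept
}

#' 18O atom fraction excess from the labeled/unlabeled density shift
#'
#' The taxon's labeled molecular weight is the unlabeled weight scaled by
#' the ratio of labeled to unlabeled WAD; the weight gain relative to the
#' maximum possible gain under full 18O substitution, corrected for
#' natural 18O abundance, is the atom fraction excess A. Multiplied by
#' 100 it is the atom percent excess (APE). Negative values arise from
#' density noise and are deliberately retained.
#'
#' @param w_labeled WAD in the 18O-amended tube(s), g mL^-1. Vectorised.
#' @param w_light WAD in the 16O-amended tube(s), g mL^-1.
#' @param constants A [qsip_constants()] object.
#' @return Atom fraction excess (dimensionless; `NA` where either WAD is
#'   undefined).
#' @examples
#' 100 * atom_fraction_excess_18O(1.705, 1.700)  # about 7.49 APE
#' @export
atom_fraction_excess_18O <- function(w_labeled, w_light,
                                     constants = qsip_constants()) {
  gc <- (w_light - constants$gc_intercept) / constants$gc_slope
  m_light <- molecular_weight_light(gc, constants)
  m_lab <- m_light * (w_labeled / w_light)
  (m_lab - m_light) / constants$delta_mw_max_18O *
    (1 - constants$natural_abundance_18O)
}

#' Labeled WAD producing a given atom fraction excess
#'
#' Inverse of [atom_fraction_excess_18O()] in its first argument; the
#' forward model used by the simulator and handy for planning.
#'
#' @param a Target atom fraction excess.
#' @param w_light Unlabeled WAD, g mL^-1.
#' @param constants A [qsip_constants()] object.
#' @return The labeled WAD, g mL^-1.
#' @export
wad_shift_for_afe <- function(a, w_light, constants = qsip_constants()) {
  gc <- (w_light - constants$gc_intercept) / constants$gc_slope
  m_light <- molecular_weight_light(gc, constants)
  w_light * (1 + a * constants$delta_mw_max_18O /
               ((1 - constants$natural_abundance_18O) * m_light))
}

#' Linear growth potential of a taxon
#'
#' Under linear population growth and the assumption that all DNA
#' synthesised during the assay carries the 18O atom fraction of the soil
#' water, the fraction of a taxon's DNA pool that is new at time t is
#' p_new = A / A_sat. The unlabeled (pre-existing) pool is
#' N_LIGHT = N_TOTAL (1 - p_new) and the absolute growth rate is
#' b = (N_TOTAL - N_LIGHT) / t. Negative A propagates to negative b;
#' nothing is clamped, significance is the bootstrap filter's job.
#'
#' @param n_total Total (labeled + unlabeled) gene abundance at time t,
#'   copies g^-1. Vectorised with `a`.
#' @param a Atom fraction excess (not percent).
#' @param a_sat Saturation atom fraction excess of new DNA (see
#'   [qsip_config()]).
#' @param t Assay duration, days.
#' @param copies_per_cell Mean 16S rRNA gene copies per cell used to
#'   express the rate in cells g^-1 day^-1.
#' @return A data.frame with columns `n_total`, `n_light`, `b`
#'   (copies g^-1 day^-1), `cells_b` (cells g^-1 day^-1), `p_new`, `t`.
#' @examples
#' growth_potential(6e8, 0.074857, a_sat = 0.7856, t = 7)
#' @export
growth_potential <- function(n_total, a, a_sat = 0.7876 - 0.002000429,
                             t = 7, copies_per_cell = 6) {
  if (t <= 0) stop("t must be positive")
  if (a_sat <= 0) stop("a_sat must be positive")
  p_new <- a / a_sat
  if (any(p_new > 1, na.rm = TRUE))
    warning(sum(p_new > 1, na.rm = TRUE),
            " super-saturated estimate(s) (p_new > 1) retained")
  n_light <- n_total * (1 - p_new)
  b <- (n_total - n_light) / t
  data.frame(n_total = n_total, n_light = n_light, b = b,
             cells_b = b / copies_per_cell, p_new = p_new, t = t)
}

#' Per-tube taxon profiles: WAD and total abundance
#'
#' For every (tube, ASV) pair with reads, scales fraction-level read
#' counts to gene copies via the fraction qPCR totals
#' ([fraction_absolute_abundance()]) and reduces them to the taxon's WAD
#' and its tube total N (sum over sequenced fractions).
#'
#' @param bundle A validated [read_experiment()] /
#'   [generate_experiment()] bundle.
#' @param asv_ids Optional restriction to a set of ASVs.
#' @return A data.frame: `tube_id`, `asv_id`, `wad`, `n_total`.
#' @export
tube_taxon_profiles <- function(bundle, asv_ids = NULL) {
  counts <- bundle$counts
  if (!is.null(asv_ids)) counts <- counts[counts$asv_id %in% asv_ids, ]
  fr <- bundle$fractions
  key <- paste(fr$tube_id, fr$fraction_index, sep = "\r")
  ckey <- paste(counts$tube_id, counts$fraction_index, sep = "\r")
  idx <- match(ckey, key)
  dens <- fr$density_g_ml[idx]
  tot <- fr$total_16s_copies[idx]
  # copies_i = count_i / (fraction read total) * fraction qPCR total
  frac_reads <- stats::ave(counts$count, ckey, FUN = sum)
  copies <- ifelse(frac_reads > 0, counts$count / frac_reads * tot, 0)
  g <- paste(counts$tube_id, counts$asv_id, sep = "\r")
  n_total <- rowsum(copies, g)
  wsum <- rowsum(copies * dens, g)
  ids <- do.call(rbind, strsplit(rownames(n_total), "\r", fixed = TRUE))
  out <- data.frame(tube_id = ids[, 1], asv_id = ids[, 2],
                    wad = ifelse(n_total[, 1] > 0, wsum[, 1] / n_total[, 1],
                                 NA_real_),
                    n_total = n_total[, 1], row.names = NULL,
                    stringsAsFactors = FALSE)
  out[order(out$tube_id, out$asv_id), , drop = FALSE]
}
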