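#' Physical calibration constants for the qSIP density model
#'
#' Returns the calibration linking DNA buoyant density, GC content,
#' molecular weight and 18O incorporation used throughout the package.
#' The defaults are the published CsCl calibration for bacterial DNA:
#' unlabeled buoyant density is a linear function of GC content,
#' nucleotide molecular weight is a linear function of GC content, and
#' full 18O substitution of the exchangeable oxygen atoms adds
#' `delta_mw_max_18O` g per mol to the mean nucleotide weight.
#'
#' @param gc_intercept Buoyant density (g mL^-1) of DNA at GC = 0.
#' @param gc_slope Increase in buoyant density (g mL^-1) per unit GC fraction.
#' @param mw_gc_slope Increase in mean nucleotide molecular weight (g mol^-1)
#'   per unit GC fraction.
#' @param mw_intercept Mean nucleotide molecular weight (g mol^-1) at GC = 0.
#' @param delta_mw_max_18O Maximum increase in molecular weight from complete
#'   18O substitution (g mol^-1).
#' @param natural_abundance_18O Background 18O atom fraction in unlabeled DNA.
#'
#' @return A named list of class `qsip_constants`.
#' @examples
#' qsip_constants()
#' @export
qsip_constants <- function(gc_intercept = 1.646057,
                           gc_slope = 0.083506,
                           mw_gc_slope = 0.496,
                           mw_intercept = 307.691,
                           delta_mw_max_18O = 12.07747,
                           natural_abundance_18O = 0.002000429) {
  k <- list(gc_intercept = gc_intercept,
            gc_slope = gc_slope,
            mw_gc_slope = mw_gc_slope,
            mw_intercept = mw_intercept,
            delta_mw_max_18O = delta_mw_max_18O,
            natural_abundance_18O = natural_abundance_18O)
  bad <- names(k)[!vapply(k, function(x) is.numeric(x) && length(x) == 1L && x > 0,
                          logical(1))]
  if (length(bad))
    stop("qsip_constants: all constants must be positive scalars; bad: ",
         paste(bad, collapse = ", "))
  class(k) <- "qsip_constants"
  k
}

#' Analysis configuration
#'
#' Assembles (and optionally reads from a YAML file) the configuration
#' shared by the reader, the estimator and the simulator. Values given
#' as arguments override values in the file, which override defaults.
#'
#' @param path Optional path to a YAML file with any subset of the fields.
#' @param cutoff_ng_ul Sequencing cutoff on per-fraction DNA concentration
#'   (ng uL^-1); fractions at or below it carry qPCR totals but no reads.
#' @param density_orientation `"heavy_first"` (fraction 1 = densest, the
#'   collection order from the tube bottom) or `"light_first"`.
#' @param copies_basis Free-text declaration of the basis of the qPCR
#'   totals (recorded in outputs, never converted).
#' @param a_sat Saturation 18O atom fraction excess of newly synthesised
#'   DNA: the soil-water 18O atom fraction of the labeled incubation minus
#'   natural abundance. Default 0.7876 - 0.002000429.
#' @param t Assay duration in days.
#' @param copies_per_cell Assumed mean 16S rRNA gene copies per cell.
#' @param constants A [qsip_constants()] object.
#' @param ... Further fields stored verbatim (e.g. simulator settings).
#'
#' @return A named list of class `qsip_config`.
#' @export
qsip_config <- function(path = NULL,
                        cutoff_ng_ul = 1.0,
                        density_orientation = c("heavy_first", "light_first"),
                        copies_basis = "copies_per_g_dry_soil",
                        a_sat = 0.7876 - 0.002000429,
                        t = 7,
                        copies_per_cell = 6,
                        constants = qsip_constants(),
                        ...) {
  cfg <- list(cutoff_ng_ul = cutoff_ng_ul,
              density_orientation = match.arg(density_orientation),
              copies_basis = copies_basis,
              a_sat = a_sat,
              t = t,
              copies_per_cell = copies_per_cell,
              constants = constants,
              ...)
  if (!is.null(path)) {
    y <- yaml::read_yaml(path)
    if (!is.null(y$qsip)) {          # constants live under their own key
      kc <- y$qsip
      cfg$constants <- do.call(qsip_constants,
                               kc[intersect(names(kc),
                                            names(formals(qsip_constants)))])
      y$qsip <- NULL
    }
    for (nm in names(y))
      if (!nm %in% names(match.call())[-1]) cfg[[nm]] <- y[[nm]]
  }
  if (!is.numeric(cfg$cutoff_ng_ul) || cfg$cutoff_ng_ul < 0)
    stop("cutoff_ng_ul must be a non-negative number")
  if (cfg$a_sat <= 0) stop("a_sat must be positive")
  if (cfg$t <= 0) stop("assay duration t must be positive")
  class(cfg) <- "qsip_config"
  cfg
}
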