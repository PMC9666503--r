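# Hand-built minimal experiment: one treatment, one replicate pair of
# T7 tubes (16O + 18O), three fractions each, two ASVs. Values chosen so
# every derived quantity is easy to recompute by hand.
minimal_tables <- function() {
  fractions <- data.frame(
    tube_id = rep(c("tube16", "tube18"), each = 3),
    fraction_index = rep(1:3, 2),
    density_g_ml = rep(c(1.72, 1.70, 1.68), 2),
    dna_conc_ng_ul = rep(c(2.0, 5.0, 1.5), 2),
    total_16s_copies = rep(c(2e6, 8e6, 1e6), 2),
    stringsAsFactors = FALSE)
  meta <- data.frame(
    tube_id = c("tube16", "tube18"),
    microcosm_id = "m1",
    fungal = "uninoculated", moisture = "replete",
    isotope = c("16O", "18O"), timepoint = "T7", replicate = 1L,
    stringsAsFactors = FALSE)
  counts <- data.frame(
    tube_id = rep(c("tube16", "tube18"), each = 6),
    fraction_index = rep(rep(1:3, each = 2), 2),
    asv_id = rep(c("a1", "a2"), 6),
    count = c(10, 30, 40, 40, 5, 15,   # 16O tube
              30, 10, 40, 40, 15, 5),  # 18O tube: a1 shifted heavy
    stringsAsFactors = FALSE)
  taxonomy <- data.frame(
    asv_id = c("a1", "a2"), domain = "Bacteria",
    phylum = c("Proteobacteria", "Actinobacteria"),
    class = "c", order = "o", family = "f", genus = c("g1", "g2"),
    stringsAsFactors = FALSE)
  co2 <- data.frame(treatment = "uninoculated_replete", replicate = 1L,
                    co2_efflux = 25, stringsAsFactors = FALSE)
  list(fractions = fractions, samples = meta, counts = counts,
       taxonomy = taxonomy, co2 = co2)
}

minimal_bundle <- function(config = qsip_config()) {
  tb <- minimal_tables()
  as_qsip_bundle(tb$fractions, tb$samples, tb$counts, tb$taxonomy,
                 tb$co2, config)
}

write_minimal_dir <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  tb <- minimal_tables()
  for (nm in names(tb))
    utils::write.table(tb[[nm]], file.path(dir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  dir
}

# A tiny simulated experiment shared by several tests (cheap: 1 fungal
# level x 2 moisture levels, 40 taxa).
small_sim <- function(seed = 7, n_taxa = 40, ...) {
  generate_experiment(
    qsip_design(fungal = "uninoculated", moisture = c("replete", "limited"),
                n_taxa = n_taxa, ...),
    seed = seed)
}

# Independent brute-force recomputation of the whole per-taxon chain on
# a counts/fractions table, written against the definitions, not the
# package internals.
brute_force_chain <- function(counts16, counts18, dens16, dens18,
                              tot16, tot18, a_sat = 0.7876 - 0.002000429,
                              t = 7, n_total = NULL) {
  wad <- function(cnt, dens, tot) {
    copies <- matrix(0, nrow(cnt), ncol(cnt))
    for (f in seq_len(ncol(cnt)))
      if (sum(cnt[, f]) > 0)
        copies[, f] <- cnt[, f] / sum(cnt[, f]) * tot[f]
    apply(copies, 1, function(cp)
      if (sum(cp) == 0) NA_real_ else sum(cp * dens) / sum(cp))
  }
  w16 <- wad(counts16, dens16, tot16)
  w18 <- wad(counts18, dens18, tot18)
  gc <- (w16 - 1.646057) / 0.083506
  m_light <- 0.496 * gc + 307.691
  m_lab <- m_light * w18 / w16
  a <- (m_lab - m_light) / 12.07747 * (1 - 0.002000429)
  if (is.null(n_total)) {
    n_total <- numeric(nrow(counts18))
    for (f in seq_len(ncol(counts18)))
      if (sum(counts18[, f]) > 0)
        n_total <- n_total + counts18[, f] / sum(counts18[, f]) * tot18[f]
  }
  b <- n_total * (a / a_sat) / t
  list(w16 = w16, w18 = w18, gc = gc, m_light = m_light, a = a, b = b)
}
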