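#' Read and validate a qSIP experiment
#'
#' Loads the five input tables of a density-fractionation experiment and
#' returns a validated bundle. Inputs are delimited text (tab default,
#' comma accepted); the ASV count table may instead be a BIOM file whose
#' sample ids are `tube_id:fraction_index`.
#'
#' Expected schemas (long format):
#' \describe{
#'   \item{fractions}{`tube_id`, `fraction_index`, `density_g_ml`,
#'     `dna_conc_ng_ul`, `total_16s_copies`, optional `sequenced`}
#'   \item{samples}{`tube_id`, `microcosm_id`, `fungal`, `moisture`,
#'     `isotope`, `timepoint`, `replicate`}
#'   \item{counts}{`tube_id`, `fraction_index`, `asv_id`, `count`}
#'   \item{taxonomy}{`asv_id`, then any of `domain` ... `genus`}
#'   \item{co2}{`treatment`, `replicate`, `co2_efflux`}
#' }
#'
#' Where `sequenced` is absent it is derived as
#' `dna_conc_ng_ul > cutoff_ng_ul`; a provided `sequenced` column wins
#' and then `dna_conc_ng_ul` may be missing. Densities that are not
#' monotone in collection order within a tube give a warning and the
#' rows are re-sorted (fraction indices are left untouched so count
#' references stay valid).
#'
#' @param paths Either a directory containing `fractions.tsv`,
#'   `samples.tsv`, `counts.tsv` (or `counts.biom`), `taxonomy.tsv`,
#'   `co2.tsv`, or a named list/character vector with those five
#'   elements (`fractions`, `samples`, `counts`, `taxonomy`, `co2`).
#' @param config A [qsip_config()].
#' @param quiet Suppress the per-table row-count report.
#' @return A `qsip_bundle`: list with `fractions`, `meta`, `counts`,
#'   `taxonomy`, `co2`, `config`.
#' @export
read_experiment <- function(paths, config = qsip_config(), quiet = FALSE) {
  p <- resolve_input_paths(paths)
  fractions <- read_delim_auto(p[["fractions"]])
  meta <- read_delim_auto(p[["samples"]])
  counts <- if (grepl("\\.biom$", p[["counts"]]))
    read_counts_biom(p[["counts"]]) else read_delim_auto(p[["counts"]])
  taxonomy <- read_delim_auto(p[["taxonomy"]])
  co2 <- read_delim_auto(p[["co2"]])
  bundle <- as_qsip_bundle(fractions, meta, counts, taxonomy, co2, config)
  if (!quiet)
    message(sprintf(
      "read_experiment: %d fraction rows, %d tubes, %d count rows, %d ASVs, %d CO2 rows",
      nrow(bundle$fractions), nrow(bundle$meta), nrow(bundle$counts),
      length(unique(bundle$counts$asv_id)), nrow(bundle$co2)))
  bundle
}

#' Assemble and validate a bundle from in-memory tables
#'
#' The workhorse behind [read_experiment()]; also used by the simulator.
#' Applies the sequencing cutoff, checks all referential and range
#' invariants, and derives the `treatment` label (`fungal_moisture`).
#'
#' @inheritParams read_experiment
#' @param fractions,meta,counts,taxonomy,co2 Data frames matching the
#'   schemas in [read_experiment()].
#' @return A validated `qsip_bundle`.
#' @export
as_qsip_bundle <- function(fractions, meta, counts, taxonomy, co2,
                           config = qsip_config()) {
  stopifnot_cols(fractions, c("tube_id", "fraction_index", "density_g_ml",
                              "total_16s_copies"), "fractions")
  stopifnot_cols(meta, c("tube_id", "fungal", "moisture", "isotope",
                         "timepoint", "replicate"), "samples")
  stopifnot_cols(counts, c("tube_id", "fraction_index", "asv_id", "count"),
                 "counts")
  stopifnot_cols(taxonomy, "asv_id", "taxonomy")
  stopifnot_cols(co2, c("treatment", "co2_efflux"), "co2")

  fractions$tube_id <- as.character(fractions$tube_id)
  meta$tube_id <- as.character(meta$tube_id)
  counts$tube_id <- as.character(counts$tube_id)
  counts$asv_id <- as.character(counts$asv_id)
  taxonomy$asv_id <- as.character(taxonomy$asv_id)

  # sequencing flag: explicit column wins, else derive from concentration
  if (is.null(fractions$sequenced)) {
    stopifnot_cols(fractions, "dna_conc_ng_ul", "fractions")
    if (anyNA(fractions$dna_conc_ng_ul))
      qsip_error("qsip_schema_error",
                 "dna_conc_ng_ul has missing values and no 'sequenced' column was provided")
    fractions$sequenced <- fractions$dna_conc_ng_ul > config$cutoff_ng_ul
  } else {
    fractions$sequenced <- as.logical(fractions$sequenced)
  }
  if (is.null(fractions$dna_conc_ng_ul))
    fractions$dna_conc_ng_ul <- NA_real_

  if (any(fractions$density_g_ml < 1.55 | fractions$density_g_ml > 1.85))
    qsip_error("qsip_schema_error",
               "fraction densities outside the physical CsCl range [1.55, 1.85] g mL^-1")
  if (any(fractions$total_16s_copies < 0, na.rm = TRUE))
    qsip_error("qsip_schema_error", "negative total_16s_copies")
  if (anyDuplicated(fractions[c("tube_id", "fraction_index")]))
    qsip_error("qsip_schema_error",
               "duplicated (tube_id, fraction_index) in fractions")

  # collection order: fraction 1 is the densest under 'heavy_first'
  fractions <- fractions[order(fractions$tube_id, fractions$fraction_index), ]
  mono <- tapply(fractions$density_g_ml, fractions$tube_id, function(d) {
    if (config$density_orientation == "heavy_first") all(diff(d) <= 0)
    else all(diff(d) >= 0)
  })
  if (any(!mono)) {
    warning("density not monotone in collection order for tube(s): ",
            paste(names(mono)[!mono], collapse = ", "),
            "; rows re-sorted by density (fraction indices kept)")
    dec <- config$density_orientation == "heavy_first"
    o <- order(fractions$tube_id,
               if (dec) -fractions$density_g_ml else fractions$density_g_ml)
    fractions <- fractions[o, ]
  }
  rownames(fractions) <- NULL

  if (anyDuplicated(meta$tube_id))
    qsip_error("qsip_schema_error", "duplicated tube_id in samples")
  meta$treatment <- paste(meta$fungal, meta$moisture, sep = "_")
  if (any(meta$timepoint == "T0" & meta$isotope != "16O"))
    qsip_error("qsip_schema_error", "T0 tubes must be isotope 16O")

  orphan <- setdiff(counts$tube_id, meta$tube_id)
  if (length(orphan))
    qsip_error("qsip_referential_error",
               paste("tube(s) in counts absent from samples:",
                     paste(orphan, collapse = ", ")))
  orphan <- setdiff(fractions$tube_id, meta$tube_id)
  if (length(orphan))
    qsip_error("qsip_referential_error",
               paste("tube(s) in fractions absent from samples:",
                     paste(orphan, collapse = ", ")))
  orphan <- setdiff(counts$tube_id, fractions$tube_id)
  if (length(orphan))
    qsip_error("qsip_referential_error",
               paste("tube(s) in counts absent from fractions:",
                     paste(orphan, collapse = ", ")))

  if (any(counts$count < 0))
    qsip_error("qsip_schema_error", "negative read counts")

  seq_key <- with(fractions, paste(tube_id, fraction_index)[sequenced])
  bad <- !paste(counts$tube_id, counts$fraction_index) %in% seq_key
  if (any(bad)) {
    off <- unique(paste0(counts$tube_id[bad], "/fraction ",
                         counts$fraction_index[bad]))
    qsip_error("qsip_referential_error",
               paste("counts present on unsequenced fraction(s):",
                     paste(utils::head(off, 5), collapse = ", ")))
  }

  miss <- setdiff(unique(counts$asv_id), taxonomy$asv_id)
  if (length(miss))
    qsip_error("qsip_referential_error",
               paste0(length(miss), " ASV(s) in counts lack a taxonomy entry, e.g. ",
                      paste(utils::head(miss, 3), collapse = ", ")))

  if (any(co2$co2_efflux < 0, na.rm = TRUE))
    qsip_error("qsip_schema_error", "negative co2_efflux")

  # every labeled T7 tube needs an unlabeled T7 partner in its treatment
  t7 <- meta[meta$timepoint == "T7", ]
  lab_tr <- unique(t7$treatment[t7$isotope == "18O"])
  unpaired <- setdiff(lab_tr, t7$treatment[t7$isotope == "16O"])
  if (length(unpaired))
    qsip_error("qsip_referential_error",
               paste("18O tubes without a 16O partner in treatment(s):",
                     paste(unpaired, collapse = ", ")))

  structure(list(fractions = fractions, meta = meta, counts = counts,
                 taxonomy = taxonomy, co2 = co2, config = config),
            class = "qsip_bundle")
}

#' @export
print.qsip_bundle <- function(x, ...) {
  tr <- table(x$meta$treatment)
  cat("qSIP experiment bundle\n")
  cat(sprintf("  tubes: %d (%d treatments)\n", nrow(x$meta), length(tr)))
  cat(sprintf("  fractions: %d (%d sequenced)\n", nrow(x$fractions),
              sum(x$fractions$sequenced)))
  cat(sprintf("  ASVs: %d, count rows: %d\n",
              length(unique(x$counts$asv_id)), nrow(x$counts)))
  invisible(x)
}

#' Write result tables
#'
#' Writes each table to `<name>.tsv` under `out_dir` with a fixed column
#' order (as given) and full double precision, plus a `manifest.tsv`
#' listing every file with its row count.
#'
#' @param tables Named list of data.frames.
#' @param out_dir Output directory (created if needed).
#' @param seed Optional seed to record in the manifest.
#' @return The manifest data.frame, invisibly.
#' @export
write_results <- function(tables, out_dir, seed = NA_integer_) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    qsip_error("qsip_io_error", paste("cannot create directory", out_dir))
  stopifnot(is.list(tables), !is.null(names(tables)), all(nzchar(names(tables))))
  files <- character(0); rows <- integer(0)
  for (nm in names(tables)) {
    f <- file.path(out_dir, paste0(nm, ".tsv"))
    utils::write.table(tables[[nm]], f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, basename(f)); rows <- c(rows, nrow(tables[[nm]]))
  }
  manifest <- data.frame(file = files, n_rows = rows, seed = seed)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Read back tables written by [write_results()]
#'
#' @param out_dir Directory written by [write_results()].
#' @return Named list of data.frames (manifest excluded).
#' @export
read_results <- function(out_dir) {
  fs <- setdiff(list.files(out_dir, pattern = "\\.tsv$"), "manifest.tsv")
  out <- lapply(file.path(out_dir, fs), read_delim_auto)
  names(out) <- sub("\\.tsv$", "", fs)
  out
}

resolve_input_paths <- function(paths) {
  need <- c("fractions", "samples", "counts", "taxonomy", "co2")
  if (length(paths) == 1 && is.character(paths) && dir.exists(paths)) {
    p <- vapply(need, function(nm) {
      cand <- file.path(paths, paste0(nm, c(".tsv", ".csv", ".biom")))
      hit <- cand[file.exists(cand)]
      if (!length(hit))
        qsip_error("qsip_io_error",
                   paste0("no ", nm, " table found under ", paths))
      hit[1]
    }, character(1))
    return(p)
  }
  p <- unlist(paths)
  miss <- setdiff(need, names(p))
  if (length(miss))
    qsip_error("qsip_io_error",
               paste("missing input path(s):", paste(miss, collapse = ", ")))
  missf <- p[need][!file.exists(p[need])]
  if (length(missf))
    qsip_error("qsip_io_error",
               paste("input file(s) not found:", paste(missf, collapse = ", ")))
  p[need]
}

read_delim_auto <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "")
}

# BIOM counts: observations are ASVs, samples are "tube_id:fraction_index"
read_counts_biom <- function(path) {
  if (!requireNamespace("biomformat", quietly = TRUE))
    qsip_error("qsip_io_error",
               "reading .biom counts requires the biomformat package")
  b <- biomformat::read_biom(path)
  m <- as.matrix(biomformat::biom_data(b))
  sk <- strsplit(colnames(m), ":", fixed = TRUE)
  bad <- lengths(sk) != 2
  if (any(bad))
    qsip_error("qsip_schema_error",
               "BIOM sample ids must be 'tube_id:fraction_index'")
  long <- data.frame(
    tube_id = rep(vapply(sk, `[`, "", 1), each = nrow(m)),
    fraction_index = rep(as.integer(vapply(sk, `[`, "", 2)), each = nrow(m)),
    asv_id = rep(rownames(m), ncol(m)),
    count = as.vector(m), stringsAsFactors = FALSE)
  long[long$count > 0, , drop = FALSE]
}
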