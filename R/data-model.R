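#' @name data-model
#' @title Quantification tables and sample metadata
#'
#' @description
#' The interchange object across all pipelines is a long-format quantification
#' table ("quant table"): one row per protein per sample, carrying either a
#' reporter-ion intensity or a precomputed fold change, plus the protein's
#' qupm category (number of unique quantified peptides, capped at "5+").
#' Sample metadata describe the experimental cell each sample occupies:
#' replicate, temperature (degrees C), ligand concentration (mM, 0 = vehicle),
#' detergent (NP40 / SDS / none), TMT plex and label.
NULL

META_COLS <- c("sample_id", "replicate", "temperature", "concentration_mM",
               "detergent", "tmt_plex", "tmt_label")

#' @noRd
tmt10_labels <- function() {
  c("126", "127L", "127H", "128L", "128H", "129L", "129H", "130L", "130H", "131")
}

# validate + normalize a sample-metadata data frame
#' @noRd
validate_meta <- function(meta) {
  missing_cols <- setdiff(META_COLS, names(meta))
  if (length(missing_cols))
    stopf("metadata is missing columns: %s", paste(missing_cols, collapse = ", "))
  meta$sample_id <- as.character(meta$sample_id)
  meta$tmt_plex <- as.character(meta$tmt_plex)
  meta$tmt_label <- as.character(meta$tmt_label)
  meta$detergent <- as.character(meta$detergent)
  if (anyDuplicated(meta$sample_id))
    stopf("duplicate sample_id in metadata: %s",
          paste(unique(meta$sample_id[duplicated(meta$sample_id)]), collapse = ", "))
  bad_det <- !meta$detergent %in% c("NP40", "SDS", "none")
  if (any(bad_det))
    stopf("invalid detergent value(s): %s", paste(unique(meta$detergent[bad_det]), collapse = ", "))
  if (any(!is.finite(meta$concentration_mM) | meta$concentration_mM < 0))
    stopf("concentration_mM must be finite and >= 0")
  if (any(!is.finite(meta$temperature)))
    stopf("temperature must be finite")
  if (any(!is.finite(meta$replicate) | meta$replicate < 1))
    stopf("replicate must be a positive integer")
  meta$replicate <- as.integer(meta$replicate)
  if (is.null(meta$condition))
    meta$condition <- ifelse(meta$concentration_mM > 0, "treated", "vehicle")
  key <- paste(meta$temperature, meta$concentration_mM, meta$detergent, meta$replicate)
  if (anyDuplicated(key))
    stopf("(temperature, concentration, detergent, replicate) does not uniquely identify samples")
  meta
}

#' Read a quantification table with sample metadata
#'
#' Reads a wide protein-by-sample table (TSV or CSV; one `protein_id` column,
#' an optional `qupm` column, then one column per sample) together with a
#' sample-metadata table, validates both against each other and returns the
#' long-format quant table used by all pipelines.
#'
#' @param path Quantification table. `.csv` is read comma-separated,
#'   anything else tab-separated.
#' @param meta_path Sample metadata table (TSV/CSV) with columns
#'   `sample_id, replicate, temperature, concentration_mM, detergent,
#'   tmt_plex, tmt_label` (and optionally `condition`).
#' @param value_kind What the numeric cells are: raw reporter
#'   `"intensity"` (must be non-negative), `"fold_change"` (must be positive)
#'   or `"log2_fold_change"`.
#' @return A list with elements `quant` (long data frame: `protein_id`,
#'   `sample_id`, `value`, `value_kind`, `qupm`) and `meta`.
#' @export
read_quant_table <- function(path, meta_path,
                             value_kind = c("intensity", "fold_change", "log2_fold_change")) {
  value_kind <- match.arg(value_kind)
  if (!file.exists(path)) stopf("quant table not found: %s", path)
  if (!file.exists(meta_path)) stopf("metadata file not found: %s", meta_path)
  sep <- function(p) if (grepl("\\.csv$", p, ignore.case = TRUE)) "," else "\t"
  wide <- read.delim(path, sep = sep(path), check.names = FALSE, stringsAsFactors = FALSE)
  meta <- read.delim(meta_path, sep = sep(meta_path), stringsAsFactors = FALSE)
  meta <- validate_meta(meta)
  if (!"protein_id" %in% names(wide)) stopf("quant table has no protein_id column")
  qupm <- if ("qupm" %in% names(wide)) bin_qupm(wide$qupm) else rep("2", nrow(wide))
  sample_cols <- setdiff(names(wide), c("protein_id", "qupm"))
  unknown <- setdiff(sample_cols, meta$sample_id)
  if (length(unknown))
    stopf("layout error: quant table contains samples absent from metadata: %s",
          paste(unknown, collapse = ", "))
  absent <- setdiff(meta$sample_id, sample_cols)
  if (length(absent))
    stopf("layout error: metadata lists sample(s) absent from the quant table: %s",
          paste(absent, collapse = ", "))
  vals <- as.matrix(wide[, meta$sample_id, drop = FALSE])
  if (!is.numeric(vals)) {
    suppressWarnings(storage.mode(vals) <- "double")
  }
  bad <- which(!is.finite(vals), arr.ind = TRUE)
  if (nrow(bad))
    stopf("parse error: non-numeric value for protein '%s', sample '%s'",
          wide$protein_id[bad[1, 1]], meta$sample_id[bad[1, 2]])
  if (value_kind == "intensity" && any(vals < 0)) {
    bad <- which(vals < 0, arr.ind = TRUE)
    stopf("parse error: negative intensity for protein '%s', sample '%s'",
          wide$protein_id[bad[1, 1]], meta$sample_id[bad[1, 2]])
  }
  if (value_kind == "fold_change" && any(vals <= 0))
    stopf("fold_change values must be strictly positive")
  quant <- data.frame(
    protein_id = rep(as.character(wide$protein_id), times = ncol(vals)),
    sample_id = rep(meta$sample_id, each = nrow(vals)),
    value = as.vector(vals),
    value_kind = value_kind,
    qupm = rep(qupm, times = ncol(vals)),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(paste(quant$protein_id, quant$sample_id)))
    stopf("duplicate (protein_id, sample_id) pairs in quant table")
  list(quant = quant, meta = meta)
}

#' Validate an experimental layout
#'
#' Checks that the sample metadata describe a coherent experiment of the
#' given kind and returns the layout (temperatures, concentrations, replicate
#' count, plex map).
#'
#' 2D-TPP plexes must span exactly two neighboring temperatures times the
#' full concentration series (one TMT10 plex per temperature pair); SPP
#' plexes must hold nine NP40 samples (vehicle + 8 doses) plus exactly one
#' SDS vehicle; TPP-TR plexes cover the full temperature gradient for one
#' condition and replicate.
#'
#' @param meta Sample-metadata data frame (see [read_quant_table()]).
#' @param kind `"TPP_2D"`, `"SPP"` or `"TPP_TR"`.
#' @return A list of class `"experiment_layout"`.
#' @export
validate_layout <- function(meta, kind = c("TPP_2D", "SPP", "TPP_TR")) {
  kind <- match.arg(kind)
  meta <- validate_meta(meta)
  temps <- sort(unique(meta$temperature))
  concs <- sort(unique(meta$concentration_mM))
  plexes <- split(meta, meta$tmt_plex)
  plex_map <- do.call(rbind, lapply(names(plexes), function(p) {
    m <- plexes[[p]]
    data.frame(tmt_plex = p, replicate = m$replicate[1],
               n_samples = nrow(m),
               temperatures = paste(sort(unique(m$temperature)), collapse = ","),
               stringsAsFactors = FALSE)
  }))

  if (kind == "TPP_2D") {
    np40 <- meta[meta$detergent != "SDS", , drop = FALSE]
    for (p in names(plexes)) {
      m <- plexes[[p]]
      pt <- sort(unique(m$temperature))
      if (length(pt) != 2)
        stopf("layout error: 2D plex '%s' spans %d temperatures (expected 2)", p, length(pt))
      idx <- match(pt, temps)
      if (diff(idx) != 1)
        stopf("layout error: 2D plex '%s' spans non-adjacent temperatures %g and %g",
              p, pt[1], pt[2])
      for (tt in pt) {
        pc <- sort(m$concentration_mM[m$temperature == tt])
        if (!identical(pc, concs))
          stopf("layout error: 2D plex '%s' misses concentrations at %g degC", p, tt)
      }
      if (length(unique(m$replicate)) != 1)
        stopf("layout error: 2D plex '%s' mixes replicates", p)
    }
    if (!0 %in% concs) stopf("layout error: 2D layout has no vehicle (0 mM) samples")
  } else if (kind == "SPP") {
    for (p in names(plexes)) {
      m <- plexes[[p]]
      sds <- m[m$detergent == "SDS", , drop = FALSE]
      np40 <- m[m$detergent == "NP40", , drop = FALSE]
      if (nrow(sds) != 1 || sds$concentration_mM != 0)
        stopf("layout error: SPP plex '%s' must contain exactly one SDS vehicle", p)
      if (nrow(np40) != 9)
        stopf("layout error: SPP plex '%s' has %d NP40 samples (expected 9)", p, nrow(np40))
      if (sum(np40$concentration_mM == 0) != 1)
        stopf("layout error: SPP plex '%s' must have one NP40 vehicle", p)
      if (length(unique(np40$concentration_mM[np40$concentration_mM > 0])) != 8)
        stopf("layout error: SPP plex '%s' must have 8 distinct doses", p)
      if (!identical(sort(unique(np40$concentration_mM)), concs))
        stopf("layout error: SPP plex '%s' does not use the shared dose series", p)
    }
  } else { # TPP_TR
    for (p in names(plexes)) {
      m <- plexes[[p]]
      if (!identical(sort(unique(m$temperature)), temps))
        stopf("layout error: TPP-TR plex '%s' does not cover the full temperature gradient", p)
      if (length(unique(m$condition)) != 1 || length(unique(m$replicate)) != 1)
        stopf("layout error: TPP-TR plex '%s' mixes conditions or replicates", p)
    }
  }

  structure(list(kind = kind, temperatures = temps, concentrations = concs,
                 n_replicates = length(unique(meta$replicate)),
                 plex_map = plex_map),
            class = "experiment_layout")
}

#' @export
print.experiment_layout <- function(x, ...) {
  cat(sprintf("%s layout: %d temperatures, %d concentrations, %d replicate(s), %d plex(es)\n",
              x$kind, length(x$temperatures), length(x$concentrations),
              x$n_replicates, nrow(x$plex_map)))
  invisible(x)
}

#' Write a results table to a tab-separated file
#'
#' Columns are written in their existing (deterministic) order with full
#' numeric precision so that a round trip through [read_results()]
#' reproduces every value to better than 1e-9 relative tolerance. An empty
#' table yields a header-only file.
#'
#' @param results A data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  stopifnot(is.data.frame(results))
  num <- vapply(results, is.numeric, logical(1))
  out <- results
  out[num] <- lapply(results[num], function(v) {
    ifelse(is.na(v), NA, sprintf("%.15g", v))
  })
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a results table written by [write_results()]
#' @param path File path.
#' @return A data frame.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stopf("results file not found: %s", path)
  read.delim(path, stringsAsFactors = FALSE)
}

#' Write a long quant table and metadata as wide TSV files
#'
#' Inverse of [read_quant_table()]: pivots the long quant table to the wide
#' protein-by-sample layout (with a `qupm` column) used for on-disk exchange.
#'
#' @param quant Long quant table.
#' @param meta Sample metadata.
#' @param quant_path,meta_path Output paths.
#' @return `quant_path`, invisibly.
#' @export
write_quant_table <- function(quant, meta, quant_path, meta_path) {
  meta <- validate_meta(meta)
  proteins <- unique(quant$protein_id)
  m <- matrix(NA_real_, length(proteins), nrow(meta),
              dimnames = list(proteins, meta$sample_id))
  m[cbind(match(quant$protein_id, proteins), match(quant$sample_id, meta$sample_id))] <-
    quant$value
  qupm <- quant$qupm[match(proteins, quant$protein_id)]
  wide <- data.frame(protein_id = proteins, qupm = qupm, m,
                     check.names = FALSE, stringsAsFactors = FALSE)
  write_results(wide, quant_path)
  write_results(meta, meta_path)
  invisible(quant_path)
}
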