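#' Read a per-cell table from CSV
#'
#' Reads a comma-delimited, UTF-8, header-first table of segmented cell (or
#' landmark object) records as exported from upstream segmentation/gating.
#' The mandatory columns are `sample_id`, `phenotype`, and the positions
#' `x_um`, `y_um`, `z_um` in micrometers (`z_um` may be constant for 2D
#' sections). Columns prefixed `ch_` are per-channel mean fluorescence
#' intensities; `volume_um3` and `sphericity` are recognized morphology
#' columns; any other columns are preserved untouched. Landmark "spot"
#' objects are not treated specially: give them their own phenotype label
#' (e.g. `"CD3_spot"`).
#'
#' @param path Path to a CSV file.
#' @param phenotypes Optional character vector: the phenotype vocabulary for
#'   the run. When supplied, records with a phenotype outside it are an error.
#' @return A validated cell-table tibble.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' cells <- simulate_tissue(ln_preset(), seed = 1)
#' write_cell_table(cells, tf)
#' read_cell_table(tf)
read_cell_table <- function(path, phenotypes = NULL) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "tissuemap_io_error")
  }
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         name_repair = "minimal")
  required <- c("sample_id", "phenotype", "x_um", "y_um", "z_um")
  missing <- setdiff(required, names(tbl))
  if (length(missing)) {
    abort(paste0("cell table is missing required column(s): ",
                 paste(missing, collapse = ", ")),
          class = "tissuemap_schema_error")
  }
  for (col in c("x_um", "y_um", "z_um")) {
    v <- tbl[[col]]
    if (!is.numeric(v)) {
      parsed <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(parsed) & !is.na(v))
      abort(paste0("non-numeric position in column '", col, "' at row ",
                   if (length(bad)) bad[1] else which(is.na(parsed))[1]),
            class = "tissuemap_parse_error")
    }
  }
  tbl$sample_id <- as.character(tbl$sample_id)
  tbl$phenotype <- as.character(tbl$phenotype)
  validate_cell_table(tbl, phenotypes = phenotypes)
}

#' Write a cell table to CSV
#'
#' Inverse of [read_cell_table()]: full-precision, lossless for all numeric
#' fields.
#'
#' @param cells A cell-table tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(cells, path) {
  cells <- validate_cell_table(cells)
  readr::write_csv(cells, path, progress = FALSE)
  invisible(path)
}

#' Validate a cell table
#'
#' Checks the cell-table contract: required columns present, positions finite,
#' channel intensities nonnegative, channel set identical across records of
#' one sample (guaranteed here by the rectangular layout: a channel column
#' must be fully non-missing within each sample), and, when a vocabulary is
#' given, every phenotype inside it.
#'
#' @inheritParams write_cell_table
#' @param phenotypes Optional phenotype vocabulary.
#' @return The validated tibble (invisibly coerced to a tibble).
#' @export
validate_cell_table <- function(cells, phenotypes = NULL) {
  required <- c("sample_id", "phenotype", "x_um", "y_um", "z_um")
  missing <- setdiff(required, names(cells))
  if (length(missing)) {
    abort(paste0("cell table is missing required column(s): ",
                 paste(missing, collapse = ", ")),
          class = "tissuemap_schema_error")
  }
  pos <- as.matrix(cells[, c("x_um", "y_um", "z_um")])
  if (nrow(cells) && !is.numeric(pos)) {
    abort("positions must be numeric", class = "tissuemap_parse_error")
  }
  if (nrow(cells) && any(!is.finite(pos))) {
    abort(paste0("non-finite position at row ",
                 which(!stats::complete.cases(pos) |
                         rowSums(!is.finite(pos)) > 0)[1]),
          class = "tissuemap_value_error")
  }
  if (!is.null(phenotypes)) {
    extra <- setdiff(unique(cells$phenotype), phenotypes)
    if (length(extra)) {
      abort(paste0("phenotype(s) outside the run vocabulary: ",
                   paste(extra, collapse = ", ")),
            class = "tissuemap_value_error")
    }
  }
  for (ch in channel_names(cells)) {
    v <- cells[[ch]]
    if (!is.numeric(v) || (length(v) && any(is.na(v)))) {
      abort(paste0("channel column '", ch,
                   "' must be numeric and complete within every sample"),
            class = "tissuemap_value_error")
    }
    if (length(v) && any(v < 0)) {
      abort(paste0("channel column '", ch, "' has negative intensities"),
            class = "tissuemap_value_error")
    }
  }
  tibble::as_tibble(cells)
}

#' Channel columns of a cell table
#'
#' @param cells A cell-table tibble.
#' @return Character vector of `ch_`-prefixed column names.
#' @export
channel_names <- function(cells) {
  grep("^ch_", names(cells), value = TRUE)
}

#' Phenotype vocabulary of a cell table
#'
#' @param cells A cell-table tibble.
#' @return Sorted character vector of observed phenotype labels.
#' @export
phenotype_names <- function(cells) {
  sort(unique(as.character(cells$phenotype)))
}

#' Read a run configuration from YAML
#'
#' A run configuration collects the analysis-wide tunables: neighborhood
#' `radius` (micrometers), feature `mode` (`"raw"`, `"composition"`, or
#' `"standardized"`), the Davies-Bouldin `sweep` range, the RNG `seed`, the
#' pseudo-space smoothing `window`, the network edge `threshold` (percent of
#' neighborhoods), and the `alpha` parameter for surfaces.
#'
#' @param path Path to a YAML file; keys not given fall back to defaults.
#' @return A named list of validated settings.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  defaults <- list(radius = 30, mode = "composition", sweep = c(2L, 10L),
                   seed = 1L, window = 50L, threshold = 0.005, alpha = NULL)
  cfg <- utils::modifyList(defaults, cfg[!vapply(cfg, is.null, logical(1))])
  if (!is.numeric(cfg$radius) || cfg$radius <= 0) {
    abort("config: radius must be > 0", class = "tissuemap_config_error")
  }
  cfg$sweep <- as.integer(cfg$sweep)
  if (length(cfg$sweep) == 2L) cfg$sweep <- seq(cfg$sweep[1], cfg$sweep[2])
  if (any(cfg$sweep < 2L) || any(cfg$sweep > 50L)) {
    abort("config: sweep range must lie within [2, 50]",
          class = "tissuemap_config_error")
  }
  if (cfg$threshold < 0) {
    abort("config: edge threshold must be >= 0",
          class = "tissuemap_config_error")
  }
  cfg
}
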