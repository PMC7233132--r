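#' Raster-scan neighborhoods over a cell table
#'
#' Sweeps a circular (2D) or spherical (3D) window of the given radius over
#' each sample on an axis-aligned grid anchored at the per-sample coordinate
#' minima, with a distance between neighborhood centers of half the radius,
#' spanning through the maxima. For every neighborhood it records the number
#' of cells of each phenotype and the per-channel intensity summed over all
#' member cells. Membership is the closed Euclidean ball: distance to the
#' center `<= radius`, measured in x-y only when the window is cylindrical
#' and in x-y-z when spherical. If a sample's z extent (`max(z) - min(z)`)
#' is smaller than the radius the data are treated as effectively 2D and a
#' cylindrical window (z ignored) is used; otherwise the window is a sphere.
#' Empty neighborhoods are retained: background carries region information.
#'
#' @param cells A cell table (see [read_cell_table()]).
#' @param radius Neighborhood radius in micrometers (> 0). 30 um is a
#'   practical default for lymphoid tissue at cellular-network scale.
#' @param phenotypes Feature vocabulary; defaults to the observed phenotypes.
#' @param geometry `"auto"` (the z-extent rule above), or force
#'   `"cylinder2D"` / `"sphere3D"`.
#' @return A neighborhood tibble (`nbhd_tbl`): one row per neighborhood with
#'   `nbhd_id`, `sample_id`, center `x`/`y`/`z`, `geometry`, `n_total`, one
#'   `n_<phenotype>` count column per phenotype and one `mfi_<channel>`
#'   summed-intensity column per channel. The radius, grid spacing,
#'   phenotype and channel vocabularies are carried as attributes.
#' @export
#' @examples
#' cells <- simulate_tissue(ln_preset(), seed = 1)
#' nb <- raster_neighborhoods(cells, radius = 30)
#' nb
raster_neighborhoods <- function(cells, radius,
                                 phenotypes = NULL,
                                 geometry = c("auto", "cylinder2D", "sphere3D")) {
  geometry <- match.arg(geometry)
  cells <- validate_cell_table(cells, phenotypes = phenotypes)
  if (nrow(cells) == 0L) {
    abort("cell table is empty", class = "tissuemap_empty_error")
  }
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0) {
    abort("radius must be a single positive number",
          class = "tissuemap_parameter_error")
  }
  phenotypes <- phenotypes %||% phenotype_names(cells)
  spacing <- radius / 2
  pieces <- lapply(split(cells, cells$sample_id), function(sc) {
    gx <- grid_axis(sc$x_um, spacing)
    gy <- grid_axis(sc$y_um, spacing)
    zext <- max(sc$z_um) - min(sc$z_um)
    geom <- resolve_geometry(geometry, zext, radius)
    gz <- if (geom == "sphere3D") grid_axis(sc$z_um, spacing)
          else (min(sc$z_um) + max(sc$z_um)) / 2
    centers <- as.matrix(expand.grid(x = gx, y = gy, z = gz,
                                     KEEP.OUT.ATTRS = FALSE))
    count_neighborhoods(sc, centers, radius, geom, phenotypes)
  })
  out <- dplyr::bind_rows(pieces)
  out$nbhd_id <- sprintf("N%06d", seq_len(nrow(out)))
  new_nbhd_tbl(out, radius = radius, phenotypes = phenotypes,
               channels = channel_names(cells))
}

#' Object-centered neighborhoods
#'
#' Like [raster_neighborhoods()] but with one neighborhood per center object
#' (typically all cells of one phenotype, e.g. blood-vessel landmarks)
#' instead of a raster grid. Membership and the cylinder-vs-sphere rule are
#' identical. The center object itself is counted when its phenotype is in
#' the feature vocabulary; set `include_center = FALSE` to subtract each
#' center's own contribution (its count and channel values), assuming the
#' centers are rows of `cells`.
#'
#' @inheritParams raster_neighborhoods
#' @param centers A cell table of center objects (nonempty).
#' @param include_center Count the center object itself? Default `TRUE`.
#' @return A neighborhood tibble; `nbhd_id` is taken from the center row
#'   order (`"C000001"`, ...).
#' @export
cell_neighborhoods <- function(cells, centers, radius,
                               phenotypes = NULL, include_center = TRUE,
                               geometry = c("auto", "cylinder2D", "sphere3D")) {
  geometry <- match.arg(geometry)
  cells <- validate_cell_table(cells, phenotypes = phenotypes)
  centers <- validate_cell_table(centers)
  if (nrow(centers) == 0L) {
    abort("centers are empty", class = "tissuemap_empty_error")
  }
  if (nrow(cells) == 0L) {
    abort("cell table is empty", class = "tissuemap_empty_error")
  }
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0) {
    abort("radius must be a single positive number",
          class = "tissuemap_parameter_error")
  }
  phenotypes <- phenotypes %||% phenotype_names(cells)
  chans <- channel_names(cells)
  centers$.center_row <- seq_len(nrow(centers))
  pieces <- lapply(split(centers, centers$sample_id), function(ctr) {
    sc <- cells[cells$sample_id == ctr$sample_id[1], , drop = FALSE]
    zext <- if (nrow(sc)) max(sc$z_um) - min(sc$z_um) else 0
    geom <- resolve_geometry(geometry, zext, radius)
    cm <- as.matrix(ctr[, c("x_um", "y_um", "z_um")])
    out <- count_neighborhoods(sc, cm, radius, geom, phenotypes)
    if (!include_center) {
      for (i in seq_len(nrow(ctr))) {
        ph <- ctr$phenotype[i]
        if (ph %in% phenotypes) {
          col <- paste0("n_", ph)
          out[[col]][i] <- out[[col]][i] - 1L
          out$n_total[i] <- out$n_total[i] - 1L
          for (ch in chans) {
            out[[paste0("mfi_", ch)]][i] <-
              out[[paste0("mfi_", ch)]][i] - ctr[[ch]][i]
          }
        }
      }
    }
    out$.center_row <- ctr$.center_row
    out
  })
  out <- dplyr::bind_rows(pieces)
  out <- out[order(out$.center_row), , drop = FALSE]
  out$nbhd_id <- sprintf("C%06d", out$.center_row)
  out$.center_row <- NULL
  new_nbhd_tbl(out, radius = radius, phenotypes = phenotypes,
               channels = chans)
}

# Grid positions from minimum through maximum with the given spacing.
grid_axis <- function(v, spacing) {
  lo <- min(v)
  hi <- max(v)
  if (hi == lo) return(lo)
  seq(lo, hi, by = spacing)
}

resolve_geometry <- function(geometry, z_extent, radius) {
  if (geometry != "auto") return(geometry)
  if (z_extent < radius) "cylinder2D" else "sphere3D"
}

# Shared counting core: calls the exact all-pairs kernel and assembles the
# per-sample tibble.
count_neighborhoods <- function(sc, centers, radius, geom, phenotypes) {
  chans <- channel_names(sc)
  phen_idx <- match(sc$phenotype, phenotypes) - 1L
  if (anyNA(phen_idx)) {
    abort("cells contain phenotypes outside the feature vocabulary",
          class = "tissuemap_value_error")
  }
  chan_mat <- if (length(chans)) as.matrix(sc[, chans, drop = FALSE])
              else matrix(0, nrow(sc), 0)
  res <- nbhd_count_cpp(as.matrix(sc[, c("x_um", "y_um", "z_um")]),
                        phen_idx, length(phenotypes), chan_mat,
                        centers, radius, geom == "sphere3D")
  counts <- res$counts
  colnames(counts) <- paste0("n_", phenotypes)
  out <- tibble::tibble(sample_id = sc$sample_id[1],
                        x = centers[, 1], y = centers[, 2], z = centers[, 3],
                        geometry = geom, n_total = rowSums(counts))
  out <- dplyr::bind_cols(out, tibble::as_tibble(counts))
  if (length(chans)) {
    mfi <- res$mfi
    colnames(mfi) <- paste0("mfi_", chans)
    out <- dplyr::bind_cols(out, tibble::as_tibble(mfi))
  }
  out
}

new_nbhd_tbl <- function(tbl, radius, phenotypes, channels) {
  tbl <- tibble::as_tibble(tbl)
  tbl <- dplyr::relocate(tbl, "nbhd_id")
  structure(tbl,
            radius = radius,
            spacing = radius / 2,
            phenotypes = phenotypes,
            channels = channels,
            class = c("nbhd_tbl", class(tbl)))
}

#' Per-phenotype count matrix of a neighborhood table
#'
#' @param nbhd A neighborhood tibble.
#' @return Numeric matrix (neighborhood x phenotype), rownames = `nbhd_id`.
#' @export
nbhd_counts <- function(nbhd) {
  cols <- grep("^n_", names(nbhd), value = TRUE)
  cols <- setdiff(cols, "n_total")
  m <- as.matrix(nbhd[, cols, drop = FALSE])
  rownames(m) <- nbhd$nbhd_id
  colnames(m) <- sub("^n_", "", cols)
  m
}

#' Neighborhood radius stored on a neighborhood table
#' @param nbhd A neighborhood tibble.
#' @return Radius in micrometers (or `NULL` if absent).
#' @export
nbhd_radius <- function(nbhd) attr(nbhd, "radius", exact = TRUE)

#' Write / read a neighborhood table
#'
#' Losslessly round-trips the neighborhood tibble through CSV; the radius and
#' geometry travel as columns so the reader can restore the attributes.
#'
#' @param nbhd A neighborhood tibble.
#' @param path CSV path.
#' @return `path` invisibly (writer); the restored tibble (reader).
#' @export
write_nbhd_table <- function(nbhd, path) {
  out <- tibble::as_tibble(nbhd)
  out$radius <- nbhd_radius(nbhd) %||% NA_real_
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_nbhd_table
#' @export
read_nbhd_table <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  radius <- if ("radius" %in% names(tbl)) tbl$radius[1] else NA_real_
  tbl$radius <- NULL
  phen <- sub("^n_", "", setdiff(grep("^n_", names(tbl), value = TRUE),
                                 "n_total"))
  chans <- sub("^mfi_", "", grep("^mfi_", names(tbl), value = TRUE))
  new_nbhd_tbl(tbl, radius = radius, phenotypes = phen, channels = chans)
}
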