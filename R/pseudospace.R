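#' Pseudo-space: a one-dimensional ordering of neighborhoods
#'
#' Collapses tissue organization onto a single axis by sorting the
#' neighborhoods on a weighted combination of cell-type abundances: the sort
#' key of a neighborhood is `sum_c w_c * f_c`, where `f_c` is the chosen
#' per-phenotype feature (composition fraction or raw count). Phenotypes
#' with negative weights sort to the left, positive weights to the right.
#' The sort is ascending and stable, with the neighborhood's input index as
#' the final tie-break. Each phenotype's feature is then smoothed along the
#' ordering with a boxcar moving average (window expressed in neighborhoods,
#' truncated at the edges) and normalized to its own maximum so different
#' cell types are comparable on one y axis (all-zero curves stay zero).
#'
#' @param nbhd A neighborhood tibble.
#' @param weights Named numeric vector of sort weights, e.g.
#'   `c(B = -1, T = 1)`; at least one must be nonzero, and names must be
#'   phenotypes of `nbhd`.
#' @param window Boxcar window width in neighborhoods (`>= 1`); `window = 1`
#'   leaves the curves unsmoothed.
#' @param feature `"composition"` (fraction of the neighborhood total,
#'   default) or `"count"` (absolute numbers).
#' @return A `pseudo_space` tibble: `pseudo_rank` (1..n along the axis),
#'   `nbhd_id`, `sort_key`, and one normalized smoothed curve column per
#'   phenotype. [autoplot()] draws the curves.
#' @export
#' @examples
#' cells <- simulate_tissue(ln_preset(), seed = 1)
#' nb <- raster_neighborhoods(cells, radius = 30)
#' ps <- pseudo_space(nb, weights = c(B = -1, T = 1), window = 50)
#' autoplot(ps)
pseudo_space <- function(nbhd, weights, window = 50L,
                         feature = c("composition", "count")) {
  feature <- match.arg(feature)
  if (!is.numeric(window) || length(window) != 1L || window < 1) {
    abort("window must be a single value >= 1",
          class = "tissuemap_parameter_error")
  }
  window <- as.integer(window)
  if (is.null(names(weights)) || all(weights == 0)) {
    abort("weights must be a named vector with at least one nonzero entry",
          class = "tissuemap_parameter_error")
  }
  m <- nbhd_counts(nbhd)
  unknown <- setdiff(names(weights), colnames(m))
  if (length(unknown)) {
    abort(paste0("weight name(s) not among phenotypes: ",
                 paste(unknown, collapse = ", ")),
          class = "tissuemap_parameter_error")
  }
  if (feature == "composition") {
    tot <- rowSums(m)
    nz <- tot > 0
    m[nz, ] <- m[nz, , drop = FALSE] / tot[nz]
  }
  key <- as.vector(m[, names(weights), drop = FALSE] %*% weights)
  ord <- order(key, seq_along(key))  # stable; index is the final tie-break
  curves <- apply(m[ord, , drop = FALSE], 2, function(v) {
    sm <- boxcar(v, window)
    mx <- max(sm)
    if (mx > 0) sm / mx else sm
  })
  out <- dplyr::bind_cols(
    tibble::tibble(pseudo_rank = seq_along(ord),
                   nbhd_id = nbhd$nbhd_id[ord],
                   sort_key = key[ord]),
    tibble::as_tibble(curves))
  structure(out, window = window, weights = weights, feature = feature,
            class = c("pseudo_space", class(out)))
}

# Edge-truncated boxcar moving average; a window of w covers indices
# i - floor((w-1)/2) .. i + floor(w/2), clipped to the series.
boxcar <- function(v, w) {
  n <- length(v)
  if (w <= 1L || n == 1L) return(v)
  lo <- pmax(seq_len(n) - (w - 1L) %/% 2L, 1L)
  hi <- pmin(seq_len(n) + w %/% 2L, n)
  cs <- cumsum(c(0, v))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
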