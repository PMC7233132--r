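#' Build a clustering feature matrix from neighborhoods
#'
#' Three feature modes are supported, all computed from the per-phenotype
#' neighborhood counts (optionally extended with the per-channel summed
#' intensities):
#' * `"raw"` — counts passed through unchanged;
#' * `"composition"` — each row divided by its total cell count, so features
#'   are fractions summing to 1 (all-zero rows of empty neighborhoods stay
#'   zero);
#' * `"standardized"` — each column z-scored (value minus column mean,
#'   divided by the column standard deviation) across all neighborhoods of
#'   the training set; multi-sample pooling is implicit since all rows enter.
#'
#' Zero-variance columns under `"standardized"` are set to 0 with a warning,
#' not an error. The standardization statistics are frozen on the returned
#' object so held-out neighborhoods can be projected onto the same scale via
#' `stats = feature_stats(trained)`.
#'
#' @param nbhd A neighborhood tibble from [raster_neighborhoods()] or
#'   [cell_neighborhoods()].
#' @param mode Feature mode; default `"composition"`.
#' @param include_channels Also include the `mfi_` summed-intensity columns
#'   as features (they are z-scored/normalized alongside the counts)?
#'   Default `FALSE`: clustering uses cell counts only.
#' @param stats Optional frozen standardization statistics (a list with
#'   `center` and `scale`) from a previous training call.
#' @return A feature tibble (`nbhd_features`): `nbhd_id` plus one numeric
#'   column per feature; the mode and any standardization statistics are
#'   attributes.
#' @export
nbhd_features <- function(nbhd,
                          mode = c("composition", "raw", "standardized"),
                          include_channels = FALSE, stats = NULL) {
  mode <- match.arg(mode)
  if (nrow(nbhd) == 0L) {
    abort("neighborhood table is empty", class = "tissuemap_empty_error")
  }
  m <- nbhd_counts(nbhd)
  if (include_channels) {
    mcols <- grep("^mfi_", names(nbhd), value = TRUE)
    if (length(mcols)) {
      mm <- as.matrix(nbhd[, mcols, drop = FALSE])
      colnames(mm) <- sub("^mfi_", "MFI:", mcols)
      m <- cbind(m, mm)
    }
  }
  center <- scale <- NULL
  if (mode == "composition") {
    tot <- rowSums(m)
    nz <- tot > 0
    m[nz, ] <- m[nz, , drop = FALSE] / tot[nz]
  } else if (mode == "standardized") {
    if (is.null(stats)) {
      center <- colMeans(m)
      scale <- apply(m, 2, stats::sd)
    } else {
      center <- stats$center
      scale <- stats$scale
    }
    degen <- !is.finite(scale) | scale == 0
    if (any(degen)) {
      warn(paste0("zero-variance feature column(s) set to 0: ",
                  paste(colnames(m)[degen], collapse = ", ")))
      scale[degen] <- 1
      center[degen] <- 0
      m[, degen] <- 0
    }
    m <- sweep(sweep(m, 2, center, "-"), 2, scale, "/")
    m[, degen] <- 0
  }
  out <- dplyr::bind_cols(tibble::tibble(nbhd_id = nbhd$nbhd_id),
                          tibble::as_tibble(m))
  structure(out, mode = mode,
            stats = if (mode == "standardized")
              list(center = center, scale = scale),
            class = c("nbhd_features", class(out)))
}

#' @rdname nbhd_features
#' @param x A feature tibble.
#' @export
feature_stats <- function(x) attr(x, "stats", exact = TRUE)

feature_matrix <- function(x) {
  if (inherits(x, "nbhd_features") || (is.data.frame(x) && "nbhd_id" %in% names(x))) {
    m <- as.matrix(x[, setdiff(names(x), "nbhd_id"), drop = FALSE])
    rownames(m) <- x$nbhd_id
    m
  } else {
    as.matrix(x)
  }
}

#' Davies-Bouldin index of a clustering
#'
#' The ratio of within-cluster to between-cluster distances, averaged over
#' clusters: `DB = (1/k) * sum_i max_{j != i} (s_i + s_j) / d_ij`, where
#' `s_i` is the mean Euclidean distance of the members of cluster `i` to its
#' centroid and `d_ij` the distance between centroids. Lower is better;
#' the minimum over a sweep of candidate cluster counts selects the number
#' of tissue regions. Singleton clusters are allowed (`s_i = 0`).
#'
#' @param x A feature tibble or numeric matrix (rows = observations).
#' @param labels Cluster label per row; every cluster must be nonempty and
#'   there must be at least two.
#' @return The DB index (a single nonnegative number).
#' @export
davies_bouldin <- function(x, labels) {
  m <- feature_matrix(x)
  labels <- as.integer(factor(labels))
  if (length(labels) != nrow(m)) {
    abort("labels must have one entry per row", class = "tissuemap_parameter_error")
  }
  k <- max(labels)
  if (k < 2L) {
    abort("need at least two clusters", class = "tissuemap_parameter_error")
  }
  if (length(unique(labels)) != k || any(tabulate(labels, k) == 0L)) {
    abort("empty cluster in labeling", class = "tissuemap_parameter_error")
  }
  cent <- rowsum(m, labels) / as.vector(tabulate(labels, k))
  s <- vapply(seq_len(k), function(i) {
    rows <- m[labels == i, , drop = FALSE]
    mean(sqrt(rowSums((rows - matrix(cent[i, ], nrow(rows), ncol(m),
                                     byrow = TRUE))^2)))
  }, numeric(1))
  dmat <- as.matrix(stats::dist(cent))
  ratios <- outer(s, s, "+") / dmat
  diag(ratios) <- -Inf
  mean(apply(ratios, 1, max))
}

#' Train a one-dimensional self-organizing map
#'
#' A batch SOM on a 1-D chain of `k` nodes. Prototypes start on `k` distinct
#' data rows sampled with the run seed, then 200 batch epochs move them
#' toward the data: each epoch assigns every row to its nearest prototype
#' (ties to the lowest index) and replaces each prototype by the mean of the
#' rows whose best-matching unit lies within the current chain neighborhood
#' (a bubble of radius decaying linearly from `ceiling(k/3)` to 0 over the
#' first 100 epochs, nearest-only thereafter). The final labels are the
#' nearest-prototype assignment. Fully deterministic given the seed.
#'
#' @param x A feature tibble or numeric matrix.
#' @param k Number of nodes (regions), `>= 2` and `<= nrow(x)`.
#' @param seed RNG seed for the prototype initialization.
#' @param epochs Number of batch epochs (default 200).
#' @return A `som_fit`: list with `prototypes` (k x feature matrix),
#'   `labels` (integer vector), `k`, `seed`.
#' @export
train_som <- function(x, k, seed = 1L, epochs = 200L) {
  m <- feature_matrix(x)
  if (!is.numeric(k) || length(k) != 1L || k < 2L) {
    abort("k must be a single integer >= 2", class = "tissuemap_parameter_error")
  }
  k <- as.integer(k)
  if (k > nrow(m)) {
    abort("k exceeds the number of observations",
          class = "tissuemap_parameter_error")
  }
  if (any(!is.finite(m))) {
    abort("features must be finite", class = "tissuemap_value_error")
  }
  uniq <- unique(m)
  if (nrow(uniq) < k) {
    abort(paste0("fewer than k = ", k, " distinct feature rows"),
          class = "tissuemap_parameter_error")
  }
  proto <- withr::with_seed(seed,
    uniq[sample.int(nrow(uniq), k), , drop = FALSE])
  r0 <- ceiling(k / 3)
  half <- 100L
  for (e in seq_len(epochs)) {
    bmu <- nearest_prototype(m, proto)
    sigma <- if (e <= half) r0 * (half - e) / half else 0
    newp <- proto
    empty <- integer()
    for (j in seq_len(k)) {
      sel <- abs(bmu - j) <= sigma
      if (any(sel)) newp[j, ] <- colMeans(m[sel, , drop = FALSE])
      else if (sigma == 0) empty <- c(empty, j)
    }
    if (length(empty)) {
      # dead-unit repair in the nearest-only phase: relocate each unclaimed
      # prototype onto the currently worst-quantized data row (deterministic)
      qerr <- sqrt(rowSums((m - newp[bmu, , drop = FALSE])^2))
      for (j in empty) {
        w <- which.max(qerr)
        newp[j, ] <- m[w, ]
        qerr[w] <- -Inf
      }
    }
    if (identical(newp, proto) && sigma == 0) {
      proto <- newp
      break
    }
    proto <- newp
  }
  labels <- nearest_prototype(m, proto)
  structure(list(prototypes = proto, labels = labels, k = k, seed = seed),
            class = "som_fit")
}

# Nearest prototype per row; ties broken toward the lowest prototype index.
nearest_prototype <- function(m, proto) {
  d2 <- outer(rowSums(m^2), rep(1, nrow(proto))) +
    outer(rep(1, nrow(m)), rowSums(proto^2)) - 2 * m %*% t(proto)
  max.col(-d2, ties.method = "first")
}

#' Select the number of tissue regions by the Davies-Bouldin criterion
#'
#' For each candidate region count in `sweep`, trains a 1-D SOM
#' ([train_som()]) on the features and evaluates the Davies-Bouldin index of
#' the resulting labels; the selected count `k` is the minimizer (ties go to
#' the smallest `k`). The DB index is evaluated on the SOM labels themselves
#' over the clusters they actually occupy.
#'
#' @param x A feature tibble from [nbhd_features()] (or a numeric matrix).
#' @param sweep Candidate region counts, within `[2, min(50, n - 1)]`.
#' @param seed RNG seed (shared across the sweep).
#' @param epochs SOM epochs per candidate.
#' @return A `region_model`: the selected `k`, the fitted `som`, integer
#'   `labels` per neighborhood, the `db_curve` tibble (`k`, `db`), `nbhd_id`
#'   when available, feature `mode`, and `seed`. [tidy()] returns the DB
#'   curve; [glance()] a one-row summary.
#' @export
#' @examples
#' cells <- simulate_tissue(ln_preset(), seed = 1)
#' nb <- raster_neighborhoods(cells, radius = 30)
#' fx <- nbhd_features(nb, mode = "composition")
#' mod <- select_regions(fx, sweep = 2:6, seed = 1)
#' glance(mod)
select_regions <- function(x, sweep = 2:10, seed = 1L, epochs = 200L) {
  m <- feature_matrix(x)
  n <- nrow(m)
  if (n < 4L) {
    abort("need at least 4 observations to select a region count",
          class = "tissuemap_insufficient_data_error")
  }
  sweep <- sort(unique(as.integer(sweep)))
  if (any(sweep < 2L) || any(sweep > min(50L, n - 1L))) {
    abort("sweep range must lie within [2, min(50, n - 1)]",
          class = "tissuemap_parameter_error")
  }
  fits <- lapply(sweep, function(k) train_som(m, k, seed = seed,
                                              epochs = epochs))
  db <- vapply(fits, function(f) {
    if (length(unique(f$labels)) < 2L) return(Inf)
    davies_bouldin(m, f$labels)
  }, numeric(1))
  best <- which.min(db)  # ties: first = smallest k
  fit <- fits[[best]]
  structure(list(k = sweep[best],
                 som = fit,
                 labels = fit$labels,
                 db_curve = tibble::tibble(k = sweep, db = db),
                 nbhd_id = rownames(m),
                 mode = attr(x, "mode", exact = TRUE) %||% NA_character_,
                 seed = seed),
            class = "region_model")
}

#' @export
print.region_model <- function(x, ...) {
  cat("Tissue region model\n")
  cat("  regions (Davies-Bouldin minimum): ", x$k, "\n", sep = "")
  cat("  sweep: ", paste(range(x$db_curve$k), collapse = ".."),
      "; feature mode: ", x$mode, "; seed: ", x$seed, "\n", sep = "")
  cat("  neighborhoods: ", length(x$labels), "\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.region_model <- function(x, ...) x$db_curve

#' @exportS3Method generics::glance
glance.region_model <- function(x, ...) {
  tibble::tibble(k = x$k, db_min = min(x$db_curve$db),
                 n = length(x$labels), mode = x$mode, seed = x$seed)
}

#' Region assignment table of a fitted model
#'
#' @param model A `region_model`.
#' @return Tibble with `nbhd_id` and integer `region`.
#' @export
region_assignment <- function(model) {
  tibble::tibble(nbhd_id = model$nbhd_id %||%
                   sprintf("N%06d", seq_along(model$labels)),
                 region = as.integer(model$labels))
}

#' Annotate (merge) regions with composite labels
#'
#' Attaches manual composite labels to machine-defined regions — e.g. map
#' regions 3 and 4 both to `"TZ"` to merge them under one annotation. The
#' underlying region indices are unchanged. An empty mapping returns the
#' assignment without an annotation column.
#'
#' @param assignment A tibble with columns `nbhd_id`, `region` (see
#'   [region_assignment()]).
#' @param mapping Named character vector: names are region indices (as
#'   strings), values the composite labels, e.g. `c("3" = "TZ", "4" = "TZ")`.
#'   Regions not named keep their numeric label as annotation.
#' @return The assignment tibble, with `annotated_region` added when
#'   `mapping` is nonempty.
#' @export
annotate_regions <- function(assignment, mapping = character()) {
  if (!all(c("nbhd_id", "region") %in% names(assignment))) {
    abort("assignment must have columns nbhd_id and region",
          class = "tissuemap_schema_error")
  }
  if (length(mapping) == 0L) {
    assignment$annotated_region <- NULL
    return(assignment)
  }
  keys <- names(mapping)
  observed <- as.character(unique(assignment$region))
  unknown <- setdiff(keys, observed)
  if (length(unknown)) {
    abort(paste0("mapping refers to unobserved region(s): ",
                 paste(unknown, collapse = ", ")),
          class = "tissuemap_parameter_error")
  }
  lab <- as.character(assignment$region)
  hit <- lab %in% keys
  lab[hit] <- unname(mapping[lab[hit]])
  assignment$annotated_region <- lab
  assignment
}

#' Write / read a region-assignment table
#'
#' The CSV has columns `neighborhood_id`, `region`, `annotated_region`
#' (the last empty when no annotation was made).
#'
#' @param assignment Assignment tibble (see [annotate_regions()]).
#' @param path CSV path.
#' @return `path` invisibly (writer); the assignment tibble (reader).
#' @export
write_assignment_table <- function(assignment, path) {
  out <- tibble::tibble(
    neighborhood_id = assignment$nbhd_id,
    region = assignment$region,
    annotated_region = assignment[["annotated_region"]] %||% NA_character_)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_assignment_table
#' @export
read_assignment_table <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           neighborhood_id = readr::col_character(),
                           region = readr::col_integer(),
                           annotated_region = readr::col_character()))
  out <- tibble::tibble(nbhd_id = tbl$neighborhood_id, region = tbl$region)
  if (!all(is.na(tbl$annotated_region))) {
    out$annotated_region <- tbl$annotated_region
  }
  out
}
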