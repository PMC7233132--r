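#' Cell-cell spatial correlation over neighborhoods
#'
#' Pearson correlation of the per-phenotype cell counts across
#' neighborhoods, revealing which cell populations co-occur locally and
#' which avoid one another. Correlations are computed per sample and
#' averaged (unweighted) over the sample cohort; they can be restricted to
#' the neighborhoods of one tissue region, since cells may associate
#' differently in different compartments. Significance uses the Student-t
#' transform of the correlation coefficient (see [cor_pvalue()]).
#'
#' Phenotypes with zero variance in a sample's neighborhoods have undefined
#' correlations: those entries are reported as missing (`NA`), never as 0,
#' and are excluded pairwise from the cohort mean.
#'
#' @param nbhd A neighborhood tibble.
#' @param scope `"all"` (whole tissue) or a region label present in
#'   `assignment` (integer region or annotated label).
#' @param assignment Region assignment tibble (required when `scope` is a
#'   region): columns `nbhd_id`, `region`, optionally `annotated_region`.
#' @param min_n Minimum neighborhoods per sample in scope (default 3).
#' @return A `spatial_cor` object: per-sample correlation and p-value
#'   matrices, the cohort mean matrix `cohort_r`, the scope, and per-sample
#'   neighborhood counts. [tidy()] gives one row per sample and phenotype
#'   pair; [autoplot()] a heatmap of the cohort means.
#' @export
#' @examples
#' cells <- simulate_tissue(ln_preset(), seed = 1)
#' nb <- raster_neighborhoods(cells, radius = 30)
#' ct <- correlate_counts(nb)
#' round(ct$cohort_r, 2)
correlate_counts <- function(nbhd, scope = "all", assignment = NULL,
                             min_n = 3L) {
  if (!identical(scope, "all")) {
    if (is.null(assignment)) {
      abort("region scope requires a region assignment",
            class = "tissuemap_parameter_error")
    }
    keep_ids <- assignment$nbhd_id[
      assignment$region == suppressWarnings(as.integer(scope)) |
        (if ("annotated_region" %in% names(assignment))
           assignment$annotated_region == as.character(scope) else FALSE)]
    nbhd <- nbhd[nbhd$nbhd_id %in% keep_ids, , drop = FALSE]
  }
  counts <- nbhd_counts(nbhd)
  samples <- split(seq_len(nrow(nbhd)), nbhd$sample_id)
  if (any(vapply(samples, length, integer(1)) < min_n)) {
    abort(paste0("fewer than ", min_n, " neighborhoods in scope for some sample"),
          class = "tissuemap_insufficient_data_error")
  }
  per_sample <- lapply(samples, function(idx) {
    m <- counts[idx, , drop = FALSE]
    r <- suppressWarnings(stats::cor(m))
    zv <- apply(m, 2, stats::sd) == 0
    r[zv, ] <- NA_real_
    r[, zv] <- NA_real_
    p <- cor_pvalue(r, nrow(m))
    diag(p) <- ifelse(is.na(diag(r)), NA_real_, 0)
    list(r = r, p = p, n = nrow(m))
  })
  rs <- lapply(per_sample, `[[`, "r")
  arr <- array(unlist(rs), dim = c(dim(rs[[1]]), length(rs)))
  cohort <- apply(arr, c(1, 2), function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
  dimnames(cohort) <- dimnames(rs[[1]])
  structure(list(samples = per_sample, cohort_r = cohort,
                 scope = scope, phenotypes = colnames(counts)),
            class = "spatial_cor")
}

#' @export
print.spatial_cor <- function(x, ...) {
  cat("Cell-cell spatial correlation (scope: ", x$scope, ")\n", sep = "")
  cat("  samples: ", length(x$samples), "; phenotypes: ",
      length(x$phenotypes), "\n", sep = "")
  cat("Cohort mean r:\n")
  print(round(x$cohort_r, 3))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.spatial_cor <- function(x, ...) {
  per <- purrr::imap_dfr(x$samples, function(s, id) {
    long_cor(s$r, s$p) |> dplyr::mutate(sample_id = id, .before = 1)
  })
  cohort <- long_cor(x$cohort_r, NULL) |>
    dplyr::mutate(sample_id = "cohort", .before = 1)
  dplyr::bind_rows(per, cohort)
}

#' @exportS3Method generics::glance
glance.spatial_cor <- function(x, ...) {
  tibble::tibble(scope = x$scope, n_samples = length(x$samples),
                 n_phenotypes = length(x$phenotypes),
                 n_nbhd_total = sum(vapply(x$samples, `[[`, numeric(1), "n")))
}

long_cor <- function(r, p) {
  out <- tibble::as_tibble(as.table(r), .name_repair = "minimal")
  names(out) <- c("phenotype_a", "phenotype_b", "r")
  if (!is.null(p)) out$p <- as.vector(p)
  out
}

#' p-value of a Pearson correlation via the Student-t transform
#'
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` follows a Student-t distribution
#' with `n - 2` degrees of freedom under the null of zero correlation; the
#' reported p-value is the two-sided tail. `|r| = 1` gives `p = 0` by
#' convention. Vectorized over `r`; `NA` propagates.
#'
#' @param r Correlation coefficient(s), in `[-1, 1]`.
#' @param n Number of paired observations (`>= 3`).
#' @return Two-sided p-value(s), same shape as `r`.
#' @export
cor_pvalue <- function(r, n) {
  if (!is.numeric(n) || length(n) != 1L || n < 3L) {
    abort("n must be a single integer >= 3", class = "tissuemap_parameter_error")
  }
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) {
    abort("|r| must not exceed 1", class = "tissuemap_value_error")
  }
  r_ <- pmin(pmax(r, -1), 1)
  t <- r_ * sqrt(n - 2) / sqrt(pmax(1 - r_^2, 0))
  p <- 2 * stats::pt(-abs(t), df = n - 2)
  p[abs(r_) == 1] <- 0
  if (is.matrix(r)) {
    p <- matrix(p, nrow(r), dimnames = dimnames(r))
  }
  p
}

#' Write a correlation result to CSV
#'
#' Long format: `sample_id` (or `"cohort"`), `phenotype_a`, `phenotype_b`,
#' `r`, `p` (empty for the cohort rows), `scope`. Losslessly re-readable.
#'
#' @param x A `spatial_cor` object.
#' @param path CSV path.
#' @return `path` invisibly (writer); a tibble (reader).
#' @export
write_correlation_table <- function(x, path) {
  out <- tidy(x)
  out$scope <- x$scope
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_correlation_table
#' @export
read_correlation_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    sample_id = readr::col_character(),
                    phenotype_a = readr::col_character(),
                    phenotype_b = readr::col_character(),
                    scope = readr::col_character(),
                    .default = readr::col_double()))
}
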