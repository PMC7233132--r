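#' Region contact matrix
#'
#' For every ordered pair of regions (i, j), the percentage of region-i
#' neighborhoods that are directly in contact with (center distance at most
#' `contact_radius` from, excluding the neighborhood itself) at least one
#' region-j neighborhood. Contact percentages are directional because region
#' sizes differ; the diagonal (self-contact) is defined the same way and
#' reported. A region with zero neighborhoods yields a row of missing
#' values.
#'
#' @param nbhd A neighborhood tibble (centers are taken from it).
#' @param assignment Region assignment tibble covering all neighborhoods
#'   (columns `nbhd_id`, `region`); an integer vector of labels in row order
#'   also works.
#' @param contact_radius Contact distance in micrometers. Default: `1.1 *
#'   spacing * sqrt(2)` with the raster spacing from `nbhd` — captures the
#'   8-neighborhood of the raster grid, robust to float error.
#' @return Numeric matrix (region x region) of contact percentages in
#'   `[0, 100]`, with region labels as dimnames and per-region neighborhood
#'   counts as the `"counts"` attribute.
#' @export
region_contact_matrix <- function(nbhd, assignment, contact_radius = NULL) {
  if (is.null(contact_radius)) {
    sp <- attr(nbhd, "spacing", exact = TRUE)
    if (is.null(sp)) {
      abort("supply contact_radius (no grid spacing on the neighborhood table)",
            class = "tissuemap_parameter_error")
    }
    contact_radius <- 1.1 * sp * sqrt(2)
  }
  if (contact_radius <= 0) {
    abort("contact_radius must be > 0", class = "tissuemap_parameter_error")
  }
  labels <- if (is.data.frame(assignment)) {
    assignment$region[match(nbhd$nbhd_id, assignment$nbhd_id)]
  } else {
    assignment
  }
  if (length(labels) != nrow(nbhd) || anyNA(labels)) {
    abort("assignment must cover every neighborhood",
          class = "tissuemap_parameter_error")
  }
  xyz <- as.matrix(nbhd[, c("x", "y", "z")])
  regions <- if (is.factor(labels)) levels(labels) else sort(unique(labels))
  labels <- as.character(labels)
  regions <- as.character(regions)
  nr <- length(regions)
  lab_idx <- match(labels, regions)
  nbrs <- radius_neighbors(xyz, contact_radius)
  touches <- matrix(FALSE, nrow(xyz), nr)
  for (i in seq_len(nrow(xyz))) {
    js <- nbrs[[i]]
    if (length(js)) touches[i, unique(lab_idx[js])] <- TRUE
  }
  out <- matrix(NA_real_, nr, nr, dimnames = list(regions, regions))
  counts <- tabulate(lab_idx, nr)
  for (ri in seq_len(nr)) {
    rows <- lab_idx == ri
    if (counts[ri] > 0) {
      out[ri, ] <- 100 * colSums(touches[rows, , drop = FALSE]) / counts[ri]
    }
  }
  attr(out, "counts") <- setNames(counts, regions)
  out
}

# Indices of all points within `radius` of each point (excluding itself),
# via kd-tree radius search with doubling k until no list saturates.
radius_neighbors <- function(xyz, radius) {
  n <- nrow(xyz)
  k <- min(n, 16L)
  repeat {
    nn <- RANN::nn2(xyz, xyz, k = k, searchtype = "radius", radius = radius)
    found <- rowSums(nn$nn.idx > 0)
    if (all(found < k) || k == n) break
    k <- min(n, 2L * k)
  }
  lapply(seq_len(n), function(i) {
    js <- nn$nn.idx[i, ]
    js[js > 0 & js != i]
  })
}

#' Build a region-interaction network
#'
#' Graph of which regions preferentially border one another: one node per
#' region, sized by its neighborhood count; an edge between two regions is
#' kept iff the contact percentage exceeds the threshold (default 0.005%,
#' deliberately permissive — nearly any observed contact qualifies). The
#' edge weight is the larger of the two directional contact percentages;
#' self-contact is kept as a node attribute rather than a loop edge.
#'
#' @param contact Matrix from [region_contact_matrix()].
#' @param threshold Edge threshold in percent of neighborhoods (default
#'   0.005); an edge is present iff contact % is strictly greater.
#' @param counts Per-region neighborhood counts; defaults to the `"counts"`
#'   attribute of `contact`.
#' @return A `region_graph`: tibbles `nodes` (`region`, `n_nbhd`,
#'   `self_contact`) and `edges` (`from`, `to`, `weight`), the `igraph`
#'   object, and the threshold. [tidy()] returns the edges.
#' @export
build_network <- function(contact, threshold = 0.005, counts = NULL) {
  counts <- counts %||% attr(contact, "counts")
  regions <- rownames(contact)
  nodes <- tibble::tibble(region = regions,
                          n_nbhd = as.integer(unname(counts[regions])),
                          self_contact = unname(diag(contact)))
  pairs <- which(upper.tri(contact), arr.ind = TRUE)
  w <- pmax(contact[pairs], contact[cbind(pairs[, 2], pairs[, 1])])
  keep <- !is.na(w) & w > threshold
  edges <- tibble::tibble(from = regions[pairs[keep, 1]],
                          to = regions[pairs[keep, 2]],
                          weight = w[keep])
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  structure(list(nodes = nodes, edges = edges, graph = g,
                 threshold = threshold, contact = contact),
            class = "region_graph")
}

#' @export
print.region_graph <- function(x, ...) {
  cat("Region interaction network: ", nrow(x$nodes), " regions, ",
      nrow(x$edges), " edges (threshold ", x$threshold, "%)\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.region_graph <- function(x, ...) x$edges

#' Write a region graph
#'
#' `write_network_tables()` emits node and edge CSVs;
#' `write_network_graphml()` a GraphML file.
#'
#' @param x A `region_graph`.
#' @param nodes_path,edges_path,path Output paths.
#' @return Paths, invisibly.
#' @export
write_network_tables <- function(x, nodes_path, edges_path) {
  readr::write_csv(x$nodes, nodes_path, progress = FALSE)
  readr::write_csv(x$edges, edges_path, progress = FALSE)
  invisible(c(nodes_path, edges_path))
}

#' @rdname write_network_tables
#' @export
write_network_graphml <- function(x, path) {
  igraph::write_graph(x$graph, path, format = "graphml")
  invisible(path)
}

#' Seeded 2-D embeddings of neighborhoods
#'
#' Wrappers around standard dimensionality-reduction methods for visualizing
#' neighborhood structure; only parameter plumbing and seeded determinism
#' are provided here. `"pca"` uses the first two principal components
#' (deterministic); `"tsne"` uses Barnes-Hut t-SNE with Euclidean distance,
#' perplexity 30, theta 0.5, and exaggeration 4 by default; `"umap"` is
#' seeded uwot.
#'
#' @param x A feature tibble or numeric matrix.
#' @param method `"pca"`, `"tsne"`, or `"umap"`.
#' @param seed RNG seed.
#' @param perplexity,theta,exaggeration t-SNE parameters.
#' @param ... Passed on to the underlying method.
#' @return An embedding tibble: `nbhd_id` (when available), `dim1`, `dim2`;
#'   method, parameters and seed as attributes.
#' @export
reduce_dimensions <- function(x, method = c("pca", "tsne", "umap"),
                              seed = 1L, perplexity = 30, theta = 0.5,
                              exaggeration = 4, ...) {
  method <- match.arg(method)
  m <- feature_matrix(x)
  if (any(!is.finite(m))) {
    abort("features must be finite", class = "tissuemap_value_error")
  }
  coords <- switch(method,
    pca = {
      pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
      cbind(pc$x[, 1], if (ncol(pc$x) > 1) pc$x[, 2] else 0)
    },
    tsne = {
      if (!requireNamespace("Rtsne", quietly = TRUE)) {
        abort("the Rtsne package is required for method = 'tsne'")
      }
      if (nrow(m) < 3 * perplexity + 1) {
        abort(paste0("t-SNE needs at least ", 3 * perplexity + 1, " rows"),
              class = "tissuemap_parameter_error")
      }
      fit <- withr::with_seed(seed,
        Rtsne::Rtsne(m, dims = 2, perplexity = perplexity, theta = theta,
                     exaggeration_factor = exaggeration,
                     check_duplicates = FALSE, pca = TRUE,
                     num_threads = 1L, ...))
      fit$Y
    },
    umap = {
      if (!requireNamespace("uwot", quietly = TRUE)) {
        abort("the uwot package is required for method = 'umap'")
      }
      withr::with_seed(seed,
        uwot::umap(m, n_components = 2, n_threads = 1, n_sgd_threads = 1, ...))
    })
  out <- tibble::tibble(dim1 = coords[, 1], dim2 = coords[, 2])
  if (!is.null(rownames(m))) {
    out <- dplyr::bind_cols(tibble::tibble(nbhd_id = rownames(m)), out)
  }
  structure(out, method = method, seed = seed,
            params = if (method == "tsne")
              list(perplexity = perplexity, theta = theta,
                   exaggeration = exaggeration),
            class = c("tissue_embedding", class(out)))
}
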