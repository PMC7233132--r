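nbhd_from_counts <- function(counts) {
  # minimal neighborhood tibble wrapping a given count matrix
  tbl <- tibble::tibble(nbhd_id = sprintf("N%06d", seq_len(nrow(counts))),
                        sample_id = "S1",
                        x = seq_len(nrow(counts)) * 1.0, y = 0, z = 0,
                        geometry = "cylinder2D",
                        n_total = rowSums(counts))
  for (j in seq_len(ncol(counts))) {
    tbl[[paste0("n_", colnames(counts)[j])]] <- counts[, j]
  }
  structure(tbl, radius = 30, spacing = 15,
            phenotypes = colnames(counts), channels = character(),
            class = c("nbhd_tbl", class(tbl)))
}

test_that("feature modes transform counts as documented", {
  counts <- cbind(A = c(2, 1, 0), B = c(2, 2, 0))
  nb <- nbhd_from_counts(counts)
  comp <- nbhd_features(nb, "composition")
  expect_equal(unname(as.matrix(comp[, -1])),
               cbind(c(0.5, 1 / 3, 0), c(0.5, 2 / 3, 0)))
  raw <- nbhd_features(nb, "raw")
  expect_equal(unname(as.matrix(raw[, -1])), unname(counts))
  std <- nbhd_features(nbhd_from_counts(cbind(A = c(1, 2, 3), B = c(5, 5, 9))),
                       "standardized")
  expect_equal(std$A, c(-1, 0, 1))
})

test_that("standardized columns have mean 0 and unit sd; zero variance warns", {
  counts <- matrix(rpois(500, 5), 100, 5,
                   dimnames = list(NULL, paste0("P", 1:5)))
  fx <- nbhd_features(nbhd_from_counts(counts), "standardized")
  m <- as.matrix(fx[, -1])
  expect_lt(max(abs(colMeans(m))), 1e-9)
  expect_lt(max(abs(apply(m, 2, sd) - 1)), 1e-9)

  counts[, 2] <- 3L
  expect_warning(
    fx0 <- nbhd_features(nbhd_from_counts(counts), "standardized"),
    regexp = "zero-variance")
  expect_true(all(as.matrix(fx0[, -1])[, 2] == 0))
})

test_that("frozen standardization statistics project held-out neighborhoods", {
  counts <- matrix(rpois(300, 5), 100, 3,
                   dimnames = list(NULL, paste0("P", 1:3)))
  train <- nbhd_features(nbhd_from_counts(counts[1:80, ]), "standardized")
  held <- nbhd_features(nbhd_from_counts(counts[81:100, ]), "standardized",
                        stats = feature_stats(train))
  st <- feature_stats(train)
  manual <- sweep(sweep(counts[81:100, ], 2, st$center), 2, st$scale, "/")
  expect_equal(unname(as.matrix(held[, -1])), unname(manual))
})

test_that("Davies-Bouldin matches hand computations", {
  # two point-mass clusters: zero scatter
  x <- matrix(c(0, 0, 10, 10), ncol = 1)
  expect_equal(davies_bouldin(x, c(1, 1, 2, 2)), 0)
  # {0,1} and {10,11}: s = 0.5 each, centroid distance 10
  x <- matrix(c(0, 1, 10, 11), ncol = 1)
  expect_equal(davies_bouldin(x, c(1, 1, 2, 2)), 0.1)
})

test_that("Davies-Bouldin matches an independent reimplementation and ranks k-means above random labels", {
  b <- make_blobs(3, 40, sd = 0.1, seed = 2)
  withr::with_seed(9, {
    for (i in 1:10) {
      labs <- sample(1:3, nrow(b$x), replace = TRUE)
      expect_equal(davies_bouldin(b$x, labs), db_oracle(b$x, labs),
                   tolerance = 1e-9)
    }
    km <- kmeans(b$x, 3, nstart = 5)
    rnd <- sample(1:3, nrow(b$x), replace = TRUE)
    expect_gt(davies_bouldin(b$x, rnd), davies_bouldin(b$x, km$cluster))
  })
  expect_error(davies_bouldin(b$x, rep(1, nrow(b$x))),
               class = "tissuemap_parameter_error")
})

test_that("the SOM recovers repeated distinct points exactly and is deterministic", {
  pts <- matrix(c(0, 0, 5, 5, 10, 0), 3, 2, byrow = TRUE)
  x <- pts[rep(1:3, each = 20), ]
  fit <- train_som(x, 3, seed = 4)
  expect_equal(sort(unique(fit$labels)), 1:3)
  expect_equal(ari(fit$labels, rep(1:3, each = 20)), 1)
  # prototypes sit on the data points
  d <- as.matrix(dist(rbind(fit$prototypes, pts)))[1:3, 4:6]
  expect_lt(max(apply(d, 1, min)), 1e-9)

  labs <- replicate(5, train_som(x, 3, seed = 4)$labels)
  expect_true(all(labs == labs[, 1]))
})

test_that("on two separable blobs the SOM equals the nearest-centroid partition", {
  b <- make_blobs(2, 60, sd = 0.1, seed = 6)
  fit <- train_som(b$x, 2, seed = 1)
  km <- kmeans(b$x, centers = rbind(colMeans(b$x[b$labels == 1, ]),
                                    colMeans(b$x[b$labels == 2, ])))
  expect_equal(ari(fit$labels, km$cluster), 1)
  expect_error(train_som(b$x, nrow(b$x) + 1, seed = 1),
               class = "tissuemap_parameter_error")
})

test_that("model selection sweeps candidate counts and picks the DB minimum", {
  b <- make_blobs(4, 40, sd = 0.1, seed = 8)
  mod <- select_regions(b$x, sweep = 2:8, seed = 3)
  expect_equal(mod$k, 4L)
  expect_equal(nrow(mod$db_curve), 7L)
  expect_equal(mod$db_curve$db[mod$db_curve$k == mod$k],
               min(mod$db_curve$db))
  # single blob: curve has one entry per candidate
  one <- make_blobs(1, 50, sd = 0.1, seed = 10)
  m1 <- select_regions(one$x, sweep = 2:5, seed = 1)
  expect_equal(nrow(m1$db_curve), 4L)
  expect_error(select_regions(b$x[1:3, ], sweep = 2:3, seed = 1),
               class = "tissuemap_insufficient_data_error")
  expect_error(select_regions(b$x, sweep = 1:5, seed = 1),
               class = "tissuemap_parameter_error")
})

test_that("duplicating the dataset does not change the selected region count", {
  b <- make_blobs(3, 30, sd = 0.1, seed = 12)
  m1 <- select_regions(b$x, sweep = 2:6, seed = 5)
  m2 <- select_regions(rbind(b$x, b$x), sweep = 2:6, seed = 5)
  expect_equal(m2$k, m1$k)
})

test_that("permuting named feature columns leaves labels unchanged", {
  counts <- matrix(rpois(600, 4), 150, 4,
                   dimnames = list(NULL, c("B", "T", "DC", "Mac")))
  fx <- nbhd_features(nbhd_from_counts(counts), "composition")
  m <- as.matrix(fx[, -1])
  f1 <- train_som(m, 3, seed = 2)
  f2 <- train_som(m[, c(3, 1, 4, 2)], 3, seed = 2)
  expect_equal(ari(f1$labels, f2$labels), 1)
})

test_that("region annotation merges labels without touching indices", {
  asg <- tibble::tibble(nbhd_id = sprintf("N%06d", 1:8),
                        region = rep(1:4, 2))
  out <- annotate_regions(asg, c("3" = "TZ", "4" = "TZ"))
  expect_equal(out$region, asg$region)
  expect_equal(unique(out$annotated_region[out$region %in% 3:4]), "TZ")
  expect_lte(length(unique(out$annotated_region)), 4L)
  expect_false("annotated_region" %in% names(annotate_regions(asg)))
  expect_error(annotate_regions(asg, c("9" = "X")),
               class = "tissuemap_parameter_error")
})
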