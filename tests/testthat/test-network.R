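test_that("a single connected region has 100% self-contact", {
  nb <- grid_nbhd(10, 10)
  asg <- tibble::tibble(nbhd_id = nb$nbhd_id, region = 1L)
  cm <- region_contact_matrix(nb, asg)
  expect_equal(unname(cm), matrix(100), ignore_attr = TRUE)
})

test_that("half-plane regions match the brute-force adjacency count", {
  nb <- grid_nbhd(20, 20)
  region <- ifelse(nb$x <= 10 * 15, 1L, 2L)
  asg <- tibble::tibble(nbhd_id = nb$nbhd_id, region = region)
  r_contact <- 1.5 * 15
  cm <- region_contact_matrix(nb, asg, contact_radius = r_contact)
  brute <- brute_contact(as.matrix(nb[, c("x", "y", "z")]), region, r_contact)
  expect_equal(unname(cm), unname(brute), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("regions farther apart than the contact radius have zero contact", {
  nb <- grid_nbhd(4, 4)
  nb2 <- grid_nbhd(4, 4)
  nb2$x <- nb2$x + 1000
  nb2$nbhd_id <- sprintf("M%06d", seq_len(nrow(nb2)))
  both <- dplyr::bind_rows(nb, nb2)
  both <- structure(both, radius = 30, spacing = 15, phenotypes = "A",
                    channels = character(),
                    class = c("nbhd_tbl", class(both)))
  asg <- tibble::tibble(nbhd_id = both$nbhd_id,
                        region = rep(1:2, each = 16))
  cm <- region_contact_matrix(both, asg)
  expect_equal(cm["1", "2"], 0)
  expect_equal(cm["2", "1"], 0)
  expect_gt(cm["1", "1"], 0)
})

test_that("edges appear only above the contact threshold", {
  contact <- matrix(c(100, 0.004, 0.004, 100), 2, 2,
                    dimnames = list(1:2, 1:2))
  attr(contact, "counts") <- c(`1` = 10L, `2` = 10L)
  g <- build_network(contact, threshold = 0.005)
  expect_equal(nrow(g$edges), 0L)
  contact[1, 2] <- contact[2, 1] <- 0.006
  g2 <- build_network(contact, threshold = 0.005)
  expect_equal(nrow(g2$edges), 1L)
  expect_equal(g2$edges$weight, 0.006)
  expect_equal(g2$nodes$self_contact, c(100, 100))
})

test_that("a three-stripe layout yields a path graph A-B-C", {
  nb <- grid_nbhd(30, 6)
  region <- cut(nb$x, breaks = c(0, 10, 20, 30) * 15 + 0.1,
                labels = c("A", "B", "C"))
  asg <- tibble::tibble(nbhd_id = nb$nbhd_id,
                        region = as.character(region))
  cm <- region_contact_matrix(nb, asg)
  g <- build_network(cm, threshold = 0.005)
  key <- paste(g$edges$from, g$edges$to)
  expect_setequal(key, c("A B", "B C"))
})

test_that("the graph is invariant under region relabeling", {
  nb <- grid_nbhd(12, 6)
  region <- ifelse(nb$x <= 6 * 15, "left", "right")
  asg <- tibble::tibble(nbhd_id = nb$nbhd_id, region = region)
  g1 <- build_network(region_contact_matrix(nb, asg))
  relab <- c(left = "R9", right = "R1")
  asg2 <- tibble::tibble(nbhd_id = nb$nbhd_id, region = relab[region])
  g2 <- build_network(region_contact_matrix(nb, asg2))
  expect_equal(nrow(g1$edges), nrow(g2$edges))
  expect_equal(sort(g1$edges$weight), sort(g2$edges$weight))
  expect_equal(sort(g1$nodes$n_nbhd), sort(g2$nodes$n_nbhd))
  expect_equal(sort(g1$nodes$self_contact), sort(g2$nodes$self_contact))
})

test_that("self-contact equals 100% minus the isolated fraction", {
  nb <- grid_nbhd(5, 1)
  nb$x[5] <- 1e4  # isolate the last neighborhood
  asg <- tibble::tibble(nbhd_id = nb$nbhd_id, region = 1L)
  cm <- region_contact_matrix(nb, asg, contact_radius = 20)
  expect_equal(cm["1", "1"], 100 * 4 / 5)
})

test_that("factor assignments with unused levels give missing rows", {
  nb <- grid_nbhd(4, 4)
  asg <- factor(rep("A", nrow(nb)), levels = c("A", "B"))
  cm <- region_contact_matrix(nb, asg)
  expect_true(all(is.na(cm["B", ])))
  expect_equal(cm["A", "A"], 100)
})

test_that("network tables and GraphML exports are written", {
  nb <- grid_nbhd(10, 4)
  region <- ifelse(nb$x <= 5 * 15, "A", "B")
  g <- build_network(region_contact_matrix(
    nb, tibble::tibble(nbhd_id = nb$nbhd_id, region = region)))
  tfn <- withr::local_tempfile(fileext = ".csv")
  tfe <- withr::local_tempfile(fileext = ".csv")
  tfg <- withr::local_tempfile(fileext = ".graphml")
  write_network_tables(g, tfn, tfe)
  write_network_graphml(g, tfg)
  expect_equal(nrow(readr::read_csv(tfn, show_col_types = FALSE)), 2L)
  expect_true(file.size(tfg) > 0)
})

test_that("PCA embeds an exact 2-D subspace with zero reconstruction error", {
  withr::with_seed(61, {
    basis <- qr.Q(qr(matrix(rnorm(10), 5, 2)))
    scores <- matrix(rnorm(200), 100, 2)
    m <- scores %*% t(basis)
  })
  emb <- reduce_dimensions(m, method = "pca")
  # the two PCs span the plane: distances are preserved
  d0 <- dist(m)
  d1 <- dist(cbind(emb$dim1, emb$dim2))
  expect_equal(as.vector(d1), as.vector(d0), tolerance = 1e-9)
})

test_that("seeded t-SNE and UMAP embeddings are reproducible and separate blobs", {
  b <- make_blobs(2, 60, sd = 0.1, seed = 63)
  e1 <- reduce_dimensions(b$x, "tsne", seed = 5)
  e2 <- reduce_dimensions(b$x, "tsne", seed = 5)
  expect_identical(e1$dim1, e2$dim1)
  co <- cbind(e1$dim1, e1$dim2)
  within1 <- as.matrix(dist(co[b$labels == 1, ]))
  between <- sqrt(sum((colMeans(co[b$labels == 1, ]) -
                         colMeans(co[b$labels == 2, ]))^2))
  expect_gt(between, quantile(within1[upper.tri(within1)], 0.95))

  u1 <- reduce_dimensions(b$x, "umap", seed = 5, n_neighbors = 10)
  u2 <- reduce_dimensions(b$x, "umap", seed = 5, n_neighbors = 10)
  expect_identical(u1$dim1, u2$dim1)

  expect_error(reduce_dimensions(b$x[1:20, ], "tsne", seed = 1),
               class = "tissuemap_parameter_error")
})
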