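# Fixture builders and independent brute-force oracles used across tests.

random_cell_table <- function(n, seed = 1, samples = 1, nphen = 3, nchan = 2,
                              box = c(0, 300), zbox = c(0, 100)) {
  withr::with_seed(seed, {
    tbl <- tibble::tibble(
      sample_id = sample(paste0("S", seq_len(samples)), n, replace = TRUE),
      phenotype = sample(LETTERS[seq_len(nphen)], n, replace = TRUE),
      x_um = runif(n, box[1], box[2]),
      y_um = runif(n, box[1], box[2]),
      z_um = runif(n, zbox[1], zbox[2]))
    for (k in seq_len(nchan)) {
      tbl[[paste0("ch_c", k)]] <- rlnorm(n, 2, 0.5)
    }
    tbl
  })
}

# All-pairs neighborhood recount: the contract for raster and cell-centered
# counting. Returns counts and summed channel intensities per center.
brute_nbhd <- function(cells, centers, radius, use_z, phenotypes) {
  chans <- grep("^ch_", names(cells), value = TRUE)
  counts <- matrix(0L, nrow(centers), length(phenotypes),
                   dimnames = list(NULL, phenotypes))
  mfi <- matrix(0, nrow(centers), length(chans),
                dimnames = list(NULL, chans))
  for (i in seq_len(nrow(centers))) {
    d2 <- (cells$x_um - centers$x[i])^2 + (cells$y_um - centers$y[i])^2
    if (use_z) d2 <- d2 + (cells$z_um - centers$z[i])^2
    member <- d2 <= radius^2
    counts[i, ] <- as.integer(table(factor(cells$phenotype[member],
                                           levels = phenotypes)))
    for (ch in chans) mfi[i, ch] <- sum(cells[[ch]][member])
  }
  list(counts = counts, mfi = mfi)
}

# Textbook Davies-Bouldin reimplementation, written independently of the
# package (explicit loops, no shared helpers).
db_oracle <- function(m, labels) {
  labs <- sort(unique(labels))
  k <- length(labs)
  cent <- list(); s <- numeric(k)
  for (i in seq_len(k)) {
    rows <- m[labels == labs[i], , drop = FALSE]
    cent[[i]] <- colMeans(rows)
    tot <- 0
    for (r in seq_len(nrow(rows))) {
      tot <- tot + sqrt(sum((rows[r, ] - cent[[i]])^2))
    }
    s[i] <- tot / nrow(rows)
  }
  acc <- 0
  for (i in seq_len(k)) {
    worst <- -Inf
    for (j in seq_len(k)) {
      if (i == j) next
      d <- sqrt(sum((cent[[i]] - cent[[j]])^2))
      worst <- max(worst, (s[i] + s[j]) / d)
    }
    acc <- acc + worst
  }
  acc / k
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Gaussian blobs with unit-separated centers on a grid.
make_blobs <- function(k, n_per, sd = 0.1, seed = 1, dim = 2) {
  centers <- as.matrix(expand.grid(rep(list(0:ceiling(sqrt(k) - 1)), dim)))[seq_len(k), , drop = FALSE]
  withr::with_seed(seed, {
    m <- do.call(rbind, lapply(seq_len(k), function(i) {
      matrix(rnorm(n_per * dim, sd = sd), n_per, dim) +
        matrix(centers[i, ], n_per, dim, byrow = TRUE)
    }))
  })
  list(x = m, labels = rep(seq_len(k), each = n_per))
}

# Dense ring of points at the given radius (for disk/annulus surfaces).
ring_points <- function(n, radius, cx = 0, cy = 0) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  cbind(cx + radius * cos(th), cy + radius * sin(th))
}

# Near-uniform points on a sphere (Fibonacci lattice).
fib_sphere <- function(n, radius = 1) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  th <- pi * (1 + sqrt(5)) * i
  radius * cbind(sin(phi) * cos(th), sin(phi) * sin(th), cos(phi))
}

# Two-compartment tissue with an interdigitated mixed middle zone.
two_zone_spec <- function() {
  tissue_spec(list(
    comp_rect("Azone", 0, 300, 0, 300, c(A = 0.008, B = 0.0002)),
    comp_rect("Bzone", 300, 600, 0, 300, c(B = 0.008, A = 0.0002)),
    comp_rect("mixed", 250, 350, 0, 300, c(A = 0.004, B = 0.004))))
}

grid_nbhd <- function(nx, ny, spacing = 15) {
  g <- expand.grid(x = seq_len(nx) * spacing, y = seq_len(ny) * spacing)
  tbl <- tibble::tibble(nbhd_id = sprintf("N%06d", seq_len(nrow(g))),
                        sample_id = "S1", x = g$x, y = g$y, z = 0,
                        geometry = "cylinder2D", n_total = 1L, n_A = 1L)
  structure(tbl, radius = 2 * spacing, spacing = spacing,
            phenotypes = "A", channels = character(),
            class = c("nbhd_tbl", class(tbl)))
}

# brute-force directional contact percentages
brute_contact <- function(xyz, labels, radius) {
  regions <- sort(unique(labels))
  out <- matrix(0, length(regions), length(regions),
                dimnames = list(regions, regions))
  d <- as.matrix(dist(xyz))
  for (ri in seq_along(regions)) {
    rows <- which(labels == regions[ri])
    for (rj in seq_along(regions)) {
      cols <- which(labels == regions[rj])
      touch <- vapply(rows, function(i) {
        any(d[i, setdiff(cols, i)] <= radius)
      }, logical(1))
      out[ri, rj] <- 100 * mean(touch)
    }
  }
  out
}

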