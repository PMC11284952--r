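# Fixtures and independent oracles shared across the test files.

# regular n-gon approximating a circle, as a tumor-field polygon
circle_field <- function(r = 1000, center = c(0, 0), n = 128L,
                         holes = list()) {
  theta <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  tt_polygon(cbind(center[1L] + r * cos(theta),
                   center[2L] + r * sin(theta)), holes)
}

circle_ring <- function(r, center = c(0, 0), n = 64L) {
  theta <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(center[1L] + r * cos(theta), center[2L] + r * sin(theta))
}

random_cells <- function(n, xlim = c(0, 1000), ylim = c(0, 1000),
                         phenotypes = timetopo_phenotypes()) {
  data.frame(cell_id = sprintf("r%05d", seq_len(n)),
             x = runif(n, xlim[1L], xlim[2L]),
             y = runif(n, ylim[1L], ylim[2L]),
             phenotype = sample(phenotypes, n, replace = TRUE))
}

# plain double-loop nearest-neighbour oracle
bf_min_dists <- function(ref, tgt, self = FALSE) {
  vapply(seq_len(nrow(ref)), function(i) {
    d <- sqrt((tgt[, 1L] - ref[i, 1L])^2 + (tgt[, 2L] - ref[i, 2L])^2)
    if (self) d[i] <- Inf
    min(d)
  }, 0)
}

# plain double-loop neighbor-count oracle over immune phenotypes
bf_count_neighbors <- function(cells, radius) {
  phen <- timetopo_immune_phenotypes()
  n <- nrow(cells)
  out <- matrix(0L, n, length(phen), dimnames = list(NULL, phen))
  codes <- match(as.character(cells$phenotype), phen)
  for (i in seq_len(n)) {
    d <- sqrt((cells$x - cells$x[i])^2 + (cells$y - cells$y[i])^2)
    ok <- d <= radius
    ok[i] <- FALSE
    out[i, ] <- tabulate(codes[ok], nbins = length(phen))
  }
  out
}

# adjusted Rand index between two partitions
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  exp_idx <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == exp_idx) return(1)
  (sum_ij - exp_idx) / (max_idx - exp_idx)
}

# end-to-end immunotype of a generated specimen
classify_specimen <- function(sp, config = timetopo_config()) {
  cells <- assign_cells_to_zones(sp$cells, sp$zones)
  dens <- compute_densities(cells, sp$zones)
  immunotype_from_densities(dens, config)
}
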