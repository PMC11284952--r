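test_that("neighbor counts handle base cases and match brute force", {
  # single immune cell: zero vector (self excluded)
  one <- as_tt_cells(data.frame(cell_id = "a", x = 0, y = 0,
                                phenotype = "t_cd8"))
  expect_identical(unname(count_neighbors(one, 50)$counts[1L, ]),
                   rep(0L, 5L))

  # three CD8 cells on a line at 0/40/80 um, radius 50
  line <- as_tt_cells(data.frame(cell_id = c("a", "b", "c"),
                                 x = c(0, 40, 80), y = 0,
                                 phenotype = "t_cd8"))
  expect_identical(unname(count_neighbors(line, 50)$counts[, "t_cd8"]),
                   c(1L, 2L, 1L))

  # non-immune cells are dropped from centers and counts
  mixed <- as_tt_cells(data.frame(cell_id = c("a", "b", "t"),
                                  x = c(0, 10, 5), y = 0,
                                  phenotype = c("t_cd8", "treg", "tumor")))
  expect_message(nb <- count_neighbors(mixed, 50), "non-immune")
  expect_identical(nrow(nb$counts), 2L)
  expect_identical(sum(nb$counts), 2L)   # only the CD8-Treg pair

  # oracle equivalence on random patterns
  set.seed(14)
  cells <- as_tt_cells(random_cells(
    400, xlim = c(0, 800), ylim = c(0, 800),
    phenotypes = timetopo_immune_phenotypes()))
  expect_identical(count_neighbors(cells, 50)$counts,
                   bf_count_neighbors(cells, 50))
})

test_that("k-means recovers planted composition blocks", {
  set.seed(4)
  # two spatially separated homogeneous discs: all-B-cell vs all-CD8
  # (uniform discs keep every cell's neighbor count well away from zero,
  # so the count profiles are linearly separable)
  blob <- function(cx, ph, n, r = 150) {
    a <- runif(n, 0, 2 * pi); rr <- r * sqrt(runif(n))
    data.frame(cell_id = sprintf("%s%03d", ph, 1:n),
               x = cx + rr * cos(a), y = rr * sin(a), phenotype = ph)
  }
  cells <- as_tt_cells(rbind(blob(0, "b_cell", 120L),
                             blob(2000, "t_cd8", 120L)))
  nb <- count_neighbors(cells, 50)
  labels <- cluster_neighborhoods(nb$counts, k = 2L, seed = 7)
  truth <- rep(1:2, each = 120L)
  expect_equal(ari(labels, truth), 1)

  # determinism under a fixed seed
  expect_identical(cluster_neighborhoods(nb$counts, k = 2L, seed = 7),
                   labels)

  # permutation of rows permutes labels consistently (same partition)
  perm <- sample(nrow(nb$counts))
  lab_perm <- cluster_neighborhoods(nb$counts[perm, ], k = 2L, seed = 7)
  expect_equal(ari(lab_perm, labels[perm]), 1)
})

test_that("degenerate and undersized inputs are handled explicitly", {
  same <- matrix(3L, nrow = 10L, ncol = 5L)
  expect_identical(cluster_neighborhoods(same, k = 4L, seed = 1),
                   rep(1L, 10L))
  expect_error(cluster_neighborhoods(matrix(0L, 2L, 5L), k = 4L),
               "clustering error")
})

test_that("cluster labels are canonicalized by descending size", {
  set.seed(2)
  counts <- rbind(matrix(rpois(300 * 5, 8), ncol = 5L),
                  matrix(rpois(30 * 5, 1), ncol = 5L))
  labels <- cluster_neighborhoods(counts, k = 2L, seed = 3)
  sizes <- table(labels)
  expect_true(all(diff(as.integer(sizes)) <= 0))
})

test_that("composition tables flag dominance at the 40% rule", {
  cells <- as_tt_cells(data.frame(
    cell_id = sprintf("c%02d", 1:10),
    x = 1:10, y = 0,
    phenotype = rep(c("t_cd4_helper", "treg", "b_cell"), c(4L, 3L, 3L))))
  comp <- neighborhood_composition(rep(1L, 10L), cells)
  cd4 <- comp[comp$phenotype == "t_cd4_helper", ]
  expect_equal(cd4$fraction, 0.40)
  expect_true(cd4$dominant)          # >= 40% counts as dominated
  expect_false(comp$dominant[comp$phenotype == "treg"])
  # fractions sum to one, counts conserve the immune total
  expect_equal(sum(comp$fraction), 1)
  expect_identical(sum(comp$count), 10L)
})

test_that("neighborhood maps round-trip and render", {
  sp <- generate_archetype("fully_infiltrated", seed = 9)
  res <- analyze_neighborhoods(assign_cells_to_zones(sp$cells, sp$zones))
  expect_identical(length(res$labels), nrow(res$map))
  expect_identical(res$map$cluster, as.integer(res$labels))
  # conservation across clusters
  expect_identical(sum(neighborhood_composition(res$labels,
                                                as_tt_cells(res$map))$count),
                   length(res$labels))
  png <- withr::local_tempfile(fileext = ".png")
  neighborhood_map(res$labels, as_tt_cells(res$map), file = png)
  expect_true(file.exists(png) && file.size(png) > 0)
})

test_that("planted two-region specimens yield spatially contiguous labels", {
  set.seed(31)
  blob <- function(cx, ph, n) {
    data.frame(cell_id = sprintf("%s%03d", ph, 1:n),
               x = rnorm(n, cx, 80), y = rnorm(n, 0, 80), phenotype = ph)
  }
  cells <- as_tt_cells(rbind(blob(0, "treg", 100L),
                             blob(1500, "macrophage_cd163", 100L)))
  nb <- count_neighbors(cells, 50)
  labels <- cluster_neighborhoods(nb$counts, k = 2L, seed = 5)
  xy <- cbind(cells$x, cells$y)
  same <- cross <- numeric(0)
  for (cl in 1:2) {
    a <- xy[labels == cl, , drop = FALSE]
    b <- xy[labels != cl, , drop = FALSE]
    same <- c(same, min_distance_to_nearest(a, a))
    cross <- c(cross, min_distance_to_nearest(a, b))
  }
  expect_lt(mean(same), mean(cross))
})
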