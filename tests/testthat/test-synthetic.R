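test_that("generated specimens are deterministic given the seed", {
  a <- generate_archetype("stroma_restricted", seed = 17)
  b <- generate_archetype("stroma_restricted", seed = 17)
  expect_identical(a$cells, b$cells)
  expect_identical(a$fields, b$fields)
  c <- generate_archetype("stroma_restricted", seed = 18)
  expect_false(identical(a$cells, c$cells))
})

test_that("zero-roughness blobs approximate circles and random blobs are valid", {
  f <- generate_tumor_fields(radius = 800, roughness = 0, n_holes = 0L,
                             seed = 1)
  expect_equal(polygon_area(f[[1L]]), pi * 800^2, tolerance = 0.01)
  for (seed in 1:20) {
    rough <- runif(1, 0, 0.3)
    f <- generate_tumor_fields(radius = runif(1, 300, 1200),
                               roughness = rough, n_holes = 0L,
                               seed = seed)
    expect_true(timetopo:::ring_is_simple(f[[1L]]$outer))
  }
  expect_error(generate_tumor_fields(radius = 50), ">= 100")
  expect_error(generate_tumor_fields(radius = 400, hole_radial = 300,
                                     hole_radius = 150), "breach")
})

test_that("cell placement follows the Poisson(density x area) law", {
  zones <- build_zones(list(circle_field(r = 564.19, n = 64L)))
  dens <- expand.grid(region = c("tumor_center", "invasive_margin"),
                      compartment = c("field", "stroma"),
                      stringsAsFactors = FALSE)
  dens$phenotype <- "t_cd8"
  dens$density <- 100

  expect_error(populate_cells(zones, transform(dens, density = -1)),
               "nonnegative")
  none <- populate_cells(zones, transform(dens, density = 0), seed = 1)
  expect_identical(nrow(none), 0L)

  expected <- 100 * zones$areas_mm2[["tumor_area"]]
  counts <- vapply(1:300, function(s) {
    nrow(populate_cells(zones, dens, seed = s))
  }, 0)
  se <- sqrt(expected / 300)
  expect_lt(abs(mean(counts) - expected), 3 * se)

  # containment: every generated cell carries the label of its source bin
  one_bin <- data.frame(region = "invasive_margin", compartment = "stroma",
                        phenotype = "treg", density = 300)
  cells <- populate_cells(zones, one_bin, seed = 5)
  lab <- assign_cells_to_zones(cells, zones)
  expect_true(all(lab$region == "invasive_margin"))
  expect_true(all(lab$compartment == "stroma"))
})

test_that("B-cell aggregates follow the Thomas process geometry", {
  zones <- build_zones(list(circle_field(r = 1000, n = 64L)))

  # forced central parent: offspring distance is Rayleigh with mean
  # sigma * sqrt(pi / 2)
  agg <- generate_b_cell_aggregates(zones, mean_offspring = 400,
                                    dispersion = 20,
                                    region = "tumor_center",
                                    compartment = "field",
                                    seed = 2, parents = rbind(c(0, 0)))
  d <- sqrt(agg$x^2 + agg$y^2)
  expect_gt(nrow(agg), 300)
  expect_lt(abs(mean(d) - 20 * sqrt(pi / 2)), 3 * 20 * sqrt((4 - pi) / 2) /
              sqrt(nrow(agg)))
  lab <- assign_cells_to_zones(agg, zones)
  expect_true(all(lab$region == "tumor_center"))

  # zero parents -> empty
  empty <- generate_b_cell_aggregates(zones, parent_intensity = 0, seed = 3)
  expect_identical(nrow(empty), 0L)
  expect_error(generate_b_cell_aggregates(zones, dispersion = 0), "dispersion")

  # clustering: aggregated cells have stochastically smaller
  # nearest-neighbour distances than a Poisson pattern of equal intensity
  wins <- trials <- 0L
  for (s in 1:25) {
    agg <- generate_b_cell_aggregates(zones, parent_intensity = 2,
                                      mean_offspring = 25, dispersion = 30,
                                      seed = s)
    if (nrow(agg) < 10) next    # Poisson parent draw may be empty
    pois <- populate_cells(zones, data.frame(
      region = "invasive_margin", compartment = "stroma",
      phenotype = "b_cell",
      density = nrow(agg) / zones$areas_mm2[["invasive_margin_stroma"]]),
      seed = s + 1000)
    if (nrow(pois) < 10) next
    nnd_agg <- median(min_distance_to_nearest(agg, agg))
    nnd_pois <- median(min_distance_to_nearest(pois, pois))
    trials <- trials + 1L
    wins <- wins + (nnd_agg < nnd_pois)
  }
  expect_gte(trials, 15L)
  expect_gte(wins / trials, 0.9)
})

test_that("stroma-restricted specimens have lower CD8 density in fields than stroma", {
  for (s in 1:3) {
    sp <- generate_archetype("stroma_restricted", seed = s)
    cells <- assign_cells_to_zones(sp$cells, sp$zones)
    dens <- compute_densities(cells, sp$zones)
    tf <- density_of(dens, "tumor_area", "field", "t_cd8")
    ts <- density_of(dens, "tumor_area", "stroma", "t_cd8")
    expect_lt(density_ratio(tf, ts), 1)
  }
})

test_that("an immune-desert specimen with zero immune densities classifies as desert", {
  fields <- generate_tumor_fields(seed = 4)
  zones <- build_zones(fields)
  dens <- data.frame(region = rep(c("tumor_center", "invasive_margin"), 2L),
                     compartment = rep(c("field", "stroma"), each = 2L),
                     phenotype = "tumor", density = c(1000, 1000, 0, 0))
  cells <- populate_cells(zones, dens, seed = 4)
  call <- immunotype_from_densities(compute_densities(cells, zones))
  expect_identical(call$label, "immune_desert")
})

test_that("synthetic NPX matrices carry the injected plate structure", {
  # no shifts, no noise, no sample effects: per-plate medians already
  # equal the overall median
  npx <- generate_npx(n_proteins = 10L, n_samples = 8L,
                      plate_shifts = c(A = 0, B = 0), missing_rate = 0,
                      noise_sd = 0, sample_sd = 0, seed = 6)
  for (p in seq_len(10L)) {
    for (pl in c("A", "B")) {
      expect_equal(median(npx$values[p, npx$plate == pl]),
                   median(npx$values[p, ]), tolerance = 1e-12)
    }
  }
  # missingness rate matches its binomial expectation over seeds
  miss <- vapply(1:100, function(s) {
    mean(generate_npx(n_proteins = 20L, n_samples = 10L,
                      missing_rate = 0.2, seed = s)$missing)
  }, 0)
  expect_lt(abs(mean(miss) - 0.2), 3 * sqrt(0.2 * 0.8 / (200 * 100)))
})
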