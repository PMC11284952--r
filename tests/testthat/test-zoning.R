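test_that("circular tumor field reproduces closed-form zone areas", {
  field <- circle_field(r = 1000, n = 128L)
  zones <- build_zones(list(field))
  a <- zones$areas_mm2
  expect_equal(a[["tumor_area"]], pi * 1.25^2, tolerance = 0.01)
  expect_equal(a[["invasive_margin"]], pi * 1.0, tolerance = 0.01)
  expect_equal(a[["tumor_center"]], pi * 0.75^2, tolerance = 0.01)
  # exact partition by construction
  expect_equal(a[["invasive_margin"]] + a[["tumor_center"]],
               a[["tumor_area"]], tolerance = 1e-9)
})

test_that("distant tumor fields give disjoint tumor-area components", {
  f1 <- circle_field(r = 1000, center = c(0, 0))
  f2 <- circle_field(r = 1000, center = c(10000, 0))
  ta <- build_tumor_area(list(f1, f2), 250)
  expect_length(ta$rings, 2L)
  expect_equal(ta$area_um2 / 1e6, 2 * pi * 1.25^2, tolerance = 0.01)
})

test_that("overlapping buffered components are merged in area", {
  # centers 2200 um apart: fields disjoint but 250 um buffers overlap
  f1 <- circle_field(r = 1000, center = c(0, 0))
  f2 <- circle_field(r = 1000, center = c(2200, 0))
  ta <- build_tumor_area(list(f1, f2), 250)
  # lens area of two r=1250 discs at distance 2200
  r <- 1250; d <- 2200
  lens <- 2 * r^2 * acos(d / (2 * r)) - d / 2 * sqrt(4 * r^2 - d^2)
  expect_equal(ta$area_um2 / 1e6, (2 * pi * r^2 - lens) / 1e6,
               tolerance = 0.01)
})

test_that("a field narrower than the margin band has an empty tumor center", {
  field <- circle_field(r = 200, n = 64L)
  expect_message(zones <- build_zones(list(field)), "tumor center empty")
  expect_equal(zones$areas_mm2[["tumor_center"]], 0)
  expect_equal(zones$areas_mm2[["invasive_margin"]],
               zones$areas_mm2[["tumor_area"]])
})

test_that("zone area invariants hold across random blob landscapes", {
  for (seed in 1:5) {
    fields <- generate_tumor_fields(radius = 900, roughness = 0.12,
                                    n_holes = 2L, hole_radius = 150,
                                    hole_radial = 350, seed = seed)
    zones <- build_zones(fields)
    a <- zones$areas_mm2
    expect_true(all(a >= 0))
    # partition and compartment additivity
    expect_equal(a[["invasive_margin"]] + a[["tumor_center"]],
                 a[["tumor_area"]], tolerance = 1e-9)
    expect_equal(a[["tumor_area_field"]] + a[["tumor_area_stroma"]],
                 a[["tumor_area"]], tolerance = 1e-9)
    expect_equal(a[["tumor_center_field"]] + a[["tumor_center_stroma"]],
                 a[["tumor_center"]], tolerance = 1e-9)
    # buffered area dominates the raw field union, monotone in buffer
    fa <- sum(vapply(fields, function(f) ring_area(f$outer), 0)) / 1e6
    expect_gt(a[["tumor_area"]], fa)
    bigger <- build_tumor_area(fields, 400)$area_um2 / 1e6
    expect_gte(bigger, a[["tumor_area"]])
    # traced contours are simple polygons
    for (r in c(zones$tumor_area$rings, zones$tumor_center$rings)) {
      expect_true(timetopo:::ring_is_simple(r))
    }
  }
})

test_that("invasive margin equals tumor area minus tumor center", {
  fields <- generate_tumor_fields(seed = 3)
  ta <- build_tumor_area(fields, 250)
  im <- build_invasive_margin(fields, ta, halfwidth = 250)
  tc <- build_tumor_center(fields, 250)
  expect_equal(im$area_um2, ta$area_um2 - tc$area_um2)
  expect_length(im$outer_rings, length(ta$rings))
})

test_that("cell zone assignment matches the closed-form circle oracle", {
  field <- circle_field(r = 1000, n = 256L)
  zones <- build_zones(list(field))
  set.seed(11)
  n <- 1000L
  cells <- as_tt_cells(data.frame(
    cell_id = sprintf("c%04d", 1:n),
    x = runif(n, -1500, 1500), y = runif(n, -1500, 1500),
    phenotype = "t_cd8"))
  got <- assign_cells_to_zones(cells, zones)
  r <- sqrt(cells$x^2 + cells$y^2)
  # keep cells clear of discretization boundaries of the 256-gon (< 0.5 um)
  clear <- abs(r - 750) > 2 & abs(r - 1000) > 2 & abs(r - 1250) > 2
  expected <- ifelse(r < 750, "tumor_center",
                     ifelse(r <= 1250, "invasive_margin", "outside"))
  expect_identical(as.character(got$region)[clear], expected[clear])
  expected_comp <- ifelse(r > 1250, NA, ifelse(r <= 1000, "field", "stroma"))
  expect_identical(as.character(got$compartment)[clear],
                   expected_comp[clear])
})

test_that("boundary cells are assigned by the stated precedence rules", {
  field <- circle_field(r = 1000, n = 128L)
  zones <- build_zones(list(field))
  probe <- as_tt_cells(data.frame(
    cell_id = c("center_of_field", "far_outside"),
    x = c(0, 1000 + 300 + 250), y = c(0, 0),
    phenotype = "tumor"))
  got <- assign_cells_to_zones(probe, zones)
  expect_identical(as.character(got$region),
                   c("tumor_center", "outside"))
  expect_identical(as.character(got$compartment), c("field", NA))
})

test_that("every in-area cell falls in exactly one region-compartment bin", {
  sp <- generate_archetype("fully_infiltrated", seed = 5)
  cells <- assign_cells_to_zones(sp$cells, sp$zones)
  inside <- cells[cells$region != "outside", ]
  expect_false(any(is.na(inside$compartment)))
  bins <- table(inside$region, inside$compartment)
  expect_equal(sum(bins), nrow(inside))
})
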