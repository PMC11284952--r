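test_that("densities are count/area and conserve counts across bins", {
  field <- circle_field(r = 1000, n = 128L)
  zones <- build_zones(list(field))
  set.seed(3)
  n <- 800L
  theta <- runif(n, 0, 2 * pi)
  r <- sqrt(runif(n)) * 1400
  cells <- as_tt_cells(data.frame(
    cell_id = sprintf("c%04d", 1:n), x = r * cos(theta), y = r * sin(theta),
    phenotype = sample(timetopo_phenotypes(), n, replace = TRUE)))
  cells <- assign_cells_to_zones(cells, zones)
  dens <- compute_densities(cells, zones, specimen_id = "sp1")

  # brute-force tally oracle per (region, compartment, phenotype)
  for (ph in c("t_cd8", "tumor", "b_cell")) {
    for (rg in c("tumor_center", "invasive_margin")) {
      for (cp in c("field", "stroma")) {
        expected <- sum(cells$phenotype == ph & cells$region == rg &
                          !is.na(cells$compartment) & cells$compartment == cp)
        got <- dens[dens$region == rg & dens$compartment == cp &
                      dens$phenotype == ph, ]
        expect_identical(got$count, as.integer(expected))
        expect_equal(got$density, expected / got$area_mm2)
      }
    }
    # marginal conservation: zone counts sum to the in-area total
    inarea <- sum(cells$phenotype == ph & cells$region != "outside")
    expect_identical(
      dens$count[dens$region == "tumor_area" & dens$compartment == "all" &
                   dens$phenotype == ph],
      as.integer(inarea))
    expect_identical(
      sum(dens$count[dens$compartment != "all" & dens$phenotype == ph &
                       dens$region != "tumor_area"]),
      as.integer(inarea))
  }
})

test_that("empty zones yield zero counts and densities", {
  zones <- build_zones(list(circle_field(r = 1000)))
  cells <- as_tt_cells(data.frame(cell_id = "a", x = 0, y = 0,
                                  phenotype = "tumor"))
  dens <- compute_densities(assign_cells_to_zones(cells, zones), zones)
  row <- dens[dens$region == "invasive_margin" & dens$compartment == "all" &
                dens$phenotype == "t_cd8", ]
  expect_identical(row$count, 0L)
  expect_identical(row$density, 0)
})

test_that("density ratios follow the degenerate-denominator rule", {
  expect_equal(density_ratio(50, 100), 0.5)
  expect_true(is.na(density_ratio(50, 0)))
  expect_true(is.na(density_ratio(NA, 100)))
})

test_that("the cohort tumor-field threshold is the cohort median", {
  fake_dt <- function(v) {
    data.frame(specimen_id = "x", region = "tumor_area",
               compartment = "field", phenotype = "t_cd8", count = 1L,
               area_mm2 = 1, density = v)
  }
  cfg <- timetopo_config(tf_cd8_threshold_mode = "cohort_median")
  expect_equal(cohort_tf_threshold(lapply(c(10, 82.8, 200), fake_dt), cfg),
               82.8)
  expect_equal(cohort_tf_threshold(list(fake_dt(55)), cfg), 55)
  expect_error(cohort_tf_threshold(list(), cfg), "empty cohort")
  # fixed mode ignores the cohort
  expect_equal(cohort_tf_threshold(list(fake_dt(55))), 82.8)
  # sort-based oracle on random cohorts
  set.seed(9)
  for (i in 1:20) {
    v <- runif(sample(3:15, 1), 0, 500)
    srt <- sort(v)
    n <- length(srt)
    oracle <- if (n %% 2 == 1) srt[(n + 1) / 2] else
      mean(srt[n / 2 + 0:1])
    expect_equal(cohort_tf_threshold(lapply(v, fake_dt), cfg), oracle)
  }
})

test_that("the immunotype decision tree follows the published branches", {
  expect_identical(call_immunotype(150, 90, 300)$label, "fully_infiltrated")
  expect_identical(call_immunotype(150, 50, 300)$label, "stroma_restricted")
  expect_identical(call_immunotype(50, 90, 300)$label, "immune_excluded")
  expect_identical(call_immunotype(50, 90, 100)$label, "immune_desert")
  # strict inequalities: equality falls to the lower branch
  expect_identical(call_immunotype(100, 90, 200)$label, "immune_desert")
  expect_identical(call_immunotype(100.01, 82.8, 0)$label,
                   "stroma_restricted")
  # missing density on the taken branch is an error naming the zone
  expect_error(call_immunotype(150, NA, 300), "tumor-field")
  expect_error(call_immunotype(50, 90, NA), "invasive-margin")
  expect_error(call_immunotype(NA, 90, 100), "tumor-center")
  # unused branch densities may be missing
  expect_identical(call_immunotype(150, 90, NA)$label, "fully_infiltrated")
})

test_that("relabelling from the recorded densities is idempotent", {
  cases <- list(c(150, 90, 300), c(150, 50, 300), c(50, 90, 300),
                c(50, 90, 100), c(0, 0, 0), c(1e4, 1e4, 1e4))
  for (cs in cases) {
    call <- call_immunotype(cs[1], cs[2], cs[3])
    again <- call_immunotype(call$tc_cd8, call$tf_cd8, call$im_cd8)
    expect_identical(again$label, call$label)
    expect_identical(again$decision_path, call$decision_path)
  }
})

test_that("immunotyping is refused for biopsies", {
  dt <- data.frame(specimen_id = "b1", region = "tumor_area",
                   compartment = "all", phenotype = "t_cd8", count = 0L,
                   area_mm2 = 1, density = 0)
  expect_error(immunotype_from_densities(dt, kind = "biopsy"), "refused")
})

test_that("cohort immunotype summaries reproduce the published arithmetic", {
  labels <- rep(c("fully_infiltrated", "stroma_restricted",
                  "immune_excluded", "immune_desert"), c(14L, 7L, 6L, 2L))
  s <- summarize_immunotypes(labels)
  expect_identical(as.integer(s$counts), c(14L, 7L, 6L, 2L))
  expect_identical(round(unname(s$percent)), c(48, 24, 21, 7))
  expect_identical(round(s$tc_infiltrated_pct), 72)
  expect_error(summarize_immunotypes(c("nope")), "unknown")
})

test_that("phenotype fractions partition their subset and conserve counts", {
  zones <- build_zones(list(circle_field(r = 1000)))
  set.seed(21)
  n <- 60L
  cells <- as_tt_cells(data.frame(
    cell_id = sprintf("c%03d", 1:n),
    x = runif(n, -400, 400), y = runif(n, -400, 400),   # all tumor center
    phenotype = "t_cd8"))
  cells$cd103 <- rep(c(TRUE, FALSE), c(36L, 24L))
  cells <- assign_cells_to_zones(cells, zones)
  fr <- phenotype_fractions(cells, group_by = "cd103",
                            subset = cells$phenotype == "t_cd8")
  resident <- fr[fr$zone == "tumor_center" & fr$group == "TRUE", ]
  expect_equal(resident$fraction, 0.6)
  expect_equal(sum(fr$fraction[fr$zone == "tumor_center"]), 1)
  expect_identical(sum(fr$count), n)
  # fractions times subset size reproduce counts
  expect_equal(fr$fraction * sum(fr$count), fr$count)
})
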