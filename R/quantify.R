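# Zone-wise quantification: densities (cells/mm^2), ratios, phenotype
# fractions, and the four-way CD8 immunotype decision tree.

#' Compute zone-wise phenotype densities
#'
#' One row per (region, compartment, phenotype) with count, zone area and
#' density, including the `all`-compartment marginals and the whole
#' tumor-area marginals. Cells labelled `outside` are excluded.
#'
#' @param cells a `tt_cells` data.frame carrying `region`/`compartment`
#'   labels (see [assign_cells_to_zones()]); unlabelled cells are assigned
#'   first when `zones` is given.
#' @param zones a `zone_set`.
#' @param specimen_id recorded in the output (taken from `cells` if
#'   present).
#' @return data.frame of class `density_table` with columns
#'   `specimen_id`, `region`, `compartment`, `phenotype`, `count`,
#'   `area_mm2`, `density`. Density is `NA` where the zone area is zero.
#' @export
compute_densities <- function(cells, zones, specimen_id = NULL) {
  if (!"region" %in% names(cells)) {
    cells <- assign_cells_to_zones(cells, zones)
  }
  if (is.null(specimen_id)) {
    specimen_id <- if ("specimen_id" %in% names(cells) && nrow(cells)) {
      as.character(cells$specimen_id[1L])
    } else {
      "specimen"
    }
  }
  inside <- cells[cells$region != "outside" & !is.na(cells$region), ]
  phenos <- timetopo_phenotypes()
  regions <- c("tumor_area", "tumor_center", "invasive_margin")
  comps <- c("all", "field", "stroma")
  rows <- list()
  for (rg in regions) {
    sub_r <- if (rg == "tumor_area") inside else inside[inside$region == rg, ]
    for (cp in comps) {
      sub <- if (cp == "all") sub_r else sub_r[!is.na(sub_r$compartment) &
                                               sub_r$compartment == cp, ]
      area_key <- if (cp == "all") rg else paste(rg, cp, sep = "_")
      area <- unname(zones$areas_mm2[[area_key]])
      cnt <- table(factor(sub$phenotype, levels = phenos))
      rows[[length(rows) + 1L]] <- data.frame(
        specimen_id = specimen_id, region = rg, compartment = cp,
        phenotype = phenos, count = as.integer(cnt),
        area_mm2 = area,
        density = if (area > 0) as.numeric(cnt) / area else NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (any(out$area_mm2 == 0)) {
    message("[quantify] zero-area zone(s); densities recorded missing")
  }
  class(out) <- c("density_table", "data.frame")
  out
}

#' Look up one density in a density table
#' @param dt a `density_table`.
#' @param region,compartment,phenotype row selector (compartment `"all"`
#'   for the zone marginal).
#' @return density in cells/mm^2, or `NA` when absent.
#' @export
density_of <- function(dt, region, compartment, phenotype) {
  hit <- dt$region == region & dt$compartment == compartment &
    dt$phenotype == phenotype
  if (!any(hit)) return(NA_real_)
  dt$density[hit][1L]
}

#' Ratio of two densities
#'
#' Missing when the denominator is zero or either input is missing.
#' @param density_a,density_b densities in cells/mm^2.
#' @return numeric ratio or `NA`.
#' @export
density_ratio <- function(density_a, density_b) {
  ifelse(is.na(density_a) | is.na(density_b) | density_b == 0,
         NA_real_, density_a / density_b)
}

#' Cohort tumor-field CD8 threshold
#'
#' The tumor-field branch threshold of the decision tree: either the
#' configured fixed value (the published cohort median, 82.8 cells/mm^2)
#' or the median tumor-field CD8 density recomputed over the given cohort.
#'
#' @param density_tables list of `density_table`s (one per resection
#'   specimen).
#' @param config a [timetopo_config()].
#' @return threshold in cells/mm^2.
#' @export
cohort_tf_threshold <- function(density_tables, config = timetopo_config()) {
  if (config$tf_cd8_threshold_mode == "fixed") {
    return(config$tf_cd8_threshold_fixed)
  }
  vals <- vapply(density_tables, density_of, 0,
                 region = "tumor_area", compartment = "field",
                 phenotype = "t_cd8")
  vals <- vals[!is.na(vals)]
  if (!length(vals)) stop("empty cohort: no tumor-field CD8 densities")
  stats::median(vals)
}

#' Assign the CD8 immunotype of a resection specimen
#'
#' The decision tree over CD8+ T-cell densities: tumor center above the
#' 100 cells/mm^2 threshold splits infiltrated tumors, which are fully
#' infiltrated when the tumor-field density also exceeds the tumor-field
#' threshold (82.8 cells/mm^2 by default) and stroma-restricted otherwise;
#' non-infiltrated tumors are immune-excluded when the invasive margin
#' exceeds 200 cells/mm^2 and immune-desert otherwise. All comparisons are
#' strict (`>`); equality falls to the lower branch.
#'
#' @param tc_cd8 CD8 density in the tumor center, cells/mm^2.
#' @param tf_cd8 CD8 density in tumor fields (whole tumor area).
#' @param im_cd8 CD8 density in the invasive margin.
#' @param config a [timetopo_config()] carrying the thresholds.
#' @param tf_threshold overrides the tumor-field threshold (e.g. a cohort
#'   median from [cohort_tf_threshold()]).
#' @param specimen_id recorded in the call.
#' @return object of class `immunotype_call` with fields `label`,
#'   `tc_cd8`, `tf_cd8`, `im_cd8`, `thresholds`, `decision_path`.
#' @export
call_immunotype <- function(tc_cd8, tf_cd8, im_cd8,
                            config = timetopo_config(),
                            tf_threshold = NULL,
                            specimen_id = "specimen") {
  thr <- c(tc = config$tc_cd8_threshold,
           tf = if (is.null(tf_threshold)) config$tf_cd8_threshold_fixed
                else tf_threshold,
           im = config$im_cd8_threshold)
  if (is.na(tc_cd8)) {
    stop("classification error: tumor-center CD8 density is missing")
  }
  path <- character()
  if (tc_cd8 > thr[["tc"]]) {
    path <- sprintf("tc %.6g > %.6g", tc_cd8, thr[["tc"]])
    if (is.na(tf_cd8)) {
      stop("classification error: tumor-field CD8 density is missing")
    }
    if (tf_cd8 > thr[["tf"]]) {
      label <- "fully_infiltrated"
      path <- c(path, sprintf("tf %.6g > %.6g", tf_cd8, thr[["tf"]]))
    } else {
      label <- "stroma_restricted"
      path <- c(path, sprintf("tf %.6g <= %.6g", tf_cd8, thr[["tf"]]))
    }
  } else {
    path <- sprintf("tc %.6g <= %.6g", tc_cd8, thr[["tc"]])
    if (is.na(im_cd8)) {
      stop("classification error: invasive-margin CD8 density is missing")
    }
    if (im_cd8 > thr[["im"]]) {
      label <- "immune_excluded"
      path <- c(path, sprintf("im %.6g > %.6g", im_cd8, thr[["im"]]))
    } else {
      label <- "immune_desert"
      path <- c(path, sprintf("im %.6g <= %.6g", im_cd8, thr[["im"]]))
    }
  }
  structure(list(specimen_id = specimen_id, label = label,
                 tc_cd8 = tc_cd8, tf_cd8 = tf_cd8, im_cd8 = im_cd8,
                 thresholds = thr, decision_path = path),
            class = "immunotype_call")
}

#' @export
print.immunotype_call <- function(x, ...) {
  cat(sprintf("<immunotype_call> %s: %s\n", x$specimen_id, x$label))
  cat(sprintf("  tc %.1f / tf %.1f / im %.1f cells/mm^2\n",
              x$tc_cd8, x$tf_cd8, x$im_cd8))
  cat("  path:", paste(x$decision_path, collapse = " ; "), "\n")
  invisible(x)
}

#' Immunotype a specimen from its density table
#'
#' @param density_table a `density_table` of a resection specimen.
#' @param kind `"resection"` or `"biopsy"`; biopsies have no invasive
#'   margin on the slide and classification is refused.
#' @inheritParams call_immunotype
#' @return an `immunotype_call`.
#' @export
immunotype_from_densities <- function(density_table,
                                      config = timetopo_config(),
                                      tf_threshold = NULL,
                                      kind = "resection") {
  if (kind != "resection") {
    stop("immunotyping refused: only resection specimens carry an invasive margin")
  }
  call_immunotype(
    tc_cd8 = density_of(density_table, "tumor_center", "all", "t_cd8"),
    tf_cd8 = density_of(density_table, "tumor_area", "field", "t_cd8"),
    im_cd8 = density_of(density_table, "invasive_margin", "all", "t_cd8"),
    config = config, tf_threshold = tf_threshold,
    specimen_id = as.character(density_table$specimen_id[1L]))
}

#' Summarize immunotype labels across a cohort
#'
#' Counts, percentages, and the share of specimens with CD8 infiltration
#' into the tumor center (fully infiltrated plus stroma-restricted).
#'
#' @param labels character vector of immunotype labels.
#' @return list with `counts`, `percent` and `tc_infiltrated_pct`.
#' @export
summarize_immunotypes <- function(labels) {
  lv <- c("fully_infiltrated", "stroma_restricted", "immune_excluded",
          "immune_desert")
  bad <- setdiff(unique(labels), lv)
  if (length(bad)) stop("unknown immunotype label(s): ",
                        paste(bad, collapse = ", "))
  cnt <- table(factor(labels, levels = lv))
  pct <- 100 * as.numeric(cnt) / sum(cnt)
  names(pct) <- lv
  list(counts = cnt, percent = pct,
       tc_infiltrated_pct = unname(pct[["fully_infiltrated"]] +
                                   pct[["stroma_restricted"]]))
}

#' Phenotype or marker-flag fractions per zone
#'
#' Fractions of a grouping over a cell subset, computed per region (e.g.
#' the resident/recruited CD103 split of CD8+ T cells, or the share of
#' each phenotype among all detected cells).
#'
#' @param cells a `tt_cells` data.frame with zone labels.
#' @param group_by column name defining the grouping (e.g. `"phenotype"`,
#'   `"cd103"`, `"ki67"`).
#' @param subset optional logical vector restricting the cells (e.g.
#'   `cells$phenotype == "t_cd8"`).
#' @param by_compartment split by field/stroma compartment instead of
#'   center/margin region.
#' @return data.frame with columns `zone`, `group`, `count`, `fraction`;
#'   fractions sum to 1 within each non-empty zone.
#' @export
phenotype_fractions <- function(cells, group_by = "phenotype",
                                subset = NULL, by_compartment = FALSE) {
  stopifnot(group_by %in% names(cells))
  if (!is.null(subset)) cells <- cells[subset, ]
  cells <- cells[!is.na(cells$region) & cells$region != "outside", ]
  zone_col <- if (by_compartment) cells$compartment else cells$region
  rows <- list()
  for (zn in unique(as.character(zone_col[!is.na(zone_col)]))) {
    sub <- cells[!is.na(zone_col) & zone_col == zn, ]
    cnt <- table(sub[[group_by]], useNA = "no")
    tot <- sum(cnt)
    rows[[length(rows) + 1L]] <- data.frame(
      zone = zn, group = names(cnt), count = as.integer(cnt),
      fraction = if (tot > 0) as.numeric(cnt) / tot else NA_real_)
  }
  if (!length(rows)) {
    return(data.frame(zone = character(0), group = character(0),
                      count = integer(0), fraction = numeric(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
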