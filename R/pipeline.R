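# Cohort orchestration: run every analysis stage over a directory of
# specimens and render the result as CSV tables, figures and a summary.

process_specimen <- function(sdir, config) {
  cells <- read_cell_table(file.path(sdir, "cells.csv"), quiet = TRUE)
  fields <- read_annotations(file.path(sdir, "fields.geojson"))
  md <- read_metadata(file.path(sdir, "metadata.csv"))
  kind <- if ("kind" %in% names(md)) md$kind[1L] else "resection"
  zones <- build_zones(fields, config)
  cells <- assign_cells_to_zones(cells, zones)
  dens <- compute_densities(cells, zones,
                            specimen_id = md$specimen_id[1L])
  call <- if (kind == "resection") {
    immunotype_from_densities(dens, config, kind = kind)
  } else {
    NULL   # biopsies carry no invasive margin; immunotyping refused
  }
  amd_m <- amd_matrix(cells)
  imm_ph <- timetopo_immune_phenotypes()
  tumor <- cells[cells$phenotype == "tumor", ]
  rf <- do.call(rbind, lapply(imm_ph, function(p) {
    res <- radius_fraction(tumor, cells[cells$phenotype == p, ],
                           r = config$radius_fraction_r,
                           counted_phenotype = "tumor",
                           probe_phenotype = p)
    data.frame(counted = "tumor", probe = p, radius = res$radius,
               fraction = res$fraction, n_counted = res$n_counted)
  }))
  nbhd <- tryCatch(analyze_neighborhoods(cells, config),
                   error = function(e) NULL)
  list(specimen_id = md$specimen_id[1L], kind = kind, metadata = md,
       zones = zones, cells = cells, densities = dens,
       immunotype = call, amd_matrix = amd_m, radius_fractions = rf,
       neighborhoods = nbhd, status = "processed", reason = NA_character_)
}

#' Run the full pipeline over a cohort directory
#'
#' Each specimen subdirectory must contain `cells.csv`, `fields.geojson`
#' and `metadata.csv` (see [simulate_cohort()] for the layout). Stages:
#' zoning, zone assignment, densities, immunotype (resections only), AMD
#' matrix, 10 um radius fractions, cellular neighborhoods. Failures are
#' isolated per specimen: the specimen is recorded as skipped with its
#' reason and the pipeline continues.
#'
#' @param cohort_dir directory of specimen subdirectories.
#' @param config a [timetopo_config()].
#' @return object of class `cohort_result`: `specimens` (per-specimen
#'   results), `immunotypes` (calls data.frame), `densities` (stacked
#'   density table), `config`, `seed`.
#' @export
run_pipeline <- function(cohort_dir, config = timetopo_config()) {
  sdirs <- list.dirs(cohort_dir, recursive = FALSE)
  if (!length(sdirs)) stop("empty cohort directory: ", cohort_dir)
  specimens <- lapply(sdirs, function(sd) {
    tryCatch(process_specimen(sd, config), error = function(e) {
      message(sprintf("[pipeline] skipping %s: %s", basename(sd),
                      conditionMessage(e)))
      list(specimen_id = basename(sd), status = "skipped",
           reason = conditionMessage(e))
    })
  })
  names(specimens) <- vapply(specimens, `[[`, "", "specimen_id")
  ok <- vapply(specimens, function(s) s$status == "processed", TRUE)
  if (!any(ok)) stop("pipeline error: zero specimens processed")
  calls <- do.call(rbind, lapply(specimens[ok], function(s) {
    if (is.null(s$immunotype)) return(NULL)
    data.frame(specimen_id = s$specimen_id, label = s$immunotype$label,
               tc_cd8 = s$immunotype$tc_cd8, tf_cd8 = s$immunotype$tf_cd8,
               im_cd8 = s$immunotype$im_cd8)
  }))
  dens <- do.call(rbind, lapply(specimens[ok], function(s) s$densities))
  rownames(dens) <- NULL
  structure(list(specimens = specimens, immunotypes = calls,
                 densities = dens, config = config,
                 seed = config$random_seed),
            class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  ok <- vapply(x$specimens, function(s) s$status == "processed", TRUE)
  cat(sprintf("<cohort_result> %d specimen(s): %d processed, %d skipped\n",
              length(x$specimens), sum(ok), sum(!ok)))
  if (!is.null(x$immunotypes)) print(table(x$immunotypes$label))
  invisible(x)
}

#' Render a cohort result to files
#'
#' Writes the already-computed tables (no analysis is re-run): immunotype
#' calls, stacked densities, per-specimen AMD matrices and radius
#' fractions, neighborhood compositions and maps (PNG), and a
#' `summary.txt` manifest. Idempotent.
#'
#' @param result a `cohort_result`.
#' @param out_dir output directory (created).
#' @return invisibly, the paths written.
#' @export
render_report <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
    p
  }
  if (!is.null(result$immunotypes)) wr(result$immunotypes, "immunotypes.csv")
  wr(result$densities, "densities.csv")
  for (s in result$specimens) {
    if (s$status != "processed") next
    amd_df <- as.data.frame(as.table(s$amd_matrix),
                            stringsAsFactors = FALSE)
    names(amd_df) <- c("reference", "target", "amd_um")
    wr(amd_df, sprintf("%s_amd.csv", s$specimen_id))
    wr(s$radius_fractions, sprintf("%s_radius_fractions.csv", s$specimen_id))
    if (!is.null(s$neighborhoods)) {
      wr(s$neighborhoods$composition,
         sprintf("%s_neighborhood_composition.csv", s$specimen_id))
      png <- file.path(out_dir, sprintf("%s_neighborhood_map.png",
                                        s$specimen_id))
      neighborhood_map(s$neighborhoods$labels,
                       s$neighborhoods$map, file = png)
      paths <- c(paths, png)
    }
  }
  status <- do.call(rbind, lapply(result$specimens, function(s) {
    data.frame(specimen_id = s$specimen_id, status = s$status,
               reason = if (is.null(s$reason)) NA_character_ else s$reason)
  }))
  wr(status, "specimen_status.csv")
  summary_path <- file.path(out_dir, "summary.txt")
  lines <- c("timetopo cohort report",
             sprintf("seed: %d", result$seed),
             sprintf("specimens processed: %d",
                     sum(status$status == "processed")),
             "files:", paste(" ", basename(paths)))
  writeLines(lines, summary_path)
  invisible(c(paths, summary_path))
}
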