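# Pipeline configuration: all numeric constants of the analysis live here.

#' Closed phenotype vocabulary
#'
#' Seven-color panel phenotypes. `timetopo_immune_phenotypes()` returns the
#' five immune phenotypes that enter density ratios, distance statistics
#' and neighborhood analysis; tumor and other cells never do.
#' @return character vector of phenotype labels.
#' @export
timetopo_phenotypes <- function() {
  c("tumor", "macrophage_cd163", "b_cell", "t_cd8", "t_cd4_helper",
    "treg", "other")
}

#' @rdname timetopo_phenotypes
#' @export
timetopo_immune_phenotypes <- function() {
  c("macrophage_cd163", "b_cell", "t_cd8", "t_cd4_helper", "treg")
}

#' Pipeline configuration
#'
#' Bundles every tunable constant of the pipeline. Defaults are the
#' published analysis constants: a 250 um stromal collar defines the tumor
#' area, the invasive margin is the 500 um outer layer of the tumor area
#' (250 um to each side of the tumor-field contour), the immunotype
#' decision tree uses strict thresholds of 100 (tumor center), 82.8 (tumor
#' fields) and 200 (invasive margin) CD8+ T cells/mm^2, contact fractions
#' use a 10 um radius, cellular neighborhoods use a 50 um radius with
#' k = 4 clusters and a 40% dominance rule, and NPX proteins must be
#' present in at least 85% of samples.
#'
#' @param tumor_area_buffer outward stromal collar around tumor fields, um.
#' @param margin_halfwidth half-width of the invasive margin band, um.
#' @param tc_cd8_threshold tumor-center CD8 density threshold, cells/mm^2.
#' @param im_cd8_threshold invasive-margin CD8 density threshold, cells/mm^2.
#' @param tf_cd8_threshold_mode `"fixed"` uses `tf_cd8_threshold_fixed`;
#'   `"cohort_median"` recomputes the tumor-field threshold as the cohort
#'   median, as the original cohort value 82.8 was obtained.
#' @param tf_cd8_threshold_fixed fixed tumor-field CD8 threshold, cells/mm^2.
#' @param radius_fraction_r contact-fraction radius, um.
#' @param neighborhood_radius neighborhood counting radius, um.
#' @param neighborhood_k number of cellular neighborhoods per specimen.
#' @param dominance_fraction phenotype fraction at which a neighborhood
#'   counts as dominated by that phenotype.
#' @param protein_presence_min minimum non-missing sample fraction for an
#'   NPX protein to be retained.
#' @param random_seed master seed; every stochastic step draws from a
#'   named substream derived from it.
#' @return an object of class `timetopo_config` (a validated list).
#' @export
timetopo_config <- function(tumor_area_buffer = 250,
                            margin_halfwidth = 250,
                            tc_cd8_threshold = 100,
                            im_cd8_threshold = 200,
                            tf_cd8_threshold_mode = c("fixed", "cohort_median"),
                            tf_cd8_threshold_fixed = 82.8,
                            radius_fraction_r = 10,
                            neighborhood_radius = 50,
                            neighborhood_k = 4L,
                            dominance_fraction = 0.40,
                            protein_presence_min = 0.85,
                            random_seed = 1L) {
  tf_cd8_threshold_mode <- match.arg(tf_cd8_threshold_mode)
  cfg <- list(tumor_area_buffer = tumor_area_buffer,
              margin_halfwidth = margin_halfwidth,
              tc_cd8_threshold = tc_cd8_threshold,
              im_cd8_threshold = im_cd8_threshold,
              tf_cd8_threshold_mode = tf_cd8_threshold_mode,
              tf_cd8_threshold_fixed = tf_cd8_threshold_fixed,
              radius_fraction_r = radius_fraction_r,
              neighborhood_radius = neighborhood_radius,
              neighborhood_k = as.integer(neighborhood_k),
              dominance_fraction = dominance_fraction,
              protein_presence_min = protein_presence_min,
              random_seed = as.integer(random_seed))
  validate_config(cfg)
  structure(cfg, class = "timetopo_config")
}

validate_config <- function(cfg) {
  stopifnot(cfg$tumor_area_buffer > 0, cfg$margin_halfwidth > 0,
            cfg$tc_cd8_threshold >= 0, cfg$im_cd8_threshold >= 0,
            cfg$tf_cd8_threshold_fixed >= 0,
            cfg$radius_fraction_r > 0, cfg$neighborhood_radius > 0,
            cfg$neighborhood_k >= 2L,
            cfg$dominance_fraction > 0, cfg$dominance_fraction <= 1,
            cfg$protein_presence_min > 0, cfg$protein_presence_min <= 1)
  invisible(cfg)
}

#' @export
print.timetopo_config <- function(x, ...) {
  cat("<timetopo_config>\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Read a pipeline configuration from YAML
#'
#' Fields mirror the arguments of [timetopo_config()]; absent fields keep
#' their defaults.
#' @param path path to a YAML file.
#' @return a `timetopo_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(timetopo_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  do.call(timetopo_config, vals)
}

# Deterministic per-module substream seed derived from the master seed.
# Keeps results of one module stable when another module's draw count
# changes. Always < 2^31.
substream_seed <- function(seed, name) {
  h <- as.numeric(seed) %% 2147483647
  for (c in utf8ToInt(name)) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}
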