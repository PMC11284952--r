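# Tissue-zone construction. The tumor area is the hole-filled union of the
# tumor-field polygons dilated outward by the stromal collar (250 um); the
# invasive margin is the band within `margin_halfwidth` of the tumor-field
# contour (250 um to each side, a 500 um layer at defaults); the tumor
# center is the remaining tumor area, i.e. the inward erosion of the filled
# fields by the halfwidth. Within every zone, the field compartment is the
# (unfilled) tumor-field polygons and the stroma compartment the rest.

#' Build the outward-buffered tumor area
#'
#' @param fields list of [tt_polygon()] tumor fields.
#' @param buffer outward buffer distance, um.
#' @return list with `rings` (one traced contour per field component) and
#'   `area_um2`.
#' @export
build_tumor_area <- function(fields, buffer) {
  if (!length(fields)) {
    stop("zoning error: specimen has no delineated tumor fields")
  }
  stopifnot(buffer > 0)
  offset_region(fields, level = buffer)
}

#' Build the eroded tumor center
#'
#' Set difference of the tumor area and the invasive-margin band: the set
#' of points deeper than `halfwidth` inside the filled tumor-field contour.
#' @param fields list of `tt_polygon`.
#' @param halfwidth inward erosion depth, um.
#' @return list with `rings` (possibly empty) and `area_um2`.
#' @export
build_tumor_center <- function(fields, halfwidth) {
  stopifnot(halfwidth > 0)
  offset_region(fields, level = -halfwidth)
}

# Offset contour of the filled field union at signed distance `level`
# (positive = dilation, negative = erosion). One ring per field component;
# dilated components that overlap are corrected by pairwise grid area.
offset_region <- function(fields, level, n_angles = 192L) {
  rings <- list()
  for (f in fields) {
    ctr <- ring_centroid(f$outer)
    r <- trace_level_ring(list(f), ctr, level, n_angles = n_angles)
    if (!is.null(r)) rings[[length(rings) + 1L]] <- r
  }
  area <- sum(vapply(rings, ring_area, 0))
  if (length(rings) > 1L) {
    for (i in seq_len(length(rings) - 1L)) {
      for (j in (i + 1L):length(rings)) {
        if (bbox_overlap(rings[[i]], rings[[j]])) {
          area <- area - component_overlap_area(rings[[i]], rings[[j]])
        }
      }
    }
  }
  list(rings = rings, area_um2 = area)
}

#' Build the invasive-margin band
#'
#' The band within `halfwidth` of the tumor-field contour clipped to the
#' tumor area: at the published defaults (250 um buffer and halfwidth)
#' this is the 500 um outer layer of the tumor area. Represented as the
#' set difference tumor area minus tumor center, which keeps
#' margin + center an exact partition of the tumor area for any
#' parameter values.
#'
#' @param fields list of [tt_polygon()] tumor fields.
#' @param tumor_area result of [build_tumor_area()] (rebuilt when `NULL`).
#' @param halfwidth half-width of the band, um.
#' @param buffer tumor-area buffer used when rebuilding, um.
#' @return list with `outer_rings`, `inner_rings` and `area_um2`.
#' @export
build_invasive_margin <- function(fields, tumor_area = NULL, halfwidth,
                                  buffer = halfwidth) {
  if (is.null(tumor_area)) tumor_area <- build_tumor_area(fields, buffer)
  center <- build_tumor_center(fields, halfwidth)
  if (!length(center$rings)) {
    message("[zoning] margin band consumes the whole tumor area")
  }
  list(outer_rings = tumor_area$rings, inner_rings = center$rings,
       area_um2 = tumor_area$area_um2 - center$area_um2)
}

#' Construct all tissue zones of a specimen
#'
#' @param fields list of [tt_polygon()] tumor-field annotations.
#' @param config a [timetopo_config()].
#' @return an object of class `zone_set`: tumor-field polygons, traced
#'   tumor-area and tumor-center contours, and a named vector `areas_mm2`
#'   with entries `tumor_area`, `invasive_margin`, `tumor_center` and the
#'   field/stroma compartment splits of each.
#' @export
build_zones <- function(fields, config = timetopo_config()) {
  buffer <- config$tumor_area_buffer
  halfwidth <- config$margin_halfwidth
  ta <- build_tumor_area(fields, buffer)
  tc <- build_tumor_center(fields, halfwidth)
  if (!length(tc$rings)) {
    message("[zoning] margin band consumes the whole tumor area; tumor center empty")
  }

  field_area <- sum(vapply(fields, polygon_area, 0))
  # stroma enclosed in the tumor center: center region restricted to holes
  center_stroma <- 0
  for (f in fields) {
    for (h in f$holes) {
      xl <- range(h[, 1L]); yl <- range(h[, 2L])
      center_stroma <- center_stroma + grid_area(function(px, py) {
        point_in_ring(px, py, h) &
          signed_distance(px, py, fields) < -halfwidth
      }, xl, yl, n = 100L)
    }
  }
  a_ta <- ta$area_um2
  a_tc <- tc$area_um2
  a_im <- a_ta - a_tc
  center_field <- a_tc - center_stroma
  margin_field <- field_area - center_field
  margin_stroma <- a_im - margin_field
  areas <- c(tumor_area = a_ta, invasive_margin = a_im, tumor_center = a_tc,
             tumor_area_field = field_area,
             tumor_area_stroma = a_ta - field_area,
             tumor_center_field = center_field,
             tumor_center_stroma = center_stroma,
             invasive_margin_field = margin_field,
             invasive_margin_stroma = margin_stroma) / 1e6
  areas[areas < 0 & areas > -1e-9] <- 0
  structure(list(fields = fields,
                 tumor_area = ta, tumor_center = tc,
                 buffer = buffer, halfwidth = halfwidth,
                 areas_mm2 = areas),
            class = "zone_set")
}

#' @export
print.zone_set <- function(x, ...) {
  cat(sprintf("<zone_set> %d tumor field(s), buffer %g um, margin halfwidth %g um\n",
              length(x$fields), x$buffer, x$halfwidth))
  a <- x$areas_mm2
  cat(sprintf("  tumor area      %8.3f mm^2 (field %.3f / stroma %.3f)\n",
              a[["tumor_area"]], a[["tumor_area_field"]],
              a[["tumor_area_stroma"]]))
  cat(sprintf("  invasive margin %8.3f mm^2\n", a[["invasive_margin"]]))
  cat(sprintf("  tumor center    %8.3f mm^2\n", a[["tumor_center"]]))
  invisible(x)
}

#' Field/stroma compartment areas of a zone
#'
#' @param zones a `zone_set`.
#' @param region one of `"tumor_area"`, `"tumor_center"`,
#'   `"invasive_margin"`.
#' @return named vector with `field` and `stroma` areas in mm^2.
#' @export
split_field_stroma <- function(zones,
                               region = c("tumor_area", "tumor_center",
                                          "invasive_margin")) {
  region <- match.arg(region)
  a <- zones$areas_mm2
  c(field = unname(a[paste0(region, "_field")]),
    stroma = unname(a[paste0(region, "_stroma")]))
}

#' Assign every cell to a tissue zone
#'
#' Each cell gets a `region` label (`tumor_center`, `invasive_margin` or
#' `outside`, by signed distance to the filled tumor-field contour; the
#' boundary is inclusive and measure-zero ties resolve margin-over-center)
#' and a `compartment` label (`field` if inside an unfilled tumor-field
#' polygon, boundary inclusive, else `stroma`; `NA` outside the tumor
#' area).
#'
#' @param cells a `tt_cells` data.frame.
#' @param zones a `zone_set`.
#' @return `cells` with `region`, `compartment` and `signed_dist_um`
#'   columns appended.
#' @export
assign_cells_to_zones <- function(cells, zones) {
  cells <- as_tt_cells(cells)
  d <- signed_distance(cells$x, cells$y, zones$fields)
  region <- ifelse(d > zones$buffer, "outside",
                   ifelse(d < -zones$halfwidth, "tumor_center",
                          "invasive_margin"))
  in_field <- point_in_fields(cells$x, cells$y, zones$fields)
  compartment <- ifelse(region == "outside", NA_character_,
                        ifelse(in_field, "field", "stroma"))
  cells$region <- factor(region,
                         levels = c("tumor_center", "invasive_margin",
                                    "outside"))
  cells$compartment <- factor(compartment, levels = c("field", "stroma"))
  cells$signed_dist_um <- d
  cells
}

#' Write a zone set as GeoJSON
#'
#' One feature per traced contour, tagged with a `zone` property
#' (`tumor_field`, `tumor_area`, `tumor_center`).
#' @param zones a `zone_set`.
#' @param path output path.
#' @export
zones_to_geojson <- function(zones, path) {
  polys <- list()
  nms <- character()
  for (f in zones$fields) {
    polys[[length(polys) + 1L]] <- f
    nms <- c(nms, "tumor_field")
  }
  for (r in zones$tumor_area$rings) {
    polys[[length(polys) + 1L]] <- tt_polygon(r)
    nms <- c(nms, "tumor_area")
  }
  for (r in zones$tumor_center$rings) {
    polys[[length(polys) + 1L]] <- tt_polygon(r)
    nms <- c(nms, "tumor_center")
  }
  names(polys) <- nms
  write_annotations(polys, path)
}
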