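# Readers and writers: phenotyped cell tables (CSV/TSV), tumor-field
# annotations (GeoJSON, RFC 7946, coordinates in um), specimen metadata
# (CSV) and NPX protein matrices (CSV with a plate column).

#' Read a phenotyped cell table
#'
#' Consumes delimited exports from cell-detection tools: one row per
#' detected cell with centroid coordinates in micrometers and a phenotype
#' label. Comma or tab delimitation is auto-detected from the header line.
#' Recognised columns: `cell_id`, `x_um` (or `x`), `y_um` (or `y`),
#' `phenotype`, and optionally logical `cd103` and `ki67` marker flags and
#' a `specimen_id`.
#'
#' @param path file path.
#' @param aliases named character vector mapping foreign phenotype strings
#'   (e.g. marker combinations like `"CD163"`) onto the closed vocabulary
#'   of [timetopo_phenotypes()].
#' @param quiet suppress the parse summary message.
#' @return a data.frame of class `tt_cells` with columns `cell_id`, `x`,
#'   `y`, `phenotype` (factor over the closed vocabulary) and any optional
#'   columns present. Unknown phenotype labels are mapped to `"other"`
#'   with a warning.
#' @export
read_cell_table <- function(path, aliases = NULL, quiet = FALSE) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  names(df)[names(df) == "x_um"] <- "x"
  names(df)[names(df) == "y_um"] <- "y"
  required <- c("cell_id", "x", "y", "phenotype")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("cell table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in c("x", "y")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) | !is.finite(v))
    if (length(bad)) {
      stop(sprintf("non-numeric %s coordinate at data line %d of %s",
                   col, bad[1L], path))
    }
    df[[col]] <- v
  }
  df$phenotype <- normalize_phenotypes(df$phenotype, aliases)
  for (fl in c("cd103", "ki67")) {
    if (fl %in% names(df)) df[[fl]] <- as.logical(df[[fl]])
  }
  if (!quiet) {
    message(sprintf("[io] parsed %d cells from %s", nrow(df), basename(path)))
  }
  as_tt_cells(df)
}

normalize_phenotypes <- function(x, aliases = NULL) {
  x <- as.character(x)
  if (!is.null(aliases)) {
    hit <- x %in% names(aliases)
    x[hit] <- unname(aliases[x[hit]])
  }
  vocab <- timetopo_phenotypes()
  unknown <- setdiff(unique(x), vocab)
  if (length(unknown)) {
    warning("unknown phenotype label(s) mapped to 'other': ",
            paste(unknown, collapse = ", "))
    x[x %in% unknown] <- "other"
  }
  factor(x, levels = vocab)
}

#' Coerce a data.frame to a validated cell table
#' @param df data.frame with `cell_id`, `x`, `y`, `phenotype` columns.
#' @return a `tt_cells` data.frame with the phenotype factor closed over
#'   [timetopo_phenotypes()].
#' @export
as_tt_cells <- function(df) {
  stopifnot(all(c("cell_id", "x", "y", "phenotype") %in% names(df)))
  if (!is.factor(df$phenotype)) {
    df$phenotype <- normalize_phenotypes(df$phenotype)
  }
  stopifnot(all(is.finite(df$x)), all(is.finite(df$y)))
  class(df) <- c("tt_cells", "data.frame")
  df
}

#' Write a cell table as CSV
#' @param cells a `tt_cells` data.frame.
#' @param path output path.
#' @export
write_cell_table <- function(cells, path) {
  out <- as.data.frame(cells)
  names(out)[names(out) == "x"] <- "x_um"
  names(out)[names(out) == "y"] <- "y_um"
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.tt_cells <- function(x, ...) {
  cat(sprintf("<tt_cells> %d cells\n", nrow(x)))
  print(table(x$phenotype))
  invisible(x)
}

#' Read tumor-field polygon annotations from GeoJSON
#'
#' Expects a FeatureCollection of Polygon or MultiPolygon features with
#' coordinates in micrometers. The first ring of each polygon is the outer
#' contour; subsequent rings are holes (enclosed stroma).
#'
#' @param path GeoJSON file path.
#' @param repair drop duplicated consecutive vertices and an explicit
#'   closing vertex before validation (default TRUE). Self-intersecting
#'   rings are always rejected.
#' @return a list of [tt_polygon()] objects.
#' @export
read_annotations <- function(path, repair = TRUE) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(gj$type) || gj$type != "FeatureCollection") {
    stop("annotation file is not a GeoJSON FeatureCollection")
  }
  polys <- list()
  for (feat in gj$features) {
    geom <- feat$geometry
    if (is.null(geom)) next
    coords <- switch(geom$type,
      Polygon = list(geom$coordinates),
      MultiPolygon = geom$coordinates,
      stop("unsupported geometry type: ", geom$type))
    for (poly in coords) {
      rings <- lapply(poly, function(r) {
        m <- do.call(rbind, lapply(r, function(pt) c(pt[[1L]], pt[[2L]])))
        if (repair) m <- m[!duplicated(m) | seq_len(nrow(m)) == 1L, , drop = FALSE]
        as_ring(m)
      })
      for (r in rings) {
        if (!ring_is_simple(r)) {
          stop("self-intersecting ring in ", path,
               " (repair cannot fix crossing edges)")
        }
      }
      polys[[length(polys) + 1L]] <- tt_polygon(rings[[1L]], rings[-1L])
    }
  }
  if (!length(polys)) stop("no polygon features found in ", path)
  polys
}

#' Write polygons as a GeoJSON FeatureCollection
#' @param polys list of `tt_polygon`, or a named list to set a `zone`
#'   property per feature.
#' @param path output path.
#' @export
write_annotations <- function(polys, path) {
  ring_coords <- function(r) {
    r <- rbind(r, r[1L, ])                      # GeoJSON rings are closed
    lapply(seq_len(nrow(r)), function(i) c(r[i, 1L], r[i, 2L]))
  }
  feats <- lapply(seq_along(polys), function(i) {
    p <- polys[[i]]
    props <- if (!is.null(names(polys)) && nzchar(names(polys)[i])) {
      list(zone = names(polys)[i])
    } else {
      stats::setNames(list(), character())
    }
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon",
                         coordinates = c(list(ring_coords(p$outer)),
                                         lapply(p$holes, ring_coords))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read specimen metadata
#'
#' CSV with one row per specimen: `specimen_id`, `kind` (resection or
#' biopsy), `site`, `hpv_status`, plus free covariate columns such as
#' `lymphovascular_invasion`.
#' @param path CSV path.
#' @return data.frame.
#' @export
read_metadata <- function(path) {
  md <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"specimen_id" %in% names(md)) {
    stop("metadata is missing required column: specimen_id")
  }
  md
}

#' Read an NPX protein matrix
#'
#' CSV with one row per sample: `sample_id`, `plate`, then one numeric
#' column per protein (NPX, log2 scale). Empty cells become missing
#' (below-LOD/absent) entries of the mask.
#'
#' @param path CSV path.
#' @return an object of class `npx_matrix`: list with `values` (protein x
#'   sample matrix), `proteins`, `samples`, `plate` (per sample) and
#'   `missing` (logical mask, same shape as `values`).
#' @export
read_npx <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c("sample_id", "plate")) {
    if (!col %in% names(df)) stop("NPX table is missing column: ", col)
  }
  prot <- names(df)[!names(df) %in% c("sample_id", "plate")]
  if (anyDuplicated(prot)) {
    stop("duplicate protein name(s): ",
         paste(unique(prot[duplicated(prot)]), collapse = ", "))
  }
  vals <- t(as.matrix(df[, prot, drop = FALSE]))
  storage.mode(vals) <- "double"
  npx_matrix(vals, proteins = prot, samples = df$sample_id, plate = df$plate)
}

#' Construct an NPX matrix object
#' @param values protein x sample numeric matrix (log2 NPX); NA marks
#'   missing entries.
#' @param proteins,samples row and column names.
#' @param plate per-sample plate labels.
#' @param missing optional logical mask; defaults to `is.na(values)`.
#' @return an `npx_matrix`.
#' @export
npx_matrix <- function(values, proteins = rownames(values),
                       samples = colnames(values), plate,
                       missing = NULL) {
  values <- as.matrix(values)
  if (is.null(missing)) missing <- is.na(values)
  stopifnot(length(proteins) == nrow(values),
            length(samples) == ncol(values),
            length(plate) == ncol(values),
            all(dim(missing) == dim(values)))
  values[missing] <- NA_real_
  dimnames(values) <- list(proteins, samples)
  dimnames(missing) <- dimnames(values)
  structure(list(values = values, proteins = proteins,
                 samples = as.character(samples),
                 plate = as.character(plate), missing = missing),
            class = "npx_matrix")
}

#' @export
print.npx_matrix <- function(x, ...) {
  cat(sprintf("<npx_matrix> %d proteins x %d samples, %d plate(s), %.1f%% missing\n",
              nrow(x$values), ncol(x$values), length(unique(x$plate)),
              100 * mean(x$missing)))
  invisible(x)
}

#' Write an NPX matrix as CSV (samples as rows, plate column included)
#' @param npx an `npx_matrix`.
#' @param path output path.
#' @export
write_npx <- function(npx, path) {
  df <- data.frame(sample_id = npx$samples, plate = npx$plate,
                   check.names = FALSE)
  df <- cbind(df, as.data.frame(t(npx$values), check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
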