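# Inter-cell distance statistics: average minimum distance (AMD) between
# phenotype pairs and within-radius contact fractions. All distances are
# Euclidean centroid-to-centroid, in micrometers, computed by default over
# cells inside the tumor area.

# pairwise minimum distances from each row of `ref` to `tgt`, chunked so
# the distance matrix never exceeds ~4e6 entries; `self` marks that ref
# and tgt are the same point set (exclude the zero self-distance)
min_dist_chunked <- function(ref, tgt, self = FALSE) {
  nr <- nrow(ref)
  nt <- nrow(tgt)
  out <- numeric(nr)
  chunk <- max(1L, floor(4e6 / nt))
  for (start in seq(1L, nr, by = chunk)) {
    idx <- start:min(start + chunk - 1L, nr)
    d2 <- outer(ref[idx, 1L], tgt[, 1L], `-`)^2 +
      outer(ref[idx, 2L], tgt[, 2L], `-`)^2
    if (self) {
      d2[cbind(seq_along(idx), idx)] <- Inf
    }
    j <- max.col(-d2, ties.method = "first")   # fast row minima
    out[idx] <- sqrt(d2[cbind(seq_len(nrow(d2)), j)])
  }
  out
}

cells_xy <- function(cells) {
  cbind(cells$x, cells$y)
}

#' Distance from each reference cell to its nearest target cell
#'
#' When reference and target are the same set of cells (same phenotype),
#' each cell's zero distance to itself is excluded.
#'
#' @param reference_cells,target_cells `tt_cells` data.frames or two-column
#'   coordinate matrices.
#' @return numeric vector, one minimum distance (um) per reference cell;
#'   `NULL` when either set is empty.
#' @export
min_distance_to_nearest <- function(reference_cells, target_cells) {
  ref <- if (is.data.frame(reference_cells)) cells_xy(reference_cells)
         else as.matrix(reference_cells)
  tgt <- if (is.data.frame(target_cells)) cells_xy(target_cells)
         else as.matrix(target_cells)
  if (!nrow(ref) || !nrow(tgt)) return(NULL)
  self <- nrow(ref) == nrow(tgt) && all(ref == tgt)
  if (self && nrow(ref) < 2L) return(NULL)
  min_dist_chunked(ref, tgt, self = self)
}

#' Average minimum distance (AMD) between two phenotypes
#'
#' Mean over reference cells of the distance to the nearest target cell.
#'
#' @inheritParams min_distance_to_nearest
#' @param reference_phenotype,target_phenotype labels recorded in the
#'   result.
#' @param keep_distances retain the per-cell minimum distances.
#' @return object of class `amd_result` with `amd` (um), `n_reference`,
#'   and optionally `per_cell_min_distances`; `amd` is `NA` when either
#'   set is empty.
#' @export
amd <- function(reference_cells, target_cells,
                reference_phenotype = NA_character_,
                target_phenotype = NA_character_,
                keep_distances = FALSE) {
  d <- min_distance_to_nearest(reference_cells, target_cells)
  res <- list(reference_phenotype = reference_phenotype,
              target_phenotype = target_phenotype,
              amd = if (is.null(d)) NA_real_ else mean(d),
              n_reference = if (is.null(d)) 0L else length(d))
  if (keep_distances) res$per_cell_min_distances <- d
  structure(res, class = "amd_result")
}

#' @export
print.amd_result <- function(x, ...) {
  cat(sprintf("<amd_result> %s -> %s: %.2f um (n = %d)\n",
              x$reference_phenotype, x$target_phenotype, x$amd,
              x$n_reference))
  invisible(x)
}

#' AMD matrix across phenotype pairs
#'
#' @param cells a `tt_cells` data.frame; when zone labels are present the
#'   computation is restricted to `zone` (default the whole tumor area,
#'   i.e. everything not `outside`).
#' @param phenotypes phenotypes to cross (default all seven).
#' @param zone `"tumor_area"`, `"tumor_center"` or `"invasive_margin"`.
#' @return numeric reference x target matrix of AMDs (um); `NA` where a
#'   phenotype is absent.
#' @export
amd_matrix <- function(cells, phenotypes = timetopo_phenotypes(),
                       zone = "tumor_area") {
  if ("region" %in% names(cells)) {
    keep <- !is.na(cells$region) & cells$region != "outside"
    if (zone != "tumor_area") keep <- keep & cells$region == zone
    cells <- cells[keep, ]
  }
  sets <- lapply(phenotypes, function(p) {
    cells_xy(cells[cells$phenotype == p, ])
  })
  names(sets) <- phenotypes
  m <- matrix(NA_real_, length(phenotypes), length(phenotypes),
              dimnames = list(reference = phenotypes,
                              target = phenotypes))
  for (i in seq_along(phenotypes)) {
    for (j in seq_along(phenotypes)) {
      res <- amd(sets[[i]], sets[[j]])
      m[i, j] <- res$amd
    }
  }
  m
}

#' Fraction of cells with a probe cell within a radius
#'
#' The fraction of `counted_cells` having at least one `probe_cells`
#' member at distance `r` or less (inclusive). Matches the radius analysis
#' read as "percentage of tumor cells within 10 um of an immune cell":
#' the counted population is the axis population.
#'
#' @param counted_cells cells forming the numerator/denominator.
#' @param probe_cells cells searched for within the radius.
#' @param r radius, um (> 0).
#' @param counted_phenotype,probe_phenotype labels recorded in the result.
#' @return object of class `radius_fraction_result` with `fraction` in
#'   `[0, 1]` (`NA` when the counted set is empty, 0 when the probe set is
#'   empty), `radius` and `n_counted`.
#' @export
radius_fraction <- function(counted_cells, probe_cells, r,
                            counted_phenotype = NA_character_,
                            probe_phenotype = NA_character_) {
  stopifnot(r > 0)
  cnt <- if (is.data.frame(counted_cells)) cells_xy(counted_cells)
         else as.matrix(counted_cells)
  prb <- if (is.data.frame(probe_cells)) cells_xy(probe_cells)
         else as.matrix(probe_cells)
  frac <- if (!nrow(cnt)) {
    NA_real_
  } else if (!nrow(prb)) {
    0
  } else {
    d <- min_dist_chunked(cnt, prb,
                          self = nrow(cnt) == nrow(prb) && all(cnt == prb))
    mean(d <= r)
  }
  structure(list(counted_phenotype = counted_phenotype,
                 probe_phenotype = probe_phenotype,
                 radius = r, fraction = frac, n_counted = nrow(cnt)),
            class = "radius_fraction_result")
}

#' @export
print.radius_fraction_result <- function(x, ...) {
  cat(sprintf("<radius_fraction> %s within %g um of %s: %.3f (n = %d)\n",
              x$counted_phenotype, x$radius, x$probe_phenotype,
              x$fraction, x$n_counted))
  invisible(x)
}
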