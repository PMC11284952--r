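# Immune cellular neighborhoods: each immune cell is described by the
# counts of the five immune phenotypes among its neighbors within 50 um,
# and the per-specimen count profiles are clustered by k-means into four
# neighborhoods. Tumor and other cells never enter the analysis.

#' Count immune neighbors within a radius
#'
#' Entry (i, p) is the number of immune cells of phenotype p within
#' `radius` (inclusive) of immune cell i, excluding the cell itself.
#'
#' @param immune_cells a `tt_cells` data.frame; non-immune phenotypes are
#'   dropped with a message.
#' @param radius neighborhood radius, um (> 0).
#' @return list with `counts` (n x 5 integer matrix over the immune
#'   phenotypes) and `cells` (the immune cells used, same row order).
#' @export
count_neighbors <- function(immune_cells, radius = 50) {
  stopifnot(radius > 0)
  phen <- timetopo_immune_phenotypes()
  drop <- !(as.character(immune_cells$phenotype) %in% phen)
  if (any(drop)) {
    message(sprintf("[neighborhoods] dropping %d non-immune cell(s)",
                    sum(drop)))
    immune_cells <- immune_cells[!drop, ]
  }
  n <- nrow(immune_cells)
  counts <- matrix(0L, n, length(phen), dimnames = list(NULL, phen))
  if (n >= 2L) {
    xy <- cells_xy(immune_cells)
    ph <- factor(as.character(immune_cells$phenotype), levels = phen)
    r2 <- radius^2
    chunk <- max(1L, floor(4e6 / n))
    for (start in seq(1L, n, by = chunk)) {
      idx <- start:min(start + chunk - 1L, n)
      d2 <- outer(xy[idx, 1L], xy[, 1L], `-`)^2 +
        outer(xy[idx, 2L], xy[, 2L], `-`)^2
      d2[cbind(seq_along(idx), idx)] <- Inf   # self-exclusion
      within <- d2 <= r2
      for (k in seq_along(phen)) {
        sel <- ph == phen[k]
        counts[idx, k] <- as.integer(rowSums(within[, sel, drop = FALSE]))
      }
    }
  }
  list(counts = counts, cells = immune_cells)
}

# k-means++ seeding (squared-distance weighted) from the current RNG
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1L, ] <- x[sample.int(n, 1L), ]
  d2 <- colSums((t(x) - centers[1L, ])^2)
  for (j in seq_len(k - 1L) + 1L) {
    if (all(d2 == 0)) {
      centers[j, ] <- x[sample.int(n, 1L), ]
    } else {
      centers[j, ] <- x[sample.int(n, 1L, prob = d2), ]
      d2 <- pmin(d2, colSums((t(x) - centers[j, ])^2))
    }
  }
  centers
}

#' Cluster neighbor-count profiles into cellular neighborhoods
#'
#' k-means on the raw count vectors with k-means++ initialization and
#' multiple restarts; labels are deterministic given the seed and are
#' canonicalized by descending cluster size.
#'
#' @param count_matrix n x 5 neighbor-count matrix from
#'   [count_neighbors()].
#' @param k number of neighborhoods (default 4).
#' @param seed integer seed.
#' @param restarts number of k-means++ restarts (>= 10 recommended).
#' @return integer vector of cluster labels in `1..k` (1 = largest).
#' @export
cluster_neighborhoods <- function(count_matrix, k = 4L, seed = 1L,
                                  restarts = 10L) {
  x <- as.matrix(count_matrix)
  storage.mode(x) <- "double"
  if (nrow(x) < k) {
    stop(sprintf("clustering error: %d immune cell(s) but k = %d",
                 nrow(x), k))
  }
  if (nrow(unique(x)) == 1L) {
    # degenerate: all profiles identical -> one effective cluster
    return(rep(1L, nrow(x)))
  }
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(restarts)) {
      ctr <- kmeanspp_centers(x, k)
      ctr <- unique(ctr)
      fit <- suppressWarnings(
        stats::kmeans(x, centers = ctr, iter.max = 100L))
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    lab <- best$cluster
    # canonical order: descending cluster size, ties by cluster mean norm
    sizes <- tabulate(lab, nbins = max(lab))
    ord <- order(-sizes, seq_along(sizes))
    relabel <- integer(max(lab))
    relabel[ord] <- seq_along(ord)
    relabel[lab]
  })
}

#' Composition of each cellular neighborhood
#'
#' Per cluster: total cell count, per-phenotype counts and fractions, and
#' a dominance flag for any phenotype making up at least
#' `dominance_fraction` of the cluster (40% by default).
#'
#' @param labels integer cluster labels.
#' @param immune_cells the immune cells the labels refer to (same order).
#' @param dominance_fraction dominance cutoff in `(0, 1]`.
#' @return data.frame with one row per (cluster, phenotype): `cluster`,
#'   `cluster_size`, `phenotype`, `count`, `fraction`, `dominant`.
#' @export
neighborhood_composition <- function(labels, immune_cells,
                                     dominance_fraction = 0.40) {
  stopifnot(length(labels) == nrow(immune_cells))
  phen <- timetopo_immune_phenotypes()
  rows <- list()
  for (cl in sort(unique(labels))) {
    sub <- immune_cells[labels == cl, ]
    cnt <- table(factor(as.character(sub$phenotype), levels = phen))
    tot <- sum(cnt)
    frac <- if (tot > 0) as.numeric(cnt) / tot else rep(NA_real_, length(phen))
    rows[[length(rows) + 1L]] <- data.frame(
      cluster = cl, cluster_size = tot, phenotype = phen,
      count = as.integer(cnt), fraction = frac,
      dominant = !is.na(frac) & frac >= dominance_fraction)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Spatial map of cellular neighborhoods
#'
#' Per-cell (x, y, cluster) table, optionally drawn to a file for visual
#' QC of where each neighborhood sits in the tissue.
#'
#' @param labels integer cluster labels.
#' @param immune_cells matching `tt_cells`.
#' @param file optional PNG path; when given the map is plotted there.
#' @return data.frame with `cell_id`, `x`, `y`, `phenotype`, `cluster`.
#' @export
neighborhood_map <- function(labels, immune_cells, file = NULL) {
  stopifnot(length(labels) == nrow(immune_cells))
  tab <- data.frame(cell_id = immune_cells$cell_id,
                    x = immune_cells$x, y = immune_cells$y,
                    phenotype = as.character(immune_cells$phenotype),
                    cluster = as.integer(labels))
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 900, res = 120)
    on.exit(grDevices::dev.off())
    pal <- grDevices::hcl.colors(max(1L, max(labels)), "Dark 3")
    plot(tab$x, tab$y, col = pal[tab$cluster], pch = 16, cex = 0.5,
         asp = 1, xlab = "x (um)", ylab = "y (um)",
         main = "Immune cellular neighborhoods")
    graphics::legend("topright", legend = paste("CN", sort(unique(labels))),
                     col = pal[sort(unique(labels))], pch = 16, cex = 0.8)
  }
  tab
}

#' Run the full neighborhood analysis for one specimen
#'
#' @param cells a `tt_cells` data.frame (zone labels optional; when
#'   present, cells outside the tumor area are dropped).
#' @param config a [timetopo_config()] (radius, k, dominance, seed).
#' @return object of class `neighborhood_result`: `counts`, `labels`,
#'   `composition`, `map`.
#' @export
analyze_neighborhoods <- function(cells, config = timetopo_config()) {
  if ("region" %in% names(cells)) {
    cells <- cells[!is.na(cells$region) & cells$region != "outside", ]
  }
  imm <- cells[as.character(cells$phenotype) %in%
                 timetopo_immune_phenotypes(), ]
  nb <- count_neighbors(imm, radius = config$neighborhood_radius)
  labels <- cluster_neighborhoods(nb$counts, k = config$neighborhood_k,
                                  seed = substream_seed(config$random_seed,
                                                        "neighborhoods"))
  structure(list(counts = nb$counts, labels = labels,
                 composition = neighborhood_composition(
                   labels, nb$cells, config$dominance_fraction),
                 map = neighborhood_map(labels, nb$cells)),
            class = "neighborhood_result")
}

#' @export
print.neighborhood_result <- function(x, ...) {
  k <- length(unique(x$labels))
  cat(sprintf("<neighborhood_result> %d immune cells in %d neighborhoods\n",
              length(x$labels), k))
  dom <- x$composition[x$composition$dominant, ]
  if (nrow(dom)) {
    for (i in seq_len(nrow(dom))) {
      cat(sprintf("  CN%d dominated by %s (%.0f%%)\n", dom$cluster[i],
                  dom$phenotype[i], 100 * dom$fraction[i]))
    }
  }
  invisible(x)
}
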