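# Secretome (NPX) processing: presence filter, plate intensity
# normalization (median alignment), hierarchical clustering of samples and
# proteins, and Spearman correlation of protein levels with immune cell
# densities. NPX is on the log2 scale throughout.

#' Filter proteins by sample presence
#'
#' A protein is retained iff it is non-missing in at least `min_presence`
#' of the samples (at least 85% by default; exactly 85% is retained since
#' the rule discards proteins present in *less than* that share).
#'
#' @param npx an `npx_matrix`.
#' @param min_presence minimum non-missing fraction in `(0, 1]`.
#' @return the filtered `npx_matrix`, with attribute `discarded` naming
#'   the dropped proteins.
#' @export
filter_proteins <- function(npx, min_presence = 0.85) {
  stopifnot(min_presence > 0, min_presence <= 1)
  presence <- rowMeans(!npx$missing)
  keep <- presence >= min_presence
  out <- npx_matrix(npx$values[keep, , drop = FALSE],
                    proteins = npx$proteins[keep],
                    samples = npx$samples, plate = npx$plate,
                    missing = npx$missing[keep, , drop = FALSE])
  attr(out, "discarded") <- npx$proteins[!keep]
  out
}

#' Plate intensity normalization (median alignment)
#'
#' Shifts every protein on every plate so that its per-plate median NPX
#' equals its pre-normalization overall median: the applied shift is
#' (overall median - plate median), per protein and plate. Missing entries
#' stay missing; a plate with no non-missing value for a protein is left
#' unshifted with a warning.
#'
#' @param npx an `npx_matrix`.
#' @return list with `npx` (normalized matrix) and `report` (class
#'   `normalization_report`): per-protein-per-plate shifts and pre/post
#'   per-plate medians.
#' @export
intensity_normalize <- function(npx) {
  plates <- unique(npx$plate)
  vals <- npx$values
  overall <- apply(vals, 1L, stats::median, na.rm = TRUE)
  shifts <- matrix(NA_real_, nrow(vals), length(plates),
                   dimnames = list(npx$proteins, plates))
  pre_med <- post_med <- shifts
  for (pl in plates) {
    cols <- npx$plate == pl
    med <- apply(vals[, cols, drop = FALSE], 1L, stats::median, na.rm = TRUE)
    pre_med[, pl] <- med
    sh <- overall - med
    undef <- is.na(sh)
    if (any(undef)) {
      warning(sprintf("plate %s: %d protein(s) all-missing, left unshifted",
                      pl, sum(undef)))
      sh[undef] <- 0
    }
    shifts[, pl] <- sh
    vals[, cols] <- vals[, cols, drop = FALSE] + sh
    post_med[, pl] <- apply(vals[, cols, drop = FALSE], 1L, stats::median,
                            na.rm = TRUE)
  }
  out <- npx_matrix(vals, proteins = npx$proteins, samples = npx$samples,
                    plate = npx$plate, missing = npx$missing)
  report <- structure(list(shifts = shifts, pre_plate_medians = pre_med,
                           post_plate_medians = post_med,
                           overall_medians = overall),
                      class = "normalization_report")
  list(npx = out, report = report)
}

#' @export
print.normalization_report <- function(x, ...) {
  dev <- max(abs(x$post_plate_medians - x$overall_medians), na.rm = TRUE)
  cat(sprintf("<normalization_report> %d proteins x %d plates; max |shift| %.3f NPX; max post-median deviation %.2e\n",
              nrow(x$shifts), ncol(x$shifts), max(abs(x$shifts), na.rm = TRUE),
              dev))
  invisible(x)
}

#' Hierarchical clustering of an NPX matrix
#'
#' Agglomerative clustering of samples and of proteins (Ward linkage on
#' Euclidean distance by default). Missing entries are mean-imputed per
#' protein for the distance computation only.
#'
#' @param npx an `npx_matrix` (filtered and normalized).
#' @param method linkage passed to [stats::hclust()].
#' @param metric distance passed to [stats::dist()].
#' @return list with `samples` and `proteins`, each an `hclust` object
#'   (single-leaf degenerate inputs yield `NULL` with the leaf name in
#'   `order_labels`), plus `sample_order` and `protein_order` leaf orders.
#' @export
hierarchical_cluster <- function(npx, method = "ward.D2",
                                 metric = "euclidean") {
  vals <- npx$values
  for (i in seq_len(nrow(vals))) {
    row <- vals[i, ]
    row[is.na(row)] <- mean(row, na.rm = TRUE)
    vals[i, ] <- row
  }
  cl <- function(m, labels) {
    if (nrow(m) < 2L) return(NULL)
    h <- stats::hclust(stats::dist(m, method = metric), method = method)
    h$labels <- labels
    h
  }
  hs <- cl(t(vals), npx$samples)
  hp <- cl(vals, npx$proteins)
  list(samples = hs, proteins = hp,
       sample_order = if (is.null(hs)) npx$samples else npx$samples[hs$order],
       protein_order = if (is.null(hp)) npx$proteins else npx$proteins[hp$order])
}

#' Correlate protein levels with an immune cell density
#'
#' Spearman rank correlation of every protein's NPX values against one
#' zone-wise density across matched specimens, pairwise-complete.
#'
#' @param npx an `npx_matrix` whose samples are specimen ids.
#' @param density_tables named list of `density_table`s keyed by specimen
#'   id (or a data.frame holding rows for several specimens).
#' @param phenotype,zone density selector (e.g. `"treg"` in
#'   `"tumor_area"`).
#' @param min_pairs minimum complete pairs per protein (refused below 4).
#' @return data.frame with `protein`, `rho`, `p`, `n`.
#' @export
correlate_densities <- function(npx, density_tables, phenotype,
                                zone = "tumor_area", min_pairs = 4L) {
  if (is.data.frame(density_tables)) {
    density_tables <- split(density_tables, density_tables$specimen_id)
  }
  dens <- vapply(npx$samples, function(s) {
    if (!s %in% names(density_tables)) return(NA_real_)
    density_of(density_tables[[s]], zone, "all", phenotype)
  }, 0)
  if (sum(!is.na(dens)) < min_pairs) {
    stop(sprintf("correlation refused: fewer than %d matched specimens",
                 min_pairs))
  }
  rows <- lapply(seq_len(nrow(npx$values)), function(i) {
    v <- npx$values[i, ]
    ok <- !is.na(v) & !is.na(dens)
    if (sum(ok) < min_pairs) {
      return(data.frame(protein = npx$proteins[i], rho = NA_real_,
                        p = NA_real_, n = sum(ok)))
    }
    ct <- suppressWarnings(
      stats::cor.test(v[ok], dens[ok], method = "spearman",
                      alternative = "two.sided", exact = FALSE))
    data.frame(protein = npx$proteins[i], rho = unname(ct$estimate),
               p = ct$p.value, n = sum(ok))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
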