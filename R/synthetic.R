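# Synthetic tissue generator. Emulates the structure the pipeline is built
# to measure: blob-shaped tumor fields with enclosed stroma pockets, zone-
# and phenotype-specific homogeneous Poisson cell placement, Thomas-type
# B-cell aggregates, the four CD8 immunotype archetypes, and NPX matrices
# with plate shifts and missingness. Purely generative; no images.

# run code under a given seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# smooth star-shaped blob: radius R * (1 + roughness * s(theta)) with s a
# random low-order Fourier series normalised to max |s| = 1
blob_ring <- function(center, radius, roughness, n_vertices = 96L) {
  theta <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  if (roughness > 0) {
    s <- rep(0, n_vertices)
    for (k in 2:4) {
      s <- s + stats::rnorm(1, 0, 1 / k) * cos(k * theta) +
        stats::rnorm(1, 0, 1 / k) * sin(k * theta)
    }
    m <- max(abs(s))
    if (m > 0) s <- s / m
    r <- radius * (1 + roughness * s)
  } else {
    r <- rep(radius, n_vertices)
  }
  cbind(center[1L] + r * cos(theta), center[2L] + r * sin(theta))
}

#' Generate synthetic tumor-field polygons
#'
#' Perturbed-circle blobs with optional enclosed stroma pockets (holes).
#' Multiple blobs are placed far enough apart that their buffered tumor
#' areas stay disjoint.
#'
#' @param n_fields number of tumor-field blobs.
#' @param radius blob radius, um (>= 100).
#' @param roughness boundary roughness in `[0, 0.3]`; 0 gives a regular
#'   polygon approximating a circle.
#' @param n_holes stroma pockets per blob.
#' @param hole_radius pocket radius, um.
#' @param hole_radial radial position of pocket centers, um.
#' @param n_vertices vertices per outer ring.
#' @param seed integer seed.
#' @return list of [tt_polygon()].
#' @export
generate_tumor_fields <- function(n_fields = 1L, radius = 1250,
                                  roughness = 0.08, n_holes = 4L,
                                  hole_radius = 230, hole_radial = 520,
                                  n_vertices = 64L, seed = 1L) {
  if (radius < 100) stop("blob radius must be >= 100 um")
  stopifnot(roughness >= 0, roughness <= 0.3, n_fields >= 1L)
  if (n_holes > 0L &&
      hole_radial + hole_radius >= radius * (1 - roughness) - 50) {
    stop("stroma pockets would breach the field boundary")
  }
  spacing <- 2 * (radius * (1 + roughness) + 300) + 200
  with_seed(seed, {
    lapply(seq_len(n_fields), function(i) {
      ctr <- c((i - 1L) * spacing, 0)
      outer <- blob_ring(ctr, radius, roughness, n_vertices)
      holes <- list()
      if (n_holes > 0L) {
        ang <- 2 * pi * (seq_len(n_holes) - 1L) / n_holes + 2 * pi * stats::runif(1)
        for (a in ang) {
          hc <- ctr + hole_radial * c(cos(a), sin(a))
          holes[[length(holes) + 1L]] <-
            blob_ring(hc, hole_radius, min(roughness, 0.1), 24L)
        }
      }
      tt_polygon(outer, holes)
    })
  })
}

# membership predicate for one (region, compartment) bin of a zone set
bin_membership <- function(zones, region, compartment = NULL) {
  force(zones); force(region); force(compartment)
  function(px, py) {
    d <- signed_distance(px, py, zones$fields)
    ok <- switch(region,
      tumor_area = d <= zones$buffer,
      tumor_center = d < -zones$halfwidth,
      invasive_margin = d <= zones$buffer & d >= -zones$halfwidth,
      stop("unknown region: ", region))
    if (!is.null(compartment) && any(ok)) {
      # test field membership only where the region test already passed
      inf <- point_in_fields(px[ok], py[ok], zones$fields, eps = 0)
      ok[ok] <- if (compartment == "field") inf else !inf
    }
    ok
  }
}

zone_bbox <- function(zones) {
  xs <- ys <- c()
  for (r in zones$tumor_area$rings) {
    xs <- c(xs, range(r[, 1L])); ys <- c(ys, range(r[, 2L]))
  }
  list(xlim = range(xs), ylim = range(ys))
}

# uniform points in an arbitrary membership region by bounding-box
# rejection sampling (draws from the current RNG stream)
sample_in_region <- function(n, member, xlim, ylim) {
  out <- matrix(numeric(0), 0L, 2L)
  guard <- 0L
  proposed <- accepted <- 0
  while (nrow(out) < n) {
    # adapt the batch size to the observed acceptance rate
    p_hat <- if (proposed > 0) max(accepted / proposed, 0.01) else 0.5
    m <- max(512L, ceiling((n - nrow(out)) / p_hat * 1.2))
    px <- stats::runif(m, xlim[1L], xlim[2L])
    py <- stats::runif(m, ylim[1L], ylim[2L])
    keep <- member(px, py)
    out <- rbind(out, cbind(px[keep], py[keep]))
    proposed <- proposed + m
    accepted <- accepted + sum(keep)
    guard <- guard + 1L
    if (guard > 200L) stop("rejection sampling failed: region appears empty")
  }
  out[seq_len(n), , drop = FALSE]
}

#' Populate tissue zones with a homogeneous Poisson cell pattern
#'
#' For every row of `zone_densities` the cell count is drawn as
#' Poisson(density x bin area) and positions uniformly within the bin.
#'
#' @param zones a `zone_set`.
#' @param zone_densities data.frame with columns `region`
#'   (`tumor_center`/`invasive_margin`), `compartment` (`field`/`stroma`),
#'   `phenotype`, `density` (cells/mm^2).
#' @param seed integer seed.
#' @return a `tt_cells` data.frame.
#' @export
populate_cells <- function(zones, zone_densities, seed = 1L) {
  if (any(zone_densities$density < 0)) {
    stop("densities must be nonnegative")
  }
  bb <- zone_bbox(zones)
  with_seed(seed, {
    rows <- list()
    for (i in seq_len(nrow(zone_densities))) {
      zd <- zone_densities[i, ]
      area <- zones$areas_mm2[[paste(zd$region, zd$compartment, sep = "_")]]
      if (is.na(area) || area <= 0) next
      n <- stats::rpois(1L, zd$density * area)
      if (n == 0L) next
      pts <- sample_in_region(n, bin_membership(zones, zd$region,
                                                zd$compartment),
                              bb$xlim, bb$ylim)
      rows[[length(rows) + 1L]] <-
        data.frame(x = pts[, 1L], y = pts[, 2L],
                   phenotype = as.character(zd$phenotype))
    }
    df <- if (length(rows)) do.call(rbind, rows) else
      data.frame(x = numeric(0), y = numeric(0), phenotype = character(0))
    df <- cbind(cell_id = if (nrow(df)) sprintf("c%06d", seq_len(nrow(df)))
                          else character(0), df)
    as_tt_cells(df)
  })
}

#' Generate B-cell aggregates by a Thomas parent-offspring process
#'
#' Poisson-distributed parent seeds inside the chosen zone bin; around
#' each, a Poisson number of B cells scattered isotropically with Gaussian
#' dispersion and clipped to the bin.
#'
#' @param zones a `zone_set`.
#' @param parent_intensity parents per mm^2.
#' @param mean_offspring mean B cells per aggregate.
#' @param dispersion Gaussian scatter sd, um (> 0).
#' @param region,compartment zone bin holding the aggregates.
#' @param seed integer seed.
#' @param parents optional matrix of forced parent coordinates (overrides
#'   the Poisson parent draw).
#' @return a `tt_cells` data.frame of B cells.
#' @export
generate_b_cell_aggregates <- function(zones, parent_intensity = 0.8,
                                       mean_offspring = 30,
                                       dispersion = 40,
                                       region = "invasive_margin",
                                       compartment = "stroma",
                                       seed = 1L, parents = NULL) {
  if (dispersion <= 0) stop("dispersion must be > 0")
  if (parent_intensity < 0) stop("parent intensity must be nonnegative")
  member <- bin_membership(zones, region, compartment)
  bb <- zone_bbox(zones)
  with_seed(seed, {
    if (is.null(parents)) {
      area <- zones$areas_mm2[[paste(region, compartment, sep = "_")]]
      np <- stats::rpois(1L, parent_intensity * area)
      parents <- if (np > 0L) {
        sample_in_region(np, member, bb$xlim, bb$ylim)
      } else {
        matrix(numeric(0), 0L, 2L)
      }
    } else {
      parents <- as.matrix(parents)
    }
    pts <- matrix(numeric(0), 0L, 2L)
    for (p in seq_len(nrow(parents))) {
      n <- stats::rpois(1L, mean_offspring)
      if (n == 0L) next
      off <- cbind(parents[p, 1L] + stats::rnorm(n, 0, dispersion),
                   parents[p, 2L] + stats::rnorm(n, 0, dispersion))
      off <- off[member(off[, 1L], off[, 2L]), , drop = FALSE]
      pts <- rbind(pts, off)
    }
    df <- data.frame(cell_id = if (nrow(pts)) sprintf("b%06d", seq_len(nrow(pts)))
                               else character(0),
                     x = pts[, 1L], y = pts[, 2L],
                     phenotype = rep("b_cell", nrow(pts)))
    as_tt_cells(df)
  })
}

# zone-by-phenotype density tables (cells/mm^2) for the four archetypes;
# CD8 values are placed so each archetype clears its decision-tree branch
# with at least a two-fold safety margin by construction
archetype_densities <- function(immunotype) {
  # density per bin in order (center,field), (center,stroma),
  # (margin,field), (margin,stroma)
  base <- list(
    tumor = c(2000, 0, 2000, 0),       # field bins only
    other = c(300, 300, 300, 300),
    macrophage_cd163 = c(150, 250, 150, 250),
    t_cd4_helper = c(80, 150, 80, 300),
    treg = c(80, 150, 80, 150),
    b_cell = c(0, 30, 0, 30))
  cd8 <- switch(immunotype,
    fully_infiltrated = c(400, 400, 400, 400),
    stroma_restricted = c(20, 1200, 20, 800),
    immune_excluded   = c(0, 0, 300, 800),
    immune_desert     = c(0, 0, 0, 10),
    stop("unknown immunotype: ", immunotype))
  base$t_cd8 <- cd8
  bins <- data.frame(region = rep(c("tumor_center", "invasive_margin"),
                                  each = 2L),
                     compartment = rep(c("field", "stroma"), 2L),
                     stringsAsFactors = FALSE)
  do.call(rbind, lapply(names(base), function(ph) {
    data.frame(bins, phenotype = ph, density = base[[ph]])
  }))
}

#' Generate a full synthetic specimen of a given immunotype archetype
#'
#' Builds tumor fields with stroma pockets, constructs zones, populates
#' every zone bin with phenotype-specific Poisson cell patterns, overlays
#' Thomas-process B-cell aggregates in the invasive-margin stroma, and
#' records the intended immunotype.
#'
#' @param immunotype one of `"fully_infiltrated"`, `"stroma_restricted"`,
#'   `"immune_excluded"`, `"immune_desert"`.
#' @param seed integer seed (bit-identical output for identical seed).
#' @param config a [timetopo_config()].
#' @param specimen_id identifier.
#' @param site anatomical site recorded in metadata.
#' @return a `specimen` list: `specimen_id`, `kind`, `site`, `hpv_status`,
#'   `cells`, `fields`, `zones`, `intended_immunotype`, `covariates`.
#' @export
generate_archetype <- function(immunotype = c("fully_infiltrated",
                                              "stroma_restricted",
                                              "immune_excluded",
                                              "immune_desert"),
                               seed = 1L, config = timetopo_config(),
                               specimen_id = NULL,
                               site = "oral_cavity") {
  immunotype <- match.arg(immunotype)
  if (is.null(specimen_id)) {
    specimen_id <- sprintf("%s_s%d", immunotype, seed)
  }
  fields <- generate_tumor_fields(seed = substream_seed(seed, "fields"))
  zones <- build_zones(fields, config)
  dens <- archetype_densities(immunotype)
  cells <- populate_cells(zones, dens,
                          seed = substream_seed(seed, "cells"))
  bagg <- generate_b_cell_aggregates(zones,
                                     seed = substream_seed(seed, "bcells"))
  if (nrow(bagg)) {
    bagg$cell_id <- sprintf("b%06d", seq_len(nrow(bagg)))
    cells <- as_tt_cells(rbind(as.data.frame(cells), as.data.frame(bagg)))
  }
  cells$specimen_id <- specimen_id
  structure(list(specimen_id = specimen_id, kind = "resection",
                 site = site, hpv_status = "negative",
                 cells = cells, fields = fields, zones = zones,
                 intended_immunotype = immunotype,
                 covariates = list()),
            class = "specimen")
}

#' @export
print.specimen <- function(x, ...) {
  cat(sprintf("<specimen> %s (%s, %s), %d cells, %d tumor field(s)",
              x$specimen_id, x$kind, x$site, nrow(x$cells),
              length(x$fields)))
  if (!is.null(x$intended_immunotype)) {
    cat(" [synthetic: ", x$intended_immunotype, "]", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Generate a synthetic NPX matrix with plate structure
#'
#' NPX value = protein baseline + sample effect + plate shift + Gaussian
#' noise, on the log2 scale; entries are masked missing i.i.d. at
#' `missing_rate`.
#'
#' @param n_proteins,n_samples matrix dimensions.
#' @param plate per-sample plate labels (recycled names of
#'   `plate_shifts`).
#' @param plate_shifts named numeric vector of per-plate NPX shifts.
#' @param missing_rate i.i.d. missingness probability in `[0, 1]`.
#' @param noise_sd Gaussian noise sd (NPX units).
#' @param sample_sd sd of the per-sample effect (NPX units); note that
#'   per-plate sample effects are confounded with plate shifts under
#'   median alignment, exactly as in the real assay.
#' @param seed integer seed.
#' @return an `npx_matrix` with attribute `true_shifts`.
#' @export
generate_npx <- function(n_proteins = 92L, n_samples = 11L,
                         plate = NULL,
                         plate_shifts = c(A = 0, B = 2),
                         missing_rate = 0.1, noise_sd = 0.3,
                         sample_sd = 0.5, seed = 1L) {
  stopifnot(missing_rate >= 0, missing_rate <= 1)
  if (is.null(plate)) {
    plate <- rep(names(plate_shifts), length.out = n_samples)
  }
  stopifnot(all(plate %in% names(plate_shifts)))
  with_seed(seed, {
    baseline <- stats::rnorm(n_proteins, 5, 2)
    sample_eff <- stats::rnorm(n_samples, 0, sample_sd)
    vals <- outer(baseline, sample_eff, `+`) +
      matrix(rep(plate_shifts[plate], each = n_proteins),
             n_proteins, n_samples) +
      matrix(stats::rnorm(n_proteins * n_samples, 0, noise_sd),
             n_proteins, n_samples)
    miss <- matrix(stats::runif(n_proteins * n_samples) < missing_rate,
                   n_proteins, n_samples)
    npx <- npx_matrix(vals,
                      proteins = sprintf("prot%03d", seq_len(n_proteins)),
                      samples = sprintf("s%02d", seq_len(n_samples)),
                      plate = plate, missing = miss)
    attr(npx, "true_shifts") <- plate_shifts
    npx
  })
}

#' Write a synthetic cohort to disk
#'
#' One subdirectory per specimen with `cells.csv`, `fields.geojson` and
#' `metadata.csv`, ready for [run_pipeline()].
#'
#' @param dir output directory (created).
#' @param archetypes character vector of immunotypes, one specimen each.
#' @param seed master seed; specimen i uses substream `i`.
#' @param config a [timetopo_config()].
#' @return invisibly, the vector of specimen directories.
#' @export
simulate_cohort <- function(dir,
                            archetypes = c("fully_infiltrated",
                                           "stroma_restricted",
                                           "immune_excluded",
                                           "immune_desert"),
                            seed = 1L, config = timetopo_config()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- character(0)
  for (i in seq_along(archetypes)) {
    sp <- generate_archetype(archetypes[i],
                             seed = substream_seed(seed, paste0("specimen", i)),
                             config = config,
                             specimen_id = sprintf("S%02d", i))
    sdir <- file.path(dir, sp$specimen_id)
    dir.create(sdir, showWarnings = FALSE)
    write_cell_table(sp$cells, file.path(sdir, "cells.csv"))
    write_annotations(sp$fields, file.path(sdir, "fields.geojson"))
    utils::write.csv(data.frame(specimen_id = sp$specimen_id,
                                kind = sp$kind, site = sp$site,
                                hpv_status = sp$hpv_status,
                                intended_immunotype = sp$intended_immunotype),
                     file.path(sdir, "metadata.csv"), row.names = FALSE)
    out <- c(out, sdir)
  }
  invisible(out)
}
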