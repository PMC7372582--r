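# Per-cell tables -> normalized, feature-selected, well-level profiles.
# The stage order is fixed: median-aggregate cells to images, QC-filter
# images, normalize to the per-plate DMSO median, select features (missing
# values, near-zero variance, pairwise correlation), z-scale globally, and
# median-aggregate images to wells. Feature selection statistics are
# computed per cell line: each line of the panel is analysed separately.

#' Aggregate per-cell features to image-level profiles
#'
#' Collapses every (plate, well, site) group to a single profile: the median
#' of each feature over that image's cells (missing cell values ignored),
#' plus the cell count `n_cells`.
#'
#' @param cells Per-cell feature tibble (see [read_cell_features()]).
#' @return Image-level tibble with `cell_line`, `plate`, `well`, `site`,
#'   `n_cells` and one median column per feature.
#' @export
aggregate_cells_to_images <- function(cells) {
  if (nrow(cells) == 0) .stop("cannot aggregate an empty cell table")
  feats <- feature_columns(cells)
  dt <- as.data.table(cells)
  agg <- dt[, c(list(n_cells = .N),
                lapply(.SD, function(v) median(v, na.rm = TRUE))),
            by = c("cell_line", "plate", "well", "site"),
            .SDcols = feats]
  as_tibble(agg)
}

#' Remove low-quality images
#'
#' Drops image profiles with fewer than `min_cells` cells (the 20-cell
#' default mirrors standard practice for artifact fields of view) and any
#' image flagged by upstream image-quality metrics. Removals are recorded,
#' with their reason, in the `"qc_log"` attribute.
#'
#' @param images Image-level profiles from [aggregate_cells_to_images()].
#' @param min_cells Strict lower bound: images with `n_cells < min_cells`
#'   are removed; an image with exactly `min_cells` cells is kept.
#' @param quality_flags Optional logical vector (one per row of `images`);
#'   `TRUE` flags an image as low-quality regardless of cell count.
#' @return Filtered image tibble with a `"qc_log"` attribute.
#' @export
qc_filter_images <- function(images, min_cells = 20, quality_flags = NULL) {
  low_n <- images$n_cells < min_cells
  flagged <- if (is.null(quality_flags)) rep(FALSE, nrow(images)) else {
    stopifnot(length(quality_flags) == nrow(images))
    quality_flags & !is.na(quality_flags)
  }
  drop <- low_n | flagged
  log <- tibble(cell_line = images$cell_line[drop],
                plate = images$plate[drop], well = images$well[drop],
                site = images$site[drop],
                reason = ifelse(low_n[drop], "low_cell_count",
                                "quality_flag"))
  out <- images[!drop, , drop = FALSE]
  attr(out, "qc_log") <- log
  out
}

#' Normalize image profiles to the plate's DMSO median
#'
#' For every (cell line, plate), each feature is divided by the median of
#' that feature over the plate's surviving DMSO image profiles, removing
#' multiplicative plate effects. By construction the per-plate DMSO median
#' of every retained feature is exactly 1 afterwards. Features whose DMSO
#' median is 0 on any plate are dropped for the run (division artifacts
#' would dominate downstream distances) and listed in the
#' `"dropped_zero_median"` attribute.
#'
#' @param images QC-filtered image profiles.
#' @param platemap Plate map assigning a role to every (plate, well).
#' @return Normalized image tibble.
#' @export
normalize_to_dmso <- function(images, platemap) {
  feats <- feature_columns(images)
  role <- platemap[, c("plate", "well", "role")]
  x <- left_join(images, role, by = c("plate", "well"))
  if (anyNA(x$role)) {
    miss <- unique(paste0(x$plate[is.na(x$role)], "/", x$well[is.na(x$role)]))
    .stop("wells missing from plate map: ",
          paste(head(miss, 5), collapse = ", "))
  }
  dropped <- character(0)
  parts <- vector("list", 0)
  for (grp in split(x, paste(x$cell_line, x$plate, sep = "\r"))) {
    dmso <- grp[grp$role == "vehicle_control", feats, drop = FALSE]
    if (nrow(dmso) == 0) {
      .stop("plate '", grp$plate[1], "' of line '", grp$cell_line[1],
            "' has no surviving DMSO image; cannot normalize")
    }
    med <- vapply(dmso, median, numeric(1), na.rm = TRUE)
    dropped <- union(dropped, feats[!is.na(med) & med == 0])
    grp[feats] <- sweep(as.matrix(grp[, feats]), 2, med, "/")
    parts[[length(parts) + 1]] <- grp
  }
  out <- bind_rows(parts)
  keep <- setdiff(feats, dropped)
  out <- out[, c(setdiff(names(out), c(feats, "role")), keep)]
  out <- arrange(out, .data$cell_line, .data$plate, .data$well, .data$site)
  attr(out, "dropped_zero_median") <- dropped
  out
}

# Near-zero-variance diagnostics for one feature (frequency ratio of the
# two most common values, and fraction of unique values).
.nzv_stats <- function(v) {
  tab <- sort(table(v), decreasing = TRUE)
  freq_ratio <- if (length(tab) == 1) Inf else tab[[1]] / tab[[2]]
  list(freq_ratio = freq_ratio, unique_frac = length(tab) / length(v))
}

#' Select informative, non-redundant features
#'
#' Drops features in three ordered passes: (1) any feature containing a
#' missing value; (2) zero- and near-zero-variance features (frequency
#' ratio of the two most common values at least `nzv_freq_cut` together
#' with a unique-value fraction of at most `nzv_unique_cut`, plus exact
#' zero variance); (3) greedy pairwise-correlation elimination until no
#' retained pair has `|r| >` `corr_cutoff` — at each step the most
#' correlated violating pair is found and the member with the larger mean
#' absolute correlation to all remaining features is removed (ties broken
#' by feature name for determinism).
#'
#' @param profiles Normalized image profiles.
#' @param nzv_freq_cut Frequency-ratio cutoff (default 95/5).
#' @param nzv_unique_cut Unique-fraction cutoff (default 0.1).
#' @param corr_cutoff Absolute Pearson correlation above which one of a
#'   feature pair is removed.
#' @return `list(profiles, report)`: the reduced table and a tibble listing
#'   every dropped feature with its reason.
#' @export
select_features <- function(profiles, nzv_freq_cut = 95 / 5,
                            nzv_unique_cut = 0.1, corr_cutoff = 0.95) {
  feats <- feature_columns(profiles)
  report <- list()
  drop <- function(fs, reason, detail = NA_real_) {
    if (length(fs) > 0) {
      report[[length(report) + 1]] <<- tibble(feature = fs, reason = reason,
                                              detail = detail)
    }
    setdiff(feats, fs)
  }

  m <- .feature_matrix(profiles, feats)
  has_na <- feats[colSums(is.na(m)) > 0]
  feats <- drop(has_na, "missing_values")

  m <- m[, feats, drop = FALSE]
  v <- apply(m, 2, stats::var)
  zero_var <- feats[v == 0]
  feats <- drop(zero_var, "zero_variance")

  nzv <- character(0)
  for (f in feats) {
    s <- .nzv_stats(m[, f])
    if (s$freq_ratio >= nzv_freq_cut && s$unique_frac <= nzv_unique_cut) {
      nzv <- c(nzv, f)
    }
  }
  feats <- drop(nzv, "near_zero_variance")

  if (length(feats) >= 2) {
    r <- abs(cor(m[, feats, drop = FALSE]))
    diag(r) <- 0
    repeat {
      mx <- max(r)
      if (mx <= corr_cutoff) break
      hits <- which(r == mx, arr.ind = TRUE)
      pair <- sort(rownames(r)[hits[1, ]])
      mac <- rowMeans(r)[pair]
      victim <- if (abs(diff(mac)) > 1e-12) pair[which.max(mac)] else pair[2]
      report[[length(report) + 1]] <- tibble(feature = victim,
                                             reason = "high_correlation",
                                             detail = mx)
      keep <- setdiff(rownames(r), victim)
      r <- r[keep, keep, drop = FALSE]
    }
    feats <- intersect(feats, rownames(r))
  }
  if (length(feats) < 2) {
    .stop("fewer than 2 features survive feature selection")
  }
  meta <- setdiff(names(profiles), feature_columns(profiles))
  list(profiles = profiles[, c(meta, feats)],
       report = if (length(report) > 0) bind_rows(report) else
         tibble(feature = character(0), reason = character(0),
                detail = numeric(0)))
}

#' Scale features globally
#'
#' Standard z-transform per feature over all rows supplied: subtract the
#' global mean, divide by the global standard deviation. After the
#' transform every feature has mean 0 and SD 1.
#'
#' @param profiles Feature-selected image profiles.
#' @return Scaled tibble; scaling parameters in attribute `"scaling"`.
#' @export
scale_features <- function(profiles) {
  feats <- feature_columns(profiles)
  m <- .feature_matrix(profiles, feats)
  mu <- colMeans(m)
  sdv <- apply(m, 2, sd)
  if (any(sdv == 0)) {
    .stop("zero-variance feature(s) reached scaling (filter upstream): ",
          paste(feats[sdv == 0], collapse = ", "))
  }
  profiles[feats] <- sweep(sweep(m, 2, mu, "-"), 2, sdv, "/")
  attr(profiles, "scaling") <- list(mean = mu, sd = sdv)
  profiles
}

#' Aggregate image profiles to well-level profiles
#'
#' Collapses the surviving images of each (cell line, plate, well) to their
#' feature-wise median and attaches compound, concentration and role from
#' the plate map. Wells whose images were all removed by QC are simply
#' absent from the output.
#'
#' @param images Scaled image profiles.
#' @param platemap Plate map; every remaining well must be present in it.
#' @return Well-profile tibble (`cell_line`, `plate`, `well`, `compound`,
#'   `concentration`, `role`, `n_images`, features).
#' @export
aggregate_images_to_wells <- function(images, platemap) {
  feats <- feature_columns(images)
  dt <- as.data.table(images)
  agg <- dt[, c(list(n_images = .N),
                lapply(.SD, median)),
            by = c("cell_line", "plate", "well"), .SDcols = feats]
  wells <- as_tibble(agg)
  out <- left_join(wells,
                   platemap[, c("plate", "well", "compound",
                                "concentration", "role")],
                   by = c("plate", "well"))
  if (anyNA(out$compound)) {
    miss <- unique(paste0(out$plate[is.na(out$compound)], "/",
                          out$well[is.na(out$compound)]))
    .stop("well(s) present in features but absent from plate map: ",
          paste(head(miss, 5), collapse = ", "))
  }
  out[, c("cell_line", "plate", "well", "compound", "concentration",
          "role", "n_images", feats)]
}

#' Run the full preprocessing chain for one cell line
#'
#' Convenience wrapper applying, in order: [aggregate_cells_to_images()],
#' [qc_filter_images()], [normalize_to_dmso()], [select_features()],
#' [scale_features()], [aggregate_images_to_wells()]. Feature selection is
#' per cell line, so call this once per line (or use
#' [preprocess_screen()] for a whole panel).
#'
#' @param cells Per-cell table of a single cell line.
#' @param platemap Plate map.
#' @inheritParams qc_filter_images
#' @inheritParams select_features
#' @return `list(wells, report, qc_log, dropped_zero_median)`.
#' @export
preprocess_line <- function(cells, platemap, min_cells = 20,
                            quality_flags = NULL, nzv_freq_cut = 95 / 5,
                            nzv_unique_cut = 0.1, corr_cutoff = 0.95) {
  images <- aggregate_cells_to_images(cells)
  images <- qc_filter_images(images, min_cells, quality_flags)
  qc_log <- attr(images, "qc_log")
  images <- normalize_to_dmso(images, platemap)
  zero_med <- attr(images, "dropped_zero_median")
  sel <- select_features(images, nzv_freq_cut, nzv_unique_cut, corr_cutoff)
  scaled <- scale_features(sel$profiles)
  wells <- aggregate_images_to_wells(scaled, platemap)
  list(wells = wells, report = sel$report, qc_log = qc_log,
       dropped_zero_median = zero_med)
}

#' Preprocess every cell line of a synthetic or real screen
#'
#' @param screen A `pheno_screen` from [generate_screen()], or a named list
#'   of per-cell tables plus a `platemap`.
#' @param platemap Plate map (taken from `screen` if it is a
#'   `pheno_screen`).
#' @param ... Passed to [preprocess_line()].
#' @return Named list (one entry per cell line) of [preprocess_line()]
#'   results.
#' @export
preprocess_screen <- function(screen, platemap = NULL, ...) {
  if (inherits(screen, "pheno_screen")) {
    platemap <- screen$platemap
    screen <- screen$cells
  }
  if (is.null(platemap)) .stop("a plate map is required")
  lapply(screen, preprocess_line, platemap = platemap, ...)
}
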