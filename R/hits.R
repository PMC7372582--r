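# Phenotypic and viability hit calling. Phenotypic activity of a well is
# its squared Mahalanobis distance, in PCA space, from the plate panel's
# DMSO distribution; viability activity is the nuclei-count z-score
# against the plate's DMSO wells. Compound-level selectivity asks for
# activity in at least two EAC (cancer) lines and none of the control
# lines (phenotypic) or a z-score margin over a control line (viability).

#' Fit a PCA model on well profiles
#'
#' Standard principal component analysis of the preprocessed well-level
#' features (already centered/scaled upstream; the model re-centers on the
#' supplied wells). Fifteen components capture most of the variation of a
#' typical feature-selected Cell Painting profile and are the default
#' working space for Mahalanobis distances; alternatively the smallest
#' number of components reaching `variance_target` can be used.
#'
#' @param wells Well-profile tibble.
#' @param n_components Number of components to retain (default 15).
#' @param variance_target If non-`NULL`, retain the smallest number of
#'   components whose cumulative explained-variance fraction reaches this
#'   value (e.g. 0.90), overriding `n_components`.
#' @return A `pheno_pca`: `rotation` (orthonormal loadings), `center`,
#'   `sdev`, `explained` (all fractions), `n_components`, and `scores`
#'   (tibble of well metadata + component scores).
#' @export
fit_pca <- function(wells, n_components = 15, variance_target = NULL) {
  feats <- feature_columns(wells)
  x <- .feature_matrix(wells, feats)
  if (nrow(x) <= n_components) {
    .stop("need more wells (", nrow(x), ") than components (",
          n_components, ")")
  }
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  explained <- pc$sdev^2 / sum(pc$sdev^2)
  rank <- sum(pc$sdev > max(pc$sdev) * 1e-10)
  if (!is.null(variance_target)) {
    n_components <- which(cumsum(explained) >= variance_target)[1]
    if (is.na(n_components)) n_components <- rank
  }
  if (rank < n_components) {
    warning("data rank (", rank, ") below requested components (",
            n_components, "); reducing", call. = FALSE)
    n_components <- rank
  }
  keep <- seq_len(n_components)
  meta <- intersect(c("cell_line", "plate", "well", "compound",
                      "concentration", "role"), names(wells))
  scores <- bind_cols(wells[, meta],
                      as_tibble(as.data.frame(pc$x[, keep, drop = FALSE])))
  structure(list(rotation = pc$rotation[, keep, drop = FALSE],
                 center = pc$center, sdev = pc$sdev,
                 explained = explained, n_components = n_components,
                 features = feats, scores = scores),
            class = "pheno_pca")
}

#' @export
print.pheno_pca <- function(x, ...) {
  cat("PCA model: ", x$n_components, " components, ",
      sprintf("%.1f%%", 100 * sum(x$explained[seq_len(x$n_components)])),
      " of variance\n", sep = "")
  invisible(x)
}

# Score matrix (wells x components) from a pheno_pca scores tibble.
.score_matrix <- function(scores, n_components) {
  as.matrix(scores[, paste0("PC", seq_len(n_components)), drop = FALSE])
}

#' DMSO reference distribution in PC space
#'
#' Mean vector and covariance matrix of the DMSO vehicle wells' component
#' scores — the null distribution against which compound activity is
#' measured. Optional Ledoit-Wolf-style shrinkage of the covariance
#' toward a scaled identity stabilizes inversion when DMSO wells are few
#' relative to the number of components.
#'
#' @param pca A [fit_pca()] model (its `scores` carry well roles), or a
#'   scores tibble with a `role` column.
#' @param shrinkage `"none"` or `"lw"`.
#' @return A `dmso_reference`: `mu`, `sigma`, `n_dmso`, `n_components`.
#' @export
dmso_reference <- function(pca, shrinkage = c("none", "lw")) {
  shrinkage <- match.arg(shrinkage)
  scores <- if (inherits(pca, "pheno_pca")) pca$scores else pca
  k <- sum(grepl("^PC[0-9]+$", names(scores)))
  d <- .score_matrix(scores[scores$role == "vehicle_control", ], k)
  n <- nrow(d)
  if (n <= k) {
    .stop("need more DMSO wells (", n, ") than components (", k, ") for ",
          "a usable covariance; reduce components or add vehicle wells")
  }
  mu <- colMeans(d)
  sigma <- stats::cov(d)
  if (shrinkage == "lw") {
    # Ledoit-Wolf shrinkage toward (tr(S)/k) I
    xc <- sweep(d, 2, mu)
    target <- diag(mean(diag(sigma)), k)
    num <- 0
    for (i in seq_len(n)) {
      xi <- tcrossprod(xc[i, ])
      num <- num + sum((xi - sigma)^2)
    }
    num <- num / n^2
    den <- sum((sigma - target)^2)
    lambda <- if (den > 0) min(1, max(0, num / den)) else 0
    sigma <- lambda * target + (1 - lambda) * sigma
    attr(sigma, "lambda") <- lambda
  }
  structure(list(mu = mu, sigma = sigma, n_dmso = n, n_components = k,
                 shrinkage = shrinkage),
            class = "dmso_reference")
}

#' Squared Mahalanobis distance to the DMSO distribution
#'
#' Computes `D^2(x) = (x - mu)' Sigma^{-1} (x - mu)` for each well's
#' component scores via Cholesky triangular solves — the covariance is
#' never explicitly inverted. `D^2 >= 0`, with equality only at the DMSO
#' mean. The squared-distance convention is the package's working scale.
#'
#' @param scores Scores tibble (from [fit_pca()] / [embed_pca()]) or a
#'   numeric matrix of component scores.
#' @param ref A [dmso_reference()].
#' @param squared Return squared distances (default) or their square root.
#' @return Numeric vector of distances, one per row of `scores`.
#' @export
mahalanobis_to_dmso <- function(scores, ref, squared = TRUE) {
  x <- if (is.matrix(scores)) scores else
    .score_matrix(scores, ref$n_components)
  if (ncol(x) != ref$n_components) {
    .stop("scores have ", ncol(x), " components but the reference expects ",
          ref$n_components)
  }
  rc <- tryCatch(rcond(as.matrix(ref$sigma)), error = function(e) 0)
  if (!is.finite(rc) || rc < 1e-12) {
    .stop("DMSO covariance is (near-)singular; consider shrinkage = 'lw' ",
          "or fewer components")
  }
  ch <- chol(ref$sigma)
  z <- forwardsolve(t(ch), t(sweep(x, 2, ref$mu)))
  d2 <- colSums(z^2)
  if (squared) d2 else sqrt(d2)
}

#' Distance threshold calibrated on the DMSO null
#'
#' The printed absolute cutoff of a screen (e.g. a squared distance of
#' 1500) is specific to that screen's data scale. For other data the
#' threshold is calibrated from the null at the requested percentile:
#'
#' * `"f"` (recommended): the exact out-of-sample null for Gaussian
#'   profiles. With `mu` and `Sigma` *estimated* from `n` DMSO wells in
#'   `p` dimensions, the squared distance of a new null well follows
#'   `p (n-1)(n+1) / (n (n-p)) * F(p, n-p)`; the chi-squared tail
#'   understates this whenever `n` is not much larger than `p`.
#' * `"chisq"`: the large-`n` limit, `qchisq(1 - alpha, df = p)`.
#' * `"empirical"`: quantile of the DMSO wells' own (in-sample)
#'   distances.
#'
#' @param ref A [dmso_reference()].
#' @param method `"f"`, `"chisq"` or `"empirical"`.
#' @param alpha Upper-tail probability (default 0.001, the 99.9th
#'   percentile).
#' @param dmso_distances DMSO-well distances (required for
#'   `method = "empirical"`).
#' @return Scalar threshold on the squared-distance scale.
#' @export
calibrate_distance_threshold <- function(ref, method = c("f", "chisq",
                                                         "empirical"),
                                         alpha = 0.001,
                                         dmso_distances = NULL) {
  method <- match.arg(method)
  p <- ref$n_components
  if (method == "f") {
    n <- ref$n_dmso
    p * (n - 1) * (n + 1) / (n * (n - p)) * stats::qf(1 - alpha, p, n - p)
  } else if (method == "chisq") {
    qchisq(1 - alpha, df = p)
  } else {
    if (is.null(dmso_distances)) {
      .stop("empirical calibration needs the DMSO wells' distances")
    }
    unname(quantile(dmso_distances, 1 - alpha, type = 7))
  }
}

#' Call phenotypic hits and EAC-selective compounds
#'
#' A compound is a phenotypic hit in a line when its Mahalanobis distance
#' exceeds the threshold (strictly: a distance exactly at the threshold is
#' not a hit). A compound is *selective* when it hits in at least
#' `min_eac_lines` EAC lines and in neither control line. Compounds
#' missing a distance for any line are excluded from selectivity calls and
#' listed in the result's `incomplete` element.
#'
#' @param distances Tibble with `compound`, `cell_line`, `distance`
#'   (squared Mahalanobis, summarized per compound x line).
#' @param eac_lines,control_lines Panel definition.
#' @param threshold Scalar, or named per-line vector of calibrated
#'   thresholds.
#' @param min_eac_lines Minimum number of hit EAC lines for selectivity.
#' @return `pheno_hits` list: `by_line` (per compound x line flags),
#'   `by_compound` (`n_eac_hits`, `n_control_hits`, `selective`),
#'   `incomplete` (compound ids), `threshold`.
#' @export
call_phenotypic_hits <- function(distances, eac_lines, control_lines,
                                 threshold = 1500, min_eac_lines = 2) {
  lines <- c(eac_lines, control_lines)
  thr <- if (length(threshold) == 1 && is.null(names(threshold))) {
    setNames(rep(threshold, length(lines)), lines)
  } else {
    missing <- setdiff(lines, names(threshold))
    if (length(missing) > 0) {
      .stop("no threshold supplied for line(s): ",
            paste(missing, collapse = ", "))
    }
    threshold[lines]
  }
  d <- distances[distances$cell_line %in% lines, , drop = FALSE]
  d$hit <- d$distance > thr[d$cell_line]

  per_cmp <- d |>
    group_by(.data$compound) |>
    summarise(
      n_lines = n_distinct(.data$cell_line),
      n_eac_hits = sum(.data$hit[.data$cell_line %in% eac_lines]),
      n_control_hits = sum(.data$hit[.data$cell_line %in% control_lines]),
      .groups = "drop")
  incomplete <- per_cmp$compound[per_cmp$n_lines < length(lines)]
  per_cmp$selective <- per_cmp$n_eac_hits >= min_eac_lines &
    per_cmp$n_control_hits == 0 &
    !(per_cmp$compound %in% incomplete)
  structure(list(by_line = as_tibble(d), by_compound = per_cmp,
                 incomplete = incomplete, threshold = thr,
                 min_eac_lines = min_eac_lines),
            class = "pheno_hits")
}

#' Nuclei-count z-scores against plate DMSO wells
#'
#' For each (cell line, plate), `z = (count - mean(DMSO counts)) /
#' sd(DMSO counts)` per well; replicate wells of a compound are then
#' summarized by their median z. Scope `"screen"` pools the DMSO wells of
#' all plates of a line instead (an option; per plate is standard
#' practice).
#'
#' @param counts Tibble `cell_line`, `plate`, `well`, `n_nuclei` (see
#'   [well_nuclei_counts()]).
#' @param platemap Plate map.
#' @param scope `"plate"` (default) or `"screen"`.
#' @return List: `per_well` (tibble with each well's z) and `per_compound`
#'   (median z per compound x cell line, DMSO excluded).
#' @export
compute_zscores <- function(counts, platemap, scope = c("plate", "screen")) {
  scope <- match.arg(scope)
  x <- left_join(counts, platemap[, c("plate", "well", "compound", "role")],
                 by = c("plate", "well"))
  if (anyNA(x$role)) .stop("count wells missing from plate map")
  grp <- if (scope == "plate") c("cell_line", "plate") else "cell_line"
  x <- x |>
    group_by(across(all_of(grp))) |>
    mutate(
      .dmso_n = sum(.data$role == "vehicle_control"),
      .dmso_mean = mean(.data$n_nuclei[.data$role == "vehicle_control"]),
      .dmso_sd = sd(.data$n_nuclei[.data$role == "vehicle_control"])) |>
    ungroup()
  if (any(x$.dmso_n < 2)) {
    .stop("every ", if (scope == "plate") "plate" else "line",
          " needs at least 2 DMSO wells for a z-score")
  }
  if (any(x$.dmso_sd == 0)) {
    bad <- unique(x$plate[x$.dmso_sd == 0])
    .stop("DMSO count SD is 0 on plate(s): ", paste(bad, collapse = ", "))
  }
  x$z <- (x$n_nuclei - x$.dmso_mean) / x$.dmso_sd
  per_well <- x[, c("cell_line", "plate", "well", "compound", "role",
                    "n_nuclei", "z")]
  per_compound <- per_well |>
    filter(.data$role == "treatment") |>
    group_by(.data$compound, .data$cell_line) |>
    summarise(z = median(.data$z), n_wells = n(), .groups = "drop")
  list(per_well = per_well, per_compound = per_compound)
}

#' Call viability hits and EAC-selective compounds
#'
#' A compound is a viability hit in an EAC line when its nuclei-count
#' z-score is at or below `eac_threshold` (z <= -3 by default: at least a
#' three-SD loss of cells). The hit counts toward selectivity only when at
#' least one control line shows a z-score gap of `margin` or more
#' (`z_control - z_eac >= margin`; e.g. an EAC z of -3 qualifies when a
#' control line sits at -1 or above). A compound is selective when at
#' least `min_eac_lines` EAC lines qualify.
#'
#' @param z Tibble `compound`, `cell_line`, `z` (per-compound medians from
#'   [compute_zscores()]).
#' @param eac_lines,control_lines Panel definition.
#' @param eac_threshold Hit threshold on the EAC z-score (inclusive).
#' @param margin Required control-minus-EAC z gap (inclusive).
#' @param min_eac_lines Minimum number of qualifying EAC lines.
#' @return `pheno_hits`-style list: `by_line` (hit and qualifying flags per
#'   compound x EAC line), `by_compound` (`n_eac_hits`, `n_qualifying`,
#'   `selective`), `incomplete`.
#' @export
call_viability_hits <- function(z, eac_lines, control_lines,
                                eac_threshold = -3, margin = 2,
                                min_eac_lines = 2) {
  zz <- z[z$cell_line %in% c(eac_lines, control_lines), , drop = FALSE]
  ctrl <- zz[zz$cell_line %in% control_lines, c("compound", "cell_line", "z")]
  ctrl_by_cmp <- split(ctrl, ctrl$compound)
  eac <- zz[zz$cell_line %in% eac_lines, , drop = FALSE]

  # a compound lacking a z in any control line cannot be assessed for
  # selectivity and is excluded
  n_ctrl <- zz |>
    filter(.data$cell_line %in% control_lines) |>
    group_by(.data$compound) |>
    summarise(n = n_distinct(.data$cell_line), .groups = "drop")
  complete <- n_ctrl$compound[n_ctrl$n == length(control_lines)]
  incomplete <- setdiff(unique(zz$compound), complete)

  eac$hit <- eac$z <= eac_threshold
  eac$qualifies <- FALSE
  for (i in which(eac$hit)) {
    cc <- ctrl_by_cmp[[eac$compound[i]]]
    if (!is.null(cc) && nrow(cc) > 0) {
      eac$qualifies[i] <- any(cc$z - eac$z[i] >= margin)
    }
  }
  per_cmp <- eac |>
    group_by(.data$compound) |>
    summarise(n_eac_hits = sum(.data$hit),
              n_qualifying = sum(.data$qualifies), .groups = "drop")
  per_cmp$selective <- per_cmp$n_qualifying >= min_eac_lines &
    !(per_cmp$compound %in% incomplete)
  structure(list(by_line = as_tibble(eac), by_compound = per_cmp,
                 incomplete = intersect(incomplete, unique(zz$compound)),
                 eac_threshold = eac_threshold, margin = margin,
                 min_eac_lines = min_eac_lines),
            class = "pheno_hits")
}

#' Combine phenotypic and viability selective hit sets
#'
#' The final screen hit list is the union of the two selective sets, with
#' per-compound provenance: `"both"`, `"phenotypic_only"` or
#' `"viability_only"`.
#'
#' @param phenotypic,viability Character vectors of selective compound ids
#'   (or `pheno_hits` results, from which the selective sets are taken).
#' @return Tibble `compound`, `source`; attribute `"sizes"` records
#'   `n_phenotypic`, `n_viability`, `n_overlap`, `n_union`.
#' @export
combine_hits <- function(phenotypic, viability) {
  pick <- function(h) {
    if (inherits(h, "pheno_hits")) {
      h$by_compound$compound[h$by_compound$selective]
    } else as.character(h)
  }
  a <- unique(pick(phenotypic))
  b <- unique(pick(viability))
  u <- union(a, b)
  out <- tibble(
    compound = sort(u),
    source = dplyr::case_when(
      sort(u) %in% a & sort(u) %in% b ~ "both",
      sort(u) %in% a ~ "phenotypic_only",
      TRUE ~ "viability_only"))
  attr(out, "sizes") <- c(n_phenotypic = length(a), n_viability = length(b),
                          n_overlap = length(intersect(a, b)),
                          n_union = length(u))
  out
}
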