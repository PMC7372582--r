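# Response-profile analyses: Spearman-distance clustering of the panel's
# per-compound responses, low-dimensional embeddings of well profiles, and
# dose-response trajectories through a reference PC space.

#' Compound-by-cell-line response matrix
#'
#' Arranges per-compound response values (z-scores or Mahalanobis
#' distances) into a compounds x cell-lines matrix and centers/scales each
#' compound's row to mean 0, SD 1, so that clustering compares response
#' *patterns* across the panel rather than magnitudes. Rows with zero
#' variance carry no pattern and are excluded (listed in attribute
#' `"excluded"`).
#'
#' @param values Tibble `compound`, `cell_line`, `value`.
#' @return Numeric matrix (rownames = compounds, colnames = cell lines).
#' @export
response_matrix <- function(values) {
  wide <- tidyr::pivot_wider(values[, c("compound", "cell_line", "value")],
                             names_from = "cell_line",
                             values_from = "value")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$compound
  rsd <- apply(m, 1, sd)
  excluded <- rownames(m)[is.na(rsd) | rsd == 0]
  m <- m[!(rownames(m) %in% excluded), , drop = FALSE]
  m <- t(scale(t(m)))
  attr(m, "excluded") <- excluded
  m
}

#' Cluster cell-line response profiles
#'
#' Distance between two cell lines is `1 - rho`, the Spearman rank
#' correlation of their response columns (range 0 for identical rankings
#' to 2 for perfectly reversed ones); agglomeration uses complete linkage.
#'
#' @param mat Response matrix from [response_matrix()] (or any
#'   compounds x lines matrix).
#' @param axis Cluster `"cell_lines"` (columns, default) or `"compounds"`
#'   (rows).
#' @return An [stats::hclust] object.
#' @export
cluster_cell_line_responses <- function(mat, axis = c("cell_lines",
                                                      "compounds")) {
  axis <- match.arg(axis)
  if (axis == "compounds") mat <- t(mat)
  if (ncol(mat) < 3) .stop("need at least 3 columns to cluster")
  if (nrow(mat) < 3) .stop("need at least 3 observations per column")
  csd <- apply(mat, 2, sd)
  if (any(is.na(csd) | csd == 0)) {
    .stop("constant response column(s), Spearman correlation undefined: ",
          paste(colnames(mat)[is.na(csd) | csd == 0], collapse = ", "))
  }
  rho <- cor(mat, method = "spearman")
  hclust(as.dist(1 - rho), method = "complete")
}

#' Export a dendrogram
#'
#' @param hc An [stats::hclust] tree.
#' @param path Output path; `format = "newick"` writes a Newick tree (via
#'   \pkg{ape}), `"json"` a merge-list with heights.
#' @param format `"newick"` or `"json"`.
#' @return `path`, invisibly.
#' @export
export_dendrogram <- function(hc, path, format = c("newick", "json")) {
  format <- match.arg(format)
  if (format == "newick") {
    ape::write.tree(ape::as.phylo(hc), file = path)
  } else {
    jsonlite::write_json(list(labels = hc$labels,
                              merge = apply(hc$merge, 1, as.list),
                              height = hc$height,
                              method = hc$method),
                         path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Check whether a set of leaves forms its own clade
#'
#' `TRUE` when some internal node of the tree contains exactly the given
#' leaves (e.g. the two control lines clustering away from the cancer
#' panel).
#'
#' @param hc An [stats::hclust] tree.
#' @param leaves Character vector of leaf labels.
#' @return Logical scalar.
#' @export
is_clade <- function(hc, leaves) {
  idx <- match(leaves, hc$labels)
  if (anyNA(idx)) .stop("leaf label(s) not in tree")
  members <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    get_side <- function(v) if (v < 0) -v else members[[v]]
    members[[i]] <- c(get_side(hc$merge[i, 1]), get_side(hc$merge[i, 2]))
  }
  any(vapply(members, function(m) setequal(m, idx), logical(1)))
}

#' Project well profiles onto principal components
#'
#' With a reference model the wells are projected without refitting (used
#' to overlay screen compounds on the reference library's space);
#' otherwise a model is fit on the supplied wells.
#'
#' @param wells Well profiles sharing the model's feature set.
#' @param model Optional [fit_pca()] model.
#' @param n_components Components to return (default: the model's).
#' @return Tibble of well metadata plus `PC1..PCk` coordinates.
#' @export
embed_pca <- function(wells, model = NULL, n_components = NULL) {
  if (is.null(model)) {
    model <- fit_pca(wells, n_components = n_components %||% 15)
  }
  missing <- setdiff(model$features, names(wells))
  if (length(missing) > 0) {
    .stop("profiles lack feature(s) required by the PCA model: ",
          paste(head(missing, 10), collapse = ", "))
  }
  k <- min(n_components %||% model$n_components, model$n_components)
  x <- .feature_matrix(wells, model$features)
  sc <- sweep(x, 2, model$center) %*% model$rotation[, seq_len(k),
                                                     drop = FALSE]
  meta <- intersect(c("cell_line", "plate", "well", "compound",
                      "concentration", "role"), names(wells))
  bind_cols(wells[, meta], as_tibble(as.data.frame(sc)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' t-SNE embedding of well profiles
#'
#' Exact (quadratic-time) t-distributed stochastic neighbor embedding:
#' per-point Gaussian bandwidths are calibrated by bisection to the target
#' perplexity, and the 2-D map is optimized by momentum gradient descent
#' with early exaggeration. Deterministic given `seed`; intended for
#' visualization of a few hundred to a few thousand wells, not for
#' quantitative downstream use.
#'
#' @param wells Well profiles (or a numeric matrix).
#' @param perplexity Effective neighborhood size (default 30).
#' @param n_iter Gradient-descent iterations (default 1000).
#' @param seed Integer seed for the random initial map.
#' @return Tibble of well metadata plus `tsne1`, `tsne2`.
#' @export
embed_tsne <- function(wells, perplexity = 30, n_iter = 1000, seed = 1L) {
  x <- if (is.matrix(wells)) wells else .feature_matrix(wells)
  n <- nrow(x)
  if (n <= 3 * perplexity) {
    .stop("perplexity ", perplexity, " too large for ", n,
          " observations (need n > 3 * perplexity)")
  }
  d2 <- as.matrix(dist(x))^2
  target <- log(perplexity)
  p <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- d2[i, -i]
    lo <- 1e-20; hi <- 1e20; beta <- 1
    for (it in 1:64) {
      w <- exp(-di * beta)
      sw <- sum(w)
      h <- log(sw) + beta * sum(di * w) / sw  # Shannon entropy
      if (abs(h - target) < 1e-7) break
      if (h > target) { lo <- beta; beta <- if (hi >= 1e20) beta * 2 else
        (beta + hi) / 2 } else { hi <- beta; beta <- (beta + lo) / 2 }
    }
    p[i, -i] <- w / sw
  }
  p <- (p + t(p)) / (2 * n)
  p <- pmax(p, 1e-12)

  set.seed(seed)
  y <- matrix(rnorm(n * 2, sd = 1e-4), n, 2)
  inc <- matrix(0, n, 2)
  momentum <- 0.5
  eta <- 200
  exaggeration <- 12
  for (it in seq_len(n_iter)) {
    pe <- if (it <= 100) p * exaggeration else p
    yd2 <- as.matrix(dist(y))^2
    qnum <- 1 / (1 + yd2)
    diag(qnum) <- 0
    q <- pmax(qnum / sum(qnum), 1e-12)
    mult <- (pe - q) * qnum
    grad <- 4 * (diag(rowSums(mult)) - mult) %*% y
    if (it == 250) momentum <- 0.8
    inc <- momentum * inc - eta * grad
    y <- y + inc
    y <- sweep(y, 2, colMeans(y))
  }
  coords <- tibble(tsne1 = y[, 1], tsne2 = y[, 2])
  if (is.matrix(wells)) return(coords)
  meta <- intersect(c("cell_line", "plate", "well", "compound",
                      "concentration", "role"), names(wells))
  bind_cols(wells[, meta], coords)
}

#' Dose-response trajectory through the reference PC space
#'
#' Projects a query compound's well profiles, dose by dose, into the
#' reference PCA space; for each dose reports the mean coordinates, the
#' Euclidean distance to the DMSO centroid, and the nearest reference
#' class by centroid distance. An inactive compound stays with the DMSO
#' controls at every dose; an active one moves toward its mechanistic
#' class as the dose rises.
#'
#' @param model Reference [fit_pca()] model.
#' @param reference_scores The reference library's scores tibble with a
#'   `label` column (class per well, including `"DMSO"`).
#' @param query Query well profiles with a `concentration` column.
#' @param doses Dose ordering (default: sorted unique query
#'   concentrations).
#' @return `dose_trajectory` list: `trajectory` tibble (one row per dose:
#'   coordinates, `dist_dmso`, `nearest_class`) and `path_length` (summed
#'   consecutive displacement in PC space).
#' @export
dose_trajectory <- function(model, reference_scores, query, doses = NULL) {
  if (!"label" %in% names(reference_scores)) {
    .stop("reference scores must carry a 'label' class column")
  }
  if (is.null(doses)) {
    doses <- sort(unique(query$concentration))
  } else if (!all(query$concentration %in% doses)) {
    .stop("query contains concentration(s) outside the stated dose order")
  }
  k <- model$n_components
  ref <- .score_matrix(reference_scores, k)
  cls <- reference_scores$label
  centroids <- rowsum(ref, cls) / as.vector(table(cls))
  if (!"DMSO" %in% rownames(centroids)) {
    .stop("reference scores contain no DMSO wells")
  }
  dmso_c <- centroids["DMSO", ]

  rows <- list()
  pts <- list()
  for (d in doses) {
    qd <- query[query$concentration == d, , drop = FALSE]
    if (nrow(qd) == 0) next
    sc <- embed_pca(qd, model, n_components = k)
    coord <- colMeans(.score_matrix(sc, k))
    cd <- sqrt(colSums((t(centroids) - coord)^2))
    rows[[length(rows) + 1]] <- bind_cols(
      tibble(concentration = d,
             dist_dmso = sqrt(sum((coord - dmso_c)^2)),
             nearest_class = names(which.min(cd))),
      as_tibble(as.data.frame(t(coord))))
    pts[[length(pts) + 1]] <- coord
  }
  traj <- bind_rows(rows)
  path_length <- if (length(pts) < 2) 0 else
    sum(vapply(seq_len(length(pts) - 1), function(i) {
      sqrt(sum((pts[[i + 1]] - pts[[i]])^2))
    }, numeric(1)))
  structure(list(trajectory = traj, path_length = path_length),
            class = "dose_trajectory")
}
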