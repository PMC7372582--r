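# Mechanism-of-action classification over well profiles: a balanced
# random forest (500 trees; class-stratified bootstraps of the smallest
# class size) trained on reference compounds pooled across the three
# screening concentrations, evaluated out-of-bag, per held-out line
# (leave-one-cell-line-out), and applied to screen compounds as per-class
# vote-share probabilities.

#' Assemble a labeled training set from reference wells
#'
#' Labels every reference-compound well with its annotated mechanistic
#' class, pooling all requested concentrations of a compound into that one
#' class. DMSO vehicle wells form their own `"DMSO"` class.
#'
#' @param wells Well profiles ([preprocess_line()] output).
#' @param annotations Reference annotations (`compound`, `moa_class`).
#' @param doses Concentrations to pool (default: all present).
#' @param include_dmso Keep DMSO wells as an additional class.
#' @return Labeled well tibble with a `label` column.
#' @export
build_training_set <- function(wells, annotations, doses = NULL,
                               include_dmso = TRUE) {
  trt <- wells[wells$role == "treatment", , drop = FALSE]
  if (!is.null(doses)) trt <- trt[trt$concentration %in% doses, , drop = FALSE]
  unannotated <- setdiff(unique(trt$compound), annotations$compound)
  if (length(unannotated) > 0) {
    .stop("compound(s) without mechanism annotation: ",
          paste(head(unannotated, 10), collapse = ", "))
  }
  trt$label <- annotations$moa_class[match(trt$compound,
                                           annotations$compound)]
  if (include_dmso) {
    dmso <- wells[wells$role == "vehicle_control", , drop = FALSE]
    dmso$label <- "DMSO"
    trt <- bind_rows(trt, dmso)
  }
  trt
}

#' Train the balanced random-forest mechanism classifier
#'
#' Grows `ntree` trees, each on a class-stratified bootstrap drawing the
#' same number of observations — the smallest class size — from every
#' class, so that class imbalance does not bias the votes. The out-of-bag
#' (OOB) error is stored with the model.
#'
#' @param training Labeled wells from [build_training_set()].
#' @param ntree Number of trees (default 500).
#' @param mtry Features per split (default: `sqrt(p)` as usual).
#' @param seed Integer seed for reproducible forests.
#' @return A `moa_classifier` with elements `forest`, `classes`,
#'   `features`, `sampsize`, `oob_error`, `oob_confusion`, `seed`.
#' @export
train_moa_classifier <- function(training, ntree = 500, mtry = NULL,
                                 seed = NULL) {
  y <- factor(training$label)
  if (nlevels(y) < 2) .stop("training set must contain at least 2 classes")
  sizes <- table(y)
  if (any(sizes < 2)) {
    .stop("class(es) with fewer than 2 observations: ",
          paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  feats <- feature_columns(training)
  x <- .feature_matrix(training, feats)
  if (!is.null(seed)) set.seed(seed)
  smallest <- min(sizes)
  if (is.null(mtry)) mtry <- max(1, floor(sqrt(length(feats))))
  forest <- randomForest::randomForest(
    x = x, y = y, ntree = ntree, mtry = mtry,
    strata = y, sampsize = rep(smallest, nlevels(y)))
  structure(list(forest = forest, classes = levels(y), features = feats,
                 sampsize = smallest, ntree = ntree,
                 oob_error = unname(forest$err.rate[ntree, "OOB"]),
                 oob_confusion = forest$confusion, seed = seed),
            class = "moa_classifier")
}

#' @export
print.moa_classifier <- function(x, ...) {
  cat("Mechanism-of-action random forest\n")
  cat("  classes:   ", paste(x$classes, collapse = ", "), "\n")
  cat("  trees:     ", x$ntree, " (balanced bootstrap of ",
      x$sampsize, "/class)\n", sep = "")
  cat("  features:  ", length(x$features), "\n")
  cat(sprintf("  OOB error: %.2f%%\n", 100 * x$oob_error))
  invisible(x)
}

#' Predict mechanism-class probabilities for well profiles
#'
#' Probabilities are the fraction of trees voting for each class; each
#' row's probabilities sum to 1.
#'
#' @param model A [train_moa_classifier()] model.
#' @param wells Well profiles sharing the model's feature set.
#' @return Tibble: well metadata, `predicted` class, and one probability
#'   column per class.
#' @export
predict_moa <- function(model, wells) {
  missing <- setdiff(model$features, names(wells))
  if (length(missing) > 0) {
    .stop("profiles lack feature(s) required by the model: ",
          paste(head(missing, 10), collapse = ", "))
  }
  x <- .feature_matrix(wells, model$features)
  prob <- predict(model$forest, x, type = "prob")
  pred <- model$classes[max.col(prob, ties.method = "first")]
  meta <- intersect(c("cell_line", "plate", "well", "compound",
                      "concentration", "role"), names(wells))
  bind_cols(wells[, meta], tibble(predicted = pred),
            as_tibble(as.data.frame(prob)))
}

#' Confusion matrix and class sensitivities
#'
#' @param truth True class labels.
#' @param predicted Predicted class labels.
#' @param classes Class set (default: union of observed labels).
#' @return A `moa_confusion`: `counts` (true x predicted), `sensitivity`
#'   (diagonal of the row-normalized matrix) and `accuracy`.
#' @export
moa_confusion_matrix <- function(truth, predicted, classes = NULL) {
  if (length(truth) != length(predicted)) {
    .stop("truth and predicted must have equal length")
  }
  if (is.null(classes)) classes <- sort(unique(c(truth, predicted)))
  bad <- setdiff(unique(c(truth, predicted)), classes)
  if (length(bad) > 0) {
    .stop("label(s) outside the class set: ", paste(bad, collapse = ", "))
  }
  counts <- table(factor(truth, classes), factor(predicted, classes))
  names(dimnames(counts)) <- c("true", "predicted")
  rs <- rowSums(counts)
  sens <- ifelse(rs > 0, diag(counts) / rs, NA_real_)
  structure(list(counts = unclass(counts),
                 sensitivity = setNames(as.numeric(sens), classes),
                 accuracy = sum(diag(counts)) / sum(counts)),
            class = "moa_confusion")
}

#' @export
print.moa_confusion <- function(x, ...) {
  cat(sprintf("Confusion matrix (accuracy %.1f%%)\n", 100 * x$accuracy))
  print(x$counts)
  invisible(x)
}

#' Restrict a panel's well profiles to their common feature set
#'
#' Feature selection runs per cell line, so different lines can retain
#' different features; cross-line training requires the intersection.
#'
#' @param well_list Named list of well-profile tibbles (one per line).
#' @return The list with every table reduced to the shared features.
#' @export
harmonize_features <- function(well_list) {
  shared <- Reduce(intersect, lapply(well_list, feature_columns))
  if (length(shared) < 2) .stop("fewer than 2 features shared across lines")
  lapply(well_list, function(w) {
    meta <- setdiff(names(w), feature_columns(w))
    w[, c(meta, shared)]
  })
}

#' Leave-one-cell-line-out cross-validation
#'
#' For each EAC line, trains the classifier on the labeled profiles of all
#' other EAC lines and tests on the held-out line — the transfer test of
#' whether mechanism signatures generalize to a line the model never saw.
#'
#' @param labeled Labeled well profiles for all EAC lines (single tibble
#'   with a `cell_line` column, shared feature set; see
#'   [harmonize_features()]).
#' @param lines Cell lines to fold over (default: all in `labeled`).
#' @param ntree,mtry,seed Passed to [train_moa_classifier()].
#' @return `loco_cv` list: per-fold tibble `folds` (line, accuracy,
#'   oob_error of its training forest), named list `confusion` of
#'   [moa_confusion_matrix()] objects, and `mean_accuracy`.
#' @export
loco_cv <- function(labeled, lines = NULL, ntree = 500, mtry = NULL,
                    seed = NULL) {
  if (is.null(lines)) lines <- unique(labeled$cell_line)
  if (length(lines) < 3) .stop("leave-one-line-out needs at least 3 lines")
  folds <- list()
  confusion <- list()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    train <- labeled[labeled$cell_line != ln & labeled$cell_line %in% lines, ]
    test <- labeled[labeled$cell_line == ln, ]
    fit <- train_moa_classifier(train, ntree = ntree, mtry = mtry,
                                seed = if (is.null(seed)) NULL else
                                  .derive_seed(seed, ln))
    pred <- predict_moa(fit, test)
    cm <- moa_confusion_matrix(test$label, pred$predicted,
                               classes = fit$classes)
    folds[[i]] <- tibble(line = ln, accuracy = cm$accuracy,
                         oob_error = fit$oob_error, n_test = nrow(test))
    confusion[[ln]] <- cm
  }
  folds <- bind_rows(folds)
  structure(list(folds = folds, confusion = confusion,
                 mean_accuracy = mean(folds$accuracy)),
            class = "loco_cv")
}

#' @export
print.loco_cv <- function(x, ...) {
  cat("Leave-one-cell-line-out cross-validation\n")
  print(as.data.frame(x$folds), row.names = FALSE)
  cat(sprintf("mean transfer accuracy: %.1f%%\n", 100 * x$mean_accuracy))
  invisible(x)
}
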