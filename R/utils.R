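# Internal helpers shared across modules.

# Metadata (non-feature) columns used by the different table shapes.
.cell_keys  <- c("cell_line", "plate", "well", "site", "cell_id")
.image_keys <- c("cell_line", "plate", "well", "site", "n_cells")
.well_keys  <- c("cell_line", "plate", "well", "compound", "concentration",
                 "role", "n_images")

.stop <- function(..., class = "phenoscreen_error") {
  rlang::abort(paste0(...), class = class)
}

#' Feature columns of a profile table
#'
#' Returns the names of the columns of `x` that hold morphology features,
#' i.e. everything that is not one of the pipeline's metadata columns
#' (`cell_line`, `plate`, `well`, `site`, `cell_id`, `n_cells`, `compound`,
#' `concentration`, `role`, `n_images`, `label`).
#'
#' @param x A cell-, image- or well-level profile table.
#' @return Character vector of feature column names.
#' @export
feature_columns <- function(x) {
  meta <- unique(c(.cell_keys, .image_keys, .well_keys, "label"))
  setdiff(names(x), meta)
}

# Extract the feature block as a numeric matrix (rows in table order).
.feature_matrix <- function(x, features = feature_columns(x)) {
  m <- as.matrix(as.data.frame(x)[, features, drop = FALSE])
  storage.mode(m) <- "double"
  m
}

# Stable per-stage seed derivation so pipeline stages can be rerun in
# isolation while the run as a whole stays deterministic. Kept below 2^31.
.derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 2654435761 + h) %% .Machine$integer.max)
}

#' Normalize a well label to zero-padded form
#'
#' Converts labels such as `"a1"` or `"A1"` to the canonical `"A01"` form so
#' that joins between feature tables and plate maps are exact.
#'
#' @param well Character vector of well labels (row letter + column number).
#' @return Character vector of normalized labels.
#' @export
normalize_well_label <- function(well) {
  m <- regmatches(well, regexec("^([A-Za-z]+)0*([0-9]+)$", well))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) {
    .stop("invalid well label(s): ", paste(unique(well[bad]), collapse = ", "))
  }
  vapply(m, function(p) sprintf("%s%02d", toupper(p[2]), as.integer(p[3])),
         character(1))
}

# Well labels for a plate filled row-major: A01..A24, B01.. (16 x 24 = 384).
.plate_wells <- function(n) {
  if (n > 384) .stop("a plate holds at most 384 wells")
  rows <- rep(LETTERS[1:16], each = 24)
  cols <- rep(1:24, times = 16)
  sprintf("%s%02d", rows, cols)[seq_len(n)]
}
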