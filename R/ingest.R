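# Reading and writing the pipeline's tabular formats. All files are plain
# CSV (comma separator, "." decimal, UTF-8, mandatory header); hit tables
# can additionally be written as JSON.

.require_columns <- function(df, required, path) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    .stop("file '", path, "' is missing required column(s): ",
          paste(missing, collapse = ", "))
  }
  invisible(df)
}

#' Read a per-cell morphology feature table
#'
#' Reads a CellProfiler-style CSV with one row per segmented cell. Key
#' columns `plate`, `well`, `site`, `cell_id` (and optionally `cell_line`)
#' are required; every remaining column is treated as a morphology feature
#' and coerced to numeric. Non-numeric feature cells become `NA` and are
#' counted in the validation report attached as attribute `"validation"`.
#'
#' @param path Path to the CSV file.
#' @param cell_line Cell-line label to assign if the file has no
#'   `cell_line` column.
#' @return A tibble of per-cell features with normalized well labels.
#' @export
read_cell_features <- function(path, cell_line = NULL) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  .require_columns(df, c("plate", "well", "site", "cell_id"), path)
  if (!"cell_line" %in% names(df)) {
    if (is.null(cell_line)) {
      .stop("file '", path, "' has no 'cell_line' column and no ",
            "cell_line label was supplied")
    }
    df$cell_line <- cell_line
  }
  feats <- setdiff(names(df), .cell_keys)
  if (length(feats) == 0) .stop("file '", path, "' has no feature columns")
  df$well <- normalize_well_label(df$well)
  df$site <- as.integer(df$site)
  df$cell_id <- as.integer(df$cell_id)

  n_bad <- 0L
  bad_by_feature <- integer(0)
  for (f in feats) {
    v <- suppressWarnings(as.numeric(df[[f]]))
    introduced <- sum(is.na(v) & !is.na(df[[f]]))
    if (introduced > 0) bad_by_feature[f] <- introduced
    n_bad <- n_bad + introduced
    df[[f]] <- v
  }
  key <- df[, c("plate", "well", "site", "cell_id")]
  if (anyDuplicated(key) > 0) {
    .stop("file '", path, "' has duplicated (plate, well, site, cell_id) keys")
  }
  out <- as_tibble(df[, c(.cell_keys, feats)])
  attr(out, "validation") <- list(n_non_numeric = n_bad,
                                  by_feature = bad_by_feature)
  out
}

#' Read and validate a plate map
#'
#' A plate map assigns a compound, concentration and role (`treatment` or
#' `vehicle_control`) to each well. Every plate must carry at least one
#' DMSO vehicle well (normalization is impossible otherwise), vehicle rows
#' must name compound `"DMSO"`, and (plate, well) pairs must be unique.
#'
#' @param path Path to the CSV file.
#' @return A validated plate-map tibble.
#' @export
read_platemap <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    plate = "c", well = "c", compound = "c",
    concentration = "d", role = "c"), progress = FALSE)
  .require_columns(df, c("plate", "well", "compound", "concentration",
                         "role"), path)
  df$well <- normalize_well_label(df$well)
  validate_platemap(as_tibble(df))
}

#' @rdname read_platemap
#' @param platemap A plate-map tibble to validate in memory.
#' @export
validate_platemap <- function(platemap) {
  if (anyDuplicated(platemap[, c("plate", "well")]) > 0) {
    .stop("plate map has duplicated (plate, well) rows")
  }
  bad_role <- setdiff(unique(platemap$role), c("treatment", "vehicle_control"))
  if (length(bad_role) > 0) {
    .stop("plate map has unknown role(s): ", paste(bad_role, collapse = ", "))
  }
  veh <- platemap$role == "vehicle_control"
  if (any(platemap$compound[veh] != "DMSO")) {
    .stop("vehicle_control wells must have compound 'DMSO'")
  }
  no_dmso <- setdiff(unique(platemap$plate), unique(platemap$plate[veh]))
  if (length(no_dmso) > 0) {
    .stop("plate(s) without any DMSO vehicle well: ",
          paste(no_dmso, collapse = ", "))
  }
  platemap
}

#' Read reference mechanism-of-action annotations
#'
#' @param path CSV with columns `compound`, `moa_class`.
#' @return Annotation tibble (one class per compound enforced).
#' @export
read_annotations <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  .require_columns(df, c("compound", "moa_class"), path)
  if (anyDuplicated(df$compound) > 0) {
    .stop("annotation file '", path, "' assigns multiple classes to: ",
          paste(unique(df$compound[duplicated(df$compound)]), collapse = ", "))
  }
  as_tibble(df[, c("compound", "moa_class")])
}

#' Write / read pipeline tables
#'
#' Plain-CSV writers and readers for cell tables, plate maps, well profiles
#' and hit tables. Finite values round-trip exactly (full precision); missing
#' values round-trip as empty cells. Hit tables can also be written as JSON.
#'
#' @param x Table to write.
#' @param path Output path.
#' @name pheno_io
#' @export
write_profiles <- function(x, path) {
  readr::write_csv(x, path, na = "")
  invisible(path)
}

#' @rdname pheno_io
#' @export
read_profiles <- function(path) {
  hdr <- names(readr::read_csv(path, n_max = 0, col_types = readr::cols(),
                               progress = FALSE))
  types <- list(cell_line = "c", plate = "c", well = "c", compound = "c",
                role = "c", site = "i", cell_id = "i", n_cells = "i",
                n_images = "i")
  spec <- do.call(readr::cols,
                  c(types[intersect(names(types), hdr)], .default = "d"))
  as_tibble(readr::read_csv(path, col_types = spec, progress = FALSE))
}

#' @rdname pheno_io
#' @param format `"csv"` or `"json"` for hit tables.
#' @export
write_hit_table <- function(x, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    readr::write_csv(x, path, na = "")
  } else {
    jsonlite::write_json(x, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null", pretty = TRUE)
  }
  invisible(path)
}

#' @rdname pheno_io
#' @export
write_platemap <- function(x, path) {
  readr::write_csv(validate_platemap(x), path, na = "")
  invisible(path)
}

#' @rdname pheno_io
#' @export
write_cell_features <- function(x, path) {
  readr::write_csv(x, path, na = "")
  invisible(path)
}
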