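# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept small so the whole suite runs in minutes.

# A small but complete panel screen: 4 lines (3 EAC + 1 control), a
# reference library and a screening section.
tiny_screen_config <- function(seed = 1, ...) {
  args <- list(
    cell_lines = c("EAC1", "EAC2", "EAC3", "CTRL1"),
    control_lines = "CTRL1",
    n_features = 40, wells_per_plate = 96, dmso_fraction = 0.15,
    n_compounds_per_class = 2, n_ref_replicates = 2,
    n_screen_compounds = 40, n_selective = 5, n_broad_actives = 0,
    cells_per_image_mean = 40, n_sites = 2, artifact_image_rate = 0,
    seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(screen_config, args)
}

# Hand-built ground-truth table (bypasses the generator).
make_truth <- function(compound, active_lines, eac, control,
                       category = "selective") {
  t <- tibble::tibble(compound = compound,
                      true_class = "DNA damage",
                      category = category,
                      active_lines = active_lines,
                      kill = 0.5)
  attr(t, "eac_lines") <- eac
  attr(t, "control_lines") <- control
  class(t) <- c("pheno_truth", class(t))
  t
}

# Directly sampled labeled well profiles (Gaussian class means), for
# classifier tests that do not need the full generator.
gaussian_labeled <- function(n_per_class = 30, n_classes = 8,
                             n_features = 40, sep = 1.5, seed = 1,
                             cell_line = "L1") {
  set.seed(seed)
  classes <- c("DMSO", paste0("class", seq_len(n_classes - 1)))
  mu <- rbind(0, matrix(rnorm((n_classes - 1) * n_features, sd = sep),
                        n_classes - 1, n_features))
  rows <- lapply(seq_along(classes), function(k) {
    x <- sweep(matrix(rnorm(n_per_class * n_features), n_per_class),
               2, mu[k, ], "+")
    colnames(x) <- paste0("f", seq_len(n_features))
    dplyr::bind_cols(
      tibble::tibble(cell_line = cell_line, plate = "P1",
                     well = sprintf("%s%02d", LETTERS[k], seq_len(n_per_class)),
                     compound = paste0("c", k), concentration = 1,
                     role = "treatment", label = classes[k]),
      tibble::as_tibble(x))
  })
  dplyr::bind_rows(rows)
}

# Minimal distance/z tibbles for hit-calling rule tests.
panel_values <- function(values, lines, compound = "X") {
  tibble::tibble(compound = compound, cell_line = lines, value = values)
}
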