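#' Configuration for a synthetic Cell Painting screen
#'
#' Builds and validates the parameter set for [generate_screen()]. The
#' defaults describe an eight-line esophageal panel (six adenocarcinoma
#' lines, one Barrett's and one squamous control line) profiled in 384-well
#' plates with ~300 cells per field of view and 733 morphology features per
#' cell, a reference library of mechanistic classes dosed at 0.1/1/10 uM,
#' and a single-dose screening library containing planted selective actives.
#'
#' Per-cell feature values are log-normal: a cell-line baseline plus a sparse
#' class signature (scaled by dose and `effect_size`), a per-plate
#' multiplicative plate effect, a per-well random effect, and per-cell noise.
#' `effect_size` is expressed in units of the per-cell log-scale noise SD.
#'
#' @param cell_lines Names of the panel's cell lines.
#' @param control_lines Which of `cell_lines` are non-cancer controls; the
#'   remainder are treated as the EAC (cancer) panel.
#' @param n_features Number of morphology features per cell.
#' @param wells_per_plate Plate capacity (row-major A01..P24 layout).
#' @param dmso_fraction Fraction of each plate's used wells that carry DMSO
#'   vehicle; must lie strictly inside (0, 1).
#' @param moa_classes Mechanistic class labels; must include `"DMSO"`.
#' @param doses Reference-library concentrations in uM.
#' @param dose_scaling Multiplier applied to the class signature at each of
#'   `doses` (same length).
#' @param effect_size Mean feature shift of a full-dose signature, in units
#'   of the per-cell noise SD. Zero gives a pure null screen.
#' @param n_compounds_per_class Reference compounds per non-DMSO class.
#' @param n_ref_replicates Replicate wells per (reference compound, dose).
#' @param n_screen_compounds Size of the single-dose screening library
#'   (0 disables the screen section).
#' @param n_selective Planted selective actives: active in at least two EAC
#'   lines and in no control line.
#' @param n_broad_actives Planted non-selective actives, active in every
#'   line (these must not survive the selectivity rules).
#' @param screen_dose Concentration (uM) of the screening library.
#' @param viability_kill Fractional reduction of expected cell count in a
#'   truly active (compound, line) pair at full dose scaling.
#' @param signature_fraction Fraction of features shifted by each class
#'   signature (sparse signatures keep feature selection non-trivial).
#' @param line_specific_signatures If `TRUE`, every cell line draws private
#'   class signatures (breaks cross-line transfer on purpose).
#' @param plate_effect_sd Log-scale SD of the per-plate, per-feature
#'   multiplicative plate effect.
#' @param well_effect_sd Log-scale SD of the per-well random effect.
#' @param cell_noise_sd Log-scale SD of per-cell noise.
#' @param cells_per_image_mean Expected cells per field of view.
#' @param n_sites Fields of view imaged per well.
#' @param artifact_image_rate Fraction of images forced below the 20-cell
#'   QC threshold (uniform 0..19 cells), emulating imaging artifacts.
#' @param include_reference Generate the annotated reference-library plates.
#' @param seed Integer seed; the whole screen is deterministic given it.
#' @return A validated `screen_config` list.
#' @export
screen_config <- function(cell_lines = c("FLO-1", "JH-EsoAD1", "OE33", "OE19",
                                         "ESO-26", "SK-GT-4",
                                         "EPC2-hTERT", "CP-A"),
                          control_lines = c("EPC2-hTERT", "CP-A"),
                          n_features = 733,
                          wells_per_plate = 384,
                          dmso_fraction = 0.1,
                          moa_classes = c("DMSO", "DNA damage",
                                          "HDAC inhibition",
                                          "microtubule disruption",
                                          "antimetabolite",
                                          "mTOR inhibition",
                                          "proteasome inhibition",
                                          "HSP90 inhibition"),
                          doses = c(0.1, 1, 10),
                          dose_scaling = c(0.25, 0.6, 1),
                          effect_size = 2,
                          n_compounds_per_class = 5,
                          n_ref_replicates = 2,
                          n_screen_compounds = 500,
                          n_selective = 20,
                          n_broad_actives = 0,
                          screen_dose = 10,
                          viability_kill = 0.5,
                          signature_fraction = 0.1,
                          line_specific_signatures = FALSE,
                          plate_effect_sd = 0.15,
                          well_effect_sd = 0.1,
                          cell_noise_sd = 0.3,
                          cells_per_image_mean = 300,
                          n_sites = 5,
                          artifact_image_rate = 0.02,
                          include_reference = TRUE,
                          seed = 1L) {
  cfg <- as.list(environment())
  cfg$cell_lines <- as.character(cell_lines)
  cfg$control_lines <- as.character(control_lines)
  if (cfg$n_screen_compounds == 0) {
    cfg$n_selective <- 0L
    cfg$n_broad_actives <- 0L
  }
  cfg$eac_lines <- setdiff(cfg$cell_lines, cfg$control_lines)
  class(cfg) <- "screen_config"
  validate_screen_config(cfg)
}

#' @rdname screen_config
#' @param config A `screen_config` to validate.
#' @export
validate_screen_config <- function(config) {
  chk <- function(ok, field, why) {
    if (!ok) .stop("invalid screen config: field '", field, "' ", why)
  }
  with(config, {
    chk(length(cell_lines) >= 1 && !anyDuplicated(cell_lines),
        "cell_lines", "must be non-empty and unique")
    chk(all(control_lines %in% cell_lines), "control_lines",
        "must be a subset of cell_lines")
    if (length(cell_lines) == 8) {
      chk(length(control_lines) == 2, "control_lines",
          "must name exactly 2 control lines in an 8-line panel")
    }
    for (f in c("n_features", "wells_per_plate", "cells_per_image_mean",
                "n_sites", "n_compounds_per_class", "n_ref_replicates")) {
      chk(config[[f]] > 0, f, "must be positive")
    }
    chk(dmso_fraction > 0 && dmso_fraction < 1, "dmso_fraction",
        "must lie strictly in (0, 1)")
    chk(effect_size >= 0, "effect_size", "must be non-negative")
    chk(n_screen_compounds >= 0, "n_screen_compounds",
        "must be non-negative")
    chk(n_selective + n_broad_actives <= n_screen_compounds,
        "n_selective", "plus n_broad_actives must not exceed n_screen_compounds")
    chk(artifact_image_rate >= 0 && artifact_image_rate < 1,
        "artifact_image_rate", "must lie in [0, 1)")
    chk("DMSO" %in% moa_classes, "moa_classes", "must include 'DMSO'")
    chk(length(doses) == length(dose_scaling), "dose_scaling",
        "must match doses in length")
    chk(viability_kill >= 0 && viability_kill < 1, "viability_kill",
        "must lie in [0, 1)")
    chk(signature_fraction > 0 && signature_fraction <= 1,
        "signature_fraction", "must lie in (0, 1]")
    if (n_selective > 0) {
      chk(length(setdiff(cell_lines, control_lines)) >= 2, "n_selective",
          "requires at least 2 EAC lines for selective actives")
    }
  })
  config
}

# Plate-map layout shared by every cell line: reference plates (all doses x
# replicates) followed by screening plates (single dose), DMSO vehicle wells
# spread evenly through each plate.
.layout_plates <- function(cfg) {
  n_dmso <- max(2L, round(cfg$dmso_fraction * cfg$wells_per_plate))
  cap <- cfg$wells_per_plate - n_dmso

  blocks <- list()
  if (cfg$include_reference) {
    classes <- setdiff(cfg$moa_classes, "DMSO")
    ref_ids <- sprintf("REF%03d", seq_len(length(classes) *
                                            cfg$n_compounds_per_class))
    ref <- tibble(
      compound = rep(ref_ids, each = length(cfg$doses) * cfg$n_ref_replicates),
      concentration = rep(rep(cfg$doses, each = cfg$n_ref_replicates),
                          times = length(ref_ids))
    )
    blocks$REF <- ref
  }
  if (cfg$n_screen_compounds > 0) {
    scr_ids <- sprintf("SCR%04d", seq_len(cfg$n_screen_compounds))
    blocks$SCR <- tibble(compound = scr_ids,
                         concentration = cfg$screen_dose)
  }

  pm <- list()
  for (prefix in names(blocks)) {
    trt <- blocks[[prefix]]
    n_plates <- ceiling(nrow(trt) / cap)
    trt$plate <- paste0(prefix, rep(seq_len(n_plates),
                                    each = cap)[seq_len(nrow(trt))])
    for (p in unique(trt$plate)) {
      tp <- trt[trt$plate == p, ]
      n_used <- nrow(tp) + n_dmso
      wells <- .plate_wells(n_used)
      dmso_idx <- unique(round(seq(1, n_used, length.out = n_dmso)))
      # rounding can collide; top up from unused slots
      while (length(dmso_idx) < n_dmso) {
        dmso_idx <- union(dmso_idx, setdiff(seq_len(n_used), dmso_idx)[1])
      }
      lay <- tibble(plate = p, well = wells,
                    compound = "DMSO", concentration = 0,
                    role = "vehicle_control")
      lay$compound[-dmso_idx] <- tp$compound
      lay$concentration[-dmso_idx] <- tp$concentration
      lay$role[-dmso_idx] <- "treatment"
      pm[[p]] <- lay
    }
  }
  bind_rows(pm)
}

#' Generate a synthetic multi-cell-line screen with known ground truth
#'
#' Simulates per-cell morphology feature tables for every cell line of the
#' panel, together with the plate map, the reference-library mechanism
#' annotations, and a ground-truth table recording each compound's true
#' class, truly active cell lines and viability effect. All downstream
#' pipeline stages can be validated against this truth.
#'
#' The generative model for feature `f` of a cell in well `w` of plate `p`
#' on line `l` is
#' `x = exp(mu_lf + plate_pf + well_wf + s_kf * g(dose) * effect + eps)`,
#' with a sparse signed class signature `s_k`, dose multiplier `g`, and
#' Gaussian log-scale noise terms; cells per image are Poisson around
#' `cells_per_image_mean`, with a configurable fraction of artifact images
#' forced to 0-19 cells. Truly active compounds additionally reduce the
#' expected cell count in their active lines (the viability phenotype).
#'
#' @param config A [screen_config()].
#' @return A `pheno_screen` list with elements `cells` (named list of
#'   per-cell tibbles, one per line), `platemap`, `annotations` (reference
#'   library only), `truth` (see [ground_truth_hit_set()]) and `config`.
#' @export
generate_screen <- function(config = screen_config()) {
  cfg <- validate_screen_config(config)
  set.seed(cfg$seed)
  nf <- cfg$n_features
  feat_names <- .feature_names(nf)
  classes <- setdiff(cfg$moa_classes, "DMSO")

  platemap <- .layout_plates(cfg)

  # --- compound ground truth -------------------------------------------
  annotations <- tibble(compound = character(0), moa_class = character(0))
  truth <- list()
  if (cfg$include_reference) {
    ref_ids <- sprintf("REF%03d",
                       seq_len(length(classes) * cfg$n_compounds_per_class))
    ref_class <- rep(classes, each = cfg$n_compounds_per_class)
    annotations <- tibble(compound = ref_ids, moa_class = ref_class)
    truth$ref <- tibble(compound = ref_ids, true_class = ref_class,
                        category = "reference",
                        active_lines = list(cfg$cell_lines), kill = 0)
  }
  if (cfg$n_screen_compounds > 0) {
    scr_ids <- sprintf("SCR%04d", seq_len(cfg$n_screen_compounds))
    status <- rep("inert", cfg$n_screen_compounds)
    planted <- sample(cfg$n_screen_compounds,
                      cfg$n_selective + cfg$n_broad_actives)
    status[planted[seq_len(cfg$n_selective)]] <- "selective"
    if (cfg$n_broad_actives > 0) {
      status[planted[cfg$n_selective + seq_len(cfg$n_broad_actives)]] <- "broad"
    }
    active <- vector("list", cfg$n_screen_compounds)
    cls <- rep(NA_character_, cfg$n_screen_compounds)
    for (i in seq_len(cfg$n_screen_compounds)) {
      active[[i]] <- character(0)
      if (status[i] == "selective") {
        k <- sample(2:length(cfg$eac_lines), 1)
        active[[i]] <- sort(sample(cfg$eac_lines, k))
        cls[i] <- sample(classes, 1)
      } else if (status[i] == "broad") {
        active[[i]] <- cfg$cell_lines
        cls[i] <- sample(classes, 1)
      }
    }
    truth$scr <- tibble(compound = scr_ids, true_class = cls,
                        category = status, active_lines = active,
                        kill = ifelse(status == "inert", 0,
                                      cfg$viability_kill))
  }
  truth <- bind_rows(truth)
  attr(truth, "eac_lines") <- cfg$eac_lines
  attr(truth, "control_lines") <- cfg$control_lines
  class(truth) <- c("pheno_truth", class(truth))

  # --- class signatures ------------------------------------------------
  n_sig <- max(1L, round(cfg$signature_fraction * nf))
  draw_sigs <- function() {
    sigs <- lapply(classes, function(k) {
      s <- numeric(nf)
      idx <- sample(nf, n_sig)
      s[idx] <- sample(c(-1, 1), n_sig, replace = TRUE)
      s
    })
    names(sigs) <- classes
    sigs
  }
  sigs_by_line <- if (cfg$line_specific_signatures) {
    setNames(lapply(cfg$cell_lines, function(l) draw_sigs()), cfg$cell_lines)
  } else {
    shared <- draw_sigs()
    setNames(rep(list(shared), length(cfg$cell_lines)), cfg$cell_lines)
  }

  dose_scale <- function(conc) {
    i <- match(conc, cfg$doses)
    ifelse(is.na(i), 1, cfg$dose_scaling[i])
  }
  truth_class <- setNames(truth$true_class, truth$compound)
  truth_active <- setNames(truth$active_lines, truth$compound)
  truth_kill <- setNames(truth$kill, truth$compound)

  # --- per-line per-cell tables ----------------------------------------
  plates <- unique(platemap$plate)
  cells <- setNames(vector("list", length(cfg$cell_lines)), cfg$cell_lines)
  for (line in cfg$cell_lines) {
    baseline <- rnorm(nf, 0, 0.5)
    sigs <- sigs_by_line[[line]]
    plate_parts <- vector("list", length(plates))
    for (pi in seq_along(plates)) {
      p <- plates[pi]
      pmap <- platemap[platemap$plate == p, ]
      nw <- nrow(pmap)
      plate_eff <- rnorm(nf, 0, cfg$plate_effect_sd)
      well_eff <- matrix(rnorm(nw * nf, 0, cfg$well_effect_sd), nw, nf)

      shift <- matrix(0, nw, nf)
      lambda <- rep(cfg$cells_per_image_mean, nw)
      for (w in seq_len(nw)) {
        cmp <- pmap$compound[w]
        if (cmp == "DMSO") next
        act <- line %in% truth_active[[cmp]]
        if (act && !is.na(truth_class[[cmp]])) {
          g <- dose_scale(pmap$concentration[w])
          shift[w, ] <- sigs[[truth_class[[cmp]]]] *
            cfg$effect_size * cfg$cell_noise_sd * g
          lambda[w] <- cfg$cells_per_image_mean *
            (1 - truth_kill[[cmp]] * g)
        }
      }
      well_mu <- sweep(well_eff + shift, 2, baseline + plate_eff, "+")

      # cells per image, with forced low-count artifact images
      counts <- rpois(nw * cfg$n_sites,
                      rep(lambda, each = cfg$n_sites))
      artifact <- runif(nw * cfg$n_sites) < cfg$artifact_image_rate
      counts[artifact] <- sample(0:19, sum(artifact), replace = TRUE)

      img_well <- rep(seq_len(nw), each = cfg$n_sites)
      img_site <- rep(seq_len(cfg$n_sites), times = nw)
      cell_img <- rep(seq_along(counts), counts)
      n_cells_total <- length(cell_img)
      if (n_cells_total == 0) next
      log_x <- well_mu[img_well[cell_img], , drop = FALSE] +
        matrix(rnorm(n_cells_total * nf, 0, cfg$cell_noise_sd),
               n_cells_total, nf)
      x <- exp(log_x)
      colnames(x) <- feat_names
      plate_parts[[pi]] <- bind_cols(
        tibble(cell_line = line, plate = p,
               well = pmap$well[img_well[cell_img]],
               site = img_site[cell_img],
               cell_id = sequence(counts)),
        as_tibble(x)
      )
    }
    cells[[line]] <- bind_rows(plate_parts)
  }

  structure(list(cells = cells, platemap = platemap,
                 annotations = annotations, truth = truth, config = cfg),
            class = "pheno_screen")
}

# CellProfiler-flavoured feature names cycling over compartment, measurement
# class, statistic and channel.
.feature_names <- function(n) {
  comp <- c("Cells", "Nuclei", "Cytoplasm")
  cat <- c("AreaShape", "Intensity", "Texture", "Granularity",
           "RadialDistribution")
  stat <- c("Mean", "Median", "StdDev", "MAD", "Max")
  chan <- c("DNA", "ER", "RNA", "AGP", "Mito")
  grid <- expand.grid(chan = chan, stat = stat, cat = cat, comp = comp,
                      stringsAsFactors = FALSE)
  base <- with(grid, paste(comp, cat, stat, chan, sep = "_"))
  idx <- seq_len(n)
  paste0(base[((idx - 1) %% length(base)) + 1], "_",
         sprintf("%03d", ((idx - 1) %/% length(base)) + 1))
}

#' Planted selective compounds of a synthetic screen
#'
#' Returns the compounds that the generator made active in at least
#' `min_eac_lines` EAC lines and in no control line: the set a perfect
#' hit-calling pipeline should recover.
#'
#' @param truth The `truth` element of a [generate_screen()] result.
#' @param min_eac_lines Minimum number of truly active EAC lines.
#' @return Character vector of compound identifiers.
#' @export
ground_truth_hit_set <- function(truth, min_eac_lines = 2) {
  if (min_eac_lines < 1) .stop("min_eac_lines must be at least 1")
  eac <- attr(truth, "eac_lines")
  ctrl <- attr(truth, "control_lines")
  keep <- vapply(truth$active_lines, function(a) {
    length(intersect(a, eac)) >= min_eac_lines &&
      length(intersect(a, ctrl)) == 0 && length(a) > 0
  }, logical(1))
  truth$compound[keep]
}

#' Per-well nuclei counts of a synthetic or real cell table
#'
#' Sums segmented cells over all fields of view of each well, the input to
#' the viability (z-score) analysis.
#'
#' @param cells A per-cell feature table (or the `cells` list of a
#'   [generate_screen()] result).
#' @return Tibble with `cell_line`, `plate`, `well`, `n_nuclei`.
#' @export
well_nuclei_counts <- function(cells) {
  if (is.list(cells) && !is.data.frame(cells)) cells <- bind_rows(cells)
  cells |>
    count(.data$cell_line, .data$plate, .data$well, name = "n_nuclei")
}
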