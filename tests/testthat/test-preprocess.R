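# Preprocessing chain: median aggregation, QC, DMSO normalization,
# feature selection, scaling, well aggregation — each against small
# closed-form examples or an independent oracle.

make_cells <- function(values_by_image, feature = "f1") {
  # values_by_image: named list "plate|well|site" -> numeric vector
  rows <- lapply(names(values_by_image), function(k) {
    p <- strsplit(k, "|", fixed = TRUE)[[1]]
    v <- values_by_image[[k]]
    d <- tibble::tibble(cell_line = "L1", plate = p[1], well = p[2],
                        site = as.integer(p[3]), cell_id = seq_along(v))
    d[[feature]] <- v
    d
  })
  dplyr::bind_rows(rows)
}

test_that("image aggregation takes the per-feature median over cells", {
  cells <- make_cells(list("P1|A01|1" = c(1, 3), "P1|A01|2" = c(1, 2, 100)))
  img <- aggregate_cells_to_images(cells)
  img <- img[order(img$site), ]
  expect_equal(img$f1, c(2, 2))
  expect_equal(img$n_cells, c(2L, 3L))
})

test_that("image aggregation matches a sort-based median oracle", {
  set.seed(7)
  v <- rnorm(200)
  oracle_median <- function(x) {
    s <- sort(x); n <- length(s)
    if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
  }
  cells <- make_cells(list("P1|A01|1" = v))
  cells$f2 <- rexp(200)
  img <- aggregate_cells_to_images(cells)
  expect_equal(img$f1, oracle_median(v))
  expect_equal(img$f2, oracle_median(cells$f2))
  # missing values are ignored within an image
  cells$f1[5] <- NA
  img2 <- aggregate_cells_to_images(cells)
  expect_equal(img2$f1, oracle_median(v[-5]))
})

test_that("QC keeps images at the threshold and removes those below", {
  img <- tibble::tibble(cell_line = "L1", plate = "P1",
                        well = sprintf("A%02d", 1:10), site = 1L,
                        n_cells = c(19L, 20L, 21L, 5L, 0L, 50L, 30L, 20L,
                                    19L, 100L),
                        f1 = rnorm(10))
  out <- qc_filter_images(img, min_cells = 20)
  expect_equal(nrow(out), 6)   # 19, 5, 0, 19 removed; both 20s kept
  expect_false(any(out$n_cells < 20))
  expect_equal(sort(attr(out, "qc_log")$well), c("A01", "A04", "A05", "A09"))
  expect_equal(nrow(qc_filter_images(img, min_cells = 0)), 10)
  flagged <- qc_filter_images(img, min_cells = 0,
                              quality_flags = c(TRUE, rep(FALSE, 9)))
  expect_equal(nrow(flagged), 9)
  expect_equal(attr(flagged, "qc_log")$reason, "quality_flag")
})

test_that("DMSO normalization divides by the plate median and self-normalizes", {
  pm <- tibble::tibble(plate = "P1", well = c("A01", "A02", "A03"),
                       compound = c("DMSO", "DMSO", "c1"),
                       concentration = c(0, 0, 10),
                       role = c("vehicle_control", "vehicle_control",
                                "treatment"))
  img <- tibble::tibble(cell_line = "L1", plate = "P1",
                        well = c("A01", "A02", "A03"), site = 1L,
                        n_cells = 50L, f1 = c(1, 3, 4))
  out <- normalize_to_dmso(img, pm)
  expect_equal(out$f1[out$well == "A03"], 4 / 2)   # DMSO median = 2
  expect_equal(median(out$f1[out$well != "A03"]), 1)
})

test_that("a plate without surviving DMSO images is a hard error", {
  pm <- tibble::tibble(plate = c("P1", "P1"), well = c("A01", "A02"),
                       compound = c("DMSO", "c1"), concentration = c(0, 10),
                       role = c("vehicle_control", "treatment"))
  img <- tibble::tibble(cell_line = "L1", plate = "P1", well = "A02",
                        site = 1L, n_cells = 50L, f1 = 2)
  expect_error(normalize_to_dmso(img, pm), "no surviving DMSO")
})

test_that("a multiplicative plate offset is removed exactly", {
  set.seed(1)
  pm <- tibble::tibble(plate = rep(c("P1", "P2"), each = 20),
                       well = rep(sprintf("A%02d", 1:20), 2),
                       compound = rep(c(rep("DMSO", 10), paste0("c", 1:10)), 2),
                       concentration = 0, role = rep(c(rep("vehicle_control", 10),
                                                       rep("treatment", 10)), 2))
  base <- rlnorm(20)
  img1 <- tibble::tibble(cell_line = "L1", plate = "P1",
                         well = sprintf("A%02d", 1:20), site = 1L,
                         n_cells = 50L, f1 = base)
  img2 <- img1
  img2$plate <- "P2"
  img2$f1 <- base * 2   # plate-wide 2x offset
  out <- normalize_to_dmso(dplyr::bind_rows(img1, img2), pm)
  expect_equal(out$f1[out$plate == "P1"], out$f1[out$plate == "P2"])
})

test_that("feature selection drops NA, constant and near-zero-variance features", {
  set.seed(2)
  n <- 50
  prof <- tibble::tibble(cell_line = "L1", plate = "P1",
                         well = sprintf("A%02d", 1:n), site = 1L,
                         n_cells = 50L,
                         good = rnorm(n),
                         good2 = rnorm(n),
                         with_na = c(NA, rnorm(n - 1)),
                         constant = rep(1, n),
                         nzv = c(rep(0, 48), 1, 1))
  sel <- select_features(prof, nzv_freq_cut = 95 / 5, nzv_unique_cut = 0.1)
  expect_setequal(feature_columns(sel$profiles), c("good", "good2"))
  rep <- sel$report
  expect_equal(rep$reason[rep$feature == "with_na"], "missing_values")
  expect_equal(rep$reason[rep$feature == "constant"], "zero_variance")
  expect_equal(rep$reason[rep$feature == "nzv"], "near_zero_variance")
})

test_that("one of a duplicated feature pair is removed", {
  set.seed(3)
  prof <- tibble::tibble(cell_line = "L1", plate = "P1",
                         well = sprintf("A%02d", 1:30), site = 1L,
                         n_cells = 50L, a = rnorm(30))
  prof$b <- prof$a
  prof$c <- rnorm(30)
  sel <- select_features(prof)
  kept <- feature_columns(sel$profiles)
  expect_length(intersect(kept, c("a", "b")), 1)
  expect_true("c" %in% kept)
})

test_that("correlation pruning matches the minimal removal set on a fixture", {
  # three clusters: a1-a3 mutually |r|>0.95, b1-b2 a correlated pair,
  # c1-c5 independent; the minimal removal set has size 3
  set.seed(4)
  n <- 200
  lat_a <- rnorm(n); lat_b <- rnorm(n)
  prof <- tibble::tibble(cell_line = "L1", plate = "P1",
                         well = sprintf("%s%02d", rep(LETTERS[1:9], length.out = n),
                                        rep(1:24, length.out = n)),
                         site = seq_len(n), n_cells = 50L,
                         a1 = lat_a + rnorm(n, sd = 0.05),
                         a2 = lat_a + rnorm(n, sd = 0.05),
                         a3 = lat_a + rnorm(n, sd = 0.05),
                         b1 = lat_b + rnorm(n, sd = 0.1),
                         b2 = lat_b + rnorm(n, sd = 0.1),
                         c1 = rnorm(n), c2 = rnorm(n), c3 = rnorm(n),
                         c4 = rnorm(n), c5 = rnorm(n))
  feats <- feature_columns(prof)
  r <- abs(cor(as.matrix(prof[feats])))
  stopifnot(min(r[c("a1", "a2", "a3"), c("a1", "a2", "a3")]) > 0.95,
            r["b1", "b2"] > 0.95)

  # oracle: exhaustive search for the smallest removal set leaving no
  # violating pair
  ok_after_removal <- function(drop) {
    keep <- setdiff(feats, drop)
    rr <- r[keep, keep]; diag(rr) <- 0
    max(rr) <= 0.95
  }
  minimal <- NA
  for (k in 0:length(feats)) {
    combos <- utils::combn(feats, k, simplify = FALSE)
    if (any(vapply(combos, ok_after_removal, logical(1)))) {
      minimal <- k
      break
    }
  }
  sel <- select_features(prof)
  removed <- sel$report$feature[sel$report$reason == "high_correlation"]
  expect_equal(length(removed), minimal)
  kept <- feature_columns(sel$profiles)
  rk <- r[kept, kept]; diag(rk) <- 0
  expect_lte(max(rk), 0.95)
})

test_that("feature selection is idempotent", {
  scr <- generate_screen(tiny_screen_config(n_features = 30, seed = 6))
  img <- normalize_to_dmso(
    qc_filter_images(aggregate_cells_to_images(scr$cells[[1]]), 20),
    scr$platemap)
  once <- select_features(img)
  twice <- select_features(once$profiles)
  expect_identical(feature_columns(once$profiles),
                   feature_columns(twice$profiles))
  expect_equal(nrow(twice$report), 0)
})

test_that("scaling yields mean 0 / SD 1 and matches a two-pass oracle", {
  prof <- tibble::tibble(cell_line = "L1", plate = "P1",
                         well = c("A01", "A02", "A03"), site = 1L,
                         n_cells = 50L, f1 = c(1, 2, 3))
  out <- scale_features(prof)
  expect_equal(mean(out$f1), 0)
  expect_equal(sd(out$f1), 1)
  expect_equal(out$f1, c(-1, 0, 1))

  set.seed(5)
  prof2 <- tibble::tibble(cell_line = "L1", plate = "P1",
                          well = sprintf("B%02d", 1:40), site = 1L,
                          n_cells = 50L, g = rlnorm(40), h = rnorm(40, 5, 9))
  out2 <- scale_features(prof2)
  for (f in c("g", "h")) {
    mu <- sum(prof2[[f]]) / 40
    s <- sqrt(sum((prof2[[f]] - mu)^2) / 39)
    expect_equal(out2[[f]], (prof2[[f]] - mu) / s, tolerance = 1e-12)
  }
  # idempotence up to floating error
  out3 <- scale_features(out2)
  expect_equal(out3$g, out2$g, tolerance = 1e-10)
  expect_error(scale_features(dplyr::mutate(prof, f1 = 1)), "zero-variance")
})

test_that("well aggregation medians images and joins the plate map", {
  pm <- tibble::tibble(plate = "P1", well = c("A01", "A02"),
                       compound = c("c1", "DMSO"), concentration = c(10, 0),
                       role = c("treatment", "vehicle_control"))
  img <- tibble::tibble(cell_line = "L1", plate = "P1",
                        well = c(rep("A01", 4), "A02"),
                        site = c(1:4, 1L), n_cells = 50L,
                        f1 = c(1, 2, 3, 4, 7))
  w <- aggregate_images_to_wells(img, pm)
  expect_equal(w$f1[w$well == "A01"], 2.5)
  expect_equal(w$n_images[w$well == "A01"], 4L)
  expect_equal(w$f1[w$well == "A02"], 7)   # single image passes through
  expect_equal(w$compound[w$well == "A01"], "c1")
  img$well[1] <- "A09"
  expect_error(aggregate_images_to_wells(img, pm), "absent from plate map")
})

test_that("full per-line chain keeps wells with >=1 surviving image", {
  cfg <- tiny_screen_config(seed = 8, artifact_image_rate = 0.1,
                            cells_per_image_mean = 60, n_sites = 1,
                            n_screen_compounds = 20, n_selective = 0)
  scr <- generate_screen(cfg)
  prep <- preprocess_line(scr$cells[["EAC1"]], scr$platemap)
  imgs <- qc_filter_images(aggregate_cells_to_images(scr$cells[["EAC1"]]), 20)
  surviving <- unique(paste(imgs$plate, imgs$well))
  expect_setequal(paste(prep$wells$plate, prep$wells$well), surviving)
  # retained features: no pair above the correlation cutoff
  feats <- feature_columns(prep$wells)
  expect_gte(length(feats), 2)
})
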