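# Hit calling: PCA, Mahalanobis distances (with independent oracles),
# threshold calibration, z-scores and the selectivity rules.

random_spd <- function(p) {
  a <- matrix(rnorm(p * p), p)
  crossprod(a) + diag(p) * 0.1
}

test_that("PCA on planar data explains everything in two components", {
  set.seed(1)
  basis <- qr.Q(qr(matrix(rnorm(15 * 2), 15, 2)))
  coords <- matrix(rnorm(100 * 2, sd = c(3, 1)), 100, 2, byrow = TRUE)
  x <- coords %*% t(basis)
  colnames(x) <- paste0("f", 1:15)
  wells <- dplyr::bind_cols(
    tibble::tibble(cell_line = "L", plate = "P", well = sprintf("W%03d", 1:100),
                   compound = "c", concentration = 1, role = "treatment"),
    tibble::as_tibble(x))
  expect_no_warning(m <- fit_pca(wells, n_components = 2))
  expect_equal(sum(m$explained[1:2]), 1, tolerance = 1e-10)
  # loadings orthonormal
  ltl <- crossprod(m$rotation)
  expect_lt(max(abs(ltl - diag(2))), 1e-8)
})

test_that("explained variance matches the covariance eigendecomposition", {
  set.seed(2)
  x <- matrix(rnorm(60 * 8), 60, 8) %*% diag(c(4, 3, 2, 1, 1, .5, .5, .2))
  colnames(x) <- paste0("f", 1:8)
  wells <- dplyr::bind_cols(
    tibble::tibble(cell_line = "L", plate = "P", well = sprintf("W%02d", 1:60),
                   compound = "c", concentration = 1, role = "treatment"),
    tibble::as_tibble(x))
  m <- fit_pca(wells, n_components = 5)
  ev <- eigen(stats::cov(x), symmetric = TRUE)$values
  expect_equal(m$explained, ev / sum(ev), tolerance = 1e-8)
})

test_that("rank-deficient data reduces the component count with a warning", {
  x <- matrix(rnorm(30 * 2), 30, 2)
  x <- cbind(x, x[, 1] + x[, 2], x[, 1] - x[, 2])
  colnames(x) <- paste0("f", 1:4)
  wells <- dplyr::bind_cols(
    tibble::tibble(cell_line = "L", plate = "P", well = sprintf("W%02d", 1:30),
                   compound = "c", concentration = 1, role = "treatment"),
    tibble::as_tibble(x))
  expect_warning(m <- fit_pca(wells, n_components = 4), "rank")
  expect_equal(m$n_components, 2)
})

test_that("squared Mahalanobis distance reproduces closed-form examples", {
  ref2 <- structure(list(mu = c(0, 0), sigma = diag(2), n_dmso = 100,
                         n_components = 2), class = "dmso_reference")
  expect_equal(mahalanobis_to_dmso(matrix(c(3, 4), 1), ref2), 25)
  expect_equal(mahalanobis_to_dmso(matrix(c(3, 4), 1), ref2,
                                   squared = FALSE), 5)
  ref1 <- structure(list(mu = 1, sigma = matrix(4), n_dmso = 100,
                         n_components = 1), class = "dmso_reference")
  expect_equal(mahalanobis_to_dmso(matrix(5), ref1), 4)
  expect_equal(mahalanobis_to_dmso(matrix(1), ref1), 0)  # zero iff x == mu
})

test_that("triangular-solve distances equal the explicit-inverse oracle", {
  set.seed(3)
  for (p in c(5, 9, 15)) {
    sigma <- random_spd(p)
    mu <- rnorm(p)
    x <- matrix(rnorm(40 * p), 40, p)
    ref <- structure(list(mu = mu, sigma = sigma, n_dmso = 100,
                          n_components = p), class = "dmso_reference")
    ours <- mahalanobis_to_dmso(x, ref)
    oracle <- stats::mahalanobis(x, mu, sigma)   # explicit solve route
    expect_equal(ours, unname(oracle), tolerance = 1e-8)
  }
})

test_that("distances are invariant under joint invertible affine maps", {
  set.seed(4)
  p <- 6
  sigma <- random_spd(p); mu <- rnorm(p)
  x <- matrix(rnorm(30 * p), 30, p)
  ref <- structure(list(mu = mu, sigma = sigma, n_dmso = 50,
                        n_components = p), class = "dmso_reference")
  d0 <- mahalanobis_to_dmso(x, ref)
  a <- matrix(rnorm(p * p), p); while (abs(det(a)) < 1e-3)
    a <- matrix(rnorm(p * p), p)
  b <- rnorm(p)
  xt <- sweep(x %*% t(a), 2, b, "+")
  reft <- structure(list(mu = as.numeric(a %*% mu + b),
                         sigma = a %*% sigma %*% t(a), n_dmso = 50,
                         n_components = p), class = "dmso_reference")
  expect_equal(mahalanobis_to_dmso(xt, reft), d0, tolerance = 1e-6)
})

test_that("singular covariance errors and shrinkage repairs it", {
  scores <- tibble::tibble(role = "vehicle_control",
                           PC1 = rnorm(30), PC2 = rnorm(30))
  scores$PC3 <- scores$PC1 + scores$PC2   # rank 2 in 3 dims
  ref <- dmso_reference(scores)
  expect_error(mahalanobis_to_dmso(as.matrix(scores[, c("PC1", "PC2", "PC3")]),
                                   ref), "singular")
  ref_lw <- dmso_reference(scores, shrinkage = "lw")
  d <- mahalanobis_to_dmso(as.matrix(scores[, c("PC1", "PC2", "PC3")]), ref_lw)
  expect_true(all(is.finite(d)) && all(d >= 0))
  expect_error(dmso_reference(scores[1:3, ]), "DMSO wells")
})

test_that("threshold calibration methods sit in the right order", {
  ref <- structure(list(mu = rep(0, 15), sigma = diag(15), n_dmso = 80,
                        n_components = 15), class = "dmso_reference")
  chisq <- calibrate_distance_threshold(ref, "chisq", alpha = 0.001)
  expect_equal(chisq, qchisq(0.999, 15))
  f <- calibrate_distance_threshold(ref, "f", alpha = 0.001)
  expect_gt(f, chisq)   # finite-n null has the heavier tail
  emp <- calibrate_distance_threshold(ref, "empirical", alpha = 0.01,
                                      dmso_distances = 1:100)
  expect_equal(emp, quantile(1:100, 0.99, names = FALSE))
})

test_that("phenotypic hit and selectivity rules, including the strict boundary", {
  eac <- paste0("E", 1:6); ctrl <- c("C1", "C2")
  d <- tibble::tibble(
    compound = rep(c("at_thr", "sel2", "sel3ctrl", "incomplete"),
                   times = c(8, 8, 8, 7)),
    cell_line = c(rep(c(eac, ctrl), 3), c(eac, "C1")),
    distance = c(rep(1500, 8),                       # exactly at threshold
                 c(2000, 1600, 10, 10, 10, 10, 10, 10),  # 2 EAC, no ctrl
                 c(2000, 1600, 1700, 10, 10, 10, 2000, 10),  # 3 EAC + C1
                 rep(2000, 7)))
  h <- call_phenotypic_hits(d, eac, ctrl, threshold = 1500,
                            min_eac_lines = 2)
  bc <- h$by_compound
  expect_false(any(h$by_line$hit[h$by_line$compound == "at_thr"]))
  expect_true(bc$selective[bc$compound == "sel2"])
  expect_false(bc$selective[bc$compound == "sel3ctrl"])
  expect_equal(h$incomplete, "incomplete")
  expect_false(bc$selective[bc$compound == "incomplete"])
})

test_that("per-line calibrated thresholds are honoured", {
  eac <- c("E1", "E2"); ctrl <- "C1"
  d <- tibble::tibble(compound = "x", cell_line = c("E1", "E2", "C1"),
                      distance = c(50, 50, 50))
  thr <- c(E1 = 40, E2 = 40, C1 = 60)
  h <- call_phenotypic_hits(d, eac, ctrl, threshold = thr, min_eac_lines = 2)
  expect_true(h$by_compound$selective)
  expect_error(call_phenotypic_hits(d, eac, ctrl, threshold = c(E1 = 40)),
               "C1")
})

test_that("z-scores match their definition and a per-well loop oracle", {
  pm <- tibble::tibble(plate = "P1", well = sprintf("A%02d", 1:10),
                       compound = c(rep("DMSO", 4), "c1", "c1", "c2", "c2",
                                    "c3", "c3"),
                       concentration = c(rep(0, 4), rep(10, 6)),
                       role = c(rep("vehicle_control", 4),
                                rep("treatment", 6)))
  counts <- tibble::tibble(cell_line = "L1", plate = "P1",
                           well = sprintf("A%02d", 1:10),
                           n_nuclei = c(90, 100, 100, 110, 70, 80, 100, 120,
                                        40, 60))
  z <- compute_zscores(counts, pm)
  dm <- mean(c(90, 100, 100, 110)); ds <- sd(c(90, 100, 100, 110))
  # per-well loop oracle
  for (i in 1:10) {
    expect_equal(z$per_well$z[z$per_well$well == sprintf("A%02d", i)],
                 (counts$n_nuclei[i] - dm) / ds)
  }
  pc <- z$per_compound
  expect_equal(pc$z[pc$compound == "c1"],
               median(((c(70, 80)) - dm) / ds))
  # count equal to the DMSO mean scores zero
  expect_equal(z$per_well$z[z$per_well$n_nuclei == dm][1], 0)

  flat <- counts; flat$n_nuclei[1:4] <- 100
  expect_error(compute_zscores(flat, pm), "SD is 0")
})

test_that("textbook z-score example: mean 100, SD 10, count 70 gives -3", {
  pm <- tibble::tibble(plate = "P1", well = c("A01", "A02", "A03", "A04"),
                       compound = c("DMSO", "DMSO", "DMSO", "c1"),
                       concentration = c(0, 0, 0, 10),
                       role = c(rep("vehicle_control", 3), "treatment"))
  counts <- tibble::tibble(cell_line = "L1", plate = "P1",
                           well = c("A01", "A02", "A03", "A04"),
                           n_nuclei = c(90, 100, 110, 70))
  z <- compute_zscores(counts, pm)
  expect_equal(mean(c(90, 100, 110)), 100)
  expect_equal(sd(c(90, 100, 110)), 10)
  expect_equal(z$per_compound$z[z$per_compound$compound == "c1"], -3)
})

test_that("viability selectivity margin rule matches its worked example", {
  eac <- paste0("E", 1:6); ctrl <- c("C1", "C2")
  mk <- function(ze, zc1, zc2 = -10) {
    tibble::tibble(compound = "x",
                   cell_line = c("E1", eac[-1], ctrl),
                   z = c(ze, rep(0, 5), zc1, zc2))
  }
  # boundary: EAC -3, control -1 qualifies (inclusive on both rules)
  h <- call_viability_hits(mk(-3, -1), eac, ctrl, min_eac_lines = 1)
  expect_true(h$by_compound$selective)
  h2 <- call_viability_hits(mk(-3, -1.01), eac, ctrl, min_eac_lines = 1)
  expect_false(h2$by_compound$selective)
  # margin 1.5 < 2 in both controls: does not qualify
  h3 <- call_viability_hits(mk(-4, -2.5, -2.5), eac, ctrl, min_eac_lines = 1)
  expect_false(h3$by_compound$selective)
  # z = -2.9 is not a hit at all
  h4 <- call_viability_hits(mk(-2.9, 5, 5), eac, ctrl, min_eac_lines = 1)
  expect_false(any(h4$by_line$hit[h4$by_line$compound == "x" &
                                    h4$by_line$cell_line == "E1"]))
  # one qualifying control suffices
  h5 <- call_viability_hits(mk(-5, 0, -10), eac, ctrl, min_eac_lines = 1)
  expect_true(h5$by_compound$selective)
})

test_that("viability selectivity needs min_eac_lines qualifying lines", {
  eac <- paste0("E", 1:6); ctrl <- c("C1", "C2")
  z <- tibble::tibble(compound = "x", cell_line = c(eac, ctrl),
                      z = c(-5, -4, 0, 0, 0, 0, 0, 0))
  expect_true(call_viability_hits(z, eac, ctrl)$by_compound$selective)
  z2 <- z; z2$z[2] <- 0
  expect_false(call_viability_hits(z2, eac, ctrl)$by_compound$selective)
  # missing control line excludes the compound
  z3 <- z[z$cell_line != "C2", ]
  h <- call_viability_hits(z3, eac, ctrl)
  expect_equal(h$incomplete, "x")
  expect_false(h$by_compound$selective)
})

test_that("hit-set union arithmetic and provenance flags", {
  ab <- combine_hits(paste0("p", 1:5), c(paste0("p", 1:2), "v1"))
  expect_equal(nrow(ab), 6)
  expect_equal(sum(ab$source == "both"), 2)
  expect_equal(sum(ab$source == "viability_only"), 1)
  expect_equal(nrow(combine_hits(c("a", "b"), c("c", "d", "e"))), 5)
  expect_equal(nrow(combine_hits(c("a", "b"), c("a", "b"))), 2)
  sizes <- attr(combine_hits(paste0("x", 1:4), character(0)), "sizes")
  expect_equal(unname(sizes["n_union"]), 4)
})
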