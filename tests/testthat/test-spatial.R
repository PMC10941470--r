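write_layer_csv <- function(df) {
  f <- tempfile(fileext = ".csv")
  utils::write.csv(df, f, row.names = FALSE, na = "")
  f
}

test_that("centroid layers load typed, with missing cells preserved", {
  f <- write_layer_csv(data.frame(
    centroid_id = paste0("c", 1:5), x = 1:5, y = 5:1,
    land = c("a", "b", "", "a", "b"), elev = c(10, 20, 30, NA, 50)))
  cl <- suppressMessages(load_centroid_layers(
    f, c(land = "categorical", elev = "numeric")))
  expect_equal(nrow(cl), 5)
  expect_true(is.na(cl$land[3]))
  expect_true(is.na(cl$elev[4]))
  expect_type(cl$elev, "double")

  f2 <- write_layer_csv(data.frame(centroid_id = "c1", x = 1, y = 1, elev = "high"))
  expect_error(load_centroid_layers(f2, c(elev = "numeric")),
               "declared numeric but row 1")
  expect_error(load_centroid_layers(f, c(ghost = "numeric")), "missing column")
})

test_that("a generated grid reloads with the generator's missing counts", {
  cfg <- synthetic_config(seed = 113, n_centroids = 5800)
  sim <- simulate_tree_nomenclature(cfg)
  grid <- simulate_covariate_grid(cfg, sim$truth)
  f <- write_layer_csv(as.data.frame(unclass(grid)))
  cl <- load_centroid_layers(f, c(truth = "categorical",
                                  degraded = "categorical",
                                  gradient = "numeric"))
  expect_equal(nrow(cl), 5800)
  expect_equal(sum(is.na(cl$truth)), 0)
  expect_equal(cl$gradient, grid$gradient, tolerance = 1e-9)
})

test_that("point-in-polygon labeling handles a checkerboard analytically", {
  # 2x2 checkerboard of unit squares, labels by cell
  square <- function(x0, y0) {
    list(list(list(x0, y0), list(x0 + 1, y0), list(x0 + 1, y0 + 1),
              list(x0, y0 + 1), list(x0, y0)))
  }
  features <- list()
  for (cx in 0:1) for (cy in 0:1) {
    features[[length(features) + 1L]] <- list(
      type = "Feature",
      properties = list(label = paste0("cell", cx, cy)),
      geometry = list(type = "Polygon", coordinates = square(cx, cy)))
  }
  gj <- tempfile(fileext = ".geojson")
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       gj, auto_unbox = TRUE, digits = NA)
  set.seed(127)
  n <- 200
  x <- runif(n, 0.01, 1.99); y <- runif(n, 0.01, 1.99)
  x <- x[abs(x - 1) > 1e-3]; y <- y[abs(y - 1) > 1e-3]
  n <- min(length(x), length(y)); x <- x[1:n]; y <- y[1:n]
  pts <- centroid_layers(paste0("p", 1:n), x, y)
  labs <- assign_points_to_polygons(pts, gj, "label")
  expect_equal(labs, paste0("cell", floor(x), floor(y)))

  outside <- centroid_layers("far", 10, 10)
  expect_true(is.na(assign_points_to_polygons(outside, gj, "label")))
  expect_error(assign_points_to_polygons(pts, gj, "nope"), "lacks property")
})

test_that("contingency counts pairwise-complete centroids only", {
  A <- c("x", "x", "y", "y", NA, "x")
  B <- c("p", "p", "q", NA, "q", "p")
  tab <- contingency(A, B)
  expect_equal(attr(tab, "N"), 4)
  expect_equal(unname(tab["x", "p"]), 3)
  expect_equal(unname(tab["y", "q"]), 1)
  # marginals match per-layer class counts on the complete subset
  keep <- !is.na(A) & !is.na(B)
  expect_equal(as.vector(rowSums(tab)), as.vector(table(A[keep])))
  expect_equal(as.vector(colSums(tab)), as.vector(table(B[keep])))
  expect_error(contingency(c(NA, "a"), c("b", NA)), "no pairwise-complete")
  expect_error(contingency(c("a", "b"), "c"), "share the centroid roster")

  ident <- contingency(c(1, 1, 2, 2), c(1, 1, 2, 2))
  expect_true(all(ident[row(ident) != col(ident)] == 0))
})

test_that("v-measure reproduces the frozen worked example and degenerate cases", {
  vm <- v_measure(contingency(c(1, 1, 2, 2), c(1, 1, 1, 2)))
  expect_equal(vm$h, 0.31127812445913283, tolerance = 1e-12)
  expect_equal(vm$c, 0.3836885465963443, tolerance = 1e-12)
  expect_equal(vm$v, 0.34371101848545077, tolerance = 1e-12)

  ident <- v_measure(contingency(c(1, 2, 1, 2), c("a", "b", "a", "b")))
  expect_equal(c(ident$h, ident$c, ident$v), c(1, 1, 1))

  # one cluster vs two equally sized classes
  degen <- v_measure(contingency(c(1, 1, 2, 2), rep("k", 4)))
  expect_equal(degen$h, 0)
  expect_equal(degen$c, 1)
  expect_equal(degen$v, 0)
})

test_that("v-measure matches the mutual-information oracle on random pairs", {
  set.seed(131)
  for (i in 1:200) {
    n <- sample(5:50, 1)
    C <- sample(seq_len(sample(2:5, 1)), n, replace = TRUE)
    K <- sample(seq_len(sample(2:5, 1)), n, replace = TRUE)
    vm <- v_measure(contingency(C, K))
    oracle <- oracle_vmeasure(C, K)
    expect_equal(vm$h, oracle$h, tolerance = 1e-12)
    expect_equal(vm$c, oracle$c, tolerance = 1e-12)
    expect_equal(vm$v, oracle$v, tolerance = 1e-12)
    # swapping layers swaps h and c, leaves v unchanged
    sw <- v_measure(contingency(K, C))
    expect_equal(sw$h, vm$c, tolerance = 1e-12)
    expect_equal(sw$c, vm$h, tolerance = 1e-12)
    expect_equal(sw$v, vm$v, tolerance = 1e-12)
  }
})

test_that("v-measure agrees with the scikit-learn reference implementation", {
  set.seed(137)
  pairs <- lapply(1:20, function(i) {
    n <- sample(8:40, 1)
    list(C = sample(1:3, n, replace = TRUE), K = sample(1:4, n, replace = TRUE))
  })
  ref <- sklearn_vmeasure(pairs)
  for (i in seq_along(pairs)) {
    vm <- v_measure(contingency(pairs[[i]]$C, pairs[[i]]$K))
    expect_equal(vm$h, ref$h[ref$pair == i], tolerance = 1e-9)
    expect_equal(vm$c, ref$c[ref$pair == i], tolerance = 1e-9)
    expect_equal(vm$v, ref$v[ref$pair == i], tolerance = 1e-9)
  }
})

test_that("v-measure is invariant to label permutation", {
  set.seed(139)
  C <- sample(1:3, 40, replace = TRUE)
  K <- sample(1:4, 40, replace = TRUE)
  vm <- v_measure(contingency(C, K))
  permC <- c(3, 1, 2)[C]
  permK <- c("d", "c", "b", "a")[K]
  vm2 <- v_measure(contingency(permC, permK))
  expect_equal(vm[c("h", "c", "v")], vm2[c("h", "c", "v")], tolerance = 1e-14)
})

test_that("quantile discretization yields near-equal bins; degenerate input errors", {
  f <- suppressMessages(discretize(1:10, 2))
  expect_equal(as.vector(table(f)), c(5, 5))
  expect_equal(as.vector(tapply(1:10, f, max)), c(5, 10))

  expect_error(suppressMessages(discretize(rep(1, 10), 2)), "distinct values")
  expect_error(suppressMessages(discretize(1:10, 1)), "n_bins")

  set.seed(149)
  for (i in 1:10) {
    n <- sample(20:60, 1); b <- sample(2:5, 1)
    x <- sample(seq(0, 1, length.out = 1000), n)
    f <- suppressMessages(discretize(x, b))
    sizes <- as.vector(table(f))
    expect_equal(length(sizes), b)
    expect_lte(max(sizes) - min(sizes), 1)
  }
  # missing propagates; user breakpoints respected
  f2 <- suppressMessages(discretize(c(1, NA, 10), breaks = c(0, 5, 10)))
  expect_true(is.na(f2[2]))
  expect_equal(as.integer(f2[c(1, 3)]), c(1L, 2L))
})

test_that("q follows the hand-derived ANOVA decomposition", {
  fd <- factor_detector_q(c(1, 2, 3, 4), c("A", "A", "B", "B"),
                          significance = "ncf")
  expect_equal(fd$sigma2, 1.25)
  expect_equal(sum(fd$strata$N_h * fd$strata$var_h), 1.0)
  expect_equal(fd$q, 0.8, tolerance = 1e-14)
  expect_equal(fd$L, 2)

  # single stratum: worst score
  fd0 <- factor_detector_q(c(1, 5, 2, 4), rep("A", 4), significance = "ncf")
  expect_equal(fd0$q, 0)
  # zero within-stratum variance: best score
  fd1 <- factor_detector_q(c(2, 2, 7, 7), c("A", "A", "B", "B"),
                           significance = "ncf")
  expect_equal(fd1$q, 1)
  expect_error(factor_detector_q(rep(3, 6), rep(c("A", "B"), 3),
                                 significance = "ncf"), "constant")
})

test_that("q equals 1 - SSW/SST from the independent ANOVA oracle", {
  set.seed(151)
  for (i in 1:200) {
    n <- sample(10:80, 1)
    L <- sample(2:6, 1)
    strata <- factor(sample(letters[1:L], n, replace = TRUE))
    while (nlevels(droplevels(strata)) < 2) {
      strata <- factor(sample(letters[1:L], n, replace = TRUE))
    }
    y <- rnorm(n) + as.integer(strata) * runif(1, 0, 2)
    fd <- factor_detector_q(y, strata, significance = "ncf")
    expect_equal(fd$q, oracle_q(y, strata), tolerance = 1e-12)
    expect_true(fd$q >= 0 && fd$q <= 1)
    # affine invariance of q
    fd2 <- factor_detector_q(3.7 * y - 11, strata, significance = "ncf")
    expect_equal(fd2$q, fd$q, tolerance = 1e-9)
  }
})

test_that("refining strata never decreases q", {
  set.seed(157)
  for (i in 1:20) {
    n <- 60
    strata <- sample(letters[1:3], n, replace = TRUE)
    y <- rnorm(n) + match(strata, letters)
    refined <- strata
    inA <- refined == "a"
    refined[inA] <- sample(c("a1", "a2"), sum(inA), replace = TRUE)
    if (length(unique(refined)) < 4) next
    q0 <- factor_detector_q(y, strata, significance = "ncf")$q
    q1 <- factor_detector_q(y, refined, significance = "ncf")$q
    expect_gte(q1, q0 - 1e-12)
  }
})

test_that("q permutation p-values are seeded and sane for signal and null", {
  set.seed(163)
  strata <- rep(c("A", "B"), each = 30)
  y_signal <- rnorm(60) + (strata == "B") * 3
  fd <- factor_detector_q(y_signal, strata, n_perm = 199, seed = 31)
  fd_again <- factor_detector_q(y_signal, strata, n_perm = 199, seed = 31)
  expect_identical(fd$p_value, fd_again$p_value)
  expect_lte(fd$p_value, 0.01)
  expect_error(factor_detector_q(y_signal, strata, n_perm = 99), "seed required")

  # the noncentral-F route estimates its noncentrality from the observed
  # stratum means, so it is deliberately conservative; only bounds are asserted
  p_ncf <- factor_detector_q(y_signal, strata, significance = "ncf")$p_value
  expect_true(p_ncf > 0 && p_ncf < 1)
  expect_lt(fd$p_value, p_ncf)
})

test_that("batch association has the expected shape and self-association", {
  set.seed(167)
  n <- 120
  part2 <- sample(paste0("g", 1:2), n, replace = TRUE)
  part3 <- sample(paste0("g", 1:3), n, replace = TRUE)
  theme <- sample(c("wet", "dry"), n, replace = TRUE)
  elev <- rnorm(n)
  rep_ <- batch_association(
    partitions = list(K2 = part2, K3 = part3),
    thematic = list(theme = theme, self = part2),
    covariates = list(elev = elev),
    n_perm = 99, seed = 3)
  expect_equal(nrow(rep_), 6)
  expect_equal(sum(rep_$kind == "categorical"), 4)
  expect_equal(rep_$v[rep_$partition == "K2" & rep_$layer == "self"], 1)
  expect_true(all(is.na(rep_$q[rep_$kind == "categorical"])))
  expect_true(all(rep_$N == n))
})

test_that("planted association strengths order the batch report", {
  cfg <- synthetic_config(seed = 173, n_units = 20, n_species = 80,
                          n_centroids = 2000, relabel_frac = 0.3,
                          q_target = 0.7)
  sim <- simulate_tree_nomenclature(cfg)
  grid <- simulate_covariate_grid(cfg, sim$truth)
  part <- paste0("g", sim$truth[grid$unit])
  rep_ <- batch_association(
    partitions = list(truthK = part),
    thematic = list(truth = grid$truth, degraded = grid$degraded),
    covariates = list(gradient = grid$gradient),
    n_perm = 99, seed = 7)
  v_truth <- rep_$v[rep_$layer == "truth"]
  v_degr <- rep_$v[rep_$layer == "degraded"]
  expect_equal(v_truth, 1)
  expect_lt(v_degr, v_truth)
  expect_gt(rep_$q[rep_$layer == "gradient"], 0.5)
})
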