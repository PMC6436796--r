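test_that("the method ladder is total and maps counts to methods", {
  expect_error(select_method(0), "at least one")
  expect_equal(select_method(1), "buffer")
  expect_equal(select_method(2), "buffer")
  expect_equal(select_method(3), "hull")
  expect_equal(select_method(4), "hull")
  expect_equal(select_method(5), "bioclim")
  expect_equal(select_method(9), "bioclim")
  expect_equal(select_method(10), "maxent_like")
  expect_equal(select_method(5000), "maxent_like")
})

test_that("thinning enforces the minimum distance and keeps sparse sets whole", {
  # two points ~0.55 km apart, 1 km threshold: one survives
  kept <- thin_points(c(-74, -74.005), c(4, 4), 1)
  expect_equal(length(kept), 1)
  # collinear points ~2.2 km apart, 1 km threshold: all survive
  lon5 <- -74 + 0.02 * (0:4)
  kept5 <- thin_points(lon5, rep(4, 5), 1)
  expect_equal(kept5, 1:5)
  expect_equal(thin_points(-74, 4, 10), 1L)
})

test_that("greedy thinning beats a naive sequential scan and respects distance", {
  withr::with_seed(31, {
    lon <- -74 + runif(30, 0, 0.2)
    lat <- 4 + runif(30, 0, 0.2)
  })
  thr <- 5
  kept <- thin_points(lon, lat, thr, seed = 5)
  d <- dist_km(cbind(lon, lat)[kept, ])
  expect_true(all(d[upper.tri(d)] >= thr))
  # naive oracle: walk the points in order, keep any far enough from kept
  dall <- dist_km(cbind(lon, lat))
  naive <- c(1L)
  for (i in 2:30) if (all(dall[i, naive] >= thr)) naive <- c(naive, i)
  expect_gte(length(kept), length(naive))
  expect_equal(kept, thin_points(lon, lat, thr, seed = 5))  # deterministic
})

test_that("random background is uniform over the accessible area", {
  stack <- make_landscape(5, size = 40)
  pvals <- vapply(1:3, function(s) {
    bg <- sample_background(stack, M = NULL, n = 1000, seed = s)
    qx <- bg$lon > (stack$grid$xmin + raster_xmax(stack$grid)) / 2
    qy <- bg$lat > (stack$grid$ymin + raster_ymax(stack$grid)) / 2
    counts <- table(factor(qx, c(FALSE, TRUE)), factor(qy, c(FALSE, TRUE)))
    stats::chisq.test(as.vector(counts))$p.value
  }, 0)
  expect_true(all(pvals > 0.001))
  # without replacement: all points distinct cells
  bg <- sample_background(stack, n = 1000, seed = 1)
  expect_equal(nrow(unique(bg)), 1000)
})

test_that("bias surfaces and target groups drive background selection", {
  stack <- make_landscape(6, size = 30)
  bias <- raster_like(stack$grid, 0)
  bias$values[, 1:15] <- 1            # western half only
  mid <- stack$grid$xmin + 15 * stack$grid$cellsize
  bg <- sample_background(stack, n = 300, mode = "bias_surface",
                          bias_raster = bias, seed = 2)
  expect_true(all(bg$lon < mid))
  tg <- data.frame(lon = rep(-74.9, 37) + 0.001 * (1:37),
                   lat = rep(0.05, 37))
  got <- sample_background(stack, mode = "target_group", target_group = tg)
  expect_equal(nrow(got), 37)
  expect_equal(got$lon, tg$lon)
  bias0 <- raster_like(stack$grid, 0)
  expect_error(sample_background(stack, mode = "bias_surface",
                                 bias_raster = bias0, seed = 1),
               "zero everywhere")
  expect_warning(sample_background(stack, n = 10000, seed = 1), "capped")
})

test_that("envelope suitability is 1 at the median and 0 beyond the extremes", {
  withr::with_seed(41, {
    env <- data.frame(a = rnorm(21), b = runif(21))
  })
  m <- fit_bioclim(env)
  med <- data.frame(a = median(env$a), b = median(env$b))
  expect_equal(predict(m, med), 1)
  beyond <- data.frame(a = max(env$a) + 1, b = median(env$b))
  expect_equal(predict(m, beyond), 0)
  # constant variable: ignored with a warning, scores 1 everywhere
  env$c <- 7
  expect_warning(m2 <- fit_bioclim(env), "constant")
  expect_equal(predict(m2, data.frame(a = median(env$a), b = median(env$b),
                                      c = -99)), 1)
})

test_that("envelope surface matches a per-cell percentile oracle", {
  stack <- make_landscape(8, size = 30)
  withr::with_seed(42, {
    idx <- sample(sum(stack$mask), 20)
  })
  cells <- which(stack$mask)[idx]
  rc <- arrayInd(cells, dim(stack$mask))
  ctr <- xy_from_cell(stack$grid, rc[, 1], rc[, 2])
  pres_env <- stack_extract(stack, ctr[, 1], ctr[, 2])[c("env1", "env2")]
  m <- fit_bioclim(pres_env)
  env_all <- data.frame(env1 = as.vector(stack$layers$env1$values),
                        env2 = as.vector(stack$layers$env2$values))
  got <- predict(m, env_all)
  # independent oracle: direct percentile score per cell and variable
  oracle_score <- function(x, train) {
    FF <- (sum(train < x) + 0.5 * sum(train == x)) / length(train)
    2 * min(FF, 1 - FF)
  }
  expected <- vapply(seq_len(nrow(env_all)), function(i) {
    min(oracle_score(env_all$env1[i], pres_env$env1),
        oracle_score(env_all$env2[i], pres_env$env2))
  }, 0)
  expect_equal(got, expected)
})

test_that("the presence-background model recovers a monotone 1-variable response", {
  stack <- stack_subset(make_landscape(9, size = 40, n_vars = 1), "env1")
  v <- stack$layers$env1$values
  cells <- which(stack$mask & v > stats::quantile(v, 0.8))
  withr::with_seed(43, cells <- sample(cells, 60, replace = TRUE))
  rc <- arrayInd(cells, dim(v))
  ctr <- xy_from_cell(stack$grid, rc[, 1], rc[, 2])
  pres_env <- stack_extract(stack, ctr[, 1], ctr[, 2])
  bg <- sample_background(stack, n = 1500, seed = 3)
  bg_env <- stack_extract(stack, bg$lon, bg$lat)
  m <- fit_maxent_like(pres_env, bg_env, features = c("linear", "quadratic",
                                                      "hinge"))
  grid <- data.frame(env1 = seq(min(v), max(v), length.out = 200))
  s <- predict(m, grid)
  expect_gt(cor(grid$env1, s, method = "spearman"), 0.95)
  expect_true(all(s >= 0 & s <= 1))
})

test_that("very strong regularization shrinks the model to a constant", {
  withr::with_seed(44, {
    pres <- data.frame(env1 = rnorm(30, 1), env2 = rnorm(30, -1))
    bg <- data.frame(env1 = rnorm(500), env2 = rnorm(500))
  })
  m <- fit_maxent_like(pres, bg, reg_multiplier = 1e4)
  s <- predict(m, bg)
  expect_lt(diff(range(s)), 1e-6)
})

test_that("spatial blocks split points into balanced geographic folds", {
  p4 <- spatial_partition(c(-1, -1, 1, 1), c(-1, 1, -1, 1), k = 4)
  expect_equal(sort(as.vector(table(p4$folds))), c(1, 1, 1, 1))
  p8 <- spatial_partition(c(-1, -1, -1, -1, 1, 1, 1, 1) + 0.01 * (1:8),
                          c(-1, -1, 1, 1, -1, -1, 1, 1) + 0.01 * (1:8), k = 4)
  expect_true(all(table(p8$folds) == 2))
  withr::with_seed(45, {
    lon <- runif(101); lat <- runif(101)
  })
  p <- spatial_partition(lon, lat, k = 4)
  expect_true(all(p$folds %in% 1:4))
  expect_lte(diff(range(table(p$folds))), 2)
  # the assign() closure reproduces the training labels
  expect_equal(p$assign(lon, lat), p$folds)
  expect_error(spatial_partition(lon, lat, k = 3), "k must be")
})

test_that("AUC and omission match brute-force pair counting", {
  expect_equal(auc_score(c(1, 1, 1), c(0, 0)), 1)
  expect_equal(auc_score(rep(0.5, 10), rep(0.5, 40)), 0.5)
  withr::with_seed(46, {
    pres <- round(runif(20), 2)       # ties on purpose
    bg <- round(runif(100), 2)
  })
  expect_equal(auc_score(pres, bg), auc_oracle(pres, bg))
  expect_equal(omission_rate(c(0.1, 0.5, 0.9), 0.5), 1 / 3)
  expect_error(auc_score(numeric(), 1), "empty")
})

test_that("tuning selects by omission, then AUC, then parsimony", {
  full <- make_landscape(10, size = 40)
  sp <- make_species(full)
  stack <- stack_subset(full, c("env1", "env2"))
  withr::with_seed(47, {
    w <- as.vector(sp$true_suitability$values); w[is.na(w)] <- 0
    cells <- sample(length(w), 60, replace = FALSE, prob = w)
  })
  rc <- arrayInd(cells, dim(stack$mask))
  ctr <- xy_from_cell(stack$grid, rc[, 1], rc[, 2])
  pres <- data.frame(lon = ctr[, 1], lat = ctr[, 2])
  bg <- sample_background(stack, n = 800, seed = 4)
  g <- tune_grid(regularization_multipliers = c(1, 2),
                 feature_classes = list("linear",
                                        c("linear", "quadratic")))
  out <- suppressWarnings(tune_sdm(pres, bg, stack, g))
  expect_equal(nrow(out$results), 4)
  # selection rule recomputed independently from the table
  tab <- out$results
  best <- tab[order(tab$mean_test_omission10, -tab$mean_test_auc,
                    tab$reg_multiplier, tab$n_feature_classes), ][1, ]
  expect_equal(out$best$reg_multiplier, best$reg_multiplier)
  expect_equal(paste(out$best$features, collapse = "+"), best$features)
  # a single-combination grid returns that combination
  g1 <- tune_grid(regularization_multipliers = 2,
                  feature_classes = list(c("linear", "quadratic")))
  out1 <- suppressWarnings(tune_sdm(pres, bg, stack, g1))
  expect_equal(out1$best$reg_multiplier, 2)
  expect_equal(out1$best$features, c("linear", "quadratic"))
})

test_that("final fits produce nested binaries bounded in [0,1] for every ladder rung", {
  full <- make_landscape(12, size = 40)
  sp <- make_species(full)
  stack <- stack_subset(full, c("env1", "env2"))
  M <- accessible_area(raster_extent_poly(stack$grid))
  pick_presences <- function(n, seed) {
    withr::with_seed(seed, {
      w <- as.vector(sp$true_suitability$values); w[is.na(w)] <- 0
      cells <- sample(length(w), n, replace = FALSE, prob = w)
    })
    rc <- arrayInd(cells, dim(stack$mask))
    ctr <- xy_from_cell(stack$grid, rc[, 1], rc[, 2])
    data.frame(lon = ctr[, 1], lat = ctr[, 2])
  }
  # buffer rung
  fb <- fit_final(pick_presences(2, 1), stack, M = M)
  expect_equal(fb$method, "buffer")
  expect_null(fb$suitability)
  expect_named(fb$binaries, "0")
  # hull rung: binary equals the rasterized hull
  p4 <- pick_presences(4, 2)
  fh <- fit_final(p4, stack, M = M)
  expect_equal(fh$method, "hull")
  hull_bin <- rasterize_polygon(convex_hull(p4$lon, p4$lat), stack$grid)
  expect_equal(fh$binaries[["0"]]$values, hull_bin$values)
  # envelope rung
  p7 <- pick_presences(7, 3)
  fe <- suppressWarnings(fit_final(p7, stack, M = M))
  expect_equal(fe$method, "bioclim")
  s <- fe$suitability$values
  expect_true(all(s >= 0 & s <= 1, na.rm = TRUE))
  # minimum-training-presence binary contains every training presence cell
  expect_true(all(raster_extract(fe$binaries[["0"]], p7$lon, p7$lat) == 1))
  # presence-background rung with nesting across percentiles
  p30 <- pick_presences(30, 4)
  fm <- suppressWarnings(fit_final(p30, stack, M = M, n_background = 1000))
  expect_equal(fm$method, "maxent_like")
  for (pair in list(c("30", "20"), c("20", "10"), c("10", "0"))) {
    inner <- fm$binaries[[pair[1]]]$values
    outer <- fm$binaries[[pair[2]]]$values
    expect_true(all(outer[inner == 1] == 1, na.rm = TRUE))
  }
  # nodata consistency with the stack
  expect_equal(is.na(fm$suitability$values), !stack$mask)
})

test_that("collinear points at the hull rung fall back to the buffer method", {
  stack <- make_landscape(13, size = 30)
  M <- accessible_area(raster_extent_poly(stack$grid))
  pres <- data.frame(lon = -74.95 + c(0, 0.01, 0.02, 0.03), lat = rep(0.05, 4))
  expect_warning(f <- fit_final(pres, stack, M = M), "degenerate")
  expect_equal(f$method, "buffer")
})
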