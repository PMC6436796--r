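# The modeling ladder ---------------------------------------------------------
#
# Method choice is driven by the number of thinned occurrences:
#   1-2 -> 10-km point buffer; 3-4 -> convex hull; 5-9 -> climate envelope
#   (bioclim); >= 10 -> L1-regularized presence-background model
#   (maxent_like). n = 5 goes to the envelope: prefer the statistical model
#   when it is feasible.

#' Select the modeling method from the occurrence count
#'
#' @param n_occurrences Number of usable occurrence records (>= 1).
#' @return One of `"buffer"`, `"hull"`, `"bioclim"`, `"maxent_like"`.
#' @export
select_method <- function(n_occurrences) {
  stopifnot(length(n_occurrences) == 1, !is.na(n_occurrences))
  if (n_occurrences <= 0) stop("need at least one occurrence")
  if (n_occurrences <= 2) "buffer"
  else if (n_occurrences <= 4) "hull"
  else if (n_occurrences <= 9) "bioclim"
  else "maxent_like"
}

#' Spatial thinning of occurrence points
#'
#' Greedy thinning: while any retained pair is closer than
#' `min_distance_km`, drop the point with the most too-close neighbours
#' (ties broken by a seeded random draw). The survivors respect the minimum
#' pairwise distance and the greedy strategy keeps close to the maximum
#' number of points.
#'
#' @param lon,lat Point coordinates.
#' @param min_distance_km Minimum allowed pairwise distance, km. The
#'   threshold comes from the analyst's exploratory assessment of sampling
#'   density and spatial autocorrelation; there is no universal default.
#' @param seed Integer seed for tie-breaking.
#' @return Integer vector: indices of retained points.
#' @export
thin_points <- function(lon, lat, min_distance_km, seed = 1L) {
  stopifnot(min_distance_km > 0, length(lon) == length(lat), length(lon) >= 1)
  n <- length(lon)
  if (n == 1) return(1L)
  d <- dist_km(cbind(lon, lat))
  adj <- d < min_distance_km
  diag(adj) <- FALSE
  keep <- rep(TRUE, n)
  withr::with_seed(seed, {
    repeat {
      deg <- rowSums(adj[, keep, drop = FALSE]) * keep
      if (max(deg) == 0) break
      worst <- which(deg == max(deg))
      drop <- if (length(worst) > 1) sample(worst, 1) else worst
      keep[drop] <- FALSE
    }
  })
  which(keep)
}

# Background sampling ----------------------------------------------------------

#' Sample background points within the accessible area
#'
#' Draws the environmental background used by presence-background modeling.
#' Candidate locations are the centers of valid stack cells inside M.
#' Modes: `"random"` (uniform over candidate cells), `"bias_surface"`
#' (cell probability proportional to a bias raster), `"target_group"`
#' (returns the supplied target-group occurrences inside M, standing in for
#' survey effort). Sampling is without replacement; when fewer valid cells
#' than `n` exist the draw is capped with a warning unless
#' `allow_replacement = TRUE`, which returns exactly `n` by sampling cells
#' with replacement.
#'
#' @param stack An `env_stack`.
#' @param M An `accessible_area` or `geo_polygon` (or `NULL` for the whole
#'   valid grid).
#' @param n Number of background points (default 10000).
#' @param mode `"random"`, `"bias_surface"` or `"target_group"`.
#' @param bias_raster `sdm_raster` of relative sampling effort
#'   (`bias_surface` mode).
#' @param target_group Data.frame with `lon`, `lat` of target-group
#'   occurrences (`target_group` mode).
#' @param allow_replacement Permit with-replacement sampling to reach
#'   exactly `n`.
#' @param seed Integer seed.
#' @return Data.frame with `lon`, `lat` of background points.
#' @export
sample_background <- function(stack, M = NULL, n = 10000,
                              mode = c("random", "bias_surface",
                                       "target_group"),
                              bias_raster = NULL, target_group = NULL,
                              allow_replacement = FALSE, seed = 1L) {
  mode <- match.arg(mode)
  geom <- if (inherits(M, "accessible_area")) M$geometry else M
  valid <- stack$mask
  if (!is.null(geom)) {
    valid <- valid & raster_cells_in_polygon(stack$grid, geom)
  }
  cells <- which(valid)
  if (!length(cells)) stop("accessible area contains no valid cells")
  if (mode == "target_group") {
    if (is.null(target_group)) stop("target_group mode needs occurrences")
    keep <- rep(TRUE, nrow(target_group))
    if (!is.null(geom)) {
      keep <- point_in_polygon(geom, target_group$lon, target_group$lat)
    }
    env_ok <- !is.na(raster_extract(
      raster_create(ifelse(stack$mask, 1, NA_real_), stack$grid$xmin,
                    stack$grid$ymin, stack$grid$cellsize),
      target_group$lon, target_group$lat))
    return(target_group[keep & env_ok, c("lon", "lat"), drop = FALSE])
  }
  prob <- NULL
  if (mode == "bias_surface") {
    if (is.null(bias_raster)) stop("bias_surface mode needs a bias raster")
    if (!same_grid(bias_raster, stack$grid)) {
      stop("bias raster is not on the stack grid")
    }
    prob <- bias_raster$values[cells]
    prob[is.na(prob)] <- 0
    if (all(prob <= 0)) stop("bias raster is zero everywhere inside M")
  }
  n_draw <- n
  replace <- FALSE
  if (length(cells) < n) {
    if (allow_replacement) {
      replace <- TRUE
    } else {
      warning(sprintf("only %d valid cells in M; background capped at that",
                      length(cells)))
      n_draw <- length(cells)
    }
  }
  chosen <- withr::with_seed(seed, {
    if (!replace && n_draw == length(cells) && is.null(prob)) cells
    else sample(cells, n_draw, replace = replace, prob = prob)
  })
  rc <- arrayInd(chosen, dim(valid))
  ctr <- xy_from_cell(stack$grid, rc[, 1], rc[, 2])
  data.frame(lon = ctr[, 1], lat = ctr[, 2])
}

# Climate envelope (bioclim) ---------------------------------------------------

#' Fit a climate-envelope model
#'
#' Classic percentile envelope: each variable's presence values define an
#' empirical distribution; a site's score on that variable is
#' `2 * min(F, 1 - F)` where `F` is the (tie-averaged) fraction of presence
#' values below the site's value — 1 at the presence median, falling to 0 at
#' and beyond the envelope limits. Site suitability is the minimum score
#' across variables. A variable constant across presences carries no
#' information and is ignored with a warning.
#'
#' @param presence_env Data.frame/matrix of environmental values at presence
#'   locations (>= 5 rows, complete cases).
#' @return An object of class `bioclim_model`.
#' @export
fit_bioclim <- function(presence_env) {
  presence_env <- as.data.frame(presence_env)
  stopifnot(nrow(presence_env) >= 5)
  if (anyNA(presence_env)) stop("presence records with incomplete environmental values")
  const <- vapply(presence_env, function(v) diff(range(v)) == 0, FALSE)
  if (any(const)) {
    warning("degenerate envelope: constant variable(s) ignored: ",
            paste(names(presence_env)[const], collapse = ", "))
  }
  structure(list(train = presence_env, active = names(presence_env)[!const]),
            class = "bioclim_model")
}

#' Predict suitability from a climate-envelope model
#' @param object A `bioclim_model`.
#' @param newdata Data.frame of environmental values with the training
#'   variables.
#' @param ... Unused.
#' @return Numeric suitability in `[0, 1]` (`NA` where inputs are `NA`).
#' @export
predict.bioclim_model <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  if (!length(object$active)) return(rep(1, nrow(newdata)))
  scores <- vapply(object$active, function(v) {
    tr <- object$train[[v]]
    x <- newdata[[v]]
    Fx <- (vapply(x, function(xi) sum(tr < xi), 0) +
             0.5 * vapply(x, function(xi) sum(tr == xi), 0)) / length(tr)
    2 * pmin(Fx, 1 - Fx)
  }, numeric(nrow(newdata)))
  scores <- matrix(scores, nrow = nrow(newdata))
  out <- apply(scores, 1, min)
  out[!stats::complete.cases(newdata[object$active])] <- NA_real_
  out
}

# MaxEnt-style presence-background model ---------------------------------------

#' @noRd
feature_builder <- function(env, classes, n_hinge_knots = 50) {
  env <- as.data.frame(env)
  vars <- names(env)
  rng <- lapply(env, range, na.rm = TRUE)
  knots <- if ("hinge" %in% classes) {
    lapply(env, function(v) {
      qs <- unique(stats::quantile(v, probs = seq(0, 1,
                                                  length.out = n_hinge_knots),
                                   names = FALSE, type = 7))
      qs
    })
  } else NULL
  build <- function(newdata) {
    newdata <- as.data.frame(newdata)
    absent <- setdiff(vars, names(newdata))
    if (length(absent)) stop("newdata lacks training variable(s): ",
                             paste(absent, collapse = ", "))
    cols <- list(); cls <- character(); varof <- list()
    scale01 <- function(x, r) (x - r[1]) / max(r[2] - r[1], 1e-12)
    for (v in vars) {
      x <- scale01(newdata[[v]], rng[[v]])
      if ("linear" %in% classes) {
        cols[[paste0("l_", v)]] <- x
        cls <- c(cls, "linear"); varof <- c(varof, list(v))
      }
      if ("quadratic" %in% classes) {
        cols[[paste0("q_", v)]] <- x^2
        cls <- c(cls, "quadratic"); varof <- c(varof, list(v))
      }
      if ("hinge" %in% classes) {
        kk <- scale01(knots[[v]], rng[[v]])
        for (j in seq_along(kk)) {
          k <- kk[j]
          if (k < 1) {
            cols[[sprintf("hf_%s_%02d", v, j)]] <- pmax(0, x - k) / (1 - k)
            cls <- c(cls, "hinge"); varof <- c(varof, list(v))
          }
          if (k > 0) {
            cols[[sprintf("hr_%s_%02d", v, j)]] <- pmax(0, k - x) / k
            cls <- c(cls, "hinge"); varof <- c(varof, list(v))
          }
        }
      }
    }
    if ("product" %in% classes && length(vars) > 1) {
      for (a in seq_along(vars)) for (b in seq_len(a - 1)) {
        va <- scale01(newdata[[vars[a]]], rng[[vars[a]]])
        vb <- scale01(newdata[[vars[b]]], rng[[vars[b]]])
        cols[[paste0("p_", vars[b], "_", vars[a])]] <- va * vb
        cls <- c(cls, "product"); varof <- c(varof, list(vars[c(a, b)]))
      }
    }
    list(x = do.call(cbind, cols), classes = cls, varof = varof)
  }
  build
}

#' Fit the L1-regularized presence-background model
#'
#' A MaxEnt-style model: environmental variables are expanded into the
#' configured feature classes (linear, quadratic, product, and two-sided
#' hinge features with knots at presence-value quantiles), then an
#' L1-penalized logistic fit contrasts presences against heavily weighted
#' background points (the standard infinitely-weighted-background
#' equivalence). The penalty is scaled per feature class and multiplied by
#' `reg_multiplier`; suitability output uses the complementary log-log
#' transform of the exponential model, bounded in `[0, 1]`. Exact numerical
#' agreement with the Java MaxEnt program is a non-goal.
#'
#' @param presence_env,background_env Environmental values at presence /
#'   background locations (same columns).
#' @param features Feature classes, subset of
#'   `c("linear", "quadratic", "product", "hinge")`.
#' @param reg_multiplier Positive multiplier on the per-class penalty
#'   (default 1).
#' @param n_hinge_knots Hinge knots per variable (default 50).
#' @return An object of class `maxent_like_model` with coefficients,
#'   the feature builder, the normalizer and entropy of the fitted
#'   exponential distribution over the background.
#' @export
fit_maxent_like <- function(presence_env, background_env,
                            features = c("linear", "quadratic", "product",
                                         "hinge"),
                            reg_multiplier = 1, n_hinge_knots = 50) {
  features <- match.arg(features, several.ok = TRUE)
  presence_env <- as.data.frame(presence_env)
  background_env <- as.data.frame(background_env)
  stopifnot(nrow(presence_env) >= 10, identical(names(presence_env),
                                                names(background_env)))
  stopifnot(reg_multiplier > 0)
  build <- feature_builder(presence_env, features, n_hinge_knots)
  tr <- build(rbind(presence_env, background_env))
  p <- c(rep(1, nrow(presence_env)), rep(0, nrow(background_env)))
  # per-class base penalties, scaled by the multiplier
  base_reg <- c(linear = 0.05, quadratic = 0.1, product = 0.2, hinge = 0.5)
  reg <- base_reg[tr$classes] * reg_multiplier
  weights <- ifelse(p == 1, 1, 100)
  lambdas <- 10^seq(4, 0, length.out = 100) * mean(reg) *
    sum(p) / sum(weights)
  fit <- glmnet::glmnet(tr$x, p, family = "binomial", weights = weights,
                        standardize = FALSE, penalty.factor = reg,
                        lambda = lambdas)
  beta <- as.numeric(fit$beta[, ncol(fit$beta)])
  names(beta) <- colnames(tr$x)
  # exponential-model bookkeeping over the background
  xb <- tr$x[p == 0, , drop = FALSE]
  eta_b <- drop(xb %*% beta)
  logZ <- log(sum(exp(eta_b - max(eta_b)))) + max(eta_b)
  raw_b <- exp(eta_b - logZ)
  entropy <- -sum(raw_b * log(pmax(raw_b, 1e-300)))
  structure(list(beta = beta, build = build, logZ = logZ, entropy = entropy,
                 classes = tr$classes, varof = tr$varof,
                 features = features, reg_multiplier = reg_multiplier),
            class = "maxent_like_model")
}

#' Predict suitability from the presence-background model
#'
#' Returns the complementary log-log output,
#' `1 - exp(-exp(H) * raw(x))`, where `raw` is the normalized exponential
#' model and `H` its entropy over the background — the conventional
#' bounded-suitability scale.
#'
#' @param object A `maxent_like_model`.
#' @param newdata Data.frame of environmental values.
#' @param type `"cloglog"` (default) or `"raw"`.
#' @param ... Unused.
#' @return Numeric vector of suitabilities.
#' @export
predict.maxent_like_model <- function(object, newdata,
                                      type = c("cloglog", "raw"), ...) {
  type <- match.arg(type)
  ft <- object$build(newdata)
  eta <- drop(ft$x %*% object$beta)
  raw <- exp(eta - object$logZ)
  out <- if (type == "raw") raw else 1 - exp(-exp(object$entropy) * raw)
  out[!stats::complete.cases(as.data.frame(newdata))] <- NA_real_
  pmin(pmax(out, 0), 1)
}

#' Per-variable coefficient mass
#'
#' Sum of absolute fitted coefficients of the features involving each
#' variable (product features count towards both variables). A quick view
#' of which predictors carry the model.
#'
#' @param model A `maxent_like_model`.
#' @return Named numeric vector, one entry per variable.
#' @export
variable_contributions <- function(model) {
  vars <- unique(unlist(model$varof))
  out <- stats::setNames(numeric(length(vars)), vars)
  for (j in seq_along(model$beta)) {
    for (v in model$varof[[j]]) out[v] <- out[v] + abs(model$beta[j])
  }
  out
}

# Evaluation -------------------------------------------------------------------

#' Rank-based AUC and omission rates
#'
#' `auc_score` is the probability that a random presence outranks a random
#' background point (ties count one half): the Mann-Whitney statistic.
#' `omission_rate` is the fraction of presences scoring strictly below the
#' threshold.
#'
#' @param presence_scores,background_scores Numeric suitability scores.
#' @return `auc_score`: a number in `[0, 1]`.
#' @export
auc_score <- function(presence_scores, background_scores) {
  if (!length(presence_scores)) stop("empty presence score set")
  if (!length(background_scores)) stop("empty background score set")
  r <- rank(c(presence_scores, background_scores))
  np <- length(presence_scores)
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) /
    (np * length(background_scores))
}

#' @rdname auc_score
#' @param threshold Suitability threshold.
#' @export
omission_rate <- function(presence_scores, threshold) {
  if (!length(presence_scores)) stop("empty presence score set")
  mean(presence_scores < threshold)
}

#' Spatial block partition of points
#'
#' Geographic cross-validation folds by median splits: points are split at
#' the longitude median, then each half at its latitude median (`k = 4`), or
#' by the longitude split alone (`k = 2`). Splits are rank-based so fold
#' sizes differ by at most one when coordinates are distinct; heavy
#' coordinate duplication triggers a best-effort split with a warning.
#'
#' @param lon,lat Point coordinates (>= k points).
#' @param k Number of folds, 2 or 4.
#' @return An object of class `spatial_blocks`: integer `folds` plus an
#'   `assign(lon, lat)` function that places new points (e.g. background)
#'   into the same blocks.
#' @export
spatial_partition <- function(lon, lat, k = 4) {
  if (!k %in% c(2, 4)) stop("k must be 2 or 4 for the block method")
  n <- length(lon)
  if (n < k) stop("need at least k points")
  split_at <- function(v) {
    s <- sort(v)
    lo <- s[ceiling(length(v) / 2)]
    hi <- s[ceiling(length(v) / 2) + 1]
    if (lo == hi) {
      warning("duplicate coordinates prevent an equal split; best effort",
              call. = FALSE)
    }
    (lo + hi) / 2
  }
  tx <- split_at(lon)
  west <- lon <= tx
  if (k == 2) {
    folds <- ifelse(west, 1L, 2L)
    assign <- function(lon, lat) ifelse(lon <= tx, 1L, 2L)
  } else {
    ty_w <- split_at(lat[west]); ty_e <- split_at(lat[!west])
    folds <- ifelse(west, ifelse(lat <= ty_w, 1L, 2L),
                    ifelse(lat <= ty_e, 3L, 4L))
    assign <- function(lon, lat) {
      ifelse(lon <= tx, ifelse(lat <= ty_w, 1L, 2L),
             ifelse(lat <= ty_e, 3L, 4L))
    }
  }
  structure(list(folds = folds, assign = assign, k = k),
            class = "spatial_blocks")
}

# Tuning -----------------------------------------------------------------------

#' Tuning grid for the presence-background model
#'
#' @param regularization_multipliers Positive multipliers to try.
#' @param feature_classes List of feature-class subsets to try.
#' @param k_partitions Spatial folds (2 or 4; default 4).
#' @return A `tune_grid` list.
#' @export
tune_grid <- function(regularization_multipliers = c(0.5, 1, 2, 4),
                      feature_classes = list(c("linear", "quadratic"),
                                             c("linear", "quadratic",
                                               "hinge")),
                      k_partitions = 4) {
  stopifnot(length(regularization_multipliers) >= 1,
            all(regularization_multipliers > 0),
            length(feature_classes) >= 1, k_partitions >= 2)
  structure(list(regularization_multipliers = regularization_multipliers,
                 feature_classes = feature_classes,
                 k_partitions = k_partitions), class = "tune_grid")
}

#' Tune the presence-background model by spatial cross-validation
#'
#' For every settings combination, k-fold geographic cross-validation
#' (presence blocks from [spatial_partition()]) yields the mean test
#' omission at the 10th-percentile training threshold and the mean test
#' AUC. Background characterizes the available environment rather than
#' labeled outcomes, so every fold trains on the full background and test
#' AUC scores the held-out presences against the full background — the
#' convention of the standard presence-background evaluation packages. The
#' winner minimizes mean omission, breaking ties by higher mean AUC and
#' then by smaller regularization multiplier (and fewer feature classes).
#'
#' @param presences Data.frame with `lon`, `lat` of presences.
#' @param background Data.frame with `lon`, `lat` of background points.
#' @param stack An `env_stack`.
#' @param grid A [tune_grid()].
#' @return List with `best` (settings) and `results` (the full evaluation
#'   table, one row per combination).
#' @export
tune_sdm <- function(presences, background, stack, grid = tune_grid()) {
  blocks <- spatial_partition(presences$lon, presences$lat,
                              k = grid$k_partitions)
  pres_env <- stack_extract(stack, presences$lon, presences$lat)
  bg_env <- stack_extract(stack, background$lon, background$lat)
  combos <- expand.grid(rm = grid$regularization_multipliers,
                        fc = seq_along(grid$feature_classes))
  rows <- lapply(seq_len(nrow(combos)), function(ci) {
    rm <- combos$rm[ci]
    fc <- grid$feature_classes[[combos$fc[ci]]]
    om <- c(); au <- c()
    for (f in seq_len(grid$k_partitions)) {
      tr_p <- which(blocks$folds != f); te_p <- which(blocks$folds == f)
      if (!length(te_p) || length(tr_p) < 10) {
        warning(sprintf("fold %d skipped: too few presences", f),
                call. = FALSE)
        next
      }
      m <- fit_maxent_like(pres_env[tr_p, , drop = FALSE], bg_env,
                           features = fc, reg_multiplier = rm)
      s_trp <- predict(m, pres_env[tr_p, , drop = FALSE])
      thr <- percentile_threshold_value(s_trp, 10)
      s_tep <- predict(m, pres_env[te_p, , drop = FALSE])
      s_bg <- predict(m, bg_env)
      om <- c(om, omission_rate(s_tep, thr))
      au <- c(au, auc_score(s_tep, s_bg))
    }
    data.frame(reg_multiplier = rm,
               features = paste(fc, collapse = "+"),
               n_feature_classes = length(fc),
               mean_test_omission10 = mean(om),
               mean_test_auc = mean(au))
  })
  results <- do.call(rbind, rows)
  best_i <- select_best_settings(results)
  list(best = list(reg_multiplier = results$reg_multiplier[best_i],
                   features = strsplit(results$features[best_i],
                                       "+", fixed = TRUE)[[1]]),
       results = results)
}

#' @noRd
select_best_settings <- function(results) {
  order(results$mean_test_omission10, -results$mean_test_auc,
        results$reg_multiplier, results$n_feature_classes)[1]
}

# Final fit --------------------------------------------------------------------

#' @noRd
percentile_threshold_value <- function(train_scores, p) {
  n <- length(train_scores)
  allowed <- floor(p / 100 * n)
  cand <- sort(unique(train_scores))
  ok <- vapply(cand, function(t) sum(train_scores < t) <= allowed, FALSE)
  max(cand[ok])
}

#' Fit the final distribution model for a species
#'
#' Runs the method chosen by the occurrence-count ladder on the full
#' occurrence set and assembles the result: a continuous suitability raster
#' (envelope and presence-background methods), binary maps at the minimum
#' and 10th/20th/30th percentile training-presence thresholds, evaluation
#' statistics, and metadata (method, settings, seeds). Everything is
#' clipped to the accessible area M. Buffer and hull methods produce a
#' binary range directly (stored under percentile 0) and no continuous
#' layer; a degenerate hull (collinear points) falls back to the buffer
#' method with a warning.
#'
#' @param presences Data.frame with `lon`, `lat`.
#' @param stack An `env_stack`.
#' @param M An `accessible_area` (or `NULL`: buffer-derived default around
#'   the presences, 200 km).
#' @param background Data.frame of background points (sampled with
#'   [sample_background()] if `NULL` and needed).
#' @param method Ladder override; default [select_method()] on the
#'   presence count.
#' @param settings For `maxent_like`: list with `reg_multiplier` and
#'   `features`, e.g. the `best` element of [tune_sdm()].
#' @param buffer_km Radius for the buffer method (default 10).
#' @param n_background Background size when sampling internally.
#' @param seed Integer seed (background sampling).
#' @return An `sdm_result`.
#' @export
fit_final <- function(presences, stack, M = NULL, background = NULL,
                      method = NULL, settings = NULL, buffer_km = 10,
                      n_background = 10000, seed = 1L) {
  n <- nrow(presences)
  if (is.null(method)) method <- select_method(n)
  if (is.null(M)) {
    M <- accessible_area(lon = presences$lon, lat = presences$lat)
  }
  geom <- M$geometry
  res <- list(method = method, n_presences = n, seed = seed,
              settings = settings)

  if (method == "hull") {
    hull <- tryCatch(convex_hull(presences$lon, presences$lat),
                     error = function(e) NULL)
    if (is.null(hull)) {
      warning("degenerate hull geometry; falling back to buffer method")
      method <- res$method <- "buffer"
    }
  }
  if (method %in% c("buffer", "hull")) {
    shape <- if (method == "buffer") {
      buffer_points(presences$lon, presences$lat, buffer_km)
    } else hull
    bin <- rasterize_polygon(shape, stack$grid)
    bin <- mask_raster(bin, geometry = geom)
    bin$values[!stack$mask] <- NA_real_
    res$suitability <- NULL
    res$binaries <- list(`0` = bin)
    res$eval <- NULL
    return(structure(res, class = "sdm_result"))
  }

  pres_env <- stack_extract(stack, presences$lon, presences$lat)
  if (anyNA(pres_env)) stop("presences fall on nodata cells")
  if (method == "bioclim") {
    model <- fit_bioclim(pres_env)
  } else {
    if (is.null(background)) {
      background <- sample_background(stack, M, n = n_background, seed = seed)
    }
    bg_env <- stack_extract(stack, background$lon, background$lat)
    st <- if (is.null(settings)) list(reg_multiplier = 1,
                                      features = c("linear", "quadratic",
                                                   "product", "hinge"))
    else settings
    model <- fit_maxent_like(pres_env, bg_env, features = st$features,
                             reg_multiplier = st$reg_multiplier)
  }
  suit <- predict_raster(model, stack)
  suit <- mask_raster(suit, geometry = geom)
  res$model <- model
  res$suitability <- suit
  train_scores <- raster_extract(suit, presences$lon, presences$lat)
  res$binaries <- stats::setNames(lapply(c(0, 10, 20, 30), function(p) {
    threshold_at_percentile(suit, presences, p)$binary
  }), c("0", "10", "20", "30"))
  # spatial-block evaluation of the final method
  res$eval <- tryCatch({
    blocks <- spatial_partition(presences$lon, presences$lat, k = 4)
    if (is.null(background)) {
      background <- sample_background(stack, M, n = min(n_background, 2000),
                                      seed = seed)
    }
    s_b <- raster_extract(suit, background$lon, background$lat)
    folds_auc <- vapply(1:4, function(f) {
      te <- blocks$folds == f
      if (!any(te)) return(NA_real_)
      auc_score(train_scores[te], s_b[!is.na(s_b)])
    }, 0)
    list(fold_auc = folds_auc, mean_auc = mean(folds_auc, na.rm = TRUE),
         train_auc = auc_score(train_scores, s_b[!is.na(s_b)]))
  }, error = function(e) NULL)
  structure(res, class = "sdm_result")
}

#' @export
print.sdm_result <- function(x, ...) {
  cat(sprintf("<sdm_result> method %s, %d presences, binaries at [%s]\n",
              x$method, x$n_presences,
              paste(names(x$binaries), collapse = ", ")))
  if (!is.null(x$eval)) cat(sprintf("  mean spatial-block AUC %.3f\n",
                                    x$eval$mean_auc))
  invisible(x)
}

#' Predict a model over a whole stack
#' @param model A `bioclim_model` or `maxent_like_model`.
#' @param stack An `env_stack`.
#' @return An `sdm_raster` of suitability on the stack grid (nodata where
#'   the stack is nodata).
#' @export
predict_raster <- function(model, stack) {
  nr <- nrow(stack$mask); nc <- ncol(stack$mask)
  env <- as.data.frame(lapply(stack$layers, function(l) as.vector(l$values)))
  vals <- rep(NA_real_, nr * nc)
  ok <- as.vector(stack$mask)
  vals[ok] <- predict(model, env[ok, , drop = FALSE])
  raster_create(matrix(vals, nr, nc), stack$grid$xmin, stack$grid$ymin,
                stack$grid$cellsize, stack$grid$crs)
}
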