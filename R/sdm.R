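#' Species distribution modeling
#'
#' Distributions are estimated from presences and mask-drawn pseudo-absences
#' with a MaxEnt-style presence/background model: linear plus quadratic
#' features of the 26 predictors, standardized on background statistics and
#' fit by L1-regularized (lasso) logistic regression — the penalized-logistic
#' equivalent of the MaxEnt family. Models are validated by k-fold test AUC;
#' species passing validation get a thresholded presence/absence surface,
#' and species with too few presences (or failing models) fall back to the
#' CA50 circular-area model: all land cells within 50 km of an occurrence.
#'
#' @name sdm
NULL

# evaluate expr with a temporary RNG state seeded by `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' SDM configuration
#'
#' Defaults: at least 10 presences to attempt a model (else CA50 only),
#' 10,000 pseudo-absences capped at the number of eligible cells, 5
#' validation folds, pass rule mean test AUC >= 0.7 and sd <= 0.15,
#' regularization multiplier 1 on a base lasso penalty of 0.01.
#'
#' @param min_presences minimum distinct presence cells to fit a model
#' @param background_n pseudo-absence draw size
#' @param k validation folds
#' @param auc_min,auc_sd_max validation pass thresholds
#' @param reg regularization multiplier (> 0)
#' @param ca50_km CA50 buffer radius in km
#' @return list of class `sdm_config`
#' @export
sdm_config <- function(min_presences = 10L, background_n = 10000L, k = 5L,
                       auc_min = 0.7, auc_sd_max = 0.15, reg = 1,
                       ca50_km = 50) {
  stopifnot(min_presences >= 1L, background_n >= 1L, k >= 2L, reg > 0,
            ca50_km > 0)
  structure(list(min_presences = as.integer(min_presences),
                 background_n = as.integer(background_n), k = as.integer(k),
                 auc_min = auc_min, auc_sd_max = auc_sd_max, reg = reg,
                 ca50_km = ca50_km),
            class = "sdm_config")
}

# lasso penalty at reg = 1: mild enough to express sharp quadratic niche
# responses at presence/background sample sizes of ~10^3, while still
# pruning uninformative features
BASE_LAMBDA <- 0.001

#' Draw pseudo-absences from the land mask
#'
#' `n` cell centers drawn uniformly without replacement from mask = 1 cells
#' that are not presence cells, reproducibly for a fixed seed. If fewer
#' eligible cells exist than requested, all of them are returned with a
#' warning.
#'
#' @param mask binary [raster_layer()]
#' @param presence_cells two-column (row, col) matrix of presence cells
#' @param n number of pseudo-absences
#' @param seed RNG seed
#' @return data frame with columns `lon`, `lat`, `row`, `col`
#' @export
sample_pseudo_absences <- function(mask, presence_cells, n, seed) {
  stopifnot(inherits(mask, "raster_layer"), mask$semantics == "binary",
            n >= 1L)
  land <- which(layer_values(mask) == 1)  # linear indices, column-major
  if (!is.null(presence_cells) && nrow(presence_cells) > 0L) {
    pres_lin <- (presence_cells[, 2L] - 1L) * mask$grid$n_rows +
      presence_cells[, 1L]
    land <- setdiff(land, pres_lin)
  }
  if (length(land) < n) {
    warning(sprintf("only %d eligible cells for %d pseudo-absences; using all",
                    length(land), n))
    chosen <- land
  } else {
    chosen <- with_seed(seed, sample(land, n))
  }
  row <- ((chosen - 1L) %% mask$grid$n_rows) + 1L
  col <- ((chosen - 1L) %/% mask$grid$n_rows) + 1L
  ctr <- cell_center(mask$grid, row, col)
  data.frame(lon = ctr[, "lon"], lat = ctr[, "lat"], row = row, col = col)
}

# standardized linear + quadratic design matrix from stack values;
# drops features from zero-variance predictors (background statistics)
build_features <- function(stack_vals, center, scale) {
  z <- sweep(sweep(stack_vals, 2L, center), 2L, scale, "/")
  x <- cbind(z, z^2)
  colnames(x) <- c(colnames(stack_vals), paste0(colnames(stack_vals), "^2"))
  x
}

cells_of <- function(grid, pts) {
  idx <- cell_index(grid, pts$lon, pts$lat)
  if (anyNA(idx)) stop("points fall outside the grid extent")
  idx
}

#' Fit the MaxEnt-style presence/background model
#'
#' Linear + quadratic features of every predictor, standardized with
#' background means/sds, L1-penalized logistic fit (glmnet) at penalty
#' `reg * 0.01` (warm-started down a fixed descending path so that larger
#' `reg` can only shrink the active set). Zero-variance predictors over the
#' background are dropped with a warning. The fitted surface is the
#' predicted presence probability over all mask cells, in [0, 1].
#'
#' @param presences,background data frames with `lon`, `lat`
#' @param stack a `predictor_stack`
#' @param mask binary [raster_layer()] delimiting predictable cells
#' @param reg regularization multiplier
#' @param seed RNG seed (glmnet fit is deterministic; seed retained for
#'   interface stability)
#' @return list of class `sdm_model`: `probability` ([raster_layer()]),
#'   `weights` (named coefficient vector), `center`, `scale`, `kept`,
#'   `lambda`
#' @export
fit_occurrence_model <- function(presences, background, stack, mask,
                                 reg = 1, seed = 1L) {
  stopifnot(reg > 0)
  grid <- stack$grid
  pres_cells <- cells_of(grid, presences)
  bg_cells <- cells_of(grid, background)
  pres_x <- stack_matrix(stack, pres_cells)
  bg_x <- stack_matrix(stack, bg_cells)
  center <- colMeans(bg_x, na.rm = TRUE)
  scale <- apply(bg_x, 2L, stats::sd, na.rm = TRUE)
  degenerate <- !is.finite(scale) | scale == 0
  if (any(degenerate)) {
    warning(sprintf("dropping %d zero-variance predictor(s): %s",
                    sum(degenerate),
                    paste(names(scale)[degenerate], collapse = ", ")))
  }
  keep <- which(!degenerate)
  if (length(keep) == 0L) stop("no usable predictors: all are degenerate over the background")
  x <- rbind(build_features(pres_x[, keep, drop = FALSE], center[keep], scale[keep]),
             build_features(bg_x[, keep, drop = FALSE], center[keep], scale[keep]))
  y <- c(rep(1L, nrow(pres_x)), rep(0L, nrow(bg_x)))
  if (anyNA(x)) stop("nodata predictor values at presence/background cells")
  lambda <- BASE_LAMBDA * reg
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 1,
                        lambda = lambda * 2^(6:0), standardize = FALSE)
  if (fit$jerr != 0) stop("glmnet did not converge (jerr = ", fit$jerr, ")")
  beta <- as.numeric(fit$beta[, ncol(fit$beta)])
  names(beta) <- rownames(fit$beta)
  a0 <- fit$a0[length(fit$a0)]

  mask_cells <- which(layer_values(mask) == 1, arr.ind = TRUE)
  mx <- build_features(stack_matrix(stack, mask_cells)[, keep, drop = FALSE],
                       center[keep], scale[keep])
  eta <- as.vector(mx %*% beta) + a0
  prob <- matrix(NA_real_, grid$n_rows, grid$n_cols)
  prob[mask_cells] <- stats::plogis(eta)
  structure(list(probability = raster_layer(grid, prob, "continuous"),
                 weights = beta, intercept = unname(a0),
                 center = center[keep], scale = scale[keep],
                 kept = names(center)[keep], lambda = lambda),
            class = "sdm_model")
}

# predicted probability of an sdm_model at arbitrary cells
predict_model_cells <- function(model, stack, cells) {
  x <- build_features(stack_matrix(stack, cells)[, model$kept, drop = FALSE],
                      model$center, model$scale)
  as.vector(stats::plogis(x %*% model$weights + model$intercept))
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC of positive scores against negatives, with
#' the conventional 1/2 credit for ties.
#'
#' @param pos,neg numeric score vectors
#' @return AUC in [0, 1]
#' @export
auc_score <- function(pos, neg) {
  stopifnot(length(pos) > 0L, length(neg) > 0L)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' k-fold validation of the occurrence model
#'
#' Presences are partitioned into k folds (seeded); the background is
#' shared across folds. Each fold's model is refit on the remaining
#' presences and scored by test AUC of held-out presences against the
#' background. The model passes when mean test AUC >= `auc_min` and its sd
#' <= `auc_sd_max`.
#'
#' @inheritParams fit_occurrence_model
#' @param k number of folds (>= 2)
#' @param config an [sdm_config()]
#' @return list of class `validation_metrics`: `mean_test_auc`,
#'   `sd_test_auc`, `fold_count`, `n_presence`, `n_background`,
#'   `threshold` (`NA` until thresholding), `passed`
#' @export
validate_kfold <- function(presences, background, stack, mask,
                           k = 5L, seed = 1L, config = sdm_config()) {
  n <- nrow(presences)
  if (k < 2L) stop("k must be >= 2")
  if (n < k) stop("too few presences for ", k, " folds")
  folds <- with_seed(seed, sample(rep_len(seq_len(k), n)))
  bg_cells <- cells_of(stack$grid, background)
  aucs <- vapply(seq_len(k), function(i) {
    train <- presences[folds != i, , drop = FALSE]
    test <- presences[folds == i, , drop = FALSE]
    m <- suppressWarnings(
      fit_occurrence_model(train, background, stack, mask,
                           reg = config$reg, seed = seed))
    pos <- predict_model_cells(m, stack, cells_of(stack$grid, test))
    neg <- predict_model_cells(m, stack, bg_cells)
    auc_score(pos, neg)
  }, numeric(1))
  mean_auc <- mean(aucs)
  sd_auc <- stats::sd(aucs)
  structure(list(mean_test_auc = mean_auc, sd_test_auc = sd_auc,
                 fold_count = k, n_presence = n,
                 n_background = nrow(background),
                 fold_aucs = aucs, threshold = NA_real_,
                 passed = mean_auc >= config$auc_min &&
                   sd_auc <= config$auc_sd_max),
            class = "validation_metrics")
}

#' Threshold a probability surface to presence/absence
#'
#' The threshold maximizes sensitivity + specificity over the candidate set
#' of distinct predicted values at presences and background points; cells
#' with probability >= threshold become presence (so on a constant surface
#' every cell is presence). Among equally good candidates the lowest is
#' chosen.
#'
#' @param probability continuous [raster_layer()] in [0, 1] (nodata outside
#'   the mask)
#' @param presences,background data frames with `lon`, `lat`
#' @return list: `presence` (binary [raster_layer()], 1 where probability
#'   >= threshold, 0 on other mask cells, nodata off-mask), `threshold`
#' @export
threshold_presence <- function(probability, presences, background) {
  grid <- probability$grid
  pv <- layer_values(probability)
  p_pres <- pv[cells_of(grid, presences)]
  p_bg <- pv[cells_of(grid, background)]
  if (anyNA(p_pres) || anyNA(p_bg)) stop("presence/background points off the modeled surface")
  cand <- sort(unique(c(p_pres, p_bg)))
  tss <- vapply(cand, function(t)
    mean(p_pres >= t) + mean(p_bg < t), numeric(1))
  thr <- cand[which.max(tss)]  # which.max takes the first (lowest) argmax
  vals <- ifelse(is.na(pv), NA_real_, as.numeric(pv >= thr))
  list(presence = raster_layer(grid, vals, "binary"), threshold = thr)
}

#' CA50 circular-area model
#'
#' The fallback distribution estimate: a cell is presence iff its center
#' lies within `radius_km` (great-circle, default 50 km) of any occurrence
#' point, intersected with the land mask. Satisfies
#' `ca50(A union B) = ca50(A) | ca50(B)`.
#'
#' @param points data frame with `lon`, `lat` (at least one row)
#' @param grid a [grid_spec()]
#' @param mask binary [raster_layer()]
#' @param radius_km buffer radius in km
#' @return binary [raster_layer()] (1 inside the buffer on land, 0 on other
#'   land cells, nodata off-mask)
#' @export
ca50 <- function(points, grid, mask, radius_km = 50) {
  if (is.null(points) || nrow(points) == 0L) stop("CA50 requires at least one georeferenced occurrence")
  stopifnot(same_grid(grid, mask$grid))
  rows <- rep(seq_len(grid$n_rows), times = grid$n_cols)
  cols <- rep(seq_len(grid$n_cols), each = grid$n_rows)
  ctr <- cell_center(grid, rows, cols)
  within <- rep(FALSE, length(rows))
  for (i in seq_len(nrow(points))) {
    d <- haversine_km(ctr[, "lon"], ctr[, "lat"], points$lon[i], points$lat[i])
    within <- within | d <= radius_km
  }
  land <- layer_values(mask) == 1
  vals <- matrix(NA_real_, grid$n_rows, grid$n_cols)
  vals[cbind(rows, cols)] <- as.numeric(within)
  vals[!land | is.na(land)] <- NA_real_
  vals[land & is.na(vals)] <- 0
  raster_layer(grid, vals, "binary")
}

#' Run the full SDM step for one species
#'
#' Dedupes georeferenced records to distinct presence cells. With at least
#' `min_presences` cells, draws pseudo-absences, validates by k folds, fits
#' the final model on all presences and thresholds it; if validation fails
#' (or presences are too few for modeling or folding) the species falls
#' back to CA50. The result always contains a distribution surface.
#'
#' @param records scrubbed occurrence data frame (georeferenced rows used)
#' @param stack a `predictor_stack`
#' @param mask binary [raster_layer()]
#' @param config an [sdm_config()]
#' @param seed RNG seed controlling pseudo-absences and fold assignment
#' @return list of class `sdm_output`: `species_id`, `model_kind`
#'   (`"maxent_like"` or `"ca50"`), `probability` (or `NULL`), `presence`,
#'   `metrics` (or `NULL`), `passed`
#' @export
run_sdm <- function(records, stack, mask, config = sdm_config(), seed = 1L) {
  sid <- unique(as.character(records$species_id))
  if (length(sid) != 1L) stop("records must belong to one species")
  geo <- records[!is.na(records$lon) & !is.na(records$lat), , drop = FALSE]
  if (nrow(geo) == 0L) stop("no georeferenced records for ", sid)
  idx <- cell_index(stack$grid, geo$lon, geo$lat)
  ok <- !is.na(idx[, "row"])
  geo <- geo[ok, , drop = FALSE]
  idx <- idx[ok, , drop = FALSE]
  pres_cells <- unique(idx)
  ctr <- cell_center(stack$grid, pres_cells[, "row"], pres_cells[, "col"])
  presences <- data.frame(lon = ctr[, "lon"], lat = ctr[, "lat"])

  fallback <- function() {
    list(species_id = sid, model_kind = "ca50", probability = NULL,
         presence = ca50(geo, stack$grid, mask, radius_km = config$ca50_km),
         metrics = NULL, passed = FALSE)
  }
  if (nrow(presences) < config$min_presences ||
      nrow(presences) < config$k) {
    return(structure(fallback(), class = "sdm_output"))
  }
  background <- sample_pseudo_absences(mask, pres_cells,
                                       n = config$background_n, seed = seed)
  metrics <- validate_kfold(presences, background, stack, mask,
                            k = config$k, seed = seed, config = config)
  if (!metrics$passed) {
    out <- fallback()
    out$metrics <- metrics
    return(structure(out, class = "sdm_output"))
  }
  model <- suppressWarnings(
    fit_occurrence_model(presences, background, stack, mask,
                         reg = config$reg, seed = seed))
  thr <- threshold_presence(model$probability, presences, background)
  metrics$threshold <- thr$threshold
  structure(list(species_id = sid, model_kind = "maxent_like",
                 probability = model$probability, presence = thr$presence,
                 model = model, metrics = metrics, passed = TRUE),
            class = "sdm_output")
}
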