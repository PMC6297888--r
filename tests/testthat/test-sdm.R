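# shared strong-signal niche scenario on the cached world
strong_niche <- function() list(predictor = "wc2.0_bio_2.5m_01",
                                optimum = 25, breadth = 0.3)

niche_fixture <- function(w, seed, n = 100L, bg_n = 1000L) {
  pts <- sample_species_occurrences(strong_niche(), w$stack, w$mask,
                                    n_g = 0L, n_h = n, seed = seed)
  ctr <- cell_center(w$grid, pts$row, pts$col)
  list(presences = unique(data.frame(lon = ctr[, "lon"], lat = ctr[, "lat"])),
       cells = unique(cbind(pts$row, pts$col)),
       background = sample_pseudo_absences(w$mask,
                                           unique(cbind(pts$row, pts$col)),
                                           n = bg_n, seed = seed + 5000L))
}

test_that("pseudo-absence sampling is uniform, exclusive and reproducible", {
  g <- grid_spec(cell_size_deg = 1, origin_lon = 0, origin_lat = 10,
                 n_rows = 10, n_cols = 10)
  land <- matrix(1, 10, 10)
  mask <- raster_layer(g, land, "binary")
  pres <- cbind(row = rep(1:2, each = 5), col = rep(1:5, 2))
  s1 <- sample_pseudo_absences(mask, pres, n = 50, seed = 3)
  expect_equal(nrow(s1), 50L)
  expect_equal(nrow(unique(s1[, c("row", "col")])), 50L)
  # no presence cell drawn
  expect_equal(nrow(merge(s1[, c("row", "col")], as.data.frame(pres))), 0L)
  s2 <- sample_pseudo_absences(mask, pres, n = 50, seed = 3)
  expect_identical(s1, s2)
  expect_false(identical(s1, sample_pseudo_absences(mask, pres, 50, seed = 4)))
  # n exceeding eligible cells -> all eligible, with a warning
  expect_warning(s3 <- sample_pseudo_absences(mask, pres, n = 95, seed = 1),
                 "eligible")
  expect_equal(nrow(s3), 90L)
})

test_that("fitted surface ranks niche centers above niche edges", {
  w <- test_world()
  fx <- niche_fixture(w, seed = 301)
  m <- suppressWarnings(fit_occurrence_model(fx$presences, fx$background,
                                             w$stack, w$mask))
  pv <- plantgap:::layer_values(m$probability)
  x <- plantgap:::layer_values(w$stack$layers[[1]]$layer)
  land <- plantgap:::layer_values(w$mask) == 1
  center_cells <- land & abs(x - 25) < 0.3
  edge_cells <- land & abs(x - 25) > 3
  expect_gt(mean(pv[center_cells]), mean(pv[edge_cells]))
  expect_true(all(pv[land] >= 0 & pv[land] <= 1))
  expect_true(all(is.na(pv[!land])))
})

test_that("uniform presences give a near-flat prediction", {
  w <- test_world()
  pres <- sample_pseudo_absences(w$mask, NULL, n = 150, seed = 71)
  bg <- sample_pseudo_absences(w$mask, NULL, n = 1000, seed = 72)
  m <- suppressWarnings(fit_occurrence_model(pres[, c("lon", "lat")],
                                             bg[, c("lon", "lat")],
                                             w$stack, w$mask))
  # "near-flat": the bulk of the surface is constant (a handful of overfit
  # bumps survive the mild default penalty, so the raw range is not used)
  pv <- plantgap:::layer_values(m$probability)
  expect_lt(sd(pv, na.rm = TRUE), 0.08)
  q <- quantile(pv, c(0.1, 0.9), na.rm = TRUE)
  expect_lt(unname(diff(q)), 0.2)
})

test_that("doubling the regularization never grows the active set", {
  w <- test_world()
  fx <- niche_fixture(w, seed = 302, n = 60L, bg_n = 400L)
  nz <- vapply(c(0.5, 1, 2, 4, 8), function(r) {
    m <- suppressWarnings(fit_occurrence_model(fx$presences, fx$background,
                                               w$stack, w$mask, reg = r))
    sum(m$weights != 0)
  }, numeric(1))
  expect_true(all(diff(nz) <= 0))
})

test_that("k-fold validation separates signal from null", {
  w <- test_world()
  fx <- niche_fixture(w, seed = 303)
  m <- validate_kfold(fx$presences, fx$background, w$stack, w$mask,
                      k = 5, seed = 1)
  expect_gt(m$mean_test_auc, 0.9)
  expect_true(m$passed)
  expect_equal(m$fold_count, 5L)
  expect_length(m$fold_aucs, 5L)
  # shuffled labels: draw "presences" uniformly -> AUC ~ 0.5
  null_pres <- sample_pseudo_absences(w$mask, NULL, n = 100, seed = 81)
  null_bg <- sample_pseudo_absences(w$mask, NULL, n = 1000, seed = 82)
  m0 <- validate_kfold(null_pres[, c("lon", "lat")],
                       null_bg[, c("lon", "lat")], w$stack, w$mask,
                       k = 5, seed = 1)
  expect_lt(abs(m0$mean_test_auc - 0.5), 0.1)
  expect_error(validate_kfold(fx$presences[1:3, ], fx$background,
                              w$stack, w$mask, k = 5), "too few")
})

test_that("threshold maximizes sensitivity + specificity", {
  g <- grid_spec(cell_size_deg = 1, origin_lon = 0, origin_lat = 4,
                 n_rows = 4, n_cols = 4)
  prob <- matrix(0.1, 4, 4)
  prob[1, 1:2] <- 0.9
  lyr <- raster_layer(g, prob)
  pres <- data.frame(lon = c(0.5, 1.5), lat = 3.5)
  bg <- data.frame(lon = rep(seq(0.5, 3.5), 2), lat = rep(c(0.5, 1.5), each = 4))
  out <- threshold_presence(lyr, pres, bg)
  v <- plantgap:::layer_values(out$presence)
  expect_equal(out$threshold, 0.9)
  expect_equal(sum(v == 1), 2)
  expect_true(all(v[prob < 0.9] == 0))

  # brute-force scan oracle on a random surface
  set.seed(91)
  prob <- matrix(runif(16), 4, 4)
  lyr <- raster_layer(g, prob)
  pres_idx <- cbind(c(1, 2, 3), c(1, 2, 3))
  ctr_p <- cell_center(g, pres_idx[, 1], pres_idx[, 2])
  bg_idx <- cbind(rep(1:4, 4), rep(1:4, each = 4))
  ctr_b <- cell_center(g, bg_idx[, 1], bg_idx[, 2])
  out <- threshold_presence(lyr, as.data.frame(ctr_p), as.data.frame(ctr_b))
  p_pres <- prob[pres_idx]; p_bg <- prob[bg_idx]
  cand <- sort(unique(c(p_pres, p_bg)))
  tss <- sapply(cand, function(t) mean(p_pres >= t) + mean(p_bg < t))
  expect_equal(out$threshold, cand[which.max(tss)])

  # constant surface: >= tie rule makes every cell presence
  out <- threshold_presence(raster_layer(g, matrix(0.4, 4, 4)),
                            as.data.frame(ctr_p), as.data.frame(ctr_b))
  expect_true(all(plantgap:::layer_values(out$presence) == 1))
})

test_that("ca50 equals the brute-force double loop and satisfies union", {
  set.seed(33)
  g <- grid_spec(cell_size_deg = 0.5, origin_lon = 0, origin_lat = 6,
                 n_rows = 12, n_cols = 12)
  mask <- raster_layer(g, matrix(1, 12, 12), "binary")
  a <- data.frame(lon = runif(2, 1, 5), lat = runif(2, 1, 5))
  b <- data.frame(lon = runif(3, 1, 5), lat = runif(3, 1, 5))
  ra <- plantgap:::layer_values(ca50(a, g, mask))
  rb <- plantgap:::layer_values(ca50(b, g, mask))
  rab <- plantgap:::layer_values(ca50(rbind(a, b), g, mask))
  expect_equal(rab, pmax(ra, rb))                      # union property
  expect_equal(ra, oracle_ca50(a, g, mask))            # brute force
  # single point at the equator: disk radius 50/111.19 ~ 0.45 degrees
  pt <- data.frame(lon = 3, lat = 3)
  r1 <- plantgap:::layer_values(ca50(pt, g, mask))
  ctr <- cell_center(g, rep(1:12, 12), rep(1:12, each = 12))
  approx_deg <- sqrt((ctr[, 1] - 3)^2 + (ctr[, 2] - 3)^2)
  inside <- matrix(NA, 12, 12)
  inside[cbind(rep(1:12, 12), rep(1:12, each = 12))] <- approx_deg
  expect_true(all(r1[inside < 0.43] == 1))
  expect_true(all(r1[inside > 0.47] == 0))
  expect_error(ca50(a[0, ], g, mask), "at least one")
})

test_that("run_sdm routes between model and CA50 and is deterministic", {
  w <- test_world()
  cfg <- sdm_config(background_n = 800L)
  sid <- w$ground_truth$selected_ids[1]
  sc <- scrub(w$occurrences[[sid]], w$mask, w$ground_truth$native_iso3[[sid]])
  out1 <- suppressWarnings(run_sdm(sc$kept, w$stack, w$mask, cfg, seed = 5))
  out2 <- suppressWarnings(run_sdm(sc$kept, w$stack, w$mask, cfg, seed = 5))
  expect_identical(out1$model_kind, out2$model_kind)
  expect_equal(plantgap:::layer_values(out1$presence),
               plantgap:::layer_values(out2$presence))
  if (out1$model_kind == "maxent_like") {
    expect_identical(plantgap:::layer_values(out1$probability),
                     plantgap:::layer_values(out2$probability))
    # presence = 1 implies probability >= threshold
    pv <- plantgap:::layer_values(out1$probability)
    bv <- plantgap:::layer_values(out1$presence)
    expect_true(all(pv[bv == 1] >= out1$metrics$threshold, na.rm = TRUE))
  }
  # presence cells are a subset of the mask
  land <- plantgap:::layer_values(w$mask) == 1
  bv <- plantgap:::layer_values(out1$presence)
  expect_true(all(is.na(bv[!land])))
  # too few presences -> CA50 pathway
  few <- sc$kept[1:4, ]
  out3 <- run_sdm(few, w$stack, w$mask, cfg, seed = 5)
  expect_identical(out3$model_kind, "ca50")
})

test_that("planted niches are recovered across seeded replicates", {
  w <- test_world()
  hits <- 0L
  for (s in 1:10) {
    fx <- niche_fixture(w, seed = 400 + s, n = 100L, bg_n = 600L)
    m <- suppressWarnings(fit_occurrence_model(fx$presences, fx$background,
                                               w$stack, w$mask))
    top <- names(which.max(abs(m$weights)))
    hits <- hits + grepl(strong_niche()$predictor, top, fixed = TRUE)
  }
  expect_gte(hits, 8L)
})
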