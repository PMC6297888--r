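test_that("the default world satisfies its structural contracts", {
  w <- test_world()
  mv <- plantgap:::layer_values(w$mask)
  expect_setequal(unique(as.vector(mv)), c(0, 1))
  expect_length(w$stack$layers, 26L)
  expect_length(w$country_polygons, w$config$n_countries)
  expect_length(w$ecoregion_polygons, w$config$n_ecoregions)
  # ecoregion raster covers exactly the land block (lake included: the
  # bands are drawn over the block before the lake is carved)
  ev <- plantgap:::layer_values(w$ecoregions)
  expect_setequal(unique(ev[!is.na(ev)]), seq_len(w$config$n_ecoregions))
  # pa raster is binary and roughly matches the target fraction of land
  pv <- plantgap:::layer_values(w$pa)
  expect_true(all(pv %in% c(0, 1)))
  land_frac <- sum(pv == 1 & mv == 1) / sum(mv == 1)
  expect_equal(land_frac, w$config$pa_fraction, tolerance = 0.1)
  # occurrence tables exist per selected species
  expect_setequal(names(w$occurrences), w$ground_truth$selected_ids)
})

test_that("planted contamination is exactly bookkept", {
  cfg <- world_config(n_species = 1L, n_g = 20L, n_h = 80L,
                      n_water = 10L, n_old = 5L, n_nonnative = 7L, seed = 17L)
  w <- generate_world(cfg)
  truth <- w$ground_truth$records$SP0001
  expect_equal(truth$expected_kept, 78L)
  out <- scrub(w$occurrences$SP0001, w$mask, w$ground_truth$native_iso3$SP0001)
  expect_equal(nrow(out$kept), 78L)
  expect_equal(sort(table(out$rejected$reason)),
               sort(table(factor(c(rep("water", 10), rep("too-old", 5),
                                   rep("non-native", 7))))),
               ignore_attr = TRUE)
  expect_identical(scrub(out$kept, w$mask,
                         w$ground_truth$native_iso3$SP0001)$kept, out$kept)
})

test_that("same seed yields byte-identical worlds on disk", {
  cfg <- world_config(n_species = 2L, seed = 23L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_world(cfg, out_dir = d1)
  generate_world(cfg, out_dir = d2)
  files <- list.files(d1, recursive = TRUE)
  expect_gt(length(files), 10L)
  for (f in files) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
  # different seeds differ
  d3 <- withr::local_tempdir()
  generate_world(world_config(n_species = 2L, seed = 24L), out_dir = d3)
  occ1 <- readLines(file.path(d1, "occurrences", "SP0001.csv"))
  occ3 <- readLines(file.path(d3, "occurrences", "SP0001.csv"))
  expect_false(identical(occ1, occ3))
})

test_that("occurrence sampling respects the niche and the G/H split", {
  w <- test_world()
  niche <- list(predictor = "wc2.0_bio_2.5m_01", optimum = 25, breadth = 0.5)
  pts <- sample_species_occurrences(niche, w$stack, w$mask, n_g = 10L,
                                    n_h = 40L, seed = 3L)
  expect_equal(sum(pts$record_type == "G"), 10L)
  x <- plantgap:::layer_values(w$stack$layers[[1]]$layer)
  vals <- x[cbind(pts$row, pts$col)]
  expect_lt(sd(vals), niche$breadth * 1.5)
  expect_lt(abs(mean(vals) - niche$optimum), 0.5)
  # all-H case and seed sensitivity
  all_h <- sample_species_occurrences(niche, w$stack, w$mask, 0L, 20L, seed = 3L)
  expect_true(all(all_h$record_type == "H"))
  expect_false(identical(
    sample_species_occurrences(niche, w$stack, w$mask, 0L, 20L, seed = 4L)$lon,
    sample_species_occurrences(niche, w$stack, w$mask, 0L, 20L, seed = 5L)$lon))
})

test_that("infeasible configurations are rejected", {
  expect_error(world_config(pa_fraction = 1.2), "pa_fraction")
  expect_error(world_config(n_h = 5L, n_water = 3L, n_old = 2L,
                            n_nonnative = 2L), "violations exceed")
  expect_error(generate_world(world_config(n_countries = 60L)),
               "more countries than land columns")
})

test_that("protected-area extremes drive in situ scores to their bounds", {
  cfg_full <- world_config(n_species = 2L, pa_fraction = 1, seed = 31L)
  w <- generate_world(cfg_full)
  expect_true(all(plantgap:::layer_values(w$pa) == 1))
  for (sid in w$ground_truth$selected_ids) {
    sc <- scrub(w$occurrences[[sid]], w$mask,
                w$ground_truth$native_iso3[[sid]])
    dist <- ca50(sc$kept, w$grid, w$mask)
    row <- score_species(sc$kept, dist, w$ecoregions, w$pa, w$mask)
    expect_equal(row$grs_in, 100)
    expect_equal(row$ers_in, 100)
    expect_equal(row$srs_in, 100)
  }
  cfg_none <- world_config(n_species = 2L, pa_fraction = 0, seed = 31L)
  w0 <- generate_world(cfg_none)
  for (sid in w0$ground_truth$selected_ids) {
    sc <- scrub(w0$occurrences[[sid]], w0$mask,
                w0$ground_truth$native_iso3[[sid]])
    dist <- ca50(sc$kept, w0$grid, w0$mask)
    row <- score_species(sc$kept, dist, w0$ecoregions, w0$pa, w0$mask)
    expect_equal(row$fcs_in, 0)
  }
})

test_that("run_pipeline produces coherent scores and indicator tables", {
  w <- test_world()
  res <- run_pipeline(w, config = sdm_config(background_n = 500L), seed = 2L)
  expect_setequal(res$scores$species_id, w$ground_truth$selected_ids)
  expect_true(all(res$scores$fcs_combined >= 0 & res$scores$fcs_combined <= 100))
  expect_true(all(res$validation$model_kind %in% c("maxent_like", "ca50")))
  glob <- res$indicator[res$indicator$scope_id == "global", ]
  expect_equal(glob$n_species, length(w$ground_truth$selected_ids))
  expect_equal(glob$mean_fcs_combined, mean(res$scores$fcs_combined))
  expect_equal(glob$n_urgent + glob$n_high + glob$n_medium +
                 glob$n_low_priority, glob$n_species)
  # scrub bookkeeping propagated
  expect_true(all(res$scrub$kept + res$scrub$rejected ==
                    nrow(w$occurrences[[1]])))
})
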