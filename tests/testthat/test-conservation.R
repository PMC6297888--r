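counts_row <- function(g, h) {
  data.frame(species_id = "S1", total_records = g + h,
             total_with_coords = g + h, g_records = g, g_with_coords = g,
             h_records = h, h_with_coords = h)
}

test_that("srs_ex is the germplasm share of records", {
  expect_equal(srs_ex(counts_row(0, 20)), 0)
  expect_equal(srs_ex(counts_row(10, 30)), 25)
  expect_equal(srs_ex(counts_row(5, 0)), 100)
  expect_equal(srs_ex(counts_row(0, 0)), 0)  # zero-denominator guard
})

test_that("grs_ex is the buffered share of distribution area", {
  g <- flat_grid(200L)
  areas <- cell_area_model(g)
  dist <- binary_row(g, 1:160)
  expect_equal(grs_ex(binary_row(g, 1:200), dist, areas), 100)  # superset cap
  expect_equal(grs_ex(NULL, dist, areas), 0)                    # no G records
  expect_equal(grs_ex(binary_row(g, 1:40), dist, areas), 25)    # 40 of 160
  expect_equal(grs_ex(binary_row(g, 1:40), binary_row(g, integer(0)), areas), 0)
})

test_that("cell areas follow the cosine model and weight grs correctly", {
  g <- grid_spec(cell_size_deg = 1, origin_lon = 0, origin_lat = 3,
                 n_rows = 6, n_cols = 1)
  areas <- cell_area_model(g)
  expect_true(all(areas$row_area_km2 > 0))
  expect_equal(areas$row_area_km2, rev(areas$row_area_km2))  # equator symmetry
  expect_equal(areas$row_area_km2[1],
               (111.19492664)^2 * cos(2.5 * pi / 180), tolerance = 1e-6)
  # area weighting: covering the 2 equator-adjacent rows of a 6-row
  # distribution yields more than 2/6 of the area
  dist <- raster_layer(g, matrix(1, 6, 1), "binary")
  buf <- raster_layer(g, matrix(c(0, 0, 1, 1, 0, 0), 6, 1), "binary")
  expect_gt(grs_ex(buf, dist, areas), 100 * 2 / 6)
})

test_that("ers counts ecoregion coverage of the distribution", {
  g <- flat_grid(8L)
  eco <- raster_layer(g, matrix(c(1, 1, 2, 2, 3, 3, 4, 4), 1, 8),
                      "categorical")
  dist <- binary_row(g, 1:8)          # spans 4 ecoregions
  expect_equal(ers_ex(binary_row(g, 1:2), dist, eco), 25)
  expect_equal(ers_ex(binary_row(g, c(1, 3, 5, 7)), dist, eco), 100)
  expect_equal(ers_ex(NULL, dist, eco), 0)
  # distribution spanning zero ecoregions -> 0, not vacuous 100
  eco_na <- raster_layer(g, matrix(NA_real_, 1, 8), "categorical")
  expect_equal(ers_ex(binary_row(g, 1:2), dist, eco_na), 0)
})

test_that("insitu_scores cover the protected-area contrasts", {
  g <- flat_grid(8L)
  areas <- cell_area_model(g)
  eco <- raster_layer(g, matrix(c(1, 1, 1, 1, 2, 2, 2, 2), 1, 8),
                      "categorical")
  dist <- binary_row(g, 1:8)
  occ <- data.frame(species_id = "S1",
                    lon = cell_center(g, rep(1, 4), 1:4)[, "lon"],
                    lat = cell_center(g, rep(1, 4), 1:4)[, "lat"],
                    iso3 = "AAA", year = 2000L, record_type = "H",
                    native_status = "N")
  # pa disjoint from distribution and occurrences -> all zeros
  off <- insitu_scores(dist, binary_row(g, integer(0)), eco, occ, areas)
  expect_equal(unname(off), c(0, 0, 0))
  # distribution entirely protected
  full <- insitu_scores(dist, binary_row(g, 1:8), eco, occ, areas)
  expect_equal(unname(full), c(100, 100, 100))
  # half protected, both ecoregions represented in the protected half
  half <- insitu_scores(dist, binary_row(g, c(1, 2, 5, 6)), eco, occ, areas)
  expect_equal(half[["grs_in"]], 50)
  expect_equal(half[["ers_in"]], 100)
  expect_equal(half[["srs_in"]], 50)  # 2 of 4 occurrences in pa cells
})

test_that("combine_and_categorize applies means and category thresholds", {
  z <- combine_and_categorize("S1", 0, 0, 0, 0, 0, 0)
  expect_equal(z$fcs_combined, 0)
  expect_identical(z$category, "urgent")
  z <- combine_and_categorize("S1", 100, 100, 100, 100, 100, 100)
  expect_equal(z$fcs_combined, 100)
  expect_identical(z$category, "low_priority")
  z <- combine_and_categorize("S1", 25, 50, 75, 0, 50, 100)
  expect_equal(z$fcs_ex, 50)
  expect_equal(z$fcs_in, 50)
  expect_equal(z$fcs_combined, 50)
  expect_identical(z$category, "medium")      # boundary: 50 -> medium
  expect_identical(combine_and_categorize("S1", 24, 25, 25, 25, 25, 25)$category,
                   "urgent")                   # combined 24.83 < 25
  expect_error(combine_and_categorize("S1", -1, 0, 0, 0, 0, 0), "0, 100")
  expect_error(combine_and_categorize("S1", 101, 0, 0, 0, 0, 0), "0, 100")
})

test_that("scores stay in [0,100] with exact fcs means on fuzzed inputs", {
  set.seed(55)
  g <- flat_grid(30L)
  areas <- cell_area_model(g)
  for (i in 1:100) {
    dist_cells <- sort(sample(30, sample(0:30, 1)))
    buf_cells <- sort(sample(30, sample(0:30, 1)))
    pa_cells <- sort(sample(30, sample(0:30, 1)))
    eco <- raster_layer(g, matrix(sample(1:4, 30, TRUE), 1, 30), "categorical")
    dist <- binary_row(g, dist_cells)
    buf <- if (length(buf_cells)) binary_row(g, buf_cells) else NULL
    gex <- grs_ex(buf, dist, areas)
    eex <- ers_ex(buf, dist, eco)
    occ_n <- sample(1:5, 1)
    occ <- data.frame(species_id = "S1",
                      lon = cell_center(g, rep(1, occ_n),
                                        sample(30, occ_n, TRUE))[, "lon"],
                      lat = rep(0, occ_n), iso3 = "AAA", year = 2000L,
                      record_type = "H", native_status = "N")
    if (i %% 10 == 0) occ <- occ[0, , drop = FALSE]  # no-occurrence case too
    ins <- insitu_scores(dist, binary_row(g, pa_cells), eco, occ, areas)
    sex <- srs_ex(counts_row(sample(0:9, 1), sample(0:9, 1)))
    all6 <- c(sex, gex, eex, ins)
    expect_true(all(all6 >= 0 & all6 <= 100))
    z <- combine_and_categorize("S1", sex, gex, eex, ins[["srs_in"]],
                                ins[["grs_in"]], ins[["ers_in"]])
    expect_equal(z$fcs_ex, mean(c(sex, gex, eex)))
    expect_equal(z$fcs_in, mean(ins))
    expect_equal(z$fcs_combined, mean(c(z$fcs_ex, z$fcs_in)))
  }
})

test_that("scores are monotone under added G records and enlarged reserves", {
  set.seed(56)
  g <- grid_spec(cell_size_deg = 0.5, origin_lon = 0, origin_lat = 5,
                 n_rows = 10, n_cols = 10)
  mask <- raster_layer(g, matrix(1, 10, 10), "binary")
  areas <- cell_area_model(g)
  eco <- raster_layer(g, matrix(sample(1:3, 100, TRUE), 10, 10), "categorical")
  for (i in 1:20) {
    dist <- raster_layer(g, matrix(rbinom(100, 1, 0.5), 10, 10), "binary")
    gpts <- data.frame(lon = runif(2, 1, 4), lat = runif(2, 1, 4))
    extra <- data.frame(lon = runif(1, 1, 4), lat = runif(1, 1, 4))
    buf1 <- ca50(gpts, g, mask)
    buf2 <- ca50(rbind(gpts, extra), g, mask)
    expect_gte(grs_ex(buf2, dist, areas), grs_ex(buf1, dist, areas))
    expect_gte(ers_ex(buf2, dist, eco), ers_ex(buf1, dist, eco))
    # srs_ex monotone in G with H fixed
    expect_gte(srs_ex(counts_row(6, 10)), srs_ex(counts_row(5, 10)))
    # enlarging pa never decreases in situ scores
    pa_small <- matrix(rbinom(100, 1, 0.3), 10, 10)
    grow <- matrix(rbinom(100, 1, 0.3), 10, 10)
    pa_big <- pmax(pa_small, grow)
    occ <- data.frame(species_id = "S1", lon = runif(5, 0.5, 4.5),
                      lat = runif(5, 0.5, 4.5), iso3 = "AAA", year = 2000L,
                      record_type = "H", native_status = "N")
    s_small <- insitu_scores(dist, raster_layer(g, pa_small, "binary"),
                             eco, occ, areas)
    s_big <- insitu_scores(dist, raster_layer(g, pa_big, "binary"),
                           eco, occ, areas)
    expect_true(all(s_big >= s_small))
  }
})

test_that("score_species assembles the nine-score row from records", {
  w <- test_world()
  sid <- w$ground_truth$selected_ids[1]
  sc <- scrub(w$occurrences[[sid]], w$mask, w$ground_truth$native_iso3[[sid]])
  dist <- ca50(sc$kept, w$grid, w$mask)
  row <- score_species(sc$kept, dist, w$ecoregions, w$pa, w$mask)
  expect_s3_class(row, "conservation_scores")
  expect_identical(row$species_id, sid)
  nine <- unlist(row[c("srs_ex", "grs_ex", "ers_ex", "fcs_ex", "srs_in",
                       "grs_in", "ers_in", "fcs_in", "fcs_combined")])
  expect_true(all(nine >= 0 & nine <= 100))
  # G share matches the generator: 15 G / 43 kept records for this species
  cnt <- summarize_occurrences(sc$kept)
  expect_equal(row$srs_ex, 100 * cnt$g_records / cnt$total_records)
})
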