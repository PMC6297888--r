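# One cached default synthetic world shared across test files (building it
# takes ~1 s; contents are deterministic for the fixed config seed).
.world_cache <- new.env()

test_world <- function() {
  if (is.null(.world_cache$default)) {
    .world_cache$default <- generate_world(world_config())
  }
  .world_cache$default
}

# tiny flat-area grid (single row => all cells share one area), used for
# score arithmetic fixtures where cell counting must equal area ratios
flat_grid <- function(n_cols = 20L) {
  grid_spec(cell_size_deg = 0.5, origin_lon = 0, origin_lat = 0.5,
            n_rows = 1L, n_cols = n_cols)
}

binary_row <- function(grid, ones) {
  v <- matrix(0, grid$n_rows, grid$n_cols)
  if (length(ones)) v[1L, ones] <- 1
  raster_layer(grid, v, "binary")
}
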