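# scene fixtures are generated in code and cached for the session
.scene_cache <- new.env(parent = emptyenv())

cached_scene <- function(rows, cols, seed) {
  key <- paste("scene", rows, cols, seed, sep = "_")
  if (is.null(.scene_cache[[key]]))
    .scene_cache[[key]] <- make_scene(rows = rows, cols = cols, seed = seed)
  .scene_cache[[key]]
}

# the standard 300 x 300 fixture used by the heavier end-to-end checks
std_scene <- function() cached_scene(300, 300, 1)

# a smaller scene for fast per-module tests
small_scene <- function() cached_scene(120, 120, 2)

# tiny raster from a matrix, legend covering 1..K
toy_raster <- function(m, K = max(m), cell_size = 100) {
  lulc_raster(m, legend = stats::setNames(paste0("class_", 1:K), 1:K),
              cell_size = cell_size)
}

six_legend <- stats::setNames(
  c("farmland", "forest", "grassland", "water", "built-up", "unused"), 1:6)
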