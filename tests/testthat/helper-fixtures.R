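# Shared in-code fixtures: small grids, stacks and maps built at test time.

tiny_grid <- function(n_rows = 6, n_cols = 8, x_min = 100, y_min = 20,
                      cell_size = 0.5) {
  sdm_grid(n_rows, n_cols, x_min, y_min, cell_size)
}

# deterministic layer: value = f(row, col)
layer_from <- function(grid, f, name = "x", kind = "continuous") {
  m <- outer(seq_len(grid$n_rows), seq_len(grid$n_cols), f)
  sdm_raster(grid, m, name = name, kind = kind)
}

# a small two-layer stack with a north-south temperature-like gradient and
# an east-west moisture-like gradient
tiny_stack <- function(grid = tiny_grid(), scenario_id = "current",
                       t_shift = 0) {
  sdm_stack(list(
    layer_from(grid, function(r, c) 30 - 0.8 * r + t_shift, name = "temp"),
    layer_from(grid, function(r, c) 100 + 20 * c, name = "moist")
  ), scenario_id = scenario_id)
}

random_binary_map <- function(grid, p = 0.5, seed = 1, species = "sp",
                              scenario_id = "future") {
  set.seed(seed)
  m <- matrix(rbinom(grid$n_rows * grid$n_cols, 1, p), grid$n_rows, grid$n_cols)
  structure(list(layer = sdm_raster(grid, m, "bin"), threshold = 0.5,
                 species = species, scenario_id = scenario_id),
            class = "sdm_range_map")
}

# balanced training set drawn from two shifted Gaussians
toy_training <- function(n_per_class = 50, shift = 2, seed = 42,
                         species = "toy") {
  set.seed(seed)
  x1 <- c(rnorm(n_per_class, shift), rnorm(n_per_class, 0))
  x2 <- c(rnorm(n_per_class, 0), rnorm(n_per_class, 0))
  structure(list(
    species = species, replicate_id = 1L,
    data = data.frame(temp = x1, moist = x2,
                      label = rep(1:0, each = n_per_class),
                      row = 1L, col = seq_len(2 * n_per_class)),
    schema = data.frame(variable = c("temp", "moist"), kind = "continuous",
                        stringsAsFactors = FALSE),
    pa_seed = seed), class = "sdm_training")
}

range_map_from <- function(grid, values, species = "sp", scenario_id = "sc",
                           threshold = 0.5) {
  structure(list(layer = sdm_raster(grid, values, "bin"),
                 threshold = threshold, species = species,
                 scenario_id = scenario_id), class = "sdm_range_map")
}
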