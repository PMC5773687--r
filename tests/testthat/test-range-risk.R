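test_that("net change rounds half away from zero", {
  expect_equal(round_half_away(c(0.5, -0.5, 1.4, -1.6, 2.5)),
               c(1, -1, 1, -2, 3))
  expect_equal(net_change_pct(1000, 100, 250), 15)
  expect_equal(net_change_pct(1000, 250, 100), -15)
})

test_that("identical maps yield zero loss, zero gain, zero net change", {
  g <- tiny_grid()
  m <- random_binary_map(g, p = 0.4, seed = 5)
  ch <- summarize_range_change(m, m)
  expect_equal(ch$loss_km2, 0)
  expect_equal(ch$gain_km2, 0)
  expect_equal(ch$net_pct, 0)
  expect_equal(ch$current_km2, ch$future_km2)
})

test_that("range-change areas match a brute-force per-cell tally", {
  g <- sdm_grid(20, 20, 100, 20, 0.25)
  cur <- random_binary_map(g, p = 0.5, seed = 3, scenario_id = "current")
  fut <- random_binary_map(g, p = 0.5, seed = 30)
  ch <- summarize_range_change(cur, fut)
  areas <- cell_area(g)
  tally <- c(loss = 0, stable = 0, gain = 0)
  for (r in seq_len(20)) for (c in seq_len(20)) {
    a <- cur$layer$values[r, c]; b <- fut$layer$values[r, c]
    if (a == 1 && b == 0) tally["loss"] <- tally["loss"] + areas[r]
    if (a == 1 && b == 1) tally["stable"] <- tally["stable"] + areas[r]
    if (a == 0 && b == 1) tally["gain"] <- tally["gain"] + areas[r]
  }
  expect_equal(ch$loss_km2, unname(tally["loss"]))
  expect_equal(ch$stable_km2, unname(tally["stable"]))
  expect_equal(ch$gain_km2, unname(tally["gain"]))
  expect_error(summarize_range_change(cur, random_binary_map(tiny_grid(), 0.5)),
               "different grids")
})

test_that("conservation laws hold on every random run", {
  for (seed in 1:20) {
    g <- sdm_grid(15, 15, 100, 20, 0.3)
    cur <- random_binary_map(g, p = runif(1, 0.2, 0.8), seed = seed,
                             scenario_id = "current")
    fut <- random_binary_map(g, p = runif(1, 0.2, 0.8), seed = seed + 1000)
    ch <- summarize_range_change(cur, fut)
    expect_equal(ch$loss_km2 + ch$stable_km2, ch$current_km2)
    expect_equal(ch$stable_km2 + ch$gain_km2, ch$future_km2)
    expect_equal(ch$current_km2, mask_area(g, cur$layer$values))
    expect_equal(ch$future_km2, mask_area(g, fut$layer$values))
  }
})

test_that("unit cell areas can be injected for area-free accounting", {
  g <- tiny_grid(4, 4)
  cur <- range_map_from(g, matrix(c(rep(1, 8), rep(0, 8)), 4, 4))
  fut <- range_map_from(g, matrix(c(rep(0, 4), rep(1, 12)), 4, 4))
  ch <- summarize_range_change(cur, fut, cell_areas = rep(1, 4))
  expect_equal(ch$current_km2, 8)
  expect_equal(ch$loss_km2, 4)
  expect_equal(ch$stable_km2, 4)
  expect_equal(ch$gain_km2, 8)
  expect_equal(ch$net_pct, 50)
})

test_that("raising the threshold never grows the current range", {
  g <- tiny_grid(10, 10)
  set.seed(8)
  sm <- structure(list(layer = sdm_raster(g, matrix(runif(100), 10, 10), "s"),
                       species = "sp", scenario_id = "current"),
                  class = "sdm_suitability")
  areas <- vapply(seq(0, 1, by = 0.1), function(t)
    mask_area(g, binarize(sm, t)$layer$values), 0)
  expect_true(all(diff(areas) <= 0))
})

test_that("an axis-aligned rectangle rasterizes to the cells whose centers it covers", {
  g <- tiny_grid(4, 4, x_min = 0, y_min = 0, cell_size = 1)
  # covers the centers of cols 1..2, rows 3..4 (lat 0..2)
  area <- list(id = "A", ring = data.frame(lon = c(0.2, 1.8, 1.8, 0.2),
                                           lat = c(0.2, 0.2, 1.8, 1.8)))
  m <- rasterize_protected_area(area, g)
  expect_equal(sum(m), 4)
  expect_equal(m[3:4, 1:2], matrix(1, 2, 2))
  # degenerate zero-area polygon: empty mask with a warning
  deg <- list(id = "D", ring = data.frame(lon = c(1, 2, 3), lat = c(1, 1, 1)))
  expect_warning(md <- rasterize_protected_area(deg, g), "no cell center")
  expect_equal(sum(md), 0)
})

test_that("point-in-polygon agrees with an independent even-odd implementation", {
  skip_if_not_installed("mgcv")
  set.seed(14)
  # an irregular (non-convex) pentagon
  ring <- data.frame(lon = c(0, 4, 5, 2.5, 1), lat = c(0, 0.5, 3, 1.5, 4))
  g <- sdm_grid(25, 25, -1, -1, 0.28)
  m <- rasterize_protected_area(list(id = "P", ring = ring), g)
  cells <- expand.grid(row = seq_len(g$n_rows), col = seq_len(g$n_cols))
  ctr <- cell_center(g, cells$row, cells$col)
  want <- mgcv::in.out(as.matrix(rbind(ring, ring[1, ])),
                       cbind(ctr$lon, ctr$lat))
  expect_equal(m[cbind(cells$row, cells$col)], want + 0)
})

test_that("the threat rule flags only newly exposed reserves", {
  g <- tiny_grid(4, 4, x_min = 0, y_min = 0, cell_size = 1)
  cur <- range_map_from(g, matrix(c(1, 1, rep(0, 14)), 4, 4, byrow = TRUE),
                        species = "sp", scenario_id = "current")
  futv <- matrix(0, 4, 4); futv[1, 1:3] <- 1; futv[4, 4] <- 1
  fut <- range_map_from(g, futv, species = "sp", scenario_id = "warm")
  pas <- protected_areas(list(
    # overlaps the current range: excluded regardless of the future
    list(id = "A", name = "a", ring = data.frame(lon = c(0.1, 1.9, 1.9, 0.1),
                                                 lat = c(3.1, 3.1, 3.9, 3.9)),
         protected_species = "x", protected_ecosystem = "e1"),
    # no current overlap, gains future-suitable cells: threatened
    list(id = "B", name = "b", ring = data.frame(lon = c(3.1, 3.9, 3.9, 3.1),
                                                 lat = c(0.1, 0.1, 0.9, 0.9)),
         protected_species = "y", protected_ecosystem = "e2"),
    # never suitable: not threatened
    list(id = "C", name = "c", ring = data.frame(lon = c(0.1, 0.9, 0.9, 0.1),
                                                 lat = c(0.1, 0.1, 0.9, 0.9)),
         protected_species = "z", protected_ecosystem = "e3")))
  th <- assess_pa_threat(cur, fut, pas)
  expect_equal(th$threatened, c(FALSE, TRUE, FALSE))
  expect_equal(th$overlap_km2[2], cell_area(g, 4))
  expect_gt(th$current_overlap_km2[1], 0)
})

test_that("threat flags match a brute-force overlay on simulated reserves", {
  d <- demo_study(seed = 12, n_presences = 40)
  g <- d$stacks$current$grid
  cur <- range_map_from(g, d$truth$true_current_range$values,
                        species = "v", scenario_id = "current")
  fut <- range_map_from(g, d$truth$true_future_range[[1]]$values,
                        species = "v", scenario_id = names(d$truth$true_future_range)[1])
  pas <- simulate_protected_areas(g, n = 10, seed = 15)
  th <- assess_pa_threat(cur, fut, pas)
  for (i in seq_along(pas$areas)) {
    m <- rasterize_protected_area(pas$areas[[i]], g)
    cur_cells <- sum(m == 1 & cur$layer$values == 1)
    fut_cells <- sum(m == 1 & fut$layer$values == 1)
    expect_equal(th$threatened[i], cur_cells == 0 && fut_cells > 0)
  }
})

test_that("risk aggregation deduplicates species and ecosystems", {
  threats <- data.frame(
    area_id = c("A", "B", "C"), name = letters[1:3],
    species = "sp", scenario = "warm",
    threatened = c(TRUE, TRUE, FALSE),
    overlap_km2 = c(100, 50, 75), current_overlap_km2 = 0,
    affected_species = c("Taxus chinensis;Ginkgo biloba", "Taxus chinensis", "q"),
    affected_ecosystem = c("montane", "montane", "karst"),
    stringsAsFactors = FALSE)
  ch <- summarize_range_change(
    range_map_from(tiny_grid(), matrix(1, 6, 8), species = "sp",
                   scenario_id = "current"),
    range_map_from(tiny_grid(), matrix(1, 6, 8), species = "sp",
                   scenario_id = "warm"))
  rep <- build_risk_report(threats, list(ch))
  expect_equal(rep$risk$n_reserves, 2)
  expect_equal(rep$risk$n_affected_plant_species, 2)  # two distinct names
  expect_equal(rep$risk$n_affected_ecosystems, 1)
  expect_equal(rep$risk$total_area_km2, 150)
  expect_equal(nrow(rep$pa_threats), 2)
  # empty case
  threats0 <- threats; threats0$threatened <- FALSE
  rep0 <- build_risk_report(threats0, list(ch))
  expect_equal(rep0$risk$n_reserves, 0)
  expect_equal(rep0$risk$n_affected_plant_species, 0)
  expect_equal(rep0$risk$total_area_km2, 0)
})

test_that("aggregate counts match a set-union oracle on random attribute tables", {
  set.seed(16)
  for (rep in 1:5) {
    n <- 12
    sp_lists <- replicate(n, paste(sample(LETTERS[1:6], sample(0:3, 1)),
                                   collapse = ";"))
    eco <- sample(c("", letters[1:4]), n, replace = TRUE)
    flag <- sample(c(TRUE, FALSE), n, replace = TRUE)
    threats <- data.frame(area_id = as.character(1:n), name = "r",
                          species = "sp", scenario = "w", threatened = flag,
                          overlap_km2 = runif(n, 0, 10), current_overlap_km2 = 0,
                          affected_species = sp_lists, affected_ecosystem = eco,
                          stringsAsFactors = FALSE)
    ch <- summarize_range_change(
      range_map_from(tiny_grid(), matrix(1, 6, 8), species = "sp",
                     scenario_id = "current"),
      range_map_from(tiny_grid(), matrix(0, 6, 8), species = "sp",
                     scenario_id = "w"))
    rr <- build_risk_report(threats, list(ch))$risk
    oracle_sp <- unique(unlist(strsplit(sp_lists[flag & sp_lists != ""], ";")))
    oracle_eco <- unique(eco[flag & eco != ""])
    expect_equal(rr$n_reserves, sum(flag))
    expect_equal(rr$n_affected_plant_species, length(oracle_sp))
    expect_equal(rr$n_affected_ecosystems, length(oracle_eco))
    expect_equal(rr$total_area_km2, sum(threats$overlap_km2[flag]))
  }
})
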