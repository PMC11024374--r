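test_that("generated city honours counts and is deterministic", {
  cfg <- small_config(seed = 11)
  city1 <- generate_city(cfg)
  city2 <- generate_city(cfg)
  expect_equal(nrow(city1$residences), 150L)
  expect_equal(unname(table(factor(city1$parks$class,
                                   levels = park_classes))[park_classes]),
               unname(cfg$park_mix[park_classes]),
               ignore_attr = TRUE)
  # byte-identical on repeat generation
  expect_identical(serialize(city1[setdiff(names(city1), "roads")], NULL),
                   serialize(city2[setdiff(names(city2), "roads")], NULL))
  expect_identical(igraph::as_data_frame(city1$roads, "both"),
                   igraph::as_data_frame(city2$roads, "both"))
})

test_that("configuration errors name the offending field", {
  expect_error(scenario_config(core_density_ratio = 0.5),
               "core_density_ratio")
  expect_error(scenario_config(park_area_ranges = list(
    community = c(0.5, 3), regional = c(2, 5), citywide = c(5, 25),
    comprehensive = c(25, 35))), "park_area_ranges")
  expect_error(small_config(road_spacing = -10), "road_spacing")
})

test_that("population equals households times block mean household size", {
  city <- generate_city(small_config(seed = 5))
  mhs <- city$blocks$mean_household_size[match(city$residences$block_id,
                                               city$blocks$id)]
  expect_equal(city$residences$population,
               round(city$residences$households * mhs))
  # every residence lies inside exactly one block
  b <- city$blocks
  inside <- vapply(seq_len(nrow(city$residences)), function(i) {
    sum(city$residences$x[i] >= b$xmin & city$residences$x[i] < b$xmax + 1e-9 &
        city$residences$y[i] >= b$ymin & city$residences$y[i] < b$ymax + 1e-9)
  }, numeric(1))
  expect_true(all(inside >= 1))
})

test_that("noise-free positive price gradient decreases with distance and
           is positively spatially autocorrelated", {
  cfg <- small_config(seed = 3, price_slope = 1.5, price_noise_amp = 0,
                      price_plateau = 1e9)
  city <- generate_city(cfg)
  d <- sqrt((city$residences$x - 1500)^2 + (city$residences$y - 1500)^2)
  o <- order(d)
  expect_true(all(diff(city$residences$price[o]) <= 0))
  # brute-force global Moran under the equity module's weights
  w <- build_weights(city$residences, k = 8)
  W <- weights_matrix(w)
  x <- city$residences$price
  z <- (x - mean(x)) / (sd(x) * sqrt((w$n - 1) / w$n))
  I <- mean(sapply(seq_len(w$n), function(i) z[i] * sum(W[i, ] * z)))
  expect_gt(I, 0)
})

test_that("core density exceeds periphery by about the configured ratio", {
  ratios <- vapply(1:20, function(s) {
    city <- generate_city(small_config(seed = 100 + s,
                                       n_residences = 250L))
    core <- in_core(city$residences$x, city$residences$y, city$extent)
    # core holds a quarter of the area: density ratio = 3 * n_core / n_peri
    3 * sum(core) / sum(!core)
  }, numeric(1))
  expect_gt(mean(ratios), 4 * 0.75)
  expect_lt(mean(ratios), 4 * 1.25)
})

test_that("park land-cover rasters have the requested patch structure", {
  park <- list(id = "T", w = 60, h = 40)
  solid <- generate_park_landcover(park, n_patches = 1, seed = 2,
                                   green_fraction = 1)
  expect_true(all(solid$grid == 1L))
  lc4 <- generate_park_landcover(park, n_patches = 4, seed = 2,
                                 green_fraction = 0.6)
  expect_equal(max(oracle_label(lc4$grid)), 4)
  lc4b <- generate_park_landcover(park, n_patches = 4, seed = 2,
                                  green_fraction = 0.6)
  expect_identical(lc4$grid, lc4b$grid)
  expect_error(generate_park_landcover(list(w = 2, h = 2), n_patches = 9,
                                       seed = 1), "infeasible")
  # patch counts hold across fragmentation levels and seeds
  for (np in c(2, 7, 12)) {
    lc <- generate_park_landcover(park, n_patches = np, seed = 30 + np,
                                  green_fraction = 0.5)
    expect_equal(max(oracle_label(lc$grid)), np)
  }
})

test_that("every entrance lies on its park boundary and is a road vertex", {
  city <- generate_city(small_config(seed = 9))
  vn <- igraph::vertex_attr(city$roads, "name")
  expect_true(all(city$entrances$node %in% vn))
  for (i in seq_len(nrow(city$entrances))) {
    e <- city$entrances[i, ]
    p <- city$parks[city$parks$id == e$park_id, ]
    on_x <- abs(abs(e$x - p$cx) - p$w / 2) < 1e-6 &&
      abs(e$y - p$cy) <= p$h / 2 + 1e-6
    on_y <- abs(abs(e$y - p$cy) - p$h / 2) < 1e-6 &&
      abs(e$x - p$cx) <= p$w / 2 + 1e-6
    expect_true(on_x || on_y)
  }
})

test_that("city round-trips losslessly through the writers and readers", {
  city <- generate_city(small_config(seed = 21, n_residences = 60L))
  dir <- withr::local_tempdir()
  write_city(city, dir)
  back <- read_city(dir)
  expect_equal(back$parks, city$parks, tolerance = 1e-12)
  expect_equal(back$residences, city$residences, tolerance = 1e-12)
  expect_equal(back$entrances, city$entrances, tolerance = 1e-12)
  expect_equal(back$parcels, city$parcels, tolerance = 1e-12)
  expect_equal(back$blocks, city$blocks, tolerance = 1e-12)
  expect_equal(sum(city$parks$id %in% sub("\\.asc$", "",
    list.files(file.path(dir, "landcover")))), nrow(city$parks))
  # road edge lengths equal geometric lengths between endpoint coordinates
  g <- back$roads
  el <- igraph::as_edgelist(g, names = FALSE)
  vx <- igraph::vertex_attr(g, "x"); vy <- igraph::vertex_attr(g, "y")
  geom <- sqrt((vx[el[, 1]] - vx[el[, 2]])^2 +
                 (vy[el[, 1]] - vy[el[, 2]])^2)
  expect_lt(max(abs(geom - igraph::edge_attr(g, "length_m"))), 1e-6)
  # land-cover rasters round-trip through the ASCII-grid reader
  lcs <- city_landcovers(city)
  pid <- city$parks$id[1]
  rt <- read_asc(file.path(dir, "landcover", paste0(pid, ".asc")))
  expect_identical(rt$grid == 1, lcs[[pid]]$grid == 1L)
  expect_equal(rt$cell, lcs[[pid]]$cell)
})
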