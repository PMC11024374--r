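test_that("blind-zone rules separate explicit, implicit and served", {
  # residence 3500 m from the only entrance: explicit
  city <- toy_line_city(
    parks = data.frame(x = 0, S_hm2 = 1, class = "comprehensive"),
    residences = data.frame(x = c(3500, 200, 2900),
                            population = c(50, 10, 10)))
  q <- toy_quality(city, C = 60)
  dist <- residence_park_distances(city)
  acc <- access_table(city, q, w_S_only, dist = dist)
  bz <- identify_blind_zones(acc, dist)
  expect_equal(bz$kind[bz$residence_id == "R01"], "explicit")
  expect_equal(bz$kind[bz$residence_id == "R02"], "none")
  expect_equal(bz$kind[bz$residence_id == "R03"], "implicit")

  # covered but crowded out: a huge co-located population next to a small
  # park keeps scores in the bottom class, while a quiet residence next to
  # a large park is fully served
  city2 <- toy_line_city(
    parks = data.frame(x = c(0, 9000), S_hm2 = c(1, 30),
                       class = c("community", "comprehensive")),
    residences = data.frame(x = c(10, 60, 110, 9000, 8600),
                            population = c(90000, 95000, 80000, 20, 30)))
  q2 <- toy_quality(city2, C = c(2, 60))
  dist2 <- residence_park_distances(city2)
  acc2 <- access_table(city2, q2, w_S_only, dist = dist2)
  bz2 <- identify_blind_zones(acc2, dist2)
  crowded <- bz2$kind[match(c("R01", "R02", "R03"), bz2$residence_id)]
  expect_true(all(crowded == "implicit"))
  expect_equal(bz2$kind[bz2$residence_id == "R04"], "none")
})

test_that("target selection is the union of low access and LL residences", {
  acc <- data.frame(residence_id = sprintf("R%d", 1:6),
                    class = c(0L, 1L, 2L, 3L, 1L, 4L))
  lisa <- list(id = acc$residence_id,
               category = c("NS", "NS", "LL", "LL", "LL", "HH"))
  t <- select_targets(acc, lisa)
  expect_setequal(t$residence_id, c("R1", "R2", "R3", "R4", "R5"))
  expect_equal(t$provenance[t$residence_id == "R2"], "low_access")
  expect_equal(t$provenance[t$residence_id == "R3"], "LL")
  expect_equal(t$provenance[t$residence_id == "R5"], "both")
  # brute-force set arithmetic
  expect_equal(nrow(t), length(union(which(acc$class <= 1),
                                     which(lisa$category == "LL"))))
})

test_that("K-curve is non-increasing and finds the knee of 3 blobs", {
  hits <- 0
  for (s in 1:10) {
    set.seed(200 + s)
    blob <- function(cx, cy) cbind(rnorm(30, cx, 0.03), rnorm(30, cy, 0.03))
    feats <- rbind(blob(0, 0), blob(1, 0), blob(0.5, 1))
    kc <- kmeans_curve(feats, k_range = 1:8, n_init = 10, seed = s)
    v <- kc$curve$avg_farthest
    # non-increasing within clustering tolerance (local-optimum jitter)
    expect_true(all(diff(v) <= 0.02 * (v[1] + 1e-12)))
    if (kc$chosen_k == 3) hits <- hits + 1
  }
  expect_gte(hits, 8)
  # identical points: flat zero curve, k = 1
  same <- matrix(1, 20, 2)
  kc0 <- kmeans_curve(same, k_range = 1:5, seed = 1)
  expect_true(all(kc0$curve$avg_farthest == 0))
  expect_equal(kc0$chosen_k, 1L)
  expect_equal(kmeans_curve(same, k_range = 1:5, seed = 1,
                            k_override = 4)$chosen_k, 4L)
  expect_error(kmeans_curve(matrix(rnorm(10), 5), k_range = 1:10),
               "more clusters")
})

test_that("PSO converges on degenerate and weighted point sets", {
  # single target: the site lands on it
  t1 <- data.frame(x = 420, y = 310, population = 7)
  p1 <- pso_site_selection(t1, k = 1, bounds = c(0, 1000, 0, 1000),
                           n_iter = 150, seed = 3)
  expect_lt(p1$objective, 7 * 1)       # within ~1 m of the optimum
  expect_true(all(diff(p1$trace) <= 0))
  # determinism
  p1b <- pso_site_selection(t1, k = 1, bounds = c(0, 1000, 0, 1000),
                            n_iter = 150, seed = 3)
  expect_identical(p1$sites, p1b$sites)

  # k = 1 on 5 weighted points vs 1 m grid search
  set.seed(17)
  t5 <- data.frame(x = runif(5, 20, 180), y = runif(5, 20, 180),
                   population = sample(1:50, 5))
  p5 <- pso_site_selection(t5, k = 1, bounds = c(0, 200, 0, 200),
                           n_iter = 250, seed = 7)
  expect_true(all(diff(p5$trace) <= 0))
  gx <- seq(0, 200, by = 1)
  best <- Inf
  for (xx in gx) {
    dx2 <- (t5$x - xx)^2
    f <- sapply(gx, function(yy) sum(t5$population *
                                       sqrt(dx2 + (t5$y - yy)^2)))
    best <- min(best, min(f))
  }
  expect_lte(p5$objective, best * 1.01)

  # more sites can only help on separated blobs
  set.seed(18)
  blobs <- data.frame(x = c(rnorm(10, 50, 2), rnorm(10, 950, 2)),
                      y = c(rnorm(10, 50, 2), rnorm(10, 950, 2)),
                      population = 1)
  f1 <- pso_site_selection(blobs, 1, c(0, 1000, 0, 1000), n_iter = 150,
                           seed = 2)$objective
  f2 <- pso_site_selection(blobs, 2, c(0, 1000, 0, 1000), n_iter = 150,
                           seed = 2)$objective
  expect_lt(f2, f1)
  expect_error(pso_site_selection(t1, k = 1, bounds = c(0, 10, 0, 10)),
               "bounds")
})

test_that("sites snap to parcels with class from the area cutoffs", {
  parcels <- data.frame(id = c("C1", "C2", "C3"),
                        cx = c(100, 110, 4000), cy = c(100, 100, 4000),
                        w = c(100, 200, 400), h = c(150, 250, 650),
                        area_hm2 = c(1.5, 10, 26))
  plan <- assign_park_classes(rbind(c(101, 101)), parcels)
  expect_equal(plan$parcel_id, "C1")
  expect_equal(plan$class, "community")
  expect_equal(plan$radius_m, 500)
  plan2 <- assign_park_classes(rbind(c(109, 99)), parcels)
  expect_equal(plan2$class, "citywide")
  expect_equal(plan2$radius_m, 2000)
  # conflict: two sites nearest the same parcel; second takes next-nearest
  plan3 <- assign_park_classes(rbind(c(100, 100), c(100, 100),
                                     c(3999, 3999)), parcels)
  expect_equal(plan3$parcel_id, c("C1", "C2", "C3"))
  expect_equal(plan3$class, c("community", "citywide", "comprehensive"))
  expect_error(assign_park_classes(matrix(0, 4, 2), parcels), "short by 1")
})

test_that("empty plans change nothing and real plans only add supply", {
  city <- generate_city(small_config(seed = 71, n_residences = 100L))
  q <- park_quality(city)
  eq <- list(k = 6, n_perm = 99, alpha = 0.05)
  ev0 <- suppressMessages(evaluate_plan(city, data.frame(), q, equity = eq,
                                        seed = 5))
  expect_true(all(unlist(ev0$deltas$mean_accessibility) == 0))
  expect_true(all(unlist(ev0$deltas$zero_count) == 0))
  expect_identical(ev0$deltas$lisa_counts_before,
                   ev0$deltas$lisa_counts_after)

  # a park in range of residences strictly increases mean accessibility
  parcels <- city$parcels
  plan <- assign_park_classes(rbind(c(city$extent[1] / 2,
                                      city$extent[2] / 2)), parcels)
  ev1 <- suppressMessages(evaluate_plan(city, plan, q, equity = eq,
                                        seed = 5,
                                        before = ev0$before))
  expect_gt(ev1$deltas$mean_accessibility[["A_comprehensive"]], 0)
  expect_false(isTRUE(all.equal(ev1$after$access$A_comprehensive,
                                ev0$before$access$A_comprehensive)))
  # additive consistency: stripping the new parks out of the after-city
  # and recomputing reproduces the before table exactly
  city_after <- parkequity:::apply_plan(city, plan, seed = 5)
  new_ids <- grep("^N", city_after$parks$id, value = TRUE)
  stripped <- city_after
  stripped$parks <- stripped$parks[!stripped$parks$id %in% new_ids, ]
  drop_ent <- stripped$entrances$park_id %in% new_ids
  stripped$roads <- igraph::delete_vertices(
    stripped$roads, stripped$entrances$node[drop_ent])
  stripped$entrances <- stripped$entrances[!drop_ent, ]
  dist_s <- residence_park_distances(stripped)
  acc_s <- suppressMessages(access_table(stripped, q, dist = dist_s))
  expect_equal(acc_s$A_comprehensive,
               ev0$before$access$A_comprehensive, tolerance = 1e-9)
})
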