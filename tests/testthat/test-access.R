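test_that("Gaussian decay kernel has the exact endpoint and half values", {
  expect_identical(gaussian_decay(0, 2000), 1)
  expect_identical(gaussian_decay(2000, 2000), 0)
  expect_identical(gaussian_decay(2500, 2000), 0)
  # direct evaluation of the kernel at half the radius
  direct <- (exp(-0.5 * 0.5^2) - exp(-0.5)) / (1 - exp(-0.5))
  expect_equal(gaussian_decay(1000, 2000), direct, tolerance = 1e-12)
  expect_equal(direct, 0.7013666, tolerance = 1e-6)
  # strictly decreasing and continuous at the boundary
  d <- seq(0, 2000, length.out = 1000)
  g <- gaussian_decay(d, 2000)
  expect_true(all(diff(g) < 0))
  expect_lt(gaussian_decay(1999.999, 2000), 1e-5)
})

test_that("network distances snap, add connectors and match Floyd-Warshall", {
  # single 700 m edge
  g <- igraph::make_empty_graph(2, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = c("a", "b"))
  g <- igraph::set_vertex_attr(g, "x", value = c(0, 700))
  g <- igraph::set_vertex_attr(g, "y", value = c(0, 0))
  g <- igraph::add_edges(g, c("a", "b"), length_m = 700)
  pts <- data.frame(id = c("o", "p"), x = c(0, 700), y = c(0, 0))
  d <- network_distance(g, pts[1, ], pts[2, ], cutoff = 1e5)
  expect_equal(d$d, 700)
  # same node: zero plus connectors
  d0 <- network_distance(g, data.frame(id = "o", x = 3, y = 4),
                         data.frame(id = "p", x = 0, y = 0), cutoff = 1e5)
  expect_equal(d0$d, 5)
  # snap limit excludes far points with a warning
  expect_warning(
    far <- network_distance(g, data.frame(id = "o", x = 0, y = 9000),
                            pts[2, ], cutoff = 1e5), "snap limit")
  expect_equal(nrow(far), 0)
  expect_error(network_distance(igraph::make_empty_graph(0), pts, pts, 10),
               "empty")

  # 5x5 jittered grid vs all-pairs brute force
  city <- generate_city(small_config(seed = 2, extent = c(1200, 1200),
                                     road_spacing = 300,
                                     n_residences = 20L,
                                     park_mix = c(community = 1L,
                                                  regional = 0L,
                                                  citywide = 0L,
                                                  comprehensive = 0L),
                                     n_candidate_parcels = 2L))
  g5 <- city$roads
  n <- igraph::vcount(g5)
  el <- igraph::as_edgelist(g5, names = FALSE)
  len <- igraph::edge_attr(g5, "length_m")
  D <- matrix(Inf, n, n); diag(D) <- 0
  for (e in seq_len(nrow(el))) {
    D[el[e, 1], el[e, 2]] <- min(D[el[e, 1], el[e, 2]], len[e])
    D[el[e, 2], el[e, 1]] <- D[el[e, 1], el[e, 2]]
  }
  Dfw <- oracle_floyd_warshall(D)
  vn <- igraph::vertex_attr(g5, "name")
  vx <- igraph::vertex_attr(g5, "x"); vy <- igraph::vertex_attr(g5, "y")
  set.seed(4)
  pick_o <- sample(n, 6); pick_d <- sample(n, 6)
  got <- network_distance(
    g5, data.frame(id = vn[pick_o], x = vx[pick_o], y = vy[pick_o]),
    data.frame(id = vn[pick_d], x = vx[pick_d], y = vy[pick_d]),
    cutoff = 1e7)
  for (r in seq_len(nrow(got))) {
    i <- match(got$origin_id[r], vn); j <- match(got$dest_id[r], vn)
    expect_equal(got$d[r], Dfw[i, j], tolerance = 1e-9)
  }
})

test_that("composite park supply is the weighted linear combination", {
  q1 <- data.frame(park_id = "p", S_hm2 = 10, ESV = 0, FCs_hm2 = 0)
  expect_equal(unname(park_supply(q1)), 7.236)
  q0 <- data.frame(park_id = "p", S_hm2 = 0, ESV = 0, FCs_hm2 = 0)
  expect_equal(unname(park_supply(q0)), 0)
  q2 <- data.frame(park_id = "p", S_hm2 = 12.5, ESV = -8.26, FCs_hm2 = 3.1)
  expect_equal(unname(park_supply(q2)),
               0.7236 * 12.5 + 0.1931 * 3.1 + 0.0833 * (-8.26))
  qneg <- data.frame(park_id = "p", S_hm2 = 0.1, ESV = -100, FCs_hm2 = 0)
  expect_warning(cneg <- park_supply(qneg), "floored")
  expect_equal(unname(cneg), 0)
  expect_error(park_supply(data.frame(park_id = "p", S_hm2 = 1)), "lacks")
})

test_that("supply-demand ratios and accessibility match hand examples", {
  # one park (C = 50), one residence (P = 100) at distance 0 -> R = 0.5
  city <- toy_line_city(parks = data.frame(x = 0, S_hm2 = 1,
                                           class = "citywide"),
                        residences = data.frame(x = 0, population = 100))
  q <- toy_quality(city, C = 50)
  cc <- catchment_config("type_specific")
  dist <- residence_park_distances(city)
  rat <- supply_demand_ratios(city, q, cc, dist, w_S_only)
  expect_equal(rat$R, 0.5)
  acc <- accessibility(rat, dist, city$residences)
  expect_equal(acc$A, 0.5)  # G(0) * R

  # two residences at d0/2: R = C / (G(d0/2) * 200) with C chosen so R=0.5
  G <- (exp(-0.125) - exp(-0.5)) / (1 - exp(-0.5))
  city2 <- toy_line_city(
    parks = data.frame(x = 0, S_hm2 = 1, class = "citywide"),
    residences = data.frame(x = c(-1000, 1000),
                            population = c(100, 100)))
  q2 <- toy_quality(city2, C = G * 200 * 0.5)
  dist2 <- residence_park_distances(city2)
  rat2 <- supply_demand_ratios(city2, q2, catchment_config("type_specific"),
                               dist2, w_S_only)
  expect_equal(rat2$R, 0.5, tolerance = 1e-12)

  # park with no residence in its catchment has R = 0 by convention
  city3 <- toy_line_city(
    parks = data.frame(x = 0, S_hm2 = 1, class = "community"),
    residences = data.frame(x = 2800, population = 50))
  q3 <- toy_quality(city3, C = 10)
  expect_message(
    rat3 <- supply_demand_ratios(city3, q3,
                                 catchment_config("type_specific"),
                                 residence_park_distances(city3), w_S_only),
    "no weighted demand")
  expect_equal(rat3$R, 0)
  acc3 <- accessibility(rat3, residence_park_distances(city3),
                        city3$residences)
  expect_equal(acc3$A, 0)
})

test_that("accessibility satisfies conservation and matches a double loop", {
  city <- toy_line_city(
    parks = data.frame(x = c(500, 2600), S_hm2 = c(1, 1),
                       class = c("citywide", "comprehensive")),
    residences = data.frame(x = c(0, 1200, 3100),
                            population = c(120, 340, 80)))
  q <- toy_quality(city, C = c(50, 80))
  cc <- catchment_config("type_specific")
  dist <- residence_park_distances(city)
  rat <- supply_demand_ratios(city, q, cc, dist, w_S_only)
  acc <- accessibility(rat, dist, city$residences)
  # brute-force double loop over residences and parks
  d0s <- c(citywide = 2000, comprehensive = 3000)
  px <- city$parks$cx; rx <- city$residences$x
  P <- city$residences$population; C <- c(50, 80)
  D <- sapply(1:2, function(j) {
    sum(sapply(1:3, function(i) {
      d <- abs(rx[i] - px[j]); d0 <- d0s[[city$parks$class[j]]]
      if (d < d0) (exp(-0.5 * (d / d0)^2) - exp(-0.5)) / (1 - exp(-0.5)) *
        P[i] else 0
    }))
  })
  R <- C / D
  A_hand <- sapply(1:3, function(i) {
    sum(sapply(1:2, function(j) {
      d <- abs(rx[i] - px[j]); d0 <- d0s[[city$parks$class[j]]]
      if (d < d0) (exp(-0.5 * (d / d0)^2) - exp(-0.5)) / (1 - exp(-0.5)) *
        R[j] else 0
    }))
  })
  expect_equal(acc$A, A_hand, tolerance = 1e-12)
  expect_equal(sum(acc$A * P), sum(C), tolerance = 1e-9)
})

test_that("uniform-mode accessibility reduces to classic G2SFCA under
           S-only weights", {
  city <- generate_city(small_config(seed = 41))
  q <- park_quality(city)
  dist <- residence_park_distances(city)
  cc <- catchment_config("uniform", d0_uniform = 1500)
  rat <- supply_demand_ratios(city, q, cc, dist, w_S_only)
  acc <- accessibility(rat, dist, city$residences)
  # classic unweighted G2SFCA: supply = park area only
  P <- setNames(city$residences$population, city$residences$id)
  S <- setNames(q$S_hm2, q$park_id)
  g <- gaussian_decay(dist$d, 1500)
  Dj <- tapply(g * P[dist$residence_id], dist$park_id, sum)
  Rj <- S[names(Dj)] / Dj
  Ai <- tapply(gaussian_decay(dist$d, 1500) * Rj[dist$park_id],
               dist$residence_id, sum)
  expect_equal(acc$A[match(names(Ai), acc$residence_id)],
               as.vector(Ai), tolerance = 1e-12)
})

test_that("larger walking radii never reduce pointwise access at fixed
           ratios and never create zero-accessibility residences", {
  for (s in 1:3) {
    city <- generate_city(small_config(seed = 60 + s))
    q <- park_quality(city)
    dist <- residence_park_distances(city, cutoff = 4000)
    cc0 <- catchment_config("uniform", d0_uniform = 500)
    rat <- suppressMessages(supply_demand_ratios(city, q, cc0, dist))
    prevA <- NULL; prev_zero <- NULL
    for (r in c(500, 1000, 2000, 3000)) {
      # fixed R_j: each A_i is non-decreasing in d0 (kernel monotonicity)
      ratr <- rat; ratr$d0 <- r
      A_fixed <- accessibility(ratr, dist, city$residences)$A
      if (!is.null(prevA)) expect_true(all(A_fixed >= prevA - 1e-12))
      prevA <- A_fixed
      # full recomputation: zero-accessibility counts are non-increasing
      ccr <- catchment_config("uniform", d0_uniform = r)
      ratf <- suppressMessages(supply_demand_ratios(city, q, ccr, dist))
      zero <- sum(accessibility(ratf, dist, city$residences)$A == 0)
      if (!is.null(prev_zero)) expect_lte(zero, prev_zero)
      prev_zero <- zero
    }
  }
})

test_that("geometric-interval classification uses multiplicative breaks", {
  r <- classify_geometric(c(1, 10, 100, 1000), n_classes = 3)
  expect_equal(r$breaks, c(10, 100), tolerance = 1e-12)
  expect_equal(r$class, c(1, 1, 2, 3))
  expect_equal(r$low_threshold, 10)
  # zeros form their own class; one positive value stays classified
  r2 <- classify_geometric(c(0, 0, 0, 5), n_classes = 5)
  expect_equal(r2$class, c(0, 0, 0, 1))
  expect_warning(r3 <- classify_geometric(c(0, 0), n_classes = 3),
                 "all scores")
  expect_equal(r3$class, c(0, 0))
  # lognormal scores: counts match independent binning with the same breaks
  set.seed(8)
  v <- rlnorm(200, 1, 1)
  r4 <- classify_geometric(v, n_classes = 5)
  a <- min(v); M <- max(v)
  br <- a * (M / a)^((1:4) / 5)
  hand <- cut(v, breaks = c(0, br, Inf), labels = FALSE)
  expect_equal(unname(table(r4$class)), unname(table(hand)))
  expect_equal(r4$class, hand)
})
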