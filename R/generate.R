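#' Generate a synthetic city
#'
#' Draws a complete synthetic city from a [scenario_config()]: a jittered
#' grid road network, residences sampled from a two-level core/periphery
#' density, block populations, a centre-peaked and spatially autocorrelated
#' housing-price surface, rectangular parks of the four size classes with
#' 1-4 boundary entrances snapped into the road network, and candidate
#' parcels for future parks. All coordinates are abstract planar meters
#' with the origin at the extent's corner.
#'
#' The generator is fully deterministic given `config$seed`: two calls with
#' the same configuration produce identical cities.
#'
#' @param config a [scenario_config()].
#' @return an object of class `city`: a list with elements `parks`
#'   (data.frame: id, class, cx, cy, w, h, area_hm2, hard_fraction,
#'   n_patches, green_fraction), `entrances` (data.frame: id, park_id, x, y,
#'   node — the entrance's own vertex name in `roads`), `residences`
#'   (data.frame: id, x, y, households, block_id, population, price),
#'   `roads` (an [igraph][igraph::igraph-package] graph with vertex
#'   coordinates `x`,`y` and edge attribute `length_m`), `parcels`
#'   (data.frame like `parks` minus quality fields), `blocks` (data.frame:
#'   id, xmin, xmax, ymin, ymax, mean_household_size, census_population),
#'   `extent`, and `config`.
#' @examples
#' city <- generate_city(scenario_config(seed = 7, n_residences = 120,
#'   extent = c(3000, 3000), park_mix = c(community = 2, regional = 1,
#'   citywide = 1, comprehensive = 0)))
#' city
#' @export
generate_city <- function(config) {
  validate_config(config)
  set.seed(config$seed)
  roads <- make_road_grid(config)
  blocks <- make_blocks(config)
  residences <- sample_residences(config, blocks)
  residences$price <- price_surface(config, residences$x, residences$y)
  blocks$census_population <- vapply(blocks$id, function(b) {
    sum(residences$population[residences$block_id == b])
  }, numeric(1))
  parks <- place_parks(config)
  ent <- place_entrances(config, parks, roads)
  parcels <- place_parcels(config, parks)
  city <- structure(
    list(parks = parks, entrances = ent$entrances, residences = residences,
         roads = ent$roads, parcels = parcels, blocks = blocks,
         extent = config$extent, config = config),
    class = "city")
  city
}

#' @export
print.city <- function(x, ...) {
  cat("Synthetic city\n")
  cat(sprintf("  extent     : %g x %g m\n", x$extent[1], x$extent[2]))
  cat(sprintf("  residences : %d (population %s)\n", nrow(x$residences),
              format(sum(x$residences$population), big.mark = ",")))
  cat(sprintf("  parks      : %d (%s)\n", nrow(x$parks),
              paste(sprintf("%d %s", table(factor(x$parks$class,
                levels = park_classes)), park_classes), collapse = ", ")))
  cat(sprintf("  entrances  : %d; road nodes: %d; parcels: %d\n",
              nrow(x$entrances), igraph::vcount(x$roads), nrow(x$parcels)))
  invisible(x)
}

#' @export
plot.city <- function(x, ...) {
  plot(NA, xlim = c(0, x$extent[1]), ylim = c(0, x$extent[2]), asp = 1,
       xlab = "x (m)", ylab = "y (m)", main = "synthetic city", ...)
  el <- igraph::as_edgelist(x$roads, names = FALSE)
  vx <- igraph::vertex_attr(x$roads, "x")
  vy <- igraph::vertex_attr(x$roads, "y")
  segments(vx[el[, 1]], vy[el[, 1]], vx[el[, 2]], vy[el[, 2]],
           col = gray(0.8))
  points(x$residences$x, x$residences$y, pch = 16, cex = 0.3,
         col = "steelblue")
  with(x$parks, graphics::rect(cx - w / 2, cy - h / 2, cx + w / 2,
                               cy + h / 2, border = "forestgreen", lwd = 2))
  points(x$entrances$x, x$entrances$y, pch = 17, cex = 0.6, col = "darkred")
  invisible(x)
}

# ---- internal generator pieces -------------------------------------------

make_road_grid <- function(cfg) {
  W <- cfg$extent[1]; H <- cfg$extent[2]; s <- cfg$road_spacing
  xs <- seq(0, W, length.out = max(2L, floor(W / s) + 1L))
  ys <- seq(0, H, length.out = max(2L, floor(H / s) + 1L))
  nx <- length(xs); ny <- length(ys)
  g <- expand.grid(ix = seq_len(nx), iy = seq_len(ny))
  jit <- cfg$road_jitter * s
  px <- pmin(pmax(xs[g$ix] + runif(nrow(g), -jit, jit), 0), W)
  py <- pmin(pmax(ys[g$iy] + runif(nrow(g), -jit, jit), 0), H)
  name <- sprintf("n%d_%d", g$ix, g$iy)
  idx <- function(ix, iy) (iy - 1L) * nx + ix
  he <- g[g$ix < nx, ]; ve <- g[g$iy < ny, ]
  edges <- rbind(
    cbind(idx(he$ix, he$iy), idx(he$ix + 1L, he$iy)),
    cbind(idx(ve$ix, ve$iy), idx(ve$ix, ve$iy + 1L)))
  graph <- igraph::make_empty_graph(n = nrow(g), directed = FALSE)
  graph <- igraph::set_vertex_attr(graph, "name", value = name)
  graph <- igraph::set_vertex_attr(graph, "x", value = px)
  graph <- igraph::set_vertex_attr(graph, "y", value = py)
  graph <- igraph::add_edges(graph, t(edges))
  el <- igraph::as_edgelist(graph, names = FALSE)
  len <- sqrt((px[el[, 1]] - px[el[, 2]])^2 + (py[el[, 1]] - py[el[, 2]])^2)
  igraph::set_edge_attr(graph, "length_m", value = len)
}

make_blocks <- function(cfg) {
  nx <- cfg$blocks_nx; ny <- cfg$blocks_ny
  bx <- seq(0, cfg$extent[1], length.out = nx + 1)
  by <- seq(0, cfg$extent[2], length.out = ny + 1)
  g <- expand.grid(ix = seq_len(nx), iy = seq_len(ny))
  data.frame(
    id = sprintf("B%d_%d", g$ix, g$iy),
    xmin = bx[g$ix], xmax = bx[g$ix + 1],
    ymin = by[g$iy], ymax = by[g$iy + 1],
    mean_household_size = round(runif(nrow(g),
      cfg$mean_household_size_range[1], cfg$mean_household_size_range[2]), 2),
    census_population = NA_real_,
    stringsAsFactors = FALSE)
}

# Rejection sampling from the three-level density: dense core, built-up
# periphery, sparse exurban fringe.
sample_residences <- function(cfg, blocks) {
  n <- cfg$n_residences
  bur <- cfg$built_up_radius %||% (0.4 * min(cfg$extent))
  frd <- cfg$fringe_density_ratio %||% 1
  xs <- numeric(0); ys <- numeric(0)
  while (length(xs) < n) {
    m <- max(2L * (n - length(xs)), 64L)
    px <- runif(m, 0, cfg$extent[1]); py <- runif(m, 0, cfg$extent[2])
    d <- sqrt((px - cfg$extent[1] / 2)^2 + (py - cfg$extent[2] / 2)^2)
    p_accept <- ifelse(in_core(px, py, cfg$extent), 1,
                       ifelse(d <= bur, 1, frd) / cfg$core_density_ratio)
    keep <- runif(m) < p_accept
    xs <- c(xs, px[keep]); ys <- c(ys, py[keep])
  }
  xs <- xs[seq_len(n)]; ys <- ys[seq_len(n)]
  hh <- sample(cfg$households_range[1]:cfg$households_range[2], n,
               replace = TRUE)
  nxb <- cfg$blocks_nx
  ix <- pmin(pmax(findInterval(xs, blocks$xmin[seq_len(nxb)]), 1L), nxb)
  iy <- pmin(pmax(findInterval(ys, unique(blocks$ymin)), 1L), cfg$blocks_ny)
  bid <- sprintf("B%d_%d", ix, iy)
  mhs <- blocks$mean_household_size[match(bid, blocks$id)]
  data.frame(id = sprintf("R%04d", seq_len(n)), x = xs, y = ys,
             households = hh, block_id = bid,
             population = round(hh * mhs), price = NA_real_,
             stringsAsFactors = FALSE)
}

# Centre-peaked gradient plus smoothed-white-noise spatial autocorrelation.
price_surface <- function(cfg, x, y) {
  cx <- cfg$extent[1] / 2; cy <- cfg$extent[2] / 2
  d <- sqrt((x - cx)^2 + (y - cy)^2)
  plateau <- cfg$price_plateau %||% (0.4 * min(cfg$extent))
  base <- cfg$price_base - cfg$price_slope * pmin(d, plateau)
  if (cfg$price_noise_amp <= 0) return(pmax(base, 0.1 * cfg$price_base))
  L <- cfg$price_noise_range
  g <- L / 2
  gx <- seq(-L, cfg$extent[1] + L, by = g)
  gy <- seq(-L, cfg$extent[2] + L, by = g)
  z <- matrix(rnorm(length(gx) * length(gy)), length(gx), length(gy))
  # separable box filter of half-width L approximates a correlation
  # length-L Gaussian process without GP machinery
  r <- max(1L, round(L / g))
  z <- apply(z, 2, running_mean, r = r)
  z <- t(apply(z, 1, running_mean, r = r))
  ixf <- (x - gx[1]) / g + 1; iyf <- (y - gy[1]) / g + 1
  ix0 <- pmin(pmax(floor(ixf), 1), length(gx) - 1)
  iy0 <- pmin(pmax(floor(iyf), 1), length(gy) - 1)
  fx <- ixf - ix0; fy <- iyf - iy0
  v <- z[cbind(ix0, iy0)] * (1 - fx) * (1 - fy) +
    z[cbind(ix0 + 1, iy0)] * fx * (1 - fy) +
    z[cbind(ix0, iy0 + 1)] * (1 - fx) * fy +
    z[cbind(ix0 + 1, iy0 + 1)] * fx * fy
  v <- (v - mean(v)) / max(sd(v), 1e-12)
  pmax(base + cfg$price_noise_amp * v, 0.1 * cfg$price_base)
}

running_mean <- function(v, r) {
  n <- length(v)
  cs <- cumsum(c(0, v))
  lo <- pmax(seq_len(n) - r, 1L); hi <- pmin(seq_len(n) + r, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

rects_overlap <- function(a, b, buffer = 0) {
  !(a["x1"] + buffer < b["x0"] || b["x1"] + buffer < a["x0"] ||
      a["y1"] + buffer < b["y0"] || b["y1"] + buffer < a["y0"])
}

place_rect <- function(cfg, area_hm2, placed, core_prob, ring_max = NULL,
                       max_tries = 500L) {
  A <- area_hm2 * 1e4
  for (i in seq_len(max_tries)) {
    aspect <- runif(1, 0.6, 1.6)
    w <- sqrt(A * aspect); h <- A / w
    if (w > cfg$extent[1] || h > cfg$extent[2]) next
    cx <- runif(1, w / 2, cfg$extent[1] - w / 2)
    cy <- runif(1, h / 2, cfg$extent[2] - h / 2)
    if (!is.null(ring_max) &&
        sqrt((cx - cfg$extent[1] / 2)^2 + (cy - cfg$extent[2] / 2)^2) >
          ring_max) next
    if (in_core(cx, cy, cfg$extent) && runif(1) > core_prob) next
    r <- c(x0 = cx - w / 2, x1 = cx + w / 2, y0 = cy - h / 2, y1 = cy + h / 2)
    clash <- FALSE
    for (p in placed) if (rects_overlap(r, p, buffer = 30)) { clash <- TRUE; break }
    if (!clash) return(list(cx = cx, cy = cy, w = w, h = h, rect = r))
  }
  stop("invalid scenario config: field 'park_area_ranges'/'extent' leave no ",
       "room to place a park of ", round(area_hm2, 2), " hm2", call. = FALSE)
}

place_parks <- function(cfg) {
  rows <- list(); placed <- list(); k <- 0L
  for (cl in park_classes) {
    for (i in seq_len(cfg$park_mix[[cl]])) {
      k <- k + 1L
      a <- runif(1, cfg$park_area_ranges[[cl]][1], cfg$park_area_ranges[[cl]][2])
      ring <- cfg$park_ring_max %||% (0.38 * min(cfg$extent))
      pos <- place_rect(cfg, a, placed, cfg$core_park_prob, ring_max = ring)
      placed[[length(placed) + 1L]] <- pos$rect
      rows[[k]] <- data.frame(
        id = sprintf("P%02d", k), class = cl, cx = pos$cx, cy = pos$cy,
        w = pos$w, h = pos$h, area_hm2 = a,
        hard_fraction = runif(1, cfg$hard_fraction_range[1],
                              cfg$hard_fraction_range[2]),
        n_patches = sample(cfg$fragmentation_levels[1]:
                             cfg$fragmentation_levels[2], 1),
        green_fraction = runif(1, cfg$green_fraction_range[1],
                               cfg$green_fraction_range[2]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(id = character(), class = character(), cx = numeric(),
                      cy = numeric(), w = numeric(), h = numeric(),
                      area_hm2 = numeric(), hard_fraction = numeric(),
                      n_patches = integer(), green_fraction = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

# Nearest point on a rectangle boundary to an outside/inside point.
rect_boundary_point <- function(px, py, r) {
  qx <- pmin(pmax(px, r["x0"]), r["x1"])
  qy <- pmin(pmax(py, r["y0"]), r["y1"])
  inside <- px > r["x0"] & px < r["x1"] & py > r["y0"] & py < r["y1"]
  if (inside) {
    dl <- c(qx - r["x0"], r["x1"] - qx, qy - r["y0"], r["y1"] - qy)
    side <- which.min(dl)
    if (side == 1) qx <- r["x0"] else if (side == 2) qx <- r["x1"]
    else if (side == 3) qy <- r["y0"] else qy <- r["y1"]
  }
  c(unname(qx), unname(qy))
}

# Entrances become vertices of the road graph, connected to their nearest
# grid node, so "walking distance to an entrance" is a plain shortest path.
place_entrances <- function(cfg, parks, roads) {
  if (!nrow(parks)) {
    return(list(entrances = data.frame(id = character(), park_id = character(),
      x = numeric(), y = numeric(), node = character(),
      stringsAsFactors = FALSE), roads = roads))
  }
  vx <- igraph::vertex_attr(roads, "x")
  vy <- igraph::vertex_attr(roads, "y")
  vn <- igraph::vertex_attr(roads, "name")
  rows <- list()
  for (i in seq_len(nrow(parks))) {
    p <- parks[i, ]
    r <- c(x0 = p$cx - p$w / 2, x1 = p$cx + p$w / 2,
           y0 = p$cy - p$h / 2, y1 = p$cy + p$h / 2)
    dx <- pmax(r["x0"] - vx, 0, vx - r["x1"])
    dy <- pmax(r["y0"] - vy, 0, vy - r["y1"])
    d <- sqrt(dx^2 + dy^2)
    n_e <- sample(cfg$entrances_range[1]:cfg$entrances_range[2], 1)
    near <- order(d)[seq_len(min(n_e, length(d)))]
    pts <- vapply(near, function(j) rect_boundary_point(vx[j], vy[j], r),
                  numeric(2))
    keep <- !duplicated(round(t(pts), 2))
    near <- near[keep]; pts <- pts[, keep, drop = FALSE]
    for (k in seq_along(near)) {
      rows[[length(rows) + 1L]] <- data.frame(
        id = sprintf("E_%s_%d", p$id, k), park_id = p$id,
        x = pts[1, k], y = pts[2, k], node = vn[near[k]],
        stringsAsFactors = FALSE)
    }
  }
  ent <- do.call(rbind, rows)
  roads <- igraph::add_vertices(roads, nrow(ent), name = ent$id,
                                x = ent$x, y = ent$y)
  near_xy <- cbind(vx[match(ent$node, vn)], vy[match(ent$node, vn)])
  len <- sqrt((ent$x - near_xy[, 1])^2 + (ent$y - near_xy[, 2])^2)
  epairs <- rbind(ent$id, ent$node)
  roads <- igraph::add_edges(roads, as.vector(epairs), length_m = len)
  # the entrance vertex itself is the network supply point from here on
  ent$node <- ent$id
  list(entrances = ent, roads = roads)
}

place_parcels <- function(cfg, parks) {
  placed <- apply(parks, 1, function(p) {
    p <- as.list(p)
    c(x0 = as.numeric(p$cx) - as.numeric(p$w) / 2,
      x1 = as.numeric(p$cx) + as.numeric(p$w) / 2,
      y0 = as.numeric(p$cy) - as.numeric(p$h) / 2,
      y1 = as.numeric(p$cy) + as.numeric(p$h) / 2)
  })
  placed <- if (nrow(parks)) asplit(t(placed), 1) else list()
  placed <- lapply(placed, function(r) setNames(as.numeric(r),
                                                c("x0", "x1", "y0", "y1")))
  rows <- list()
  cls_prob <- c(community = 0.45, regional = 0.25, citywide = 0.2,
                comprehensive = 0.1)
  for (i in seq_len(cfg$n_candidate_parcels)) {
    cl <- sample(park_classes, 1, prob = cls_prob)
    a <- runif(1, cfg$park_area_ranges[[cl]][1], cfg$park_area_ranges[[cl]][2])
    pos <- place_rect(cfg, a, placed, core_prob = 1)
    placed[[length(placed) + 1L]] <- pos$rect
    rows[[i]] <- data.frame(id = sprintf("C%02d", i), cx = pos$cx,
                            cy = pos$cy, w = pos$w, h = pos$h, area_hm2 = a,
                            stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(id = character(), cx = numeric(), cy = numeric(),
                      w = numeric(), h = numeric(), area_hm2 = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
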