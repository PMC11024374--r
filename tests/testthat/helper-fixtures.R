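# Small scenario configurations and hand-built toy cities used across the
# unit tests. Everything is generated in code at test time.

small_config <- function(seed = 1L, n_residences = 150L, ...) {
  args <- list(
    seed = seed, extent = c(3000, 3000), road_spacing = 300,
    n_residences = n_residences,
    park_mix = c(community = 2L, regional = 1L, citywide = 2L,
                 comprehensive = 0L),
    park_area_ranges = list(community = c(0.5, 2), regional = c(2, 5),
                            citywide = c(5, 12), comprehensive = c(25, 30)),
    n_candidate_parcels = 8L, blocks_nx = 3L, blocks_ny = 3L,
    park_ring_max = 1500, fringe_density_ratio = 1)
  args[names(list(...))] <- list(...)
  do.call(scenario_config, args)
}

# A city on a straight east-west road: residences and park entrances sit
# exactly on road vertices, so network distances equal |x| differences.
# parks: data.frame(x, S_hm2, class); residences: data.frame(x, population)
toy_line_city <- function(parks, residences) {
  xs <- sort(unique(c(parks$x, residences$x)))
  n <- length(xs)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = sprintf("v%d", seq_len(n)))
  g <- igraph::set_vertex_attr(g, "x", value = xs)
  g <- igraph::set_vertex_attr(g, "y", value = rep(0, n))
  if (n > 1) {
    g <- igraph::add_edges(g, as.vector(rbind(seq_len(n - 1), 2:n)),
                           length_m = diff(xs))
  }
  node_of <- function(x) sprintf("v%d", match(x, xs))
  pk <- data.frame(
    id = sprintf("P%02d", seq_len(nrow(parks))),
    class = parks$class, cx = parks$x, cy = 0,
    w = 10, h = 10, area_hm2 = parks$S_hm2,
    hard_fraction = 0, n_patches = 1L, green_fraction = 1,
    stringsAsFactors = FALSE)
  ent <- data.frame(id = sprintf("E%02d", seq_len(nrow(parks))),
                    park_id = pk$id, x = parks$x, y = 0,
                    node = node_of(parks$x), stringsAsFactors = FALSE)
  res <- data.frame(id = sprintf("R%02d", seq_len(nrow(residences))),
                    x = residences$x, y = 0,
                    households = 1L, block_id = "B1",
                    population = residences$population,
                    price = 1000 + residences$x, stringsAsFactors = FALSE)
  structure(list(parks = pk, entrances = ent, residences = res, roads = g,
                 parcels = data.frame(), blocks = data.frame(),
                 extent = c(max(xs) + 1, 1), config = NULL),
            class = "city")
}

# Quality table where the composite supply C_j (under weights (1,0,0))
# equals the stated supply values.
toy_quality <- function(city, C) {
  data.frame(park_id = city$parks$id, S_hm2 = C, ESV = 0, FCs_hm2 = 0,
             stringsAsFactors = FALSE)
}

w_S_only <- c(S = 1, FCs = 0, ESV = 0)
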