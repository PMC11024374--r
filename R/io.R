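#' Write a city to disk in open interchange formats
#'
#' Emits `parks.geojson`, `entrances.geojson`, `residences.geojson`,
#' `parcels.geojson`, `roads.graphml` (edge attribute `length_m`),
#' `blocks.csv`, `config.yml` and one Esri ASCII grid per park under
#' `landcover/`. Everything is plain text and round-trips losslessly
#' through [read_city()].
#'
#' @param city a [generate_city()] result (or the equivalent structure).
#' @param dir output directory (created if missing).
#' @param landcovers optional named list of `landcover` objects per park id;
#'   by default they are generated deterministically via
#'   [city_landcovers()].
#' @return `dir`, invisibly.
#' @export
write_city <- function(city, dir, landcovers = city_landcovers(city)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory ", dir)
  write_geojson(park_features(city$parks), file.path(dir, "parks.geojson"))
  write_geojson(point_features(city$entrances, c("park_id", "node")),
                file.path(dir, "entrances.geojson"))
  write_geojson(point_features(city$residences,
                               c("households", "block_id", "population",
                                 "price")),
                file.path(dir, "residences.geojson"))
  write_geojson(parcel_features(city$parcels),
                file.path(dir, "parcels.geojson"))
  igraph::write_graph(city$roads, file.path(dir, "roads.graphml"),
                      format = "graphml")
  write.csv(city$blocks, file.path(dir, "blocks.csv"), row.names = FALSE)
  yaml::write_yaml(config_to_list(city$config), file.path(dir, "config.yml"))
  lcdir <- file.path(dir, "landcover")
  dir.create(lcdir, showWarnings = FALSE)
  for (pid in names(landcovers)) {
    write_asc(landcovers[[pid]], file.path(lcdir, paste0(pid, ".asc")))
  }
  invisible(dir)
}

#' Deterministic land-cover rasters for all parks of a city
#'
#' Per-park seeds are derived from the scenario seed plus the park's row
#' index, so the rasters are reproducible from the city alone.
#'
#' @param city a `city`.
#' @return named list of `landcover` objects, one per park id.
#' @export
city_landcovers <- function(city) {
  cfg <- city$config
  out <- list()
  for (i in seq_len(nrow(city$parks))) {
    p <- city$parks[i, ]
    out[[p$id]] <- generate_park_landcover(
      p, n_patches = p$n_patches, seed = cfg$seed + i,
      cell_size = cfg$landcover_cell, green_fraction = p$green_fraction)
  }
  out
}

#' Read a city written by [write_city()]
#'
#' @param dir directory holding the files written by [write_city()].
#' @return a `city` object (without re-reading land-cover rasters; use
#'   [read_asc()] for those).
#' @export
read_city <- function(dir) {
  need <- c("parks.geojson", "entrances.geojson", "residences.geojson",
            "parcels.geojson", "roads.graphml", "blocks.csv", "config.yml")
  miss <- need[!file.exists(file.path(dir, need))]
  if (length(miss)) stop("missing city files in ", dir, ": ",
                         paste(miss, collapse = ", "))
  parks <- parks_from_geojson(file.path(dir, "parks.geojson"))
  entrances <- points_from_geojson(file.path(dir, "entrances.geojson"),
                                   c("park_id", "node"))
  entrances <- entrances[, c("id", "park_id", "x", "y", "node")]
  residences <- points_from_geojson(file.path(dir, "residences.geojson"),
                                    c("households", "block_id", "population",
                                      "price"))
  residences$households <- as.integer(residences$households)
  parcels <- parcels_from_geojson(file.path(dir, "parcels.geojson"))
  roads <- igraph::read_graph(file.path(dir, "roads.graphml"),
                              format = "graphml")
  blocks <- read.csv(file.path(dir, "blocks.csv"), stringsAsFactors = FALSE)
  cfg <- config_from_list(yaml::read_yaml(file.path(dir, "config.yml")))
  structure(list(parks = parks, entrances = entrances,
                 residences = residences, roads = roads, parcels = parcels,
                 blocks = blocks, extent = cfg$extent, config = cfg),
            class = "city")
}

# ---- GeoJSON --------------------------------------------------------------

rect_ring <- function(cx, cy, w, h) {
  x0 <- cx - w / 2; x1 <- cx + w / 2; y0 <- cy - h / 2; y1 <- cy + h / 2
  list(list(x0, y0), list(x1, y0), list(x1, y1), list(x0, y1), list(x0, y0))
}

park_features <- function(parks) {
  lapply(seq_len(nrow(parks)), function(i) {
    p <- parks[i, ]
    list(type = "Feature",
         geometry = list(type = "Polygon",
                         coordinates = list(rect_ring(p$cx, p$cy, p$w, p$h))),
         properties = list(id = p$id, class = p$class, cx = p$cx, cy = p$cy,
                           w = p$w, h = p$h, area_hm2 = p$area_hm2,
                           hard_fraction = p$hard_fraction,
                           n_patches = p$n_patches,
                           green_fraction = p$green_fraction))
  })
}

parcel_features <- function(parcels) {
  lapply(seq_len(nrow(parcels)), function(i) {
    p <- parcels[i, ]
    list(type = "Feature",
         geometry = list(type = "Polygon",
                         coordinates = list(rect_ring(p$cx, p$cy, p$w, p$h))),
         properties = list(id = p$id, cx = p$cx, cy = p$cy, w = p$w,
                           h = p$h, area_hm2 = p$area_hm2))
  })
}

point_features <- function(df, prop_cols) {
  lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    props <- c(list(id = r$id), as.list(r[prop_cols]))
    list(type = "Feature",
         geometry = list(type = "Point", coordinates = list(r$x, r$y)),
         properties = props)
  })
}

write_geojson <- function(features, path) {
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  invisible(path)
}

read_geojson_features <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)$features
}

props_df <- function(features, cols) {
  rows <- lapply(features, function(f) {
    p <- f$properties
    as.data.frame(p[cols], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

parks_from_geojson <- function(path) {
  f <- read_geojson_features(path)
  df <- props_df(f, c("id", "class", "cx", "cy", "w", "h", "area_hm2",
                      "hard_fraction", "n_patches", "green_fraction"))
  df$n_patches <- as.integer(df$n_patches)
  df
}

parcels_from_geojson <- function(path) {
  f <- read_geojson_features(path)
  props_df(f, c("id", "cx", "cy", "w", "h", "area_hm2"))
}

points_from_geojson <- function(path, prop_cols) {
  f <- read_geojson_features(path)
  df <- props_df(f, c("id", prop_cols))
  df$x <- vapply(f, function(g) as.numeric(g$geometry$coordinates[[1]]),
                 numeric(1))
  df$y <- vapply(f, function(g) as.numeric(g$geometry$coordinates[[2]]),
                 numeric(1))
  df[, c("id", "x", "y", prop_cols)]
}

# ---- Esri ASCII grid ------------------------------------------------------

#' Write / read an Esri ASCII grid
#'
#' `write_asc()` stores a `landcover` raster (or a bare matrix) as a plain
#' `.asc` file; `read_asc()` reads it back. Grid rows run south to north
#' internally and are flipped to the format's north-first row order on
#' disk.
#'
#' @param lc a `landcover` object or a numeric matrix.
#' @param path file path.
#' @param cell,origin cell size (m) and lower-left corner, used when `lc`
#'   is a bare matrix.
#' @return `read_asc()` returns a `landcover` object.
#' @export
write_asc <- function(lc, path, cell = 1, origin = c(0, 0)) {
  if (inherits(lc, "landcover")) {
    grid <- lc$grid; cell <- lc$cell; origin <- lc$origin
  } else grid <- lc
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(grid)), paste("nrows", nrow(grid)),
    paste("xllcorner", format(origin[1], digits = 15)),
    paste("yllcorner", format(origin[2], digits = 15)),
    paste("cellsize", format(cell, digits = 15)),
    "NODATA_value -9999"), con)
  for (r in rev(seq_len(nrow(grid)))) {
    writeLines(paste(grid[r, ], collapse = " "), con)
  }
  invisible(path)
}

#' @rdname write_asc
#' @export
read_asc <- function(path) {
  hdr <- readLines(path, n = 6)
  kv <- strsplit(trimws(hdr), "\\s+")
  vals <- setNames(vapply(kv, function(x) as.numeric(x[2]), numeric(1)),
                   tolower(vapply(kv, `[`, character(1), 1)))
  dat <- scan(path, skip = 6, quiet = TRUE)
  grid <- matrix(dat, nrow = vals["nrows"], ncol = vals["ncols"],
                 byrow = TRUE)
  grid <- grid[rev(seq_len(nrow(grid))), , drop = FALSE]
  structure(list(grid = grid, cell = unname(vals["cellsize"]),
                 origin = unname(vals[c("xllcorner", "yllcorner")]),
                 park_id = sub("\\.asc$", "", basename(path))),
            class = "landcover")
}

# ---- scenario config <-> YAML --------------------------------------------

config_to_list <- function(cfg) {
  l <- unclass(cfg)
  l$park_mix <- as.list(l$park_mix)
  l
}

config_from_list <- function(l) {
  l$park_mix <- unlist(l$park_mix)
  l$park_area_ranges <- lapply(l$park_area_ranges, as.numeric)
  do.call(scenario_config, l)
}
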