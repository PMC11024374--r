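#' Park size classes and walking catchment radii
#'
#' Parks are classed by area: community (< 2 hm2), regional (2-5 hm2),
#' citywide (5-25 hm2) and comprehensive (>= 25 hm2), with walking service
#' radii of 500, 1000, 2000 and 3000 m respectively.
#'
#' @format `park_classes` is a character vector of the four class names in
#'   increasing size order; `class_radii` a named numeric vector of catchment
#'   radii in meters; `class_area_cutoffs` the area cutoffs in hm2.
#' @name park-classes
NULL

#' @rdname park-classes
#' @export
park_classes <- c("community", "regional", "citywide", "comprehensive")

#' @rdname park-classes
#' @export
class_radii <- c(community = 500, regional = 1000, citywide = 2000,
                 comprehensive = 3000)

#' @rdname park-classes
#' @export
class_area_cutoffs <- c(community = 2, regional = 5, citywide = 25)

#' Classify a park by its area
#'
#' @param area_hm2 numeric vector of park areas in hectares (hm2).
#' @return character vector of class names (see [park_classes]).
#' @examples
#' park_class_from_area(c(1.5, 3, 10, 40))
#' @export
park_class_from_area <- function(area_hm2) {
  stopifnot(is.numeric(area_hm2), all(area_hm2 > 0))
  cls <- character(length(area_hm2))
  cls[area_hm2 < class_area_cutoffs["community"]] <- "community"
  cls[area_hm2 >= class_area_cutoffs["community"] &
        area_hm2 < class_area_cutoffs["regional"]] <- "regional"
  cls[area_hm2 >= class_area_cutoffs["regional"] &
        area_hm2 < class_area_cutoffs["citywide"]] <- "citywide"
  cls[area_hm2 >= class_area_cutoffs["citywide"]] <- "comprehensive"
  cls
}

#' Scenario configuration for the synthetic-city generator
#'
#' Bundles every knob of [generate_city()] with validation. The defaults are
#' the package's reference scenario: a 6 x 6 km city whose central quarter
#' (by area) holds residences at four times the peripheral density while
#' parks are predominantly placed outside it — a densely populated,
#' under-parked core with an over-supplied fringe — plus a housing-price
#' surface that rises away from the cheap old core, with spatially
#' correlated noise.
#'
#' @param seed integer seed driving every random draw of the generator.
#' @param extent numeric length-2, width and height of the city in meters.
#' @param road_spacing target spacing of road-grid nodes (m).
#' @param road_jitter fraction of `road_spacing` used as uniform node jitter.
#' @param n_residences number of residential points (housing communities).
#' @param core_density_ratio ratio (> 1) of core to built-up periphery
#'   residence sampling density; the core is the central square holding a
#'   quarter of the extent's area.
#' @param built_up_radius radius (m) of the built-up area around the city
#'   centre; beyond it only a sparse exurban fringe remains. `NULL`
#'   (default) uses 40% of the smaller extent side. Set
#'   `fringe_density_ratio = 1` for a flat two-level core/periphery city.
#' @param fringe_density_ratio sampling density of the fringe relative to
#'   the built-up periphery (in (0, 1]).
#' @param households_range integer interval for households per residence.
#' @param price_base base housing price at the city centre (currency/m2).
#' @param price_slope linear price change per meter of distance to centre;
#'   positive means prices fall away from the centre. The reference default
#'   is negative: the dense old core is the cheap, under-parked area while
#'   affluent newer districts ring it.
#' @param price_noise_amp standard deviation of the spatially correlated
#'   price noise (currency/m2).
#' @param price_noise_range correlation length of the price noise (m).
#' @param park_mix named integer vector: number of parks per class.
#' @param park_area_ranges named list of length-2 numeric vectors, area
#'   sampling interval (hm2) per class; must respect the class cutoffs.
#' @param hard_fraction_range interval for the hard-surface (paved) fraction
#'   of each park.
#' @param fragmentation_levels integer interval for the number of green
#'   land-cover patches per park.
#' @param green_fraction_range interval for the green fraction of each
#'   park's land-cover raster.
#' @param landcover_cell land-cover raster cell size (m).
#' @param core_park_prob probability of keeping a candidate park whose
#'   centre falls in the core (< 1 encodes the under-parked core).
#' @param park_ring_max maximum distance (m) of a park centre from the
#'   city centre; parks are built where the city has developed, so the far
#'   fringe beyond this ring has none (and can hold explicit blind zones).
#'   `NULL` (default) uses 38% of the smaller extent side.
#' @param price_plateau distance (m) beyond which the price gradient stops:
#'   outskirt estates price like the ring rather than rising indefinitely.
#'   `NULL` (default) uses 40% of the smaller extent side.
#' @param entrances_range integer interval for entrances per park.
#' @param n_candidate_parcels number of candidate parcels for new parks.
#' @param blocks_nx,blocks_ny administrative block grid dimensions.
#' @param mean_household_size_range interval for block mean household size.
#' @param snap_limit maximum snapping distance from a point to the road
#'   network (m) before it is excluded with a warning.
#' @return an object of class `scenario_config` (a validated list).
#' @seealso [generate_city()]
#' @export
scenario_config <- function(seed = 1L,
                            extent = c(10000, 10000),
                            road_spacing = 400,
                            road_jitter = 0.15,
                            n_residences = 800L,
                            core_density_ratio = 4,
                            built_up_radius = NULL,
                            fringe_density_ratio = 0.05,
                            households_range = c(100L, 600L),
                            price_base = 8000,
                            price_slope = -1.2,
                            price_plateau = NULL,
                            price_noise_amp = 1500,
                            price_noise_range = 800,
                            park_mix = c(community = 6L, regional = 4L,
                                         citywide = 3L, comprehensive = 1L),
                            park_area_ranges = list(
                              community = c(0.5, 2),
                              regional = c(2, 5),
                              citywide = c(5, 25),
                              comprehensive = c(25, 35)),
                            hard_fraction_range = c(0.05, 0.30),
                            fragmentation_levels = c(1L, 12L),
                            green_fraction_range = c(0.5, 0.9),
                            landcover_cell = 1,
                            core_park_prob = 0.15,
                            park_ring_max = NULL,
                            entrances_range = c(1L, 4L),
                            n_candidate_parcels = 40L,
                            blocks_nx = 4L, blocks_ny = 4L,
                            mean_household_size_range = c(2.4, 3.4),
                            snap_limit = 500) {
  cfg <- list(seed = as.integer(seed), extent = as.numeric(extent),
              road_spacing = road_spacing, road_jitter = road_jitter,
              n_residences = as.integer(n_residences),
              core_density_ratio = core_density_ratio,
              built_up_radius = built_up_radius,
              fringe_density_ratio = fringe_density_ratio,
              households_range = as.integer(households_range),
              price_base = price_base, price_slope = price_slope,
              price_plateau = price_plateau,
              price_noise_amp = price_noise_amp,
              price_noise_range = price_noise_range,
              park_mix = park_mix, park_area_ranges = park_area_ranges,
              hard_fraction_range = hard_fraction_range,
              fragmentation_levels = as.integer(fragmentation_levels),
              green_fraction_range = green_fraction_range,
              landcover_cell = landcover_cell,
              core_park_prob = core_park_prob,
              park_ring_max = park_ring_max,
              entrances_range = as.integer(entrances_range),
              n_candidate_parcels = as.integer(n_candidate_parcels),
              blocks_nx = as.integer(blocks_nx),
              blocks_ny = as.integer(blocks_ny),
              mean_household_size_range = mean_household_size_range,
              snap_limit = snap_limit)
  class(cfg) <- "scenario_config"
  validate_config(cfg)
  cfg
}

#' Validate a scenario configuration
#'
#' Checks the structural invariants of a [scenario_config()]; errors name
#' the offending field.
#'
#' @param cfg a `scenario_config` (or plain list with the same fields).
#' @return `cfg`, invisibly, if valid.
#' @export
validate_config <- function(cfg) {
  fail <- function(field, msg) {
    stop(sprintf("invalid scenario config: field '%s' %s", field, msg),
         call. = FALSE)
  }
  if (length(cfg$extent) != 2 || any(!is.finite(cfg$extent)) ||
      any(cfg$extent <= 0)) fail("extent", "must be two positive numbers")
  if (!is.finite(cfg$core_density_ratio) || cfg$core_density_ratio <= 1)
    fail("core_density_ratio", "must exceed 1")
  if (cfg$n_residences < 0) fail("n_residences", "must be non-negative")
  if (!setequal(names(cfg$park_mix), park_classes))
    fail("park_mix", "must name all four park classes")
  if (any(cfg$park_mix < 0)) fail("park_mix", "counts must be non-negative")
  for (cl in park_classes) {
    rng <- cfg$park_area_ranges[[cl]]
    if (is.null(rng) || length(rng) != 2 || rng[1] > rng[2])
      fail("park_area_ranges", sprintf("needs a valid interval for '%s'", cl))
    lo <- c(community = 0, regional = 2, citywide = 5, comprehensive = 25)[cl]
    hi <- c(community = 2, regional = 5, citywide = 25,
            comprehensive = Inf)[cl]
    if (rng[1] < lo || rng[2] > hi)
      fail("park_area_ranges",
           sprintf("interval for '%s' violates the class cutoffs", cl))
  }
  # largest park must fit inside the extent with room to spare
  max_a_m2 <- max(vapply(cfg$park_area_ranges, max, numeric(1))) * 1e4
  if (sqrt(max_a_m2) > 0.9 * min(cfg$extent))
    fail("park_area_ranges", "largest park area exceeds the extent")
  if (cfg$hard_fraction_range[1] < 0 || cfg$hard_fraction_range[2] > 1)
    fail("hard_fraction_range", "must lie in [0, 1]")
  if (cfg$fragmentation_levels[1] < 1)
    fail("fragmentation_levels", "patch counts must be >= 1")
  if (cfg$entrances_range[1] < 1)
    fail("entrances_range", "every park needs at least one entrance")
  if (cfg$road_spacing <= 0 || cfg$road_spacing > min(cfg$extent))
    fail("road_spacing", "must be positive and smaller than the extent")
  invisible(cfg)
}

#' The shipped reference scenario
#'
#' The scenario used throughout the package's worked examples and
#' end-to-end checks: the [scenario_config()] defaults with the given seed.
#'
#' @param seed integer seed.
#' @return a `scenario_config`.
#' @export
reference_scenario <- function(seed = 1L) scenario_config(seed = seed)

#' @export
print.scenario_config <- function(x, ...) {
  cat("Synthetic-city scenario\n")
  cat(sprintf("  extent        : %g x %g m\n", x$extent[1], x$extent[2]))
  cat(sprintf("  residences    : %d (core/periphery density ratio %g)\n",
              x$n_residences, x$core_density_ratio))
  cat(sprintf("  parks         : %s\n",
              paste(sprintf("%s=%d", names(x$park_mix), x$park_mix),
                    collapse = ", ")))
  cat(sprintf("  seed          : %d\n", x$seed))
  invisible(x)
}

#' Is a point inside the dense core?
#'
#' The core is the central square holding a quarter of the extent's area
#' (half the side length in each dimension).
#'
#' @param x,y point coordinates (m).
#' @param extent the city extent `c(width, height)`.
#' @return logical vector.
#' @export
in_core <- function(x, y, extent) {
  hw <- extent[1] / 4; hh <- extent[2] / 4
  cx <- extent[1] / 2; cy <- extent[2] / 2
  abs(x - cx) <= hw & abs(y - cy) <= hh
}
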