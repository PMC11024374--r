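#' Gaussian distance-decay kernel
#'
#' The normalized Gaussian decay used by the catchment model:
#' \deqn{G(d, d_0) = \frac{e^{-\frac12 (d/d_0)^2} - e^{-\frac12}}
#'                        {1 - e^{-\frac12}}, \quad d \le d_0;
#'       \qquad G = 0, \ d \ge d_0.}
#' It equals 1 at \eqn{d = 0}, decreases strictly on \eqn{[0, d_0]} and is
#' continuous at the catchment edge, where it reaches 0.
#'
#' @param d distance(s), meters, >= 0.
#' @param d0 catchment radius, meters, > 0 (scalar or vector like `d`).
#' @return decay weight(s) in `[0, 1]`.
#' @examples
#' gaussian_decay(c(0, 1000, 2000), 2000)
#' @export
gaussian_decay <- function(d, d0) {
  stopifnot(all(d >= 0), all(d0 > 0))
  g <- (exp(-0.5 * (d / d0)^2) - exp(-0.5)) / (1 - exp(-0.5))
  ifelse(d >= d0, 0, g)
}

#' Catchment configuration
#'
#' Parks serve walkers within a maximum radius `d0`. In `type_specific`
#' mode each park uses its class radius (500/1000/2000/3000 m for
#' community/regional/citywide/comprehensive); in `uniform` mode every park
#' uses the same radius, which is how the sensitivity of accessibility to
#' walking distance is examined.
#'
#' @param mode `"type_specific"` or `"uniform"`.
#' @param d0_uniform radius (m) used in uniform mode.
#' @param d0_by_class named radii (m) used in type-specific mode.
#' @return object of class `catchment_config`.
#' @export
catchment_config <- function(mode = c("type_specific", "uniform"),
                             d0_uniform = 2000,
                             d0_by_class = class_radii) {
  mode <- match.arg(mode)
  stopifnot(d0_uniform > 0, all(d0_by_class > 0))
  structure(list(mode = mode, d0_uniform = d0_uniform,
                 d0_by_class = d0_by_class),
            class = "catchment_config")
}

park_d0 <- function(catchment, park_class) {
  if (catchment$mode == "uniform") rep(catchment$d0_uniform,
                                       length(park_class))
  else unname(catchment$d0_by_class[park_class])
}

#' Network walking distances between point sets
#'
#' Snaps each origin (and, if given as coordinates, each destination) to
#' its nearest road-network vertex, adding the Euclidean connector length,
#' and computes shortest-path distances along edge attribute `length_m`.
#' Points farther than `snap_limit` from any vertex are excluded with a
#' warning. Pairs beyond `cutoff` are dropped from the result.
#'
#' @param roads igraph road network with vertex `x`, `y` and edge
#'   `length_m`.
#' @param origins data.frame with `id`, `x`, `y`.
#' @param destinations data.frame with `id`, `x`, `y`, or a character
#'   vector of vertex names to be used directly (no connector).
#' @param cutoff maximum distance (m) retained.
#' @param snap_limit maximum snapping distance (m).
#' @return data.frame `origin_id`, `dest_id`, `d` (network meters).
#' @export
network_distance <- function(roads, origins, destinations, cutoff,
                             snap_limit = 500) {
  if (igraph::vcount(roads) == 0) stop("road network is empty",
                                       call. = FALSE)
  stopifnot(cutoff > 0)
  vx <- igraph::vertex_attr(roads, "x")
  vy <- igraph::vertex_attr(roads, "y")
  vn <- igraph::vertex_attr(roads, "name")
  snap <- function(pts, what) {
    nearest <- integer(nrow(pts)); conn <- numeric(nrow(pts))
    for (i in seq_len(nrow(pts))) {
      d2 <- (vx - pts$x[i])^2 + (vy - pts$y[i])^2
      nearest[i] <- which.min(d2)
      conn[i] <- sqrt(d2[nearest[i]])
    }
    far <- conn > snap_limit
    if (any(far)) {
      warning(sum(far), " ", what, "(s) farther than the ", snap_limit,
              " m snap limit were excluded")
    }
    list(node = nearest, conn = conn, keep = !far)
  }
  so <- snap(origins, "origin")
  if (is.character(destinations)) {
    dn <- match(destinations, vn)
    if (anyNA(dn)) stop("unknown destination vertices", call. = FALSE)
    sd_ <- list(node = dn, conn = rep(0, length(dn)),
                keep = rep(TRUE, length(dn)))
    dest_ids <- destinations
  } else {
    sd_ <- snap(destinations, "destination")
    dest_ids <- destinations$id
  }
  o_keep <- which(so$keep); d_keep <- which(sd_$keep)
  if (!length(o_keep) || !length(d_keep)) {
    return(data.frame(origin_id = character(), dest_id = character(),
                      d = numeric(), stringsAsFactors = FALSE))
  }
  o_nodes <- unique(so$node[o_keep]); d_nodes <- unique(sd_$node[d_keep])
  D <- igraph::distances(roads, v = o_nodes, to = d_nodes,
                         weights = igraph::edge_attr(roads, "length_m"))
  oi <- match(so$node[o_keep], o_nodes); di <- match(sd_$node[d_keep],
                                                     d_nodes)
  full <- D[oi, di, drop = FALSE] + so$conn[o_keep] +
    rep(sd_$conn[d_keep], each = length(o_keep))
  hit <- which(is.finite(full) & full <= cutoff, arr.ind = TRUE)
  data.frame(origin_id = origins$id[o_keep][hit[, 1]],
             dest_id = dest_ids[d_keep][hit[, 2]],
             d = full[hit], stringsAsFactors = FALSE)
}

#' Sparse residence-to-park network distances
#'
#' Walking distance from each residence to each park, where a park is
#' reached through its nearest entrance (minimum over the park's entrance
#' vertices), stored only up to `cutoff`.
#'
#' @param city a `city`.
#' @param cutoff maximum distance retained (m); 3000 m — the largest
#'   catchment radius — by default.
#' @param snap_limit see [network_distance()].
#' @return data.frame `residence_id`, `park_id`, `d`.
#' @export
residence_park_distances <- function(city, cutoff = 3000,
                                     snap_limit = city$config$snap_limit %||% 500) {
  if (!nrow(city$entrances)) {
    return(data.frame(residence_id = character(), park_id = character(),
                      d = numeric(), stringsAsFactors = FALSE))
  }
  de <- network_distance(city$roads, city$residences, city$entrances$node,
                         cutoff = cutoff, snap_limit = snap_limit)
  de$park_id <- city$entrances$park_id[match(de$dest_id,
                                             city$entrances$node)]
  agg <- aggregate(d ~ origin_id + park_id, data = de, FUN = min)
  data.frame(residence_id = agg$origin_id, park_id = agg$park_id,
             d = agg$d, stringsAsFactors = FALSE)
}

#' Composite park supply
#'
#' The weighted supply capacity of a park,
#' \eqn{C_j = w_S S_j + w_{FCs} FCs_j + w_{ESV} ESV_j} with areas in hm2.
#' Negative composites (possible since ESV may be negative) are floored at
#' 0 with a warning.
#'
#' @param quality data.frame from [park_quality()] (columns `S_hm2`, `ESV`,
#'   `FCs_hm2`).
#' @param weights named weights `c(S, FCs, ESV)`; see
#'   [default_supply_weights()].
#' @return numeric vector of supplies \eqn{C_j}, named by park id.
#' @export
park_supply <- function(quality, weights = default_supply_weights()) {
  need <- c("S_hm2", "ESV", "FCs_hm2")
  if (!all(need %in% names(quality)))
    stop("quality table lacks ", paste(setdiff(need, names(quality)),
                                       collapse = ", "), call. = FALSE)
  C <- weights[["S"]] * quality$S_hm2 + weights[["FCs"]] * quality$FCs_hm2 +
    weights[["ESV"]] * quality$ESV
  if (any(C < 0)) {
    warning(sum(C < 0), " park(s) had negative composite supply; floored ",
            "at 0")
    C <- pmax(C, 0)
  }
  setNames(C, quality$park_id)
}

#' Supply-demand ratios (catchment step 1)
#'
#' For each park \eqn{j}, the Gaussian-weighted population within its
#' catchment is \eqn{D_j = \sum_{k: d_{kj} \le d_0(j)} G(d_{kj}, d_0(j))
#' P_k} and the supply-demand ratio \eqn{R_j = C_j / D_j} (0 when no
#' population is in reach, with a notice).
#'
#' @param city a `city`.
#' @param quality park quality table ([park_quality()]).
#' @param catchment a [catchment_config()].
#' @param dist sparse distances from [residence_park_distances()].
#' @param weights supply weights.
#' @return data.frame `park_id`, `C`, `D`, `R`, `d0`.
#' @export
supply_demand_ratios <- function(city, quality, catchment,
                                 dist = residence_park_distances(city),
                                 weights = default_supply_weights()) {
  C <- park_supply(quality, weights)
  parks <- city$parks
  d0 <- setNames(park_d0(catchment, parks$class), parks$id)
  P <- setNames(city$residences$population, city$residences$id)
  g <- gaussian_decay(dist$d, d0[dist$park_id])
  contrib <- g * P[dist$residence_id]
  D <- setNames(rep(0, nrow(parks)), parks$id)
  got <- tapply(contrib, dist$park_id, sum)
  D[names(got)] <- got
  if (any(D == 0)) {
    message(sum(D == 0), " park(s) have no weighted demand in reach; R set",
            " to 0")
  }
  R <- ifelse(D > 0, C[parks$id] / D, 0)
  data.frame(park_id = parks$id, C = unname(C[parks$id]), D = unname(D),
             R = unname(R), d0 = unname(d0[parks$id]),
             stringsAsFactors = FALSE)
}

#' Accessibility scores (catchment step 2)
#'
#' Each residence sums the Gaussian-weighted supply-demand ratios of all
#' parks in reach: \eqn{A_i = \sum_{j: d_{ij} \le d_0(j)} G(d_{ij},
#' d_0(j)) R_j}. Residences with no park in range score 0. When every park
#' has positive weighted demand, \eqn{\sum_i P_i A_i = \sum_j C_j}
#' (conservation of supplied capacity).
#'
#' @param ratios output of [supply_demand_ratios()] (same catchment!).
#' @param dist the same sparse distance table.
#' @param residences the city's residences data.frame.
#' @return data.frame `residence_id`, `A`, `P`.
#' @export
accessibility <- function(ratios, dist, residences) {
  R <- setNames(ratios$R, ratios$park_id)
  d0 <- setNames(ratios$d0, ratios$park_id)
  g <- gaussian_decay(dist$d, d0[dist$park_id])
  term <- g * R[dist$park_id]
  A <- setNames(rep(0, nrow(residences)), residences$id)
  got <- tapply(term, dist$residence_id, sum)
  A[names(got)] <- got
  data.frame(residence_id = residences$id, A = unname(A),
             P = residences$population, stringsAsFactors = FALSE)
}

#' Geometric-interval classification of accessibility scores
#'
#' Zero scores form their own class (label 0). Positive scores are split
#' into `n_classes` multiplicative intervals with breaks
#' \eqn{b_m = a (M/a)^{m/K}}, where `a` and `M` are the smallest and
#' largest positive scores and `K = n_classes`; class `m` covers
#' \eqn{(b_{m-1}, b_m]}. The upper bound of the lowest positive class is
#' returned as `low_threshold`.
#'
#' @param values numeric scores, >= 0.
#' @param n_classes number of positive classes (>= 2).
#' @return list with `class` (integer labels, 0 = zero class), `breaks`,
#'   and `low_threshold`.
#' @export
classify_geometric <- function(values, n_classes = 5) {
  stopifnot(n_classes >= 2, all(values >= 0))
  cls <- integer(length(values))
  pos <- values > 0
  if (!any(pos)) {
    warning("all scores are zero; single zero class")
    return(list(class = cls, breaks = numeric(0), low_threshold = 0))
  }
  a <- min(values[pos]); M <- max(values[pos])
  if (a == M) {
    cls[pos] <- 1L
    return(list(class = cls, breaks = a, low_threshold = a))
  }
  breaks <- a * (M / a)^(seq_len(n_classes - 1) / n_classes)
  # relative fudge keeps values that sit exactly on a break (up to
  # floating-point noise) in the lower class
  cls[pos] <- 1L + findInterval(values[pos], breaks * (1 + 1e-12),
                                left.open = TRUE)
  list(class = cls, breaks = breaks, low_threshold = breaks[1])
}

#' Full accessibility table across walking radii
#'
#' Computes the G2SFCA accessibility of every residence for each uniform
#' walking radius (500, 1000, 2000, 3000 m by default) plus the
#' comprehensive score under class-specific radii, and classifies the
#' comprehensive score by geometric intervals.
#'
#' @param city a `city`.
#' @param quality park quality table.
#' @param weights supply weights.
#' @param radii uniform radii (m) to scan.
#' @param n_classes classes for [classify_geometric()].
#' @param dist optional precomputed [residence_park_distances()] (3000 m
#'   cutoff).
#' @return data.frame of class `access_table`: `residence_id`, one
#'   `A_<radius>` column per uniform radius, `A_comprehensive`, `P`,
#'   `class`; attributes `breaks` and `low_threshold`.
#' @export
access_table <- function(city, quality, weights = default_supply_weights(),
                         radii = c(500, 1000, 2000, 3000), n_classes = 5,
                         dist = residence_park_distances(city)) {
  out <- data.frame(residence_id = city$residences$id,
                    stringsAsFactors = FALSE)
  for (r in radii) {
    cc <- catchment_config("uniform", d0_uniform = r)
    rat <- supply_demand_ratios(city, quality, cc, dist, weights)
    out[[sprintf("A_%d", r)]] <- accessibility(rat, dist,
                                               city$residences)$A
  }
  cc <- catchment_config("type_specific")
  rat <- supply_demand_ratios(city, quality, cc, dist, weights)
  acc <- accessibility(rat, dist, city$residences)
  out$A_comprehensive <- acc$A
  out$P <- acc$P
  cl <- classify_geometric(out$A_comprehensive, n_classes)
  out$class <- cl$class
  attr(out, "breaks") <- cl$breaks
  attr(out, "low_threshold") <- cl$low_threshold
  class(out) <- c("access_table", "data.frame")
  out
}

#' @export
print.access_table <- function(x, ...) {
  cat(sprintf("Accessibility table: %d residences\n", nrow(x)))
  acols <- grep("^A_", names(x), value = TRUE)
  for (cn in acols) {
    cat(sprintf("  %-16s mean %10.4g  zero count %d\n", cn, mean(x[[cn]]),
                sum(x[[cn]] == 0)))
  }
  cat(sprintf("  lowest-class upper bound: %.6f\n",
              attr(x, "low_threshold")))
  invisible(x)
}
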