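#' Identify explicit and implicit service blind zones
#'
#' Explicit blind zones are residences that cannot reach any park entrance
#' within 3000 m of network walking. Implicit blind zones are covered (an
#' entrance is within 3000 m) but still receive bottom-class service:
#' their comprehensive accessibility is zero or falls in the lowest
#' positive geometric-interval class — the signature of supply-demand
#' imbalance in dense areas.
#'
#' @param access an [access_table()].
#' @param dist [residence_park_distances()] computed with a 3000 m cutoff.
#' @return data.frame `residence_id`, `kind` (`explicit`, `implicit`,
#'   `none`).
#' @export
identify_blind_zones <- function(access, dist) {
  covered_ids <- unique(dist$residence_id[dist$d <= 3000])
  covered <- access$residence_id %in% covered_ids
  lowest <- access$class <= 1L   # zero class or lowest positive class
  kind <- rep("none", nrow(access))
  kind[!covered] <- "explicit"
  kind[covered & lowest] <- "implicit"
  data.frame(residence_id = access$residence_id, kind = kind,
             stringsAsFactors = FALSE)
}

#' Select optimization-target residences
#'
#' The optimization targets are the union of the low-accessibility
#' residences (comprehensive score in the zero or lowest positive class,
#' i.e. at or below the lowest-class upper bound) and the significant
#' low-low (LL) LISA residences — spatial inequity plus social inequity.
#'
#' @param access an [access_table()].
#' @param lisa a [bivariate_moran()] result on the same residences.
#' @return data.frame `residence_id`, `provenance`
#'   (`low_access`, `LL`, `both`); class `target_set`.
#' @export
select_targets <- function(access, lisa) {
  stopifnot(identical(access$residence_id, lisa$id))
  low <- access$class <= 1L
  ll <- lisa$category == "LL"
  sel <- low | ll
  if (!any(sel)) warning("no optimization targets; downstream plan is empty")
  provenance <- ifelse(low & ll, "both", ifelse(low, "low_access", "LL"))
  out <- data.frame(residence_id = access$residence_id[sel],
                    provenance = provenance[sel], stringsAsFactors = FALSE)
  class(out) <- c("target_set", "data.frame")
  out
}

#' Features for clustering the optimization targets
#'
#' The two-dimensional feature space for the cluster-count analysis:
#' comprehensive accessibility and a socioeconomic-match score derived
#' from the LISA category (HH = 1, HL = 0.75, NS = 0.5, LH = 0.25,
#' LL = 0 — larger means accessibility and socioeconomic level agree
#' favourably). Both features are min-max standardized in
#' [kmeans_curve()].
#'
#' @param access an [access_table()].
#' @param lisa a [bivariate_moran()] result.
#' @param targets a [select_targets()] set.
#' @return numeric matrix (one row per target) with columns
#'   `accessibility`, `match`.
#' @export
planning_features <- function(access, lisa, targets) {
  i <- match(targets$residence_id, access$residence_id)
  match_code <- c(HH = 1, HL = 0.75, NS = 0.5, LH = 0.25, LL = 0)
  cbind(accessibility = access$A_comprehensive[i],
        match = unname(match_code[lisa$category[i]]))
}

#' K-means cluster-count curve and knee selection
#'
#' For each candidate `k`, runs `n_init` seeded K-means starts on the
#' min-max standardized feature matrix and records the average farthest
#' distance from cluster members to their centre. The number of new parks
#' is chosen at the knee: the `k` with the largest positive second
#' difference of the curve (override via `k_override`).
#'
#' @param features numeric matrix (targets x features).
#' @param k_range integer vector of candidate cluster counts, within
#'   `[1, n)`.
#' @param n_init number of random starts per `k`.
#' @param seed integer seed.
#' @param k_override optional fixed `k` (planning knowledge beats the
#'   knee).
#' @return object of class `kcurve`: list with `curve` (data.frame `k`,
#'   `avg_farthest`), `chosen_k`, `rule`.
#' @export
kmeans_curve <- function(features, k_range = 1:12, n_init = 5, seed = 1L,
                         k_override = NULL) {
  m <- as.matrix(features)
  n <- nrow(m)
  if (n < max(k_range)) stop("more clusters requested than targets",
                             call. = FALSE)
  for (j in seq_len(ncol(m))) {
    rng <- max(m[, j]) - min(m[, j])
    m[, j] <- if (rng == 0) 0 else (m[, j] - min(m[, j])) / rng
  }
  set.seed(seed)
  vals <- vapply(k_range, function(k) {
    if (k == 1 || nrow(unique(m)) == 1) {
      ctr <- matrix(colMeans(m), 1)
      cl <- rep(1L, n)
    } else {
      km <- suppressWarnings(
        kmeans(m, centers = min(k, nrow(unique(m))), nstart = n_init,
               iter.max = 50))
      ctr <- km$centers; cl <- km$cluster
    }
    d <- sqrt(rowSums((m - ctr[cl, , drop = FALSE])^2))
    mean(tapply(d, cl, max))
  }, numeric(1))
  if (!is.null(k_override)) {
    chosen <- as.integer(k_override); rule <- "override"
  } else if (all(vals < 1e-12) || length(k_range) < 3) {
    chosen <- min(k_range); rule <- "degenerate"
  } else {
    d2 <- vals[-c(length(vals), length(vals) - 1)] -
      2 * vals[-c(1, length(vals))] + vals[-(1:2)]
    chosen <- k_range[-c(1, length(k_range))][which.max(d2)]
    rule <- "max_second_difference"
  }
  structure(list(curve = data.frame(k = k_range, avg_farthest = vals),
                 chosen_k = chosen, rule = rule),
            class = "kcurve")
}

#' @export
print.kcurve <- function(x, ...) {
  cat(sprintf("K-means curve over k = %d..%d; chosen k = %d (%s)\n",
              min(x$curve$k), max(x$curve$k), x$chosen_k, x$rule))
  invisible(x)
}

#' @export
plot.kcurve <- function(x, ...) {
  plot(x$curve$k, x$curve$avg_farthest, type = "b", xlab = "k",
       ylab = "average farthest distance", ...)
  graphics::abline(v = x$chosen_k, lty = 2)
  invisible(x)
}

#' Particle-swarm site selection for new parks
#'
#' Places `k` new park sites minimizing the population-weighted sum of
#' distances from each target residence to its nearest site:
#' \eqn{f(s) = \sum_t P_t \min_s \|t - s\|} (Euclidean during the search;
#' land use enters afterwards via [assign_park_classes()]). Standard
#' global-best PSO with constriction-style parameters (inertia 0.729,
#' cognitive = social = 1.494) and velocities clamped to 20% of the bounds
#' span; deterministic given `seed`.
#'
#' @param targets data.frame with `x`, `y` and `population` (weights).
#' @param k number of sites (>= 1).
#' @param bounds `c(xmin, xmax, ymin, ymax)`; defaults to the targets'
#'   bounding box.
#' @param n_particles,n_iter swarm size and iterations.
#' @param seed integer seed.
#' @param inertia,c1,c2 PSO hyperparameters.
#' @return object of class `pso_result`: list with `sites` (k x 2 matrix),
#'   `objective`, `trace` (best objective per iteration, non-increasing),
#'   `initial_objective`.
#' @export
pso_site_selection <- function(targets, k, bounds = NULL, n_particles = 30,
                               n_iter = 200, seed = 1L, inertia = 0.729,
                               c1 = 1.494, c2 = 1.494) {
  stopifnot(k >= 1, nrow(targets) >= 1)
  tx <- targets$x; ty <- targets$y
  tp <- if (!is.null(targets$population)) targets$population
        else rep(1, nrow(targets))
  if (is.null(bounds)) bounds <- c(range(tx), range(ty))
  if (bounds[1] > min(tx) || bounds[2] < max(tx) ||
      bounds[3] > min(ty) || bounds[4] < max(ty))
    stop("bounds must contain all targets", call. = FALSE)
  span <- c(bounds[2] - bounds[1], bounds[4] - bounds[3])
  lo <- rep(c(bounds[1], bounds[3]), each = k)
  hi <- rep(c(bounds[2], bounds[4]), each = k)
  vmax <- 0.2 * rep(span, each = k)
  fitness <- function(pos) {
    sx <- pos[seq_len(k)]; sy <- pos[k + seq_len(k)]
    d2 <- outer(tx, sx, "-")^2 + outer(ty, sy, "-")^2
    f <- sum(tp * sqrt(do.call(pmin, as.data.frame(d2))))
    if (!is.finite(f)) stop("non-finite PSO fitness", call. = FALSE)
    f
  }
  set.seed(seed)
  dim_ <- 2L * k
  X <- matrix(runif(n_particles * dim_, lo, hi), n_particles, dim_,
              byrow = TRUE)
  V <- matrix(0, n_particles, dim_)
  fx <- apply(X, 1, fitness)
  Pb <- X; fpb <- fx
  gi <- which.min(fpb)
  gb <- Pb[gi, ]; fgb <- fpb[gi]
  initial <- fgb
  trace <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    r1 <- matrix(runif(n_particles * dim_), n_particles)
    r2 <- matrix(runif(n_particles * dim_), n_particles)
    V <- inertia * V + c1 * r1 * (Pb - X) +
      c2 * r2 * matrix(gb, n_particles, dim_, byrow = TRUE) - c2 * r2 * X
    V <- pmin(pmax(V, matrix(-vmax, n_particles, dim_, byrow = TRUE)),
              matrix(vmax, n_particles, dim_, byrow = TRUE))
    X <- X + V
    X <- pmin(pmax(X, matrix(lo, n_particles, dim_, byrow = TRUE)),
              matrix(hi, n_particles, dim_, byrow = TRUE))
    fx <- apply(X, 1, fitness)
    better <- fx < fpb
    Pb[better, ] <- X[better, ]; fpb[better] <- fx[better]
    gi <- which.min(fpb)
    if (fpb[gi] < fgb) { fgb <- fpb[gi]; gb <- Pb[gi, ] }
    trace[it] <- fgb
  }
  structure(list(sites = cbind(x = gb[seq_len(k)], y = gb[k + seq_len(k)]),
                 objective = fgb, trace = trace,
                 initial_objective = initial, k = k),
            class = "pso_result")
}

#' @export
print.pso_result <- function(x, ...) {
  cat(sprintf("PSO siting: k = %d, objective %.1f -> %.1f over %d iters\n",
              x$k, x$initial_objective, x$objective, length(x$trace)))
  invisible(x)
}

#' Snap sites to candidate parcels and assign park classes
#'
#' Each PSO site is snapped to the nearest still-unused candidate parcel
#' (centroid distance; a taken parcel sends the site to the next-nearest),
#' imposing the land-use constraint on the continuous optimum. The new
#' park's class and catchment radius follow from the parcel's area via the
#' class cutoffs (< 2 hm2 community / 500 m; 2-5 regional / 1000 m; 5-25
#' citywide / 2000 m; >= 25 comprehensive / 3000 m); the planned area is
#' the parcel area.
#'
#' @param sites a `pso_result` or a k x 2 matrix of site coordinates.
#' @param parcels the city's candidate parcels data.frame.
#' @return data.frame of class `siting_plan`: `site_x`, `site_y`,
#'   `parcel_id`, `cx`, `cy`, `w`, `h`, `class`, `radius_m`, `area_hm2`.
#' @export
assign_park_classes <- function(sites, parcels) {
  pso <- NULL
  if (inherits(sites, "pso_result")) { pso <- sites; sites <- sites$sites }
  sites <- as.matrix(sites)
  if (!nrow(parcels)) stop("no candidate parcels", call. = FALSE)
  if (nrow(sites) > nrow(parcels))
    stop("more sites (", nrow(sites), ") than candidate parcels (",
         nrow(parcels), "): short by ", nrow(sites) - nrow(parcels),
         call. = FALSE)
  taken <- logical(nrow(parcels))
  rows <- list()
  for (i in seq_len(nrow(sites))) {
    d <- sqrt((parcels$cx - sites[i, 1])^2 + (parcels$cy - sites[i, 2])^2)
    d[taken] <- Inf
    j <- which.min(d)
    taken[j] <- TRUE
    cls <- park_class_from_area(parcels$area_hm2[j])
    rows[[i]] <- data.frame(
      site_x = sites[i, 1], site_y = sites[i, 2],
      parcel_id = parcels$id[j], cx = parcels$cx[j], cy = parcels$cy[j],
      w = parcels$w[j], h = parcels$h[j], class = cls,
      radius_m = unname(class_radii[cls]), area_hm2 = parcels$area_hm2[j],
      stringsAsFactors = FALSE)
  }
  plan <- do.call(rbind, rows)
  if (!is.null(pso)) {
    attr(plan, "objective") <- pso$objective
    attr(plan, "initial_objective") <- pso$initial_objective
  }
  class(plan) <- c("siting_plan", "data.frame")
  plan
}

#' Per-class quality defaults for planned parks
#'
#' Planned parks have no observed land cover, so their ESV takes the
#' per-class defaults shipped with the package and FCs comes from a
#' default hard-surface fraction.
#'
#' @return list with `esv` (named per-class scores) and `hard_fraction`.
#' @export
new_park_defaults <- function() {
  list(esv = c(community = 77.53, regional = -8.26, citywide = 42.74,
               comprehensive = 7.51),
       hard_fraction = 0.2)
}

# Build the after-city: append planned parks with entrances snapped into
# the road network. Deterministic given `seed`.
apply_plan <- function(city, plan, seed = 1L) {
  if (!nrow(plan)) return(city)
  set.seed(seed)
  new_parks <- data.frame(
    id = sprintf("N%02d", seq_len(nrow(plan))), class = plan$class,
    cx = plan$cx, cy = plan$cy, w = plan$w, h = plan$h,
    area_hm2 = plan$area_hm2,
    hard_fraction = new_park_defaults()$hard_fraction,
    n_patches = 1L, green_fraction = 0.7, stringsAsFactors = FALSE)
  ent <- place_entrances(city$config, new_parks, city$roads)
  # place_entrances re-adds existing entrance vertices' graph: it was given
  # the full road graph, so new entrance vertices append cleanly
  city$parks <- rbind(city$parks, new_parks)
  city$entrances <- rbind(city$entrances, ent$entrances)
  city$roads <- ent$roads
  city
}

#' Evaluate a siting plan: before/after accessibility and equity
#'
#' Appends the planned parks to the city (entrances snapped into the road
#' network; quality from [new_park_defaults()]), re-runs the accessibility
#' and equity stages, and reports the changes: mean accessibility and
#' zero-accessibility counts per walking radius, blind-zone counts, and
#' LISA category counts. Existing parks keep their measured quality, so
#' removing the planned parks reproduces the before state exactly.
#'
#' @param city the original `city`.
#' @param plan a [assign_park_classes()] siting plan (possibly empty).
#' @param quality the original [park_quality()] table.
#' @param weights supply weights.
#' @param radii uniform walking radii to report.
#' @param n_classes geometric-interval classes.
#' @param equity list with `k`, `n_perm`, `alpha` for the LISA stage.
#' @param seed integer seed (entrance placement and permutation tests).
#' @param before optional precomputed list(access, lisa, blind) to avoid
#'   recomputing the pre-plan state.
#' @return object of class `plan_evaluation`: list with `before`, `after`
#'   (each: access, lisa, blind), and `deltas`.
#' @export
evaluate_plan <- function(city, plan, quality,
                          weights = default_supply_weights(),
                          radii = c(500, 1000, 2000, 3000), n_classes = 5,
                          equity = list(k = 8, n_perm = 999, alpha = 0.05),
                          seed = 1L, before = NULL) {
  run_state <- function(cty, qual) {
    dist <- residence_park_distances(cty)
    acc <- access_table(cty, qual, weights, radii, n_classes, dist)
    w <- build_weights(cty$residences, k = equity$k)
    lis <- bivariate_moran(acc$A_comprehensive, cty$residences$price, w,
                           n_perm = equity$n_perm, alpha = equity$alpha,
                           seed = seed)
    blind <- identify_blind_zones(acc, dist)
    list(access = acc, lisa = lis, blind = blind)
  }
  if (is.null(before)) before <- run_state(city, quality)
  city2 <- apply_plan(city, plan, seed = seed)
  if (nrow(plan)) {
    nd <- new_park_defaults()
    new_q <- data.frame(
      park_id = sprintf("N%02d", seq_len(nrow(plan))),
      S_hm2 = plan$area_hm2,
      ESV = unname(nd$esv[plan$class]),
      FCs_hm2 = nd$hard_fraction * plan$area_hm2, stringsAsFactors = FALSE)
    quality2 <- rbind(quality, new_q)
  } else quality2 <- quality
  after <- run_state(city2, quality2)
  acols <- grep("^A_", names(before$access), value = TRUE)
  deltas <- list(
    mean_accessibility = vapply(acols, function(cn) {
      mean(after$access[[cn]]) - mean(before$access[[cn]])
    }, numeric(1)),
    zero_count = vapply(acols, function(cn) {
      sum(after$access[[cn]] == 0) - sum(before$access[[cn]] == 0)
    }, numeric(1)),
    blind_counts_before = table(factor(before$blind$kind,
      levels = c("explicit", "implicit", "none"))),
    blind_counts_after = table(factor(after$blind$kind,
      levels = c("explicit", "implicit", "none"))),
    lisa_counts_before = before$lisa$counts,
    lisa_counts_after = after$lisa$counts)
  structure(list(before = before, after = after, deltas = deltas,
                 plan = plan),
            class = "plan_evaluation")
}

#' @export
print.plan_evaluation <- function(x, ...) {
  cat(sprintf("Plan evaluation: %d new park(s)\n", nrow(x$plan)))
  d <- x$deltas
  cat("  mean accessibility change per radius:\n")
  for (cn in names(d$mean_accessibility)) {
    cat(sprintf("    %-16s %+10.3g (zero count %+d)\n", cn,
                d$mean_accessibility[[cn]], d$zero_count[[cn]]))
  }
  cat(sprintf("  LL communities: %d -> %d; blind (explicit/implicit): %d/%d -> %d/%d\n",
              d$lisa_counts_before[["LL"]], d$lisa_counts_after[["LL"]],
              d$blind_counts_before[["explicit"]],
              d$blind_counts_before[["implicit"]],
              d$blind_counts_after[["explicit"]],
              d$blind_counts_after[["implicit"]]))
  invisible(x)
}
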