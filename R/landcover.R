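#' Generate a binary land-cover raster for a park
#'
#' Produces a green/other raster over the park's bounding box containing
#' exactly `n_patches` 4-connected green components. The raster is
#' partitioned into `n_patches` rectangular tiles (recursively split along
#' the longest side); one patch is grown inside each tile by randomized
#' frontier expansion, with a one-cell separation margin along shared tile
#' edges so patches can never merge.
#'
#' @param park one row of a city's `parks` data.frame (or any list with
#'   `w`, `h` in meters and optionally `id`, `cx`, `cy`).
#' @param n_patches number of green patches (>= 1).
#' @param seed integer seed; the raster is reproducible given
#'   (park, n_patches, seed).
#' @param cell_size raster cell size in meters (default 1 m).
#' @param green_fraction target green fraction of the raster in (0, 1].
#' @return an object of class `landcover`: list with `grid` (integer matrix,
#'   rows = y from the south edge, 1 = green), `cell`, `origin` (xll, yll)
#'   and `park_id`.
#' @examples
#' lc <- generate_park_landcover(list(id = "P01", w = 40, h = 30),
#'                               n_patches = 4, seed = 1)
#' table(lc$grid)
#' @export
generate_park_landcover <- function(park, n_patches, seed, cell_size = 1,
                                    green_fraction = 0.7) {
  stopifnot(n_patches >= 1, cell_size > 0,
            green_fraction > 0, green_fraction <= 1)
  nr <- max(1L, round(as.numeric(park$h) / cell_size))
  nc <- max(1L, round(as.numeric(park$w) / cell_size))
  if (n_patches > nr * nc)
    stop("patch count ", n_patches, " infeasible for a ", nr, "x", nc,
         " raster", call. = FALSE)
  set.seed(seed)
  tiles <- split_tiles(1L, nr, 1L, nc, n_patches)
  if (length(tiles) < n_patches)
    stop("patch count ", n_patches, " infeasible for a ", nr, "x", nc,
         " raster", call. = FALSE)
  # interior of each tile: drop the last row/col when another tile follows
  interiors <- lapply(tiles, function(t) {
    r1 <- if (t[2] < nr) t[2] - 1L else t[2]
    c1 <- if (t[4] < nc) t[4] - 1L else t[4]
    c(t[1], r1, t[3], c1)
  })
  sizes <- vapply(interiors, function(t) {
    max(0, t[2] - t[1] + 1) * max(0, t[4] - t[3] + 1)
  }, numeric(1))
  if (any(sizes < 1L))
    stop("patch count ", n_patches, " infeasible for a ", nr, "x", nc,
         " raster", call. = FALSE)
  target <- round(green_fraction * nr * nc)
  if (target > sum(sizes)) target <- sum(sizes)
  alloc <- pmax(1L, round(target * sizes / sum(sizes)))
  alloc <- pmin(alloc, sizes)
  # nudge rounding so the total matches the target where capacity allows
  gap <- target - sum(alloc)
  while (gap != 0) {
    if (gap > 0) {
      i <- which(alloc < sizes)[1]
      if (is.na(i)) break
      add <- min(gap, sizes[i] - alloc[i]); alloc[i] <- alloc[i] + add
      gap <- gap - add
    } else {
      i <- which(alloc > 1L)[1]
      if (is.na(i)) break
      take <- min(-gap, alloc[i] - 1L); alloc[i] <- alloc[i] - take
      gap <- gap + take
    }
  }
  grid <- matrix(0L, nr, nc)
  for (i in seq_len(n_patches)) {
    grid <- grow_patch(grid, interiors[[i]], alloc[i], nr)
  }
  origin <- c(
    if (!is.null(park$cx)) as.numeric(park$cx) - as.numeric(park$w) / 2 else 0,
    if (!is.null(park$cy)) as.numeric(park$cy) - as.numeric(park$h) / 2 else 0)
  structure(list(grid = grid, cell = cell_size, origin = origin,
                 park_id = if (!is.null(park$id)) park$id else NA_character_),
            class = "landcover")
}

#' @export
print.landcover <- function(x, ...) {
  cat(sprintf("landcover raster %s: %d x %d cells of %g m, green %.1f%%\n",
              x$park_id, nrow(x$grid), ncol(x$grid), x$cell,
              100 * mean(x$grid == 1L)))
  invisible(x)
}

# Recursive split of a [r0,r1]x[c0,c1] tile range into n tiles.
split_tiles <- function(r0, r1, c0, c1, n) {
  if (n == 1L) return(list(c(r0, r1, c0, c1)))
  n1 <- n %/% 2L; n2 <- n - n1
  nr <- r1 - r0 + 1L; nc <- c1 - c0 + 1L
  if (nr >= nc) {
    cut <- r0 + max(1L, round(nr * n1 / n)) - 1L
    cut <- min(cut, r1 - 1L)
    c(split_tiles(r0, cut, c0, c1, n1), split_tiles(cut + 1L, r1, c0, c1, n2))
  } else {
    cut <- c0 + max(1L, round(nc * n1 / n)) - 1L
    cut <- min(cut, c1 - 1L)
    c(split_tiles(r0, r1, c0, cut, n1), split_tiles(r0, r1, cut + 1L, c1, n2))
  }
}

# Randomized frontier growth of a single 4-connected patch inside an
# interior window; operates on linear cell indices for speed.
grow_patch <- function(grid, win, n_cells, nr) {
  r0 <- win[1]; r1 <- win[2]; c0 <- win[3]; c1 <- win[4]
  inwin <- function(idx) {
    r <- (idx - 1L) %% nr + 1L; cc <- (idx - 1L) %/% nr + 1L
    r >= r0 & r <= r1 & cc >= c0 & cc <= c1
  }
  sr <- (r0 + r1) %/% 2L; sc <- (c0 + c1) %/% 2L
  seed_idx <- (sc - 1L) * nr + sr
  patch <- logical(length(grid))
  patch[seed_idx] <- TRUE
  count <- 1L
  frontier <- seed_idx
  cell_nbrs <- function(idx) {
    r <- (idx - 1L) %% nr + 1L
    nb <- c(idx[r > 1L] - 1L, idx[r < nr] + 1L, idx - nr, idx + nr)
    nb[nb >= 1L & nb <= length(grid)]
  }
  while (count < n_cells && length(frontier)) {
    nb <- cell_nbrs(frontier)
    nb <- unique(nb[inwin(nb) & !patch[nb]])
    if (!length(nb)) break
    nb <- nb[sample.int(length(nb)) <= ceiling(0.7 * length(nb))]
    if (length(nb) > n_cells - count) {
      nb <- sample(nb, n_cells - count)
    }
    patch[nb] <- TRUE
    count <- count + length(nb)
    frontier <- nb
    if (count < n_cells && !length(frontier)) {
      # re-seed the frontier from the whole patch boundary
      frontier <- which(patch)
    }
  }
  if (count < n_cells) {
    # fill deterministically from remaining window cells adjacent to patch
    repeat {
      all_idx <- which(patch)
      nb <- cell_nbrs(all_idx)
      nb <- unique(nb[inwin(nb) & !patch[nb]])
      if (!length(nb) || count >= n_cells) break
      nb <- head(nb, n_cells - count)
      patch[nb] <- TRUE; count <- count + length(nb)
    }
  }
  grid[patch] <- 1L
  grid
}

#' Label 4-connected green patches in a binary raster
#'
#' @param grid integer/logical matrix; non-zero cells are green.
#' @return integer matrix of the same shape: 0 for background, 1..n for the
#'   patch labels.
#' @examples
#' m <- matrix(0L, 4, 4); m[1:2, 1:2] <- 1L; m[4, 4] <- 1L
#' max(label_patches(m))  # 2 patches
#' @export
label_patches <- function(grid) {
  nr <- nrow(grid); nc <- ncol(grid)
  green <- which(grid != 0)
  lab <- matrix(0L, nr, nc)
  if (!length(green)) return(lab)
  gmask <- grid != 0
  # lattice graph over green cells (right + down neighbours)
  r <- (green - 1L) %% nr + 1L
  right <- green + nr
  e_r <- right <= nr * nc & gmask[pmin(right, nr * nc)]
  down <- green + 1L
  e_d <- r < nr & gmask[pmin(down, nr * nc)]
  pos <- integer(nr * nc); pos[green] <- seq_along(green)
  edges <- rbind(
    cbind(pos[green[e_r]], pos[right[e_r]]),
    cbind(pos[green[e_d]], pos[down[e_d]]))
  g <- igraph::make_empty_graph(n = length(green), directed = FALSE)
  if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  lab[green] <- as.integer(comp)
  lab
}
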