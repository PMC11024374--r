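#' Landscape-pattern indices of a park's green land cover
#'
#' Computes nine class-level landscape-pattern indices on the 4-connected
#' green patches of a binary raster, using the standard raster formula
#' sheet. With patch areas \eqn{a_i} (hm2), patch perimeters \eqn{p_i} (m),
#' landscape (raster) area \eqn{A} (hm2, \eqn{A_{m^2}} in m2), number of
#' patches \eqn{n}, total green edge \eqn{E} (m), single-count like
#' (green-green) adjacencies \eqn{g} and the maximum like-adjacency count
#' \eqn{g_{max}} attainable by the same number of green cells:
#'
#' * `MESH` = \eqn{\sum a_i^2 / A} (hm2) — effective mesh size;
#' * `SPLIT` = \eqn{A^2 / \sum a_i^2} — splitting index;
#' * `AI` = \eqn{100\, g / g_{max}} (%) — aggregation index (0 when no
#'   like adjacency is possible, with a warning);
#' * `AREA_AM` = \eqn{\sum a_i^2 / \sum a_i} (hm2) — area-weighted mean
#'   patch area;
#' * `SHAPE_MN` = mean of \eqn{0.25\, p_i / \sqrt{a_{i,m^2}}} — mean shape
#'   index;
#' * `DIVISION` = \eqn{1 - \sum (a_i/A)^2} — division index;
#' * `PD` = \eqn{100\, n / A} — patches per 100 hm2;
#' * `LPI` = \eqn{100 \max a_i / A} (%) — largest patch index;
#' * `LSI` = \eqn{0.25\, E / \sqrt{A_{m^2}}} — landscape shape index.
#'
#' A landscape covered by one patch gives LPI = 100, DIVISION = 0,
#' SPLIT = 1, MESH = A and AI = 100; a checkerboard gives AI = 0.
#'
#' @param lc a `landcover` object (see [generate_park_landcover()] /
#'   [read_asc()]), or a binary matrix.
#' @param cell_size cell size in meters when `lc` is a bare matrix.
#' @return one-row data.frame with columns `park_id`, `MESH`, `SPLIT`,
#'   `AI`, `AREA_AM`, `SHAPE_MN`, `DIVISION`, `PD`, `LPI`, `LSI`.
#' @export
compute_patch_indices <- function(lc, cell_size = 1) {
  if (inherits(lc, "landcover")) {
    grid <- lc$grid; cell_size <- lc$cell
    pid <- lc$park_id
  } else { grid <- lc; pid <- NA_character_ }
  if (!length(grid) || !any(grid != 0))
    stop("raster has no green cells: landscape indices undefined",
         call. = FALSE)
  lab <- label_patches(grid)
  n <- max(lab)
  cells <- tabulate(lab[lab > 0], nbins = n)
  cell_hm2 <- cell_size^2 / 1e4
  a <- cells * cell_hm2                     # patch areas, hm2
  A <- length(grid) * cell_hm2              # landscape area, hm2
  # like adjacencies per patch (single count); patches of different labels
  # can never be 4-adjacent, so grouping by label is exact
  nr <- nrow(grid)
  right_same <- lab[, -ncol(grid), drop = FALSE] > 0 &
    lab[, -ncol(grid), drop = FALSE] == lab[, -1, drop = FALSE]
  down_same <- lab[-nr, , drop = FALSE] > 0 &
    lab[-nr, , drop = FALSE] == lab[-1, , drop = FALSE]
  gl <- tabulate(c(lab[, -ncol(grid)][right_same], lab[-nr, ][down_same]),
                 nbins = n)
  g <- sum(gl)
  perim <- (4 * cells - 2 * gl) * cell_size # patch perimeters, m
  E <- sum(perim)
  gmax <- max_like_adjacencies(sum(cells))
  if (gmax == 0) {
    warning("no like adjacency is possible for a single green cell; AI = 0")
    ai <- 0
  } else ai <- 100 * g / gmax
  data.frame(
    park_id = pid,
    MESH = sum(a^2) / A,
    SPLIT = A^2 / sum(a^2),
    AI = ai,
    AREA_AM = sum(a^2) / sum(a),
    SHAPE_MN = mean(0.25 * perim / sqrt(cells * cell_size^2)),
    DIVISION = 1 - sum((a / A)^2),
    PD = 100 * n / A,
    LPI = 100 * max(a) / A,
    LSI = 0.25 * E / sqrt(length(grid) * cell_size^2),
    stringsAsFactors = FALSE)
}

# Maximum single-count like adjacencies for n cells packed into the most
# compact (largest-square) arrangement.
max_like_adjacencies <- function(n_cells) {
  m <- floor(sqrt(n_cells))
  r <- n_cells - m^2
  if (r == 0) 2 * m * (m - 1)
  else if (r <= m) 2 * m * (m - 1) + 2 * r - 1
  else 2 * m * (m - 1) + 2 * r - 2
}

#' Direction-aware min-max standardization of landscape indices
#'
#' Positive indices (`AI`, `LPI`, `MESH` — larger is better green
#' structure) are scaled to \eqn{(x - min)/(max - min)}; negative indices
#' (`PD`, `LSI`, `AREA_AM`, `SHAPE_MN`, `DIVISION`, `SPLIT`) are inverted,
#' \eqn{(max - x)/(max - min)}, so 1 always means "least fragmented".
#' Constant columns are mapped to 0.5 with a warning.
#'
#' @param indices data.frame from rbinding [compute_patch_indices()] rows
#'   over parks (>= 2 rows).
#' @return numeric matrix in `[0, 1]`, rownames = park ids.
#' @export
standardize_indices <- function(indices) {
  if (nrow(indices) < 2)
    stop("standardization needs at least two parks", call. = FALSE)
  pos <- c("AI", "LPI", "MESH")
  neg <- c("PD", "LSI", "AREA_AM", "SHAPE_MN", "DIVISION", "SPLIT")
  m <- as.matrix(indices[, c(pos, neg)])
  rownames(m) <- indices$park_id
  out <- m
  for (j in colnames(m)) {
    x <- m[, j]
    rng <- max(x) - min(x)
    if (rng == 0) {
      warning("index '", j, "' is constant across parks; standardized to 0.5")
      out[, j] <- 0.5
    } else if (j %in% pos) {
      out[, j] <- (x - min(x)) / rng
    } else {
      out[, j] <- (max(x) - x) / rng
    }
  }
  out
}

#' Ecological-service composite from PCA of standardized indices
#'
#' Runs a correlation-matrix PCA on the standardized index matrix, retains
#' components with eigenvalue above 1 (Kaiser criterion; the leading
#' component is always kept), orients each retained component so its
#' loading sum is positive, weights component scores by their share of the
#' retained explained variance, and rescales the weighted score linearly to
#' mean 50 and standard deviation 25 across parks. Scores can be negative
#' for strongly fragmented parks.
#'
#' @param std standardized matrix from [standardize_indices()] (>= 3 rows).
#' @return named numeric vector of ESV scores, one per park.
#' @export
esv_from_pca <- function(std) {
  if (nrow(std) < 3)
    stop("ESV composite needs at least three parks", call. = FALSE)
  keep_cols <- apply(std, 2, function(x) sd(x) > 1e-12)
  if (!all(keep_cols)) {
    warning("dropping constant standardized columns from the PCA: ",
            paste(colnames(std)[!keep_cols], collapse = ", "))
  }
  m <- std[, keep_cols, drop = FALSE]
  pc <- prcomp(m, center = TRUE, scale. = TRUE)
  ev <- pc$sdev^2
  retain <- which(ev > 1)
  if (!length(retain)) retain <- 1L
  scores <- pc$x[, retain, drop = FALSE]
  loads <- pc$rotation[, retain, drop = FALSE]
  flip <- ifelse(colSums(loads) < 0, -1, 1)
  scores <- sweep(scores, 2, flip, `*`)
  wts <- ev[retain] / sum(ev[retain])
  raw <- drop(scores %*% wts)
  s <- sd(raw)
  esv <- if (s < 1e-12) rep(50, length(raw)) else 50 + 25 * (raw - mean(raw)) / s
  names(esv) <- rownames(std)
  esv
}

#' Recreational-facility capacity from hard-surface area
#'
#' FCs is the park's paved ("hard") surface area in hm2, either from an
#' explicit area or from a paved fraction of the park area.
#'
#' @param park list/row with `area_hm2` and either `hard_fraction` or
#'   `hard_area_m2`.
#' @return hard-surface area in hm2 (0 <= FCs <= park area).
#' @examples
#' compute_fcs(list(area_hm2 = 10, hard_fraction = 0.2))  # 2
#' compute_fcs(list(area_hm2 = 10, hard_area_m2 = 35000)) # 3.5
#' @export
compute_fcs <- function(park) {
  if (!is.null(park$hard_area_m2)) {
    fcs <- as.numeric(park$hard_area_m2) / 1e4
  } else if (!is.null(park$hard_fraction)) {
    if (park$hard_fraction < 0)
      stop("hard-surface fraction must be non-negative", call. = FALSE)
    fcs <- as.numeric(park$hard_fraction) * as.numeric(park$area_hm2)
  } else stop("park has neither 'hard_fraction' nor 'hard_area_m2'",
              call. = FALSE)
  if (fcs < 0) stop("hard-surface area must be non-negative", call. = FALSE)
  min(fcs, as.numeric(park$area_hm2))
}

#' Analytic-hierarchy-process weights from a pairwise judgment matrix
#'
#' Weights are the normalized principal eigenvector of the positive
#' reciprocal judgment matrix; consistency is assessed by
#' \eqn{CR = ((\lambda_{max} - n)/(n - 1)) / RI(n)} with Saaty's
#' random-index table, passing below 0.1.
#'
#' @param judgment n x n positive reciprocal matrix (`a_ji = 1/a_ij`,
#'   unit diagonal).
#' @return object of class `ahp_weights`: list with `weights` (sums to 1),
#'   `lambda_max`, `CR` and `pass`.
#' @examples
#' ahp_weights(matrix(c(1, 2, 5, 1/2, 1, 3, 1/5, 1/3, 1), 3, byrow = TRUE))
#' @export
ahp_weights <- function(judgment) {
  m <- as.matrix(judgment)
  n <- nrow(m)
  if (n != ncol(m) || any(m <= 0))
    stop("judgment matrix must be square and positive", call. = FALSE)
  if (max(abs(m * t(m) - 1)) > 1e-8 || max(abs(diag(m) - 1)) > 1e-12)
    stop("judgment matrix must be reciprocal with unit diagonal",
         call. = FALSE)
  e <- eigen(m)
  i <- which.max(Re(e$values))
  lambda <- Re(e$values[i])
  v <- abs(Re(e$vectors[, i]))
  w <- v / sum(v)
  ri_table <- c(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45, 1.49)
  cr <- if (n <= 2) 0 else ((lambda - n) / (n - 1)) / ri_table[n]
  structure(list(weights = setNames(w, rownames(m) %||% colnames(m)),
                 lambda_max = lambda, CR = cr, pass = cr < 0.1),
            class = "ahp_weights")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ahp_weights <- function(x, ...) {
  cat("AHP weights:", paste(sprintf("%.4f", x$weights), collapse = ", "),
      "\n")
  cat(sprintf("lambda_max = %.4f, CR = %.4f (%s)\n", x$lambda_max, x$CR,
              if (x$pass) "consistent, CR < 0.1" else "inconsistent"))
  invisible(x)
}

#' Default supply weights for the composite park supply
#'
#' The shipped weights for area (S), hard-surface capacity (FCs) and the
#' ecological-service composite (ESV) in the supply term
#' \eqn{C_j = w_1 S_j + w_2 FCs_j + w_3 ESV_j}: 0.7236, 0.1931 and 0.0833.
#' Use [ahp_weights()] to regenerate weights from your own judgment matrix.
#'
#' @return named numeric vector `c(S, FCs, ESV)` summing to 1.
#' @export
default_supply_weights <- function() {
  c(S = 0.7236, FCs = 0.1931, ESV = 0.0833)
}

#' Park quality table: area, ESV and FCs per park
#'
#' Generates (or takes) each park's land-cover raster, computes the nine
#' landscape indices, standardizes them across parks, collapses them to the
#' ESV composite by PCA, and adds the hard-surface FCs — the complete
#' supply-side quality input of the accessibility model.
#'
#' @param city a `city`.
#' @param landcovers optional named list of `landcover` rasters per park id
#'   (default: deterministic [city_landcovers()]).
#' @return data.frame with columns `park_id`, `S_hm2`, `ESV`, `FCs_hm2`.
#' @export
park_quality <- function(city, landcovers = city_landcovers(city)) {
  parks <- city$parks
  stopifnot(nrow(parks) >= 3)
  idx <- do.call(rbind, lapply(parks$id, function(pid) {
    compute_patch_indices(landcovers[[pid]])
  }))
  esv <- esv_from_pca(standardize_indices(idx))
  data.frame(
    park_id = parks$id,
    S_hm2 = parks$area_hm2,
    ESV = unname(esv[parks$id]),
    FCs_hm2 = vapply(seq_len(nrow(parks)),
                     function(i) compute_fcs(parks[i, ]), numeric(1)),
    stringsAsFactors = FALSE)
}
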