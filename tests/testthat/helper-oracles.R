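# Independent brute-force oracles. These deliberately use naive
# cell-by-cell / double-loop algorithms, distinct from the package's
# implementations, so agreement is informative.

# Flood-fill labeling of 4-connected non-zero cells (explicit stack).
oracle_label <- function(grid) {
  nr <- nrow(grid); nc <- ncol(grid)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (c0 in seq_len(nc)) for (r0 in seq_len(nr)) {
    if (grid[r0, c0] != 0 && lab[r0, c0] == 0L) {
      cur <- cur + 1L
      stack <- list(c(r0, c0))
      while (length(stack)) {
        rc <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        r <- rc[1]; cc <- rc[2]
        if (r < 1 || r > nr || cc < 1 || cc > nc) next
        if (grid[r, cc] == 0 || lab[r, cc] != 0L) next
        lab[r, cc] <- cur
        stack <- c(stack, list(c(r - 1, cc), c(r + 1, cc),
                               c(r, cc - 1), c(r, cc + 1)))
      }
    }
  }
  lab
}

# Cell-by-cell landscape indices from the documented formula sheet.
oracle_patch_indices <- function(grid, cell_size = 1) {
  lab <- oracle_label(grid)
  n <- max(lab)
  stopifnot(n >= 1)
  nr <- nrow(grid); nc <- ncol(grid)
  cells <- numeric(n); adj <- numeric(n); perim <- numeric(n)
  total_adj <- 0
  for (c0 in seq_len(nc)) for (r0 in seq_len(nr)) {
    l <- lab[r0, c0]
    if (l == 0) next
    cells[l] <- cells[l] + 1
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      r <- r0 + d[1]; cc <- c0 + d[2]
      like <- r >= 1 && r <= nr && cc >= 1 && cc <= nc && lab[r, cc] == l
      if (!like) perim[l] <- perim[l] + cell_size
      if (like) adj[l] <- adj[l] + 0.5
    }
  }
  a <- cells * cell_size^2 / 1e4
  A <- nr * nc * cell_size^2 / 1e4
  g <- sum(adj)
  ncell <- sum(cells)
  m <- floor(sqrt(ncell)); rr <- ncell - m^2
  gmax <- if (rr == 0) 2 * m * (m - 1) else if (rr <= m)
    2 * m * (m - 1) + 2 * rr - 1 else 2 * m * (m - 1) + 2 * rr - 2
  list(MESH = sum(a^2) / A,
       SPLIT = A^2 / sum(a^2),
       AI = if (gmax == 0) 0 else 100 * g / gmax,
       AREA_AM = sum(a^2) / sum(a),
       SHAPE_MN = mean(0.25 * perim / sqrt(cells * cell_size^2)),
       DIVISION = 1 - sum((a / A)^2),
       PD = 100 * n / A,
       LPI = 100 * max(a) / A,
       LSI = 0.25 * sum(perim) / sqrt(nr * nc * cell_size^2))
}

# All-pairs shortest paths by Floyd-Warshall on a dense matrix.
oracle_floyd_warshall <- function(D) {
  n <- nrow(D)
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  }
  D
}

# Textbook univariate local Moran with a full weight matrix.
oracle_local_moran <- function(x, W) {
  n <- length(x)
  z <- x - mean(x)
  m2 <- sum(z^2) / n
  sapply(seq_len(n), function(i) (z[i] / m2) * sum(W[i, ] * z))
}

# Dense weight matrix from a parkequity spatial_weights object.
weights_matrix <- function(w) {
  W <- matrix(0, w$n, w$n)
  for (i in seq_len(w$n)) W[i, w$nb[i, ]] <- w$w
  W
}

# Principal eigenvector + lambda by plain power iteration.
oracle_power_iteration <- function(M, iters = 2000) {
  v <- rep(1, nrow(M))
  for (i in seq_len(iters)) {
    v2 <- as.vector(M %*% v)
    v <- v2 / sqrt(sum(v2^2))
  }
  lambda <- as.numeric(t(v) %*% M %*% v) / sum(v^2)
  list(weights = v / sum(v), lambda = lambda)
}

# ESV composite recomputed through an explicit eigendecomposition of the
# correlation matrix (vs the package's prcomp route).
oracle_esv <- function(std) {
  keep <- apply(std, 2, function(x) sd(x) > 1e-12)
  m <- std[, keep, drop = FALSE]
  z <- scale(m)
  e <- eigen(stats::cor(m))
  retain <- which(e$values > 1)
  if (!length(retain)) retain <- 1L
  vec <- e$vectors[, retain, drop = FALSE]
  flip <- ifelse(colSums(vec) < 0, -1, 1)
  vec <- sweep(vec, 2, flip, `*`)
  scores <- z %*% vec
  wts <- e$values[retain] / sum(e$values[retain])
  raw <- drop(scores %*% wts)
  50 + 25 * (raw - mean(raw)) / sd(raw)
}
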