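## Online self-organizing map over per-gene expression profiles.

#' Train a self-organizing map on standardized expression profiles
#'
#' Online SOM on a rectangular grid (5x5 for the default 25 units). One
#' random gene profile is presented per iteration; the best-matching unit
#' and its grid neighbourhood (Gaussian kernel) move toward it. The
#' learning rate decays linearly 0.05 to 0.01 and the neighbourhood radius
#' 2 to 0.5 over the run. After training every gene is assigned to its
#' best-matching unit, and each unit gets a per-population "eigen profile":
#' the first eigenvector of its member genes' group-mean profiles,
#' sign-fixed to a positive mean (the value rendered per condition in the
#' cluster heat map).
#'
#' @param zmat genes-by-samples matrix of standardized values (from
#'   [zTransform()]).
#' @param population sample population labels (needed for the eigen
#'   profiles; `NULL` skips them).
#' @param n_units number of grid units (default 25).
#' @param iterations training iterations (default 20000).
#' @param seed RNG seed; training is deterministic under it.
#' @param lr_range learning-rate schedule (start, end).
#' @param radius_range neighbourhood-radius schedule (start, end).
#' @return a [SOMGrid].
#' @export
somTrain <- function(zmat, population = NULL, n_units = 25,
                     iterations = 20000, seed = 1,
                     lr_range = c(0.05, 0.01), radius_range = c(2, 0.5)) {
  zmat <- as.matrix(zmat)
  n_genes <- nrow(zmat)
  d <- ncol(zmat)
  if (n_genes < n_units)
    warning("fewer genes (", n_genes, ") than units (", n_units,
            "); some units will be empty")
  ## squarest grid factorization
  rows <- floor(sqrt(n_units))
  while (n_units %% rows != 0L) rows <- rows - 1L
  cols <- n_units %/% rows
  grid_xy <- cbind(rep(seq_len(rows), times = cols),
                   rep(seq_len(cols), each = rows))
  grid_d2 <- as.matrix(stats::dist(grid_xy))^2
  set.seed(seed)
  ## random init scaled to the data: training then organizes the map and
  ## the quantization error decreases as the neighbourhood shrinks
  W <- matrix(rnorm(n_units * d, mean = mean(zmat), sd = stats::sd(zmat)),
              n_units, d, dimnames = list(paste0("U", seq_len(n_units)),
                                          colnames(zmat)))
  order_idx <- sample(n_genes, iterations, replace = TRUE)
  qe_at <- unique(round(seq(1, iterations, length.out = 10)))
  qe <- numeric(0)
  quantErr <- function() {
    D <- outer(rowSums(zmat^2), rowSums(W^2), `+`) - 2 * zmat %*% t(W)
    mean(sqrt(pmax(apply(D, 1, min), 0)))
  }
  for (it in seq_len(iterations)) {
    x <- zmat[order_idx[it], ]
    frac <- (it - 1) / max(iterations - 1, 1)
    lr <- lr_range[1] + frac * (lr_range[2] - lr_range[1])
    sigma <- radius_range[1] + frac * (radius_range[2] - radius_range[1])
    bmu <- which.min(rowSums(sweep(W, 2, x)^2))
    h <- exp(-grid_d2[bmu, ] / (2 * sigma^2))
    W <- W + (lr * h) * sweep(-W, 2, x, `+`)
    if (it %in% qe_at) qe <- c(qe, quantErr())
  }
  D <- outer(rowSums(zmat^2), rowSums(W^2), `+`) - 2 * zmat %*% t(W)
  assignment <- setNames(apply(D, 1, which.min), rownames(zmat))
  eig <- matrix(NA_real_, n_units, 0)
  if (!is.null(population)) {
    gm <- groupMeans(zmat, population)
    eig <- matrix(NA_real_, n_units, ncol(gm),
                  dimnames = list(rownames(W), colnames(gm)))
    for (u in seq_len(n_units)) {
      members <- which(assignment == u)
      if (!length(members)) next
      block <- gm[members, , drop = FALSE]
      if (nrow(block) == 1L) {
        v <- block[1, ] / sqrt(sum(block[1, ]^2))
      } else {
        v <- svd(block, nu = 0, nv = 1)$v[, 1]
      }
      if (mean(v) < 0) v <- -v
      eig[u, ] <- v
    }
  }
  SOMGrid(codebook = W,
          assignment = setNames(as.integer(assignment), rownames(zmat)),
          gridDim = as.integer(c(rows, cols)),
          iterations = as.integer(iterations),
          eigenProfiles = eig, qeHistory = qe)
}
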