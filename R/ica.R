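#' Construct a component set
#'
#' Pairs of spatial maps (z-scored over the mask) and unit-variance time
#' courses, as produced by [spatial_ica()].
#'
#' @param maps List of 3D arrays (one per component).
#' @param courses `n_frames x n_components` matrix.
#' @param mask The [brain_mask()] the maps live on.
#' @param explained_variance Fraction of data variance retained by the
#'   component subspace, in (0, 1].
#' @return An object of class `component_set`.
#' @export
component_set <- function(maps, courses, mask, explained_variance) {
  courses <- as.matrix(courses)
  if (length(maps) != ncol(courses)) stop("maps and courses must be paired")
  if (!(explained_variance > 0 && explained_variance <= 1))
    stop("explained variance must lie in (0, 1]")
  structure(list(maps = maps, courses = courses, mask = mask,
                 n_components = length(maps),
                 n_frames = nrow(courses),
                 explained_variance = explained_variance),
            class = "component_set")
}

# Symmetric fixed-point ICA (tanh contrast) on whitened data Z (K x samples).
# Returns the K x K orthogonal unmixing matrix. Deterministic given the
# initial matrix W0.
fastica_symm <- function(Z, W0, max_iter = 1000, tol = 1e-4) {
  sym_decorrelate <- function(W) {
    sw <- W %*% t(W)
    e <- eigen(sw, symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12)), nrow(W)) %*%
      t(e$vectors) %*% W
  }
  W <- sym_decorrelate(W0)
  n <- ncol(Z)
  mu <- 1            # damping factor; shrunk when the update oscillates
  conv_prev <- Inf
  for (it in seq_len(max_iter)) {
    WZ <- W %*% Z
    G <- tanh(WZ)
    gprime <- rowMeans(1 - G^2)
    W1 <- (G %*% t(Z)) / n - diag(gprime, nrow(W)) %*% W
    # convergence is judged on the undamped candidate (a damped step being
    # small must not masquerade as a fixed point); the damped step is what
    # is applied, which breaks the 2-cycles the symmetric iteration can
    # fall into
    W1u <- sym_decorrelate(W1)
    conv <- max(abs(abs(diag(W1u %*% t(W))) - 1))
    if (conv < tol) return(list(W = W1u, converged = TRUE, iter = it))
    W <- if (mu >= 1) W1u else sym_decorrelate(mu * W1 + (1 - mu) * W)
    if (conv >= conv_prev) mu <- max(mu * 0.9, 0.05)
    conv_prev <- conv
  }
  list(W = W, converged = FALSE, iter = max_iter)
}

#' Single-session spatial ICA
#'
#' The in-mask voxels x frames matrix is reduced to `n_components` by PCA
#' over time, then a fixed-point ICA (symmetric orthogonalization, tanh
#' contrast) rotates the whitened spatial data to maximize spatial
#' non-Gaussianity. Maps are z-scored over the mask; each course is unit
#' variance; map signs are fixed so every map's skewness is >= 0. Up to
#' `restarts` seeded re-initializations are attempted on non-convergence.
#'
#' @param series A [bold_series()] (already high-pass filtered).
#' @param mask A [brain_mask()].
#' @param n_components Number of components (default 40; must be below
#'   `n_frames`).
#' @param seed Integer seed controlling the (deterministic) initialization.
#' @param max_iter,tol Fixed-point iteration controls.
#' @param restarts Maximum seeded restarts on non-convergence.
#' @return A [component_set()].
#' @export
spatial_ica <- function(series, mask, n_components = 40, seed,
                        max_iter = 1000, tol = 1e-4, restarts = 5) {
  stopifnot(inherits(series, "bold_series"), inherits(mask, "brain_mask"))
  if (missing(seed)) stop("spatial_ica requires an explicit seed")
  if (n_components >= series$n_frames)
    stop("n_components must be below n_frames")
  X <- mask_matrix(series, mask)                 # voxels x frames
  idx <- attr(X, "voxel_index")
  X <- X - rowMeans(X)                           # remove voxel means
  X <- sweep(X, 2, colMeans(X))                  # centre each frame map
  K <- n_components
  sv <- svd(X, nu = 0, nv = K)
  total_var <- sum(X^2)
  expl <- sum(sv$d[seq_len(K)]^2) / total_var
  nvox <- nrow(X)
  # whitened spatial data: K x voxels, unit variance per row
  Z <- t(X %*% sv$v) / (sv$d[seq_len(K)] / sqrt(nvox))
  fit <- NULL
  for (r in seq_len(restarts)) {
    W0 <- with_seed(seed + (r - 1L) * 1000003L,
                    matrix(stats::rnorm(K * K), K, K))
    fit <- fastica_symm(Z, W0, max_iter = max_iter, tol = tol)
    if (fit$converged) break
  }
  if (!fit$converged)
    stop("fixed-point ICA did not converge after ", restarts,
         " seeded restarts; try a different seed or fewer components")
  S <- fit$W %*% Z                               # K x voxels spatial sources
  # mixing: courses such that X ~ t(S) %*% courses'
  A <- t(X) %*% t(S) / nvox                      # frames x K
  # sign convention: non-negative map skewness
  sk <- apply(S, 1, function(v) mean((v - mean(v))^3))
  flip <- ifelse(sk < 0, -1, 1)
  S <- S * flip
  A <- sweep(A, 2, flip, `*`)
  # unit-variance courses; maps z-scored over the mask
  cs <- apply(A, 2, stats::sd)
  cs[cs == 0] <- 1
  A <- sweep(A, 2, cs, `/`)
  maps <- vector("list", K)
  d <- series$grid$dim
  for (k in seq_len(K)) {
    v <- S[k, ]
    v <- (v - mean(v)) / stats::sd(v)
    m <- array(0, dim = d)
    m[idx] <- v
    maps[[k]] <- m
  }
  component_set(maps, A, mask, explained_variance = min(expl, 1))
}

# 26-connected cluster labelling of a logical 3D array; returns cluster
# sizes (voxels), descending.
cluster_sizes_26 <- function(bin) {
  d <- dim(bin)
  idx <- which(bin)
  if (length(idx) == 0) return(integer(0))
  co <- arrayInd(idx, d)
  key <- (co[, 1]) + (co[, 2] - 1) * (d[1] + 2L) +
    (co[, 3] - 1) * (d[1] + 2L) * (d[2] + 2L)
  lookup <- new.env(hash = TRUE, size = length(idx))
  for (i in seq_along(idx)) assign(as.character(key[i]), i, envir = lookup)
  parent <- seq_along(idx)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  okey <- offs$dx + offs$dy * (d[1] + 2L) + offs$dz * (d[1] + 2L) * (d[2] + 2L)
  for (i in seq_along(idx)) {
    for (o in okey) {
      j <- mget(as.character(key[i] + o), envir = lookup,
                ifnotfound = list(NULL))[[1]]
      if (!is.null(j)) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_along(idx), find, integer(1))
  sort(as.integer(table(roots)), decreasing = TRUE)
}

#' FIX-style per-component features
#'
#' Spatial features are computed on the thresholded map (`|z| >=
#' z_threshold` inside the mask, 26-connected clusters); temporal features
#' come from the course periodogram and moments.
#'
#' @param cs A [component_set()].
#' @param mask A [brain_mask()] (defaults to the set's own mask).
#' @param z_threshold Map threshold (> 0), default 2.3.
#' @param tr_vol Sampling interval for spectral features; defaults to
#'   1.6 s when the component set carries none.
#' @return `data.frame` with one row per component: `n_clusters`,
#'   `largest_cluster_frac`, `supra_frac`, `rim_frac`, `slice_conc`,
#'   `low_band_frac`, `peak_freq`, `kurtosis`, `empty_map`.
#' @export
extract_features <- function(cs, mask = NULL, z_threshold = 2.3,
                             tr_vol = 1.6) {
  stopifnot(inherits(cs, "component_set"))
  if (z_threshold <= 0) stop("z threshold must be > 0")
  if (is.null(mask)) mask <- cs$mask
  mask_arr <- mask$voxels
  n_mask <- sum(mask_arr)
  rim <- mask_boundary(mask_arr)
  nt <- cs$n_frames
  out <- data.frame(n_clusters = integer(cs$n_components))
  for (k in seq_len(cs$n_components)) {
    m <- cs$maps[[k]]
    supra <- abs(m) >= z_threshold & mask_arr
    ns <- sum(supra)
    if (ns == 0) {
      out$n_clusters[k] <- 0L
      out$largest_cluster_frac[k] <- 0
      out$supra_frac[k] <- 0
      out$rim_frac[k] <- 0
      out$slice_conc[k] <- 0
      out$empty_map[k] <- TRUE
    } else {
      sizes <- cluster_sizes_26(supra)
      out$n_clusters[k] <- length(sizes)
      out$largest_cluster_frac[k] <- sizes[1] / ns
      out$supra_frac[k] <- ns / n_mask
      out$rim_frac[k] <- sum(supra & rim) / ns
      out$slice_conc[k] <- max(apply(supra, 3, sum)) / ns
      out$empty_map[k] <- FALSE
    }
    x <- cs$courses[, k]
    x <- x - mean(x)
    pw <- Mod(stats::fft(x))^2
    half <- 2:(floor(nt / 2) + 1)
    freqs <- (half - 1) / (nt * tr_vol)
    p <- pw[half]
    tot <- sum(p)
    out$low_band_frac[k] <- if (tot > 0)
      sum(p[freqs >= 0.01 & freqs <= 0.1]) / tot else 0
    out$peak_freq[k] <- if (tot > 0) freqs[which.max(p)] else 0
    v <- mean(x^2)
    out$kurtosis[k] <- if (v > 0) mean(x^4) / v^2 else 0
  }
  out
}

#' Regress artifact components out of a 4D series ("cleaning")
#'
#' Aggressive mode removes, from every voxel course, the least-squares fit
#' of the artifact courses plus an intercept. Soft mode fits the full
#' course set and subtracts only the artifact betas. An empty artifact
#' list returns the input unchanged.
#'
#' @param series A [bold_series()].
#' @param cs The [component_set()] from [spatial_ica()].
#' @param artifact_idx Integer component indices (1-based) to remove.
#' @param mode `"aggressive"` (default) or `"soft"`.
#' @return The cleaned [bold_series()].
#' @export
clean_series <- function(series, cs, artifact_idx,
                         mode = c("aggressive", "soft")) {
  stopifnot(inherits(series, "bold_series"), inherits(cs, "component_set"))
  mode <- match.arg(mode)
  artifact_idx <- as.integer(artifact_idx)
  if (length(artifact_idx) == 0) return(series)
  if (any(artifact_idx < 1 | artifact_idx > cs$n_components))
    stop("artifact index out of range 1..", cs$n_components)
  flat <- matrix(series$data, ncol = series$n_frames)
  if (mode == "aggressive") {
    X <- cbind(1, cs$courses[, artifact_idx, drop = FALSE])
    beta <- solve(crossprod(X), crossprod(X, t(flat)))
    fitted <- t(X[, -1, drop = FALSE] %*% beta[-1, , drop = FALSE])
  } else {
    X <- cbind(1, cs$courses)
    beta <- solve(crossprod(X), crossprod(X, t(flat)))
    keep <- 1 + artifact_idx
    fitted <- t(X[, keep, drop = FALSE] %*% beta[keep, , drop = FALSE])
  }
  bold_series(array(flat - fitted, dim = dim(series$data)), series$grid,
              series$tr_vol)
}
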