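#' Edgewise two-sample t statistics between groups of z matrices
#'
#' Pooled-variance two-sample t per off-diagonal edge for the one-tailed
#' contrast A > B; the opposite contrast is the exact sign flip. Edges
#' with zero pooled variance get t = 0 and are flagged.
#'
#' @param group_a,group_b Lists of symmetric z-space matrices (>= 2 each,
#'   common ROI set).
#' @return List with `t` (matrix, contrast A > B), `df`, and
#'   `zero_variance` (logical matrix of flagged edges).
#' @export
edgewise_t <- function(group_a, group_b) {
  ga <- lapply(group_a, function(x) if (inherits(x, "fc_matrix")) x$m else x)
  gb <- lapply(group_b, function(x) if (inherits(x, "fc_matrix")) x$m else x)
  if (length(ga) < 2 || length(gb) < 2) stop("need >= 2 subjects per group")
  p <- nrow(ga[[1]])
  if (!all(vapply(c(ga, gb), function(m) all(dim(m) == p), logical(1))))
    stop("matrices must share one ROI set")
  na <- length(ga); nb <- length(gb)
  aa <- simplify2array(ga); bb <- simplify2array(gb)
  ma <- apply(aa, c(1, 2), mean); mb <- apply(bb, c(1, 2), mean)
  va <- apply(aa, c(1, 2), stats::var); vb <- apply(bb, c(1, 2), stats::var)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  tmat <- (ma - mb) / se
  zero <- se == 0
  tmat[zero] <- 0
  diag(tmat) <- 0
  list(t = tmat, df = na + nb - 2, zero_variance = zero & upper.tri(zero))
}

# Union-find max/all connected components over suprathreshold edges.
# edges: two-column matrix of node indices. Returns component membership.
edge_components <- function(edges, n_nodes) {
  parent <- seq_len(n_nodes)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (r in seq_len(nrow(edges))) {
    a <- find(edges[r, 1]); b <- find(edges[r, 2])
    if (a != b) parent[a] <- b
  }
  vapply(seq_len(n_nodes), find, integer(1))
}

#' Connected components of suprathreshold edges
#'
#' Builds the graph over ROIs whose edges have `t >= threshold` and
#' returns its connected components; a component's size is its edge count
#' (the extent variant of the network-based statistic).
#'
#' @param tmat Symmetric t matrix.
#' @param threshold Positive t threshold.
#' @return List of components, each with `nodes`, `edges` (two-column
#'   matrix), `n_edges`, `n_nodes`; ordered by decreasing `n_edges`.
#' @export
suprathreshold_components <- function(tmat, threshold) {
  p <- nrow(tmat)
  ut <- which(upper.tri(tmat) & tmat >= threshold, arr.ind = TRUE)
  if (nrow(ut) == 0) return(list())
  memb <- edge_components(ut, p)
  roots <- unique(memb[unique(as.integer(ut))])
  comps <- lapply(roots, function(r) {
    sel <- memb[ut[, 1]] == r
    e <- ut[sel, , drop = FALSE]
    nodes <- sort(unique(as.integer(e)))
    list(nodes = nodes, edges = e, n_edges = nrow(e),
         n_nodes = length(nodes))
  })
  comps[order(-vapply(comps, `[[`, integer(1), "n_edges"))]
}

# Max component edge count among edges (upper-tri index pairs) marked TRUE.
max_component_edges <- function(keep_idx, edge_nodes, n_nodes) {
  if (length(keep_idx) == 0) return(0L)
  e <- edge_nodes[keep_idx, , drop = FALSE]
  memb <- edge_components(e, n_nodes)
  max(tabulate(memb[e[, 1]]))
}

#' Network-based statistic group comparison
#'
#' Edgewise one-tailed two-sample t-tests in both directions, connected
#' suprathreshold components, and FWER-corrected p-values from the
#' permutation distribution of the maximal component size (group labels
#' permuted with sizes preserved; each contrast has its own null).
#' `p = (1 + #\{perm max >= observed size\}) / (P + 1)`, so p-values are
#' never zero; results are reproducible given the seed.
#'
#' @param group_a,group_b Lists of z-space matrices.
#' @param threshold t threshold (> 0), default 2.2.
#' @param n_perm Number of permutations P, default 5000.
#' @param seed Integer seed.
#' @return An object of class `nbs_result`: per contrast (`a_gt_b`,
#'   `b_gt_a`) the t matrix, component list with `p_fwer` attached, and
#'   the permutation null of the max component size.
#' @export
nbs_test <- function(group_a, group_b, threshold = 2.2, n_perm = 5000, seed) {
  if (missing(seed)) stop("nbs_test requires an explicit seed")
  if (threshold <= 0) stop("threshold must be > 0")
  if (n_perm < 1) stop("need >= 1 permutation")
  na <- length(group_a); nb <- length(group_b)
  if (na + nb < 4) stop("need >= 4 subjects in total")
  obs <- edgewise_t(group_a, group_b)
  p <- nrow(obs$t)
  ut_idx <- which(upper.tri(obs$t))
  edge_nodes <- arrayInd(ut_idx, c(p, p))
  mats <- lapply(c(group_a, group_b),
                 function(x) if (inherits(x, "fc_matrix")) x$m else x)
  Z <- t(vapply(mats, function(m) m[ut_idx], numeric(length(ut_idx))))
  n <- na + nb
  t_for <- function(sel_a) {
    za <- Z[sel_a, , drop = FALSE]; zb <- Z[!sel_a, , drop = FALSE]
    ma <- colMeans(za); mb <- colMeans(zb)
    va <- (colSums(za^2) - na * ma^2) / (na - 1)
    vb <- (colSums(zb^2) - nb * mb^2) / (nb - 1)
    se <- sqrt(pmax(((na - 1) * va + (nb - 1) * vb) / (n - 2), 0) *
                 (1 / na + 1 / nb))
    tv <- (ma - mb) / se
    tv[se == 0] <- 0
    tv
  }
  null1 <- integer(n_perm)
  null2 <- integer(n_perm)
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      sel <- logical(n)
      sel[sample.int(n, na)] <- TRUE
      tv <- t_for(sel)
      null1[b] <- max_component_edges(which(tv >= threshold), edge_nodes, p)
      null2[b] <- max_component_edges(which(-tv >= threshold), edge_nodes, p)
    }
  })
  contrast <- function(tmat, null) {
    comps <- suprathreshold_components(tmat, threshold)
    for (i in seq_along(comps)) {
      comps[[i]]$p_fwer <- (1 + sum(null >= comps[[i]]$n_edges)) / (n_perm + 1)
    }
    list(t = tmat, components = comps, null_max_size = null)
  }
  structure(list(a_gt_b = contrast(obs$t, null1),
                 b_gt_a = contrast(-obs$t, null2),
                 threshold = threshold, n_perm = n_perm, seed = seed,
                 df = obs$df),
            class = "nbs_result")
}

#' @export
print.nbs_result <- function(x, ...) {
  cat(sprintf("<nbs_result> threshold %.2f, %d permutations\n",
              x$threshold, x$n_perm))
  for (nm in c("a_gt_b", "b_gt_a")) {
    co <- x[[nm]]$components
    cat(sprintf("  contrast %s: %d component(s)%s\n", nm, length(co),
                if (length(co))
                  paste0(" (largest ", co[[1]]$n_edges, " edges, p = ",
                         signif(co[[1]]$p_fwer, 3), ")") else ""))
  }
  invisible(x)
}
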