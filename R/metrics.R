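#' Patristic (cophenetic) distance matrix of a tree
#'
#' First-principles computation of all pairwise tip-to-tip path lengths:
#' d(i, j) is the sum of branch lengths along the path between tips i
#' and j.  For every internal node, pairs of tips drawn from different
#' child subtrees satisfy d(i, j) = depth(i) + depth(j) - 2 depth(node),
#' which is accumulated in one postorder sweep.
#'
#' @param tree a `phylo` object with branch lengths.
#' @return A symmetric matrix with dimnames equal to the tip labels and
#'   a zero diagonal.
#' @export
cophenetic_distances <- function(tree) {
  validate_tree(tree)
  ti <- tree_indices(tree)
  n <- ti$ntip
  D <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  if (n == 1L) return(D)
  tipsets <- vector("list", ti$ntot)
  for (i in seq_len(n)) tipsets[[i]] <- i
  for (v in rev(ti$bfs)) {
    ch <- ti$children[[v]]
    if (!length(ch)) next
    sets <- tipsets[ch]
    nch <- length(sets)
    for (a in seq_len(nch - 1L)) {
      for (b in seq((a + 1L), nch)) {
        ta <- sets[[a]]; tb <- sets[[b]]
        d <- outer(ti$depth[ta], ti$depth[tb], "+") - 2 * ti$depth[v]
        D[ta, tb] <- d
        D[tb, ta] <- t(d)
      }
    }
    tipsets[[v]] <- unlist(sets, use.names = FALSE)
  }
  D
}

# Resolve a community (character tip labels) against a distance matrix
# or tree tip set; errors on unknown labels.
resolve_community <- function(community, labels, what = "distance matrix") {
  if (length(community) == 0L) return(integer(0))
  community <- as.character(community)
  if (anyDuplicated(community)) community <- unique(community)
  idx <- match(community, labels)
  if (anyNA(idx)) {
    stop("community members absent from the ", what, ": ",
         paste(community[is.na(idx)], collapse = ", "))
  }
  idx
}

#' Mean pairwise distance (MPD) of a community
#'
#' Unweighted presence-absence MPD: the arithmetic mean of the patristic
#' distances over all n(n-1)/2 distinct pairs of co-occurring taxa.
#' Undefined (returned as `NA`) for communities of fewer than two taxa;
#' downstream surfaces record such cells as missing, never as zero.
#'
#' @param community character vector of tip labels present at a site.
#' @param dist a distance matrix from [cophenetic_distances()].
#' @return The mean pairwise distance, or `NA_real_` when n < 2.
#' @export
mpd <- function(community, dist) {
  idx <- resolve_community(community, rownames(dist))
  n <- length(idx)
  if (n < 2L) return(NA_real_)
  d <- dist[idx, idx, drop = FALSE]
  sum(d) / (n * (n - 1))
}

#' Mean nearest taxon distance (MNTD) of a community
#'
#' The mean, over community members, of the patristic distance to the
#' nearest co-occurring taxon.  `NA` for communities of fewer than two
#' taxa.
#'
#' @inheritParams mpd
#' @return The mean nearest-taxon distance, or `NA_real_` when n < 2.
#' @export
mntd <- function(community, dist) {
  idx <- resolve_community(community, rownames(dist))
  n <- length(idx)
  if (n < 2L) return(NA_real_)
  d <- dist[idx, idx, drop = FALSE]
  diag(d) <- Inf
  mean(apply(d, 1L, min))
}

#' Faith's phylogenetic diversity (PD) of a community
#'
#' Total branch length of the minimal subtree spanning the community's
#' tips.  By default the spanning subtree is the union of tip-to-tip
#' paths (it is not forced down to the tree root), so a single-species
#' community has PD = 0; set `include_root = TRUE` for the root-inclusive
#' variant that also counts the path from the subtree to the root.
#'
#' @param community character vector of tip labels.
#' @param tree a `phylo` object.
#' @param include_root include the stem path from the community's most
#'   recent common ancestor up to the tree root (default FALSE).
#' @return Summed branch length, or `NA_real_` for an empty community.
#' @export
faith_pd <- function(community, tree, include_root = FALSE) {
  validate_tree(tree)
  idx <- resolve_community(community, tree$tip.label, what = "tree")
  n <- length(idx)
  if (n == 0L) return(NA_real_)
  ti <- tree_indices(tree)
  cnt <- numeric(ti$ntot)
  cnt[idx] <- 1
  for (v in rev(ti$bfs)) {
    ch <- ti$children[[v]]
    if (length(ch)) cnt[v] <- sum(cnt[ch])
  }
  child <- tree$edge[, 2]
  keep <- cnt[child] > 0
  if (!include_root) keep <- keep & cnt[child] < n
  sum(tree$edge.length[keep])
}

# --- vectorized per-cell metric computation over a presence matrix ----

# P: binary cells x species matrix whose columns align with `labels`.
cells_mpd <- function(P, D) {
  n <- rowSums(P)
  s2 <- rowSums((P %*% D) * P)  # each unordered pair counted twice
  out <- s2 / (n * (n - 1))
  out[n < 2] <- NA_real_
  out
}

cells_mntd <- function(P, D) {
  n <- rowSums(P)
  out <- rep(NA_real_, nrow(P))
  Dinf <- D
  diag(Dinf) <- Inf
  for (i in which(n >= 2)) {
    sp <- which(P[i, ] > 0)
    d <- Dinf[sp, sp, drop = FALSE]
    out[i] <- mean(apply(d, 1L, min))
  }
  out
}

cells_pd <- function(P, tree, include_root = FALSE) {
  ti <- tree_indices(tree)
  sp_idx <- match(colnames(P), tree$tip.label)
  # per-edge membership: M[s, e] = 1 iff species s is in the clade below
  # edge e; built by accumulating indicator columns up the tree.
  ind <- matrix(0, nrow = ncol(P), ncol = ti$ntot)
  ind[cbind(seq_len(ncol(P)), sp_idx)] <- 1
  for (v in rev(ti$bfs)) {
    ch <- ti$children[[v]]
    if (length(ch) == 1L) ind[, v] <- ind[, ch]
    else if (length(ch) > 1L) ind[, v] <- rowSums(ind[, ch, drop = FALSE])
  }
  child <- tree$edge[, 2]
  M <- ind[, child, drop = FALSE]
  cnt <- P %*% M                      # cells x edges: community tips below edge
  n <- rowSums(P)
  keep <- cnt > 0
  if (!include_root) keep <- keep & (cnt < n)
  out <- as.numeric(keep %*% tree$edge.length)
  out[n < 1] <- NA_real_
  out
}

#' Summarize a metric across a set of trees
#'
#' Computes one community metric (MPD, MNTD or Faith's PD) for every
#' grid cell of a presence-absence matrix, once per tree in a posterior
#' set, and returns the per-cell mean together with the range (min, max)
#' across trees.  Cells where the metric is undefined (fewer than two
#' taxa for MPD/MNTD, no taxa for PD) are missing in all three columns.
#'
#' @param community_matrix a [community_matrix()] object.
#' @param trees a list of `phylo` objects; every species column of the
#'   matrix must appear in every tree.
#' @param metric one of `"mpd"`, `"mntd"`, `"pd"`.
#' @param include_root root-inclusive PD variant (see [faith_pd()]).
#' @return A [metric_surface()] with columns `cell`, `x`, `y`, `value`
#'   (the across-tree mean), `vmin`, `vmax`.
#' @export
summarize_over_trees <- function(community_matrix, trees,
                                 metric = c("mpd", "mntd", "pd"),
                                 include_root = FALSE) {
  metric <- match.arg(metric)
  stopifnot(inherits(community_matrix, "community_matrix"))
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (length(trees) < 1L) stop("need at least one tree")
  P <- community_matrix$pa
  species <- colnames(P)
  for (k in seq_along(trees)) {
    missing <- setdiff(species, trees[[k]]$tip.label)
    if (length(missing)) {
      stop(sprintf("tree %d is missing %d species: %s", k, length(missing),
                   paste(missing, collapse = ", ")))
    }
  }
  vals <- matrix(NA_real_, nrow = nrow(P), ncol = length(trees))
  for (k in seq_along(trees)) {
    tr <- trees[[k]]
    vals[, k] <- switch(metric,
      mpd = cells_mpd(P, cophenetic_distances(tr)[species, species, drop = FALSE]),
      mntd = cells_mntd(P, cophenetic_distances(tr)[species, species, drop = FALSE]),
      pd = cells_pd(P, tr, include_root = include_root)
    )
  }
  metric_surface(
    grid = community_matrix$grid,
    value = rowMeans(vals),
    vmin = apply(vals, 1L, min),
    vmax = apply(vals, 1L, max),
    metric = metric,
    group = community_matrix$group,
    n_trees = length(trees)
  )
}
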