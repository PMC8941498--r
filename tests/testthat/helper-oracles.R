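# Brute-force oracles, independent of the package's implementations:
# everything here works by explicitly walking root paths on the ape edge
# table and looping over pairs.

# root path of a tip: vector of edge row indices from tip up to the root
edge_path_to_root <- function(tree, node) {
  path <- integer(0)
  repeat {
    row <- which(tree$edge[, 2] == node)
    if (!length(row)) break
    path <- c(path, row)
    node <- tree$edge[row, 1]
  }
  path
}

# patristic distance by path walking: symmetric difference of root paths
oracle_tip_distance <- function(tree, i, j) {
  pi_ <- edge_path_to_root(tree, i)
  pj <- edge_path_to_root(tree, j)
  shared <- intersect(pi_, pj)
  sum(tree$edge.length[setdiff(pi_, shared)]) +
    sum(tree$edge.length[setdiff(pj, shared)])
}

oracle_cophenetic <- function(tree) {
  n <- length(tree$tip.label)
  D <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      D[i, j] <- D[j, i] <- oracle_tip_distance(tree, i, j)
    }
  }
  D
}

# double-loop MPD / MNTD on a distance matrix
oracle_mpd <- function(community, D) {
  n <- length(community)
  if (n < 2) return(NA_real_)
  tot <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) tot <- tot + D[community[i], community[j]]
  }
  tot / (n * (n - 1) / 2)
}

oracle_mntd <- function(community, D) {
  n <- length(community)
  if (n < 2) return(NA_real_)
  tot <- 0
  for (i in seq_len(n)) {
    best <- Inf
    for (j in seq_len(n)) {
      if (i != j) best <- min(best, D[community[i], community[j]])
    }
    tot <- tot + best
  }
  tot / n
}

# Faith's PD as the union of edges over all tip-to-tip paths
oracle_pd <- function(community, tree, include_root = FALSE) {
  n <- length(community)
  if (n == 0) return(NA_real_)
  idx <- match(community, tree$tip.label)
  if (include_root) {
    edges <- unique(unlist(lapply(idx, function(i) edge_path_to_root(tree, i))))
    return(sum(tree$edge.length[edges]))
  }
  if (n == 1) return(0)
  edges <- integer(0)
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      pi_ <- edge_path_to_root(tree, idx[i])
      pj <- edge_path_to_root(tree, idx[j])
      shared <- intersect(pi_, pj)
      edges <- union(edges, c(setdiff(pi_, shared), setdiff(pj, shared)))
    }
  }
  sum(tree$edge.length[edges])
}

# random tree/community instances for the oracle equivalence suite
random_instance <- function(seed, max_tips = 30) {
  set.seed(seed)
  n <- sample(4:max_tips, 1)
  tree <- gen_tree(n, birth_rate = 1, death_rate = sample(c(0, 0.3), 1),
                   seed = seed)
  size <- sample(2:n, 1)
  community <- sample(tree$tip.label, size)
  list(tree = tree, community = community)
}

# small deterministic surface on a tiny grid, for overlap/dispersion tests
tiny_surface <- function(values, nx = length(values), ny = 1) {
  g <- grid_spec(0, 0, nx, ny, 1)
  metric_surface(g, values)
}
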