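#' Read a phylogenetic tree from a Newick file
#'
#' Thin wrapper around [ape::read.tree()] that enforces the invariants
#' required by the community metrics: branch lengths present, finite and
#' non-negative, and unique tip labels.  Trees are standard `ape`
#' `phylo` objects throughout the package.
#'
#' @param path path to a Newick file, or a Newick string when
#'   `text = TRUE`.
#' @param text interpret `path` as the Newick string itself.
#' @return A `phylo` object.
#' @export
read_newick <- function(path, text = FALSE) {
  str <- if (text) path else paste(readLines(path, warn = FALSE), collapse = "")
  # cheap structural pre-check so malformed input reports a position
  depth <- 0L
  chars <- strsplit(str, "", fixed = TRUE)[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop(sprintf("malformed Newick: unmatched ')' at position %d", i))
    }
  }
  if (depth != 0L) {
    stop(sprintf("malformed Newick: %d unclosed '(' at end of string (length %d)",
                 depth, length(chars)))
  }
  tree <- tryCatch(ape::read.tree(text = str),
                   error = function(e) stop("malformed Newick: ", conditionMessage(e)))
  if (is.null(tree)) stop("malformed Newick: parser returned no tree")
  validate_tree(tree)
  tree
}

#' Write a tree as Newick
#'
#' @param tree a `phylo` object.
#' @param path output file.
#' @param digits significant digits for branch lengths (default 12, so
#'   round trips preserve lengths to at least 10 significant digits).
#' @export
write_newick <- function(tree, path, digits = 12) {
  validate_tree(tree)
  ape::write.tree(tree, file = path, digits = digits)
  invisible(path)
}

#' Validate a tree for use with the community metrics
#'
#' Checks that the object is a rooted `phylo` with unique tip labels and
#' finite, non-negative branch lengths on every edge.
#'
#' @param tree a `phylo` object.
#' @return The tree, invisibly.
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("`tree` must be a `phylo` object")
  if (anyDuplicated(tree$tip.label)) {
    dups <- unique(tree$tip.label[duplicated(tree$tip.label)])
    stop("duplicate tip labels: ", paste(dups, collapse = ", "))
  }
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths; lengths are required")
  }
  if (anyNA(tree$edge.length) || any(!is.finite(tree$edge.length))) {
    stop("tree has missing or non-finite branch lengths")
  }
  if (any(tree$edge.length < 0)) stop("tree has negative branch lengths")
  invisible(tree)
}

# Shared traversal scaffolding: parent/child arrays, a breadth-first
# order from the root (parents always precede children), and node depths
# (sum of branch lengths from the root).
tree_indices <- function(tree) {
  ntip <- length(tree$tip.label)
  ntot <- ntip + tree$Nnode
  root <- ntip + 1L
  parent <- integer(ntot)
  plen <- numeric(ntot)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  plen[tree$edge[, 2]] <- tree$edge.length
  children <- vector("list", ntot)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]
    children[[p]] <- c(children[[p]], tree$edge[e, 2])
  }
  bfs <- integer(ntot)
  bfs[1] <- root
  head <- 1L; tail <- 1L
  depth <- numeric(ntot)
  while (head <= tail) {
    v <- bfs[head]
    ch <- children[[v]]
    if (length(ch)) {
      depth[ch] <- depth[v] + plen[ch]
      bfs[(tail + 1L):(tail + length(ch))] <- ch
      tail <- tail + length(ch)
    }
    head <- head + 1L
  }
  list(ntip = ntip, ntot = ntot, root = root, parent = parent,
       plen = plen, children = children, bfs = bfs, depth = depth)
}
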