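#' Enumerate the unordered edges of a graph on R nodes
#'
#' Edges are listed in the stable row-major upper-triangle order
#' (1,2), (1,3), ..., (1,R), (2,3), ..., (R-1,R). All per-edge vectors in the
#' package (t-statistics, p-values, feature columns) follow this enumeration.
#'
#' @param n_rois number of nodes (ROIs).
#' @return integer matrix with columns `i`, `j` (i < j), one row per edge.
#' @export
edge_pairs <- function(n_rois) {
  stopifnot(n_rois >= 2)
  m <- t(utils::combn(n_rois, 2L))
  colnames(m) <- c("i", "j")
  m
}

# Deterministic per-stage child seeds from one global seed.
# Stage names hash to fixed small offsets so a resumed stage sees the same
# stream regardless of which stages ran before it. Result stays < 2^31.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) + 9973 * h) %% 2147483547L)
}

# Largest connected-component edge count of the graph given by an edge matrix
# (columns i, j). Nodes are implicit. Plain R; fast for the sparse
# supra-threshold graphs that arise under permutation.
max_component_edges <- function(edges) {
  ne <- nrow(edges)
  if (is.null(ne) || ne == 0L) return(0L)
  nodes <- unique(as.vector(edges))
  idx <- match(edges, nodes)
  dim(idx) <- dim(edges)
  parent <- seq_along(nodes)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (e in seq_len(ne)) {
    a <- find(idx[e, 1L]); b <- find(idx[e, 2L])
    if (a != b) parent[a] <- b
  }
  roots <- vapply(seq_along(nodes), find, integer(1L))
  edge_root <- roots[idx[, 1L]]
  max(tabulate(edge_root, nbins = length(nodes)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
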