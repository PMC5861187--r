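# shared fixtures and independent oracles

# a 10-edge connected component (two 5-edge fans sharing a path) on ROIs 1..11
planted_pairs <- function() {
  cbind(i = c(1, 2, 3, 4, 5, 1, 2, 3, 4, 5),
        j = c(2, 3, 4, 5, 6, 7, 8, 9, 10, 11))
}

planted_truth <- function(seed, n_rois = 20L, target_r = 0.4,
                          parameter = "extraversion") {
  p <- planted_pairs()
  ground_truth(n_rois,
               planted_edges = data.frame(i = p[, 1L], j = p[, 2L],
                                          parameter = parameter,
                                          beta = edge_effect_for_r(target_r)),
               seed = seed)
}

# connectivity stack for a null or planted cohort, full pipeline order
make_stack <- function(n_subjects, truth, scores = NULL) {
  scores <- scores %||% generate_scores(n_subjects, seed = truth$seed)
  build_connectivity(generate_timeseries(scores, truth))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent connected-components oracle: min-label propagation to a fixed
# point, then edge counts per component label
oracle_component_sizes <- function(edges) {
  if (is.null(nrow(edges)) || !nrow(edges)) return(integer())
  a <- as.character(edges[, 1L]); b <- as.character(edges[, 2L])
  nodes <- sort(unique(c(a, b)))
  labels <- stats::setNames(seq_along(nodes), nodes)
  repeat {
    changed <- FALSE
    for (e in seq_along(a)) {
      m <- min(labels[[a[e]]], labels[[b[e]]])
      if (labels[[a[e]]] != m || labels[[b[e]]] != m) {
        labels[[a[e]]] <- m; labels[[b[e]]] <- m; changed <- TRUE
      }
    }
    if (!changed) break
  }
  sort(as.integer(table(labels[a])), decreasing = TRUE)
}

# Jaccard overlap between two edge sets given as i/j matrices
edge_jaccard <- function(a, b) {
  key <- function(m) paste(pmin(m[, 1L], m[, 2L]), pmax(m[, 1L], m[, 2L]))
  length(intersect(key(a), key(b))) / length(union(key(a), key(b)))
}

# brute-force smallest k with binomial upper-tail CDF crossing, by summation
brute_force_chance_k <- function(n, p, alpha) {
  probs <- vapply(0:n, function(k) choose(n, k) * p^k * (1 - p)^(n - k),
                  numeric(1L))
  cdf <- cumsum(probs)
  # inverse-CDF convention: smallest k with P(X <= k) >= 1 - alpha
  min(which(cdf >= 1 - alpha - 1e-12)) - 1L
}
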