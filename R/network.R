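#' Edge-wise regression of connectivity on a psychometric score
#'
#' For each of the R(R-1)/2 unordered edges (in [edge_pairs()] order), fits
#' the simple regression `r_edge ~ intercept + score` across subjects and
#' returns the slope t-statistic with `n_effective - 2` degrees of freedom
#' and its two-sided p-value. Subjects with missing scores are dropped and
#' recorded in `n_effective`. Edges exactly linear in the score get
#' `t = +/-Inf`, `p = 0` (flagged in `perfect_fit`).
#'
#' @param stack a [connectivity_stack()].
#' @param scores numeric vector aligned with `stack$subjects`.
#' @return list of class `edge_stats`: `t`, `p`, `pairs`, `n_effective`,
#'   `roi_ids`, `perfect_fit`.
#' @export
edge_regression <- function(stack, scores) {
  stopifnot(length(scores) == length(stack$subjects))
  keep <- is.finite(scores)
  if (sum(keep) < 4L)
    stop("insufficient data: edge regression needs >= 4 subjects with observed scores")
  if (stats::var(scores[keep]) == 0)
    stop("degenerate design: score column is constant")
  E <- edge_matrix(stack)[keep, , drop = FALSE]
  fit <- edge_t_from_matrix(E, scores[keep])
  structure(list(t = fit$t, p = fit$p, pairs = edge_pairs(length(stack$roi_ids)),
                 n_effective = sum(keep), roi_ids = stack$roi_ids,
                 perfect_fit = fit$perfect),
            class = "edge_stats")
}

# slope t of each column of E on score via the correlation identity
# t = r * sqrt(df) / sqrt(1 - r^2); exact for simple linear regression
edge_t_from_matrix <- function(E, score) {
  n <- length(score)
  df <- n - 2L
  z <- score - mean(score)
  Ec <- sweep(E, 2L, colMeans(E))
  denom <- sqrt(sum(z^2) * colSums(Ec^2))
  r <- as.vector(crossprod(z, Ec)) / denom
  r[denom == 0] <- 0                    # constant edge: zero slope, t = 0
  r <- pmin(pmax(r, -1), 1)
  perfect <- abs(r) >= 1 - 1e-12
  t <- ifelse(perfect, sign(r) * Inf, r * sqrt(df) / sqrt(1 - r^2))
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  list(t = t, p = p, df = df, perfect = perfect)
}

#' Connected components of the supra-threshold edge graph
#'
#' Keeps edges with p < `primary_p` (a two-sided threshold: positive and
#' negative slopes are admitted jointly on |t|) and partitions the resulting
#' graph, with ROIs as nodes, into connected components.
#'
#' @param stats an `edge_stats` from [edge_regression()].
#' @param primary_p primary (uncorrected) edge threshold in (0, 1).
#' @return list of components, each with `edges` (matrix i, j in ROI ids),
#'   `t` (observed edge t-values), `n_edges`, `nodes`; ordered by decreasing
#'   edge count. Empty list if nothing is supra-threshold. Every
#'   supra-threshold edge belongs to exactly one component.
#' @export
extract_components <- function(stats, primary_p = 0.005) {
  stopifnot(primary_p > 0, primary_p < 1)
  sel <- which(stats$p < primary_p)
  if (!length(sel)) return(list())
  ep <- stats$pairs[sel, , drop = FALSE]
  g <- igraph::graph_from_edgelist(cbind(as.character(ep[, 1L]),
                                         as.character(ep[, 2L])),
                                   directed = FALSE)
  memb <- igraph::components(g)$membership
  comp_of_edge <- memb[as.character(ep[, 1L])]
  out <- lapply(split(seq_along(sel), comp_of_edge), function(ix) {
    e <- ep[ix, , drop = FALSE]
    list(edges = cbind(i = stats$roi_ids[e[, 1L]], j = stats$roi_ids[e[, 2L]]),
         t = stats$t[sel[ix]], n_edges = length(ix),
         nodes = sort(unique(as.vector(e))))
  })
  unname(out[order(-vapply(out, `[[`, integer(1L), "n_edges"))])
}

# Permutation null of the max component edge count. Edge columns and the
# score are centered and scaled to unit norm, so every permutation's edge
# correlations are a single crossproduct; permuting a centered unit-norm
# vector preserves both properties. Thresholding |r| > r_crit is equivalent
# to |t| > t_crit with r_crit = t_crit / sqrt(df + t_crit^2).
unit_norm_cols <- function(E) {
  Ec <- sweep(E, 2L, colMeans(E))
  norms <- sqrt(colSums(Ec^2))
  sweep(Ec, 2L, pmax(norms, .Machine$double.eps), "/")
}

perm_max_sizes <- function(Zn, P, pairs, t_crit, df, chunk = 500L) {
  r_crit <- t_crit / sqrt(df + t_crit^2)
  n_perm <- ncol(P)
  out <- integer(n_perm)
  for (start in seq(1L, n_perm, by = chunk)) {
    ix <- start:min(start + chunk - 1L, n_perm)
    Rmat <- crossprod(P[, ix, drop = FALSE], Zn)   # exact correlations
    out[ix] <- apply(Rmat, 1L, function(r) {
      sel <- which(abs(r) > r_crit)
      if (!length(sel)) return(0L)
      max_component_edges(pairs[sel, , drop = FALSE])
    })
  }
  out
}

#' Network-based statistic with permutation FWE correction
#'
#' Runs the edge-wise regression, extracts supra-threshold components, and
#' assigns each component a familywise-error-corrected p-value from the
#' permutation distribution of the maximum component edge count: scores are
#' randomly permuted across subjects (breaking the subject link, the same
#' null as shuffling the correlation matrices), the regression and component
#' extraction are re-run, and the largest component size is recorded.
#' `FWE p = (1 + #[perm max >= observed size]) / (n_perm + 1)`.
#'
#' @param stack a [connectivity_stack()].
#' @param scores numeric vector aligned with subjects.
#' @param primary_p primary edge threshold (default 0.005).
#' @param n_perm permutations (default 5000; >= 100).
#' @param seed permutation RNG seed.
#' @param alpha_fwe significance level for flagging components.
#' @param parameter name stored on returned components.
#' @return list of class `nbs_result`: `components` (each a
#'   `network_component` with `fwe_p` and `significant`), `perm_max`
#'   (permutation maxima), `stats`, `params`.
#' @export
nbs_fwe <- function(stack, scores, primary_p = 0.005, n_perm = 5000L,
                    seed = 1L, alpha_fwe = 0.05, parameter = "score") {
  stopifnot(n_perm >= 100L)
  keep <- is.finite(scores)
  stats <- edge_regression(stack, scores)
  comps <- extract_components(stats, primary_p)
  E <- edge_matrix(stack)[keep, , drop = FALSE]
  sc <- scores[keep]
  n <- length(sc)
  df <- n - 2L
  Zn <- unit_norm_cols(E)
  zs <- sc - mean(sc)
  zs <- zs / sqrt(sum(zs^2))
  set.seed(derive_seed(seed, "nbs"))
  P <- vapply(seq_len(n_perm), function(b) sample(zs), numeric(n))
  t_crit <- stats::qt(primary_p / 2, df, lower.tail = FALSE)
  perm_max <- perm_max_sizes(Zn, P, stats$pairs, t_crit, df)
  components <- lapply(comps, function(cm) {
    fwe_p <- (1 + sum(perm_max >= cm$n_edges)) / (n_perm + 1)
    structure(c(cm, list(parameter = parameter, fwe_p = fwe_p,
                         significant = fwe_p <= alpha_fwe,
                         primary_p = primary_p, n_perm = n_perm)),
              class = "network_component")
  })
  structure(list(components = components, perm_max = perm_max, stats = stats,
                 params = list(primary_p = primary_p, n_perm = n_perm,
                               seed = seed, alpha_fwe = alpha_fwe,
                               n_effective = n)),
            class = "nbs_result")
}

#' @export
print.network_component <- function(x, ...) {
  cat(sprintf("network_component [%s]: %d edges over %d ROIs, FWE p = %.4g%s\n",
              x$parameter, x$n_edges, length(x$nodes), x$fwe_p,
              if (isTRUE(x$significant)) " *" else ""))
  invisible(x)
}

#' Tune the primary threshold toward a target network size
#'
#' Bisects the primary edge threshold within `[p_floor, p_ceiling]` to bring
#' the largest FWE-significant component as close as possible to `target`
#' edges (ties toward the smaller threshold). If the largest significant
#' component at `p_ceiling` already has <= `target` edges it is returned
#' unchanged; if nothing is significant at `p_ceiling`, returns `NULL`.
#' The permutation null is computed once and re-thresholded, so the
#' component significance at every candidate threshold uses the same
#' permutation stream.
#'
#' @param stack,scores,n_perm,seed,alpha_fwe,parameter as in [nbs_fwe()].
#' @param target desired edge count (default 15).
#' @param p_floor,p_ceiling threshold search bounds (defaults 1e-6, 0.005).
#' @param max_iter bisection iterations.
#' @return a `network_component` (with `primary_p` the tuned threshold) or
#'   `NULL`.
#' @export
target_edge_count <- function(stack, scores, target = 15L, p_floor = 1e-6,
                              p_ceiling = 0.005, n_perm = 5000L, seed = 1L,
                              alpha_fwe = 0.05, parameter = "score",
                              max_iter = 30L) {
  stopifnot(p_floor < p_ceiling)
  keep <- is.finite(scores)
  stats <- edge_regression(stack, scores)
  E <- edge_matrix(stack)[keep, , drop = FALSE]
  n <- sum(keep); df <- n - 2L
  Zn <- unit_norm_cols(E)
  sc <- scores[keep]
  zs <- sc - mean(sc)
  zs <- zs / sqrt(sum(zs^2))
  set.seed(derive_seed(seed, "nbs"))
  P <- vapply(seq_len(n_perm), function(b) sample(zs), numeric(n))
  eval_at <- function(p_thr) {
    comps <- extract_components(stats, p_thr)
    if (!length(comps)) return(NULL)
    t_crit <- stats::qt(p_thr / 2, df, lower.tail = FALSE)
    perm_max <- perm_max_sizes(Zn, P, stats$pairs, t_crit, df)
    sizes <- vapply(comps, `[[`, integer(1L), "n_edges")
    fwe <- (1 + vapply(sizes, function(sz) sum(perm_max >= sz), numeric(1L))) /
      (n_perm + 1)
    sig <- which(fwe <= alpha_fwe)
    if (!length(sig)) return(NULL)
    best <- sig[which.max(sizes[sig])]
    structure(c(comps[[best]], list(parameter = parameter, fwe_p = fwe[best],
                                    significant = TRUE, primary_p = p_thr,
                                    n_perm = n_perm)),
              class = "network_component")
  }
  at_ceiling <- eval_at(p_ceiling)
  if (is.null(at_ceiling)) return(NULL)
  if (at_ceiling$n_edges <= target) return(at_ceiling)
  lo <- p_floor; hi <- p_ceiling
  best <- at_ceiling
  score_of <- function(cm) abs(cm$n_edges - target)
  for (it in seq_len(max_iter)) {
    mid <- sqrt(lo * hi)                 # geometric bisection: p spans decades
    cand <- eval_at(mid)
    if (!is.null(cand) &&
        (score_of(cand) < score_of(best) ||
         (score_of(cand) == score_of(best) && mid < best$primary_p)))
      best <- cand
    if (is.null(cand) || cand$n_edges < target) lo <- mid else hi <- mid
    if (!is.null(cand) && cand$n_edges == target) break
  }
  best
}
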