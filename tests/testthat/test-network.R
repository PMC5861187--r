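# build a connectivity stack whose edge values are fully controlled:
# subject s's matrix entries come from the given subjects x edges matrix
stack_from_edges <- function(E, n_rois) {
  pairs <- edge_pairs(n_rois)
  n <- nrow(E)
  mats <- array(0, c(n, n_rois, n_rois))
  for (s in seq_len(n)) {
    m <- diag(n_rois)
    m[pairs] <- E[s, ]
    m[pairs[, c(2, 1)]] <- E[s, ]
    mats[s, , ] <- m
  }
  connectivity_stack(sprintf("s%03d", seq_len(n)), mats, seq_len(n_rois))
}

test_that("edge regression matches the closed-form simple-regression t", {
  # printed fixture: 6 subjects, 3 ROIs (3 edges)
  sc <- c(41, 48, 52, 55, 61, 70)
  E <- rbind(c(0.10, -0.20, 0.05),
             c(0.15, -0.10, 0.00),
             c(0.18, -0.05, 0.10),
             c(0.25, 0.00, -0.05),
             c(0.28, 0.05, 0.02),
             c(0.35, 0.12, 0.01))
  stack <- stack_from_edges(E, 3)
  stats <- edge_regression(stack, sc)
  for (e in 1:3) {
    x <- sc; y <- E[, e]; n <- 6
    b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    resid <- y - mean(y) - b * (x - mean(x))
    se <- sqrt(sum(resid^2) / (n - 2) / sum((x - mean(x))^2))
    expect_equal(stats$t[e], b / se, tolerance = 1e-10)
    expect_equal(stats$p[e], 2 * pt(abs(b / se), n - 2, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
  expect_equal(stats$n_effective, 6)
})

test_that("edge regression oracle agreement holds over random fixtures", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 12; R <- 5
    E <- matrix(rnorm(n * R * (R - 1) / 2, 0, 0.2), n)
    sc <- rnorm(n, 50, 10)
    stats <- edge_regression(stack_from_edges(E, R), sc)
    tref <- apply(E, 2, function(y)
      summary(lm(y ~ sc))$coefficients["sc", "t value"])
    expect_equal(stats$t, tref, tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("edge regression handles nulls, missing scores and degenerate designs", {
  set.seed(2)
  n <- 100; R <- 15
  E <- matrix(rnorm(n * R * (R - 1) / 2, 0, 0.2), n)
  stack <- stack_from_edges(E, R)
  sc <- rnorm(n, 50, 10)
  stats <- edge_regression(stack, sc)
  ks <- suppressWarnings(ks.test(stats$p, "punif"))
  expect_gt(ks$p.value, 0.01)
  # missing scores dropped
  sc2 <- sc; sc2[1:10] <- NA
  expect_equal(edge_regression(stack, sc2)$n_effective, 90)
  expect_error(edge_regression(stack, rep(3, n)), "degenerate")
  # exact linear edge flagged infinite
  E3 <- E; E3[, 7] <- 0.01 * sc
  s3 <- edge_regression(stack_from_edges(E3, R), sc)
  expect_true(s3$perfect_fit[7])
  expect_equal(abs(s3$t[7]), Inf)
})

test_that("component extraction partitions the supra-threshold graph", {
  # constructed t-map: a 10-edge component plus one isolated edge
  n <- 30; R <- 15
  set.seed(9)
  E <- matrix(rnorm(n * R * (R - 1) / 2, 0, 0.05), n)
  sc <- rnorm(n, 50, 10)
  pp <- planted_pairs()                 # touches ROIs 1..11
  pairs <- edge_pairs(R)
  key <- paste(pairs[, 1], pairs[, 2])
  strong <- c(paste(pp[, 1], pp[, 2]), "13 14")
  for (k in strong) E[, key == k] <- 0.01 * (sc - 50) + rnorm(n, 0, 0.03)
  stats <- edge_regression(stack_from_edges(E, R), sc)
  comps <- extract_components(stats, 1e-6)
  sizes <- vapply(comps, `[[`, integer(1), "n_edges")
  expect_equal(sizes, c(10L, 1L))
  # matches the independent label-propagation oracle
  supra <- stats$pairs[stats$p < 1e-6, , drop = FALSE]
  expect_equal(sizes, oracle_component_sizes(supra))
  # partition: each supra edge in exactly one component
  all_edges <- do.call(rbind, lapply(comps, `[[`, "edges"))
  expect_equal(nrow(all_edges), nrow(supra))
  expect_false(anyDuplicated(paste(all_edges[, 1], all_edges[, 2])) > 0)
  # no supra edges -> empty list
  expect_equal(extract_components(stats, 1e-300), list())
})

test_that("a fully supra-threshold graph is one complete component", {
  n <- 20; R <- 6
  set.seed(10)
  sc <- rnorm(n, 50, 10)
  E <- sapply(seq_len(R * (R - 1) / 2), function(e) 0.01 * (sc - 50) + rnorm(n, 0, 0.01))
  stats <- edge_regression(stack_from_edges(E, R), sc)
  comps <- extract_components(stats, 0.005)
  expect_length(comps, 1)
  expect_equal(comps[[1]]$n_edges, R * (R - 1) / 2)
})

test_that("NBS permutation p-values respect the add-one floor and determinism", {
  set.seed(11)
  n <- 40; R <- 8
  sc <- rnorm(n, 50, 10)
  E <- matrix(rnorm(n * R * (R - 1) / 2, 0, 0.05), n)
  pairs <- edge_pairs(R); key <- paste(pairs[, 1], pairs[, 2])
  for (k in c("1 2", "2 3", "3 4", "4 5")) E[, key == k] <- 0.012 * (sc - 50) + rnorm(n, 0, 0.05)
  stack <- stack_from_edges(E, R)
  res <- nbs_fwe(stack, sc, primary_p = 0.005, n_perm = 100, seed = 7)
  big <- res$components[[1]]
  expect_gte(big$n_edges, 4)
  expect_equal(big$fwe_p, 1 / 101)      # observed exceeds all permuted maxima
  expect_true(big$significant)
  # determinism: identical permutation stream
  res2 <- nbs_fwe(stack, sc, primary_p = 0.005, n_perm = 100, seed = 7)
  expect_identical(res$perm_max, res2$perm_max)
  expect_equal(vapply(res$components, `[[`, numeric(1), "fwe_p"),
               vapply(res2$components, `[[`, numeric(1), "fwe_p"))
  # p monotone non-increasing in observed size
  sizes <- vapply(res$components, `[[`, integer(1), "n_edges")
  ps <- vapply(res$components, `[[`, numeric(1), "fwe_p")
  expect_true(all(diff(ps[order(sizes)]) <= 0))
})

test_that("edge-count targeting lands on the closest attainable network size", {
  # graded effects: component shrinks as the threshold tightens
  set.seed(12)
  n <- 80; R <- 12
  sc <- rnorm(n, 50, 10)
  nE <- R * (R - 1) / 2
  E <- matrix(rnorm(n * nE, 0, 0.05), n)
  pairs <- edge_pairs(R)
  # chain 1-2-3-...-12 plus extra fan edges, strength decaying along the list
  chain <- cbind(1:(R - 1), 2:R)
  fan <- cbind(rep(1:6, each = 2), rep(7:12, 2))
  planted <- unique(rbind(chain, fan))
  planted <- planted[planted[, 1] < planted[, 2], , drop = FALSE]
  key <- paste(pairs[, 1], pairs[, 2])
  for (e in seq_len(nrow(planted))) {
    k <- paste(planted[e, 1], planted[e, 2])
    slope <- 0.012 * (1 - 0.8 * (e - 1) / nrow(planted))
    E[, key == k] <- slope * (sc - 50) + rnorm(n, 0, 0.15)
  }
  stack <- stack_from_edges(pmin(pmax(E, -0.99), 0.99), R)
  target <- 8L
  got <- target_edge_count(stack, sc, target = target, n_perm = 200, seed = 3)
  # grid-scan oracle over 50 thresholds on the observed p-values only
  stats <- edge_regression(stack, sc)
  grid <- exp(seq(log(1e-6), log(0.005), length.out = 50))
  sizes <- vapply(grid, function(th) {
    s <- oracle_component_sizes(stats$pairs[stats$p < th, , drop = FALSE])
    if (length(s)) max(s) else 0L
  }, integer(1))
  attainable <- sizes[sizes > 0]
  expect_false(is.null(got))
  # the bisection is at least as close to the target as a 50-point grid scan
  expect_lte(abs(got$n_edges - target), min(abs(attainable - target)))
  # and its reported size matches the oracle at its own tuned threshold
  oracle_at <- oracle_component_sizes(
    stats$pairs[stats$p < got$primary_p, , drop = FALSE])
  expect_equal(got$n_edges, max(oracle_at))
})

test_that("small or absent networks are returned unchanged or as none", {
  set.seed(13)
  n <- 60; R <- 8
  sc <- rnorm(n, 50, 10)
  E <- matrix(rnorm(n * R * (R - 1) / 2, 0, 0.05), n)
  pairs <- edge_pairs(R); key <- paste(pairs[, 1], pairs[, 2])
  small <- cbind(c(1, 2, 3), c(2, 3, 4))
  for (e in 1:3) E[, key == paste(small[e, 1], small[e, 2])] <-
    0.015 * (sc - 50) + rnorm(n, 0, 0.04)
  stack <- stack_from_edges(E, R)
  # fewer edges than target even at the ceiling: returned as-is
  got <- target_edge_count(stack, sc, target = 15, n_perm = 200, seed = 5)
  base <- nbs_fwe(stack, sc, primary_p = 0.005, n_perm = 200, seed = 5)
  expect_equal(got$n_edges, base$components[[1]]$n_edges)
  expect_equal(got$primary_p, 0.005)
  # nothing significant: none
  Enull <- matrix(rnorm(n * R * (R - 1) / 2, 0, 0.05), n)
  expect_null(target_edge_count(stack_from_edges(Enull, R), sc,
                                n_perm = 200, seed = 5))
})
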