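make_gm_fixture <- function(n = 24, dims = c(6L, 6L, 6L), seed = 1,
                            noise_sd = 0.1) {
  set.seed(seed)
  tab <- generate_scores(n, seed = seed)
  truth <- ground_truth(8, seed = seed)
  generate_gm_maps(tab, truth, grid = list(dim = dims, voxel_mm = 3),
                   parcellation = generate_parcellation(dims, 2L),
                   noise_sd = noise_sd)
}

test_that("voxelwise t-statistics match an independent lm() oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 20; dims <- c(4L, 4L, 3L)
    data <- array(rnorm(n * prod(dims)), c(n, dims))
    sc <- rnorm(n, 50, 10); tbv <- rnorm(n, 1000, 50)
    stack <- gm_stack(sprintf("s%02d", 1:n), data, 3, diag(4))
    stack$tbv <- tbv
    reg <- voxelwise_regression(stack, sc)
    for (v in sample(prod(dims), 10)) {
      idx <- arrayInd(v, dims)
      fit <- summary(lm(data[, idx[1], idx[2], idx[3]] ~ sc + tbv))
      expect_equal(reg$t[idx[1], idx[2], idx[3]],
                   fit$coefficients["sc", "t value"], tolerance = 1e-8)
      expect_equal(reg$p[idx[1], idx[2], idx[3]],
                   fit$coefficients["sc", "Pr(>|t|)"], tolerance = 1e-8)
    }
    expect_equal(reg$df, n - 3)
  }
})

test_that("voxelwise regression flags perfect fits and refuses bad designs", {
  n <- 10; dims <- c(3L, 3L, 3L)
  sc <- rnorm(n, 50, 10)
  data <- array(rnorm(n * prod(dims)), c(n, dims))
  data[, 2, 2, 2] <- 3 * sc          # exact linear voxel
  stack <- gm_stack(sprintf("s%02d", 1:n), data, 3, diag(4))
  stack$tbv <- rnorm(n, 100, 5)
  reg <- voxelwise_regression(stack, sc)
  expect_true(reg$perfect_fit[2, 2, 2])
  expect_equal(reg$t[2, 2, 2], Inf)

  expect_error(voxelwise_regression(stack, rep(1, n)), "constant")
  sc3 <- sc; sc3[4:n] <- NA
  expect_error(voxelwise_regression(stack, sc3), "insufficient")
})

test_that("under permuted scores the t-volume p-values are uniform", {
  set.seed(42)
  n <- 30; dims <- c(10L, 10L, 10L)
  data <- array(rnorm(n * prod(dims)), c(n, dims))
  stack <- gm_stack(sprintf("s%02d", 1:n), data, 3, diag(4))
  reg <- voxelwise_regression(stack, sample(rnorm(n, 50, 10)))
  ks <- suppressWarnings(ks.test(as.vector(reg$p), "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("disabled thresholds make every parcel voxel significant", {
  gm <- make_gm_fixture()
  tab <- generate_scores(24, seed = 1)
  reg <- voxelwise_regression(gm, tab$extraversion)
  masks <- small_volume_fwe(reg, gm$parcellation, gm, tab$extraversion,
                            n_perm = 100, alpha_fwe = 1, alpha_unc = 1, seed = 1)
  all_mask <- Reduce(`|`, masks$masks)
  expect_true(all(all_mask))
})

test_that("permutation small-volume correction controls the FWE rate under the null", {
  # scaled calibration: 60 null replicates, per-parcel familywise rate <= alpha
  n_rep <- 60; alpha <- 0.05
  hits <- 0L; parcels_total <- 0L
  for (rep_i in seq_len(n_rep)) {
    set.seed(1000 + rep_i)
    n <- 20; dims <- c(6L, 6L, 6L)
    data <- array(rnorm(n * prod(dims)), c(n, dims))
    stack <- gm_stack(sprintf("s%02d", 1:n), data, 3, diag(4),
                      parcellation = generate_parcellation(dims, 2L))
    sc <- rnorm(n, 50, 10)
    reg <- voxelwise_regression(stack, sc)
    masks <- small_volume_fwe(reg, NULL, stack, sc, n_perm = 100,
                              alpha_fwe = alpha, alpha_unc = 1,
                              seed = 2000 + rep_i)
    hits <- hits + sum(vapply(masks$masks, any, logical(1)))
    parcels_total <- parcels_total + length(masks$masks)
  }
  rate <- hits / parcels_total
  mc_se <- sqrt(alpha * (1 - alpha) / parcels_total)
  expect_lte(rate, alpha + 3 * mc_se)
})

test_that("a strongly planted focus is detected in nearly all replicate seeds", {
  found <- vapply(1:15, function(seed) {
    tab <- generate_scores(60, seed = seed)
    truth <- ground_truth(8, planted_foci = data.frame(
      parcel = 3, parameter = "extraversion", beta = 0.03), seed = seed)
    gm <- generate_gm_maps(tab, truth, grid = list(dim = c(6L, 6L, 6L), voxel_mm = 3),
                           parcellation = generate_parcellation(c(6L, 6L, 6L), 2L))
    reg <- voxelwise_regression(gm, tab$extraversion)
    masks <- small_volume_fwe(reg, NULL, gm, tab$extraversion, n_perm = 100,
                              seed = seed)
    fv <- gm$focus_voxels
    masks$masks[["3"]][fv$x[1], fv$y[1], fv$z[1]]
  }, logical(1))
  expect_gte(sum(found), 14)
})

test_that("ROI definition centers on the peak voxel with deterministic ties", {
  dims <- c(5L, 5L, 5L)
  tvol <- array(0, dims)
  affine <- diag(c(2, 2, 2, 1))
  # singleton mask
  m1 <- array(FALSE, dims); m1[2, 3, 4] <- TRUE
  tvol[2, 3, 4] <- 5
  rois <- define_rois(list(`1` = m1), tvol, affine, diameter_mm = 5,
                      parameter = "p")
  expect_equal(unlist(rois[1, c("x", "y", "z")], use.names = FALSE),
               c(2, 4, 6))  # (idx - 1) * voxel
  expect_equal(rois$radius_mm, 2.5)
  expect_equal(rois$peak_t, 5)
  # tie on |t|: earliest linear (column-major, x-fastest) index wins
  m2 <- array(FALSE, dims)
  m2[4, 1, 1] <- TRUE; m2[1, 2, 1] <- TRUE   # linear indices 4 and 6
  tvol2 <- array(0, dims); tvol2[4, 1, 1] <- -7; tvol2[1, 2, 1] <- 7
  r2 <- define_rois(list(`1` = m2), tvol2, affine, parameter = "p")
  expect_equal(unlist(r2[1, c("x", "y", "z")], use.names = FALSE), c(6, 0, 0))
  expect_equal(r2$peak_t, -7)
})

test_that("overlap dedup follows the sphere-intersection rule and is idempotent", {
  base <- data.frame(radius_mm = 2.5, peak_t = 5, parameter = "p", parcel = 1L)
  mk <- function(xyz) cbind(data.frame(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]), base)
  # centers 4.9 mm apart: overlap (4.9 < 5.0) -> second removed
  r <- dedup_rois(roi_set(mk(rbind(c(0, 0, 0), c(4.9, 0, 0)))))
  expect_equal(nrow(r), 1)
  # 5.1 mm apart: kept
  r <- dedup_rois(roi_set(mk(rbind(c(0, 0, 0), c(5.1, 0, 0)))))
  expect_equal(nrow(r), 2)
  # exactly the radius sum: spheres touch but do not intersect -> kept
  r <- dedup_rois(roi_set(mk(rbind(c(0, 0, 0), c(5, 0, 0)))))
  expect_equal(nrow(r), 2)
  # idempotence and order stability on a random cloud
  set.seed(8)
  cloud <- roi_set(mk(matrix(runif(60, 0, 20), ncol = 3)))
  d1 <- dedup_rois(cloud)
  d2 <- dedup_rois(d1)
  expect_equal(as.data.frame(d1), as.data.frame(d2))
  expect_true(!is.unsorted(match(paste(d1$x, d1$y, d1$z),
                                 paste(cloud$x, cloud$y, cloud$z))))
})

test_that("a 187-ROI set with 24 later duplicates dedups to 163", {
  set.seed(13)
  n_unique <- 163
  centers <- matrix(runif(3 * n_unique, 0, 300), ncol = 3)  # sparse: no accidental overlap
  dup_of <- sample(n_unique, 24)
  all_centers <- rbind(centers, centers[dup_of, , drop = FALSE])
  ord <- c(seq_len(n_unique), n_unique + seq_len(24))
  # interleave duplicates later in the list (they must be the ones removed)
  df <- data.frame(x = all_centers[ord, 1], y = all_centers[ord, 2],
                   z = all_centers[ord, 3], radius_mm = 2.5, peak_t = 1,
                   parameter = "p", parcel = 1L)
  out <- dedup_rois(roi_set(df))
  expect_equal(nrow(out), 163)
  expect_equal(out$id, seq_len(163))
})
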