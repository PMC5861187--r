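#' Pipeline configuration
#'
#' Collects every stage parameter with the published defaults: uncorrected
#' voxel threshold 0.001 with parcel-level FWE 0.05, 5-mm ROI spheres,
#' 0.01-0.1 Hz band, primary edge threshold 0.005 with 5000 permutations,
#' 15 target edges, 8 classes, dyadic C/gamma grids, alpha 0.05.
#'
#' @param ... overrides of any default field.
#' @param seed single integer; every stage derives its own child stream from
#'   it deterministically.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(..., seed = 1L) {
  cfg <- list(alpha_unc = 0.001, alpha_fwe = 0.05, diameter_mm = 5,
              low_hz = 0.01, high_hz = 0.1, primary_p = 0.005,
              n_perm_svc = 1000L, n_perm_nbs = 5000L, target_edges = 15L,
              n_classes = 8L, c_grid = default_c_grid(),
              gamma_grid = default_gamma_grid(), alpha = 0.05,
              seed = as.integer(seed))
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config fields: ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

#' Generate a complete synthetic dataset
#'
#' Emits every input the training flow consumes — score table, gray-matter
#' stack (with parcellation and TBV) and per-subject ROI time series with
#' nuisance matrices — from one `ground_truth`. In the synthetic world,
#' parcel k of the atlas is the anatomical home of time-series column k, so
#' planted connectivity edges are recoverable through the morphometry stage.
#'
#' @param n_subjects cohort size.
#' @param truth a [ground_truth()].
#' @param grid volume geometry for [generate_gm_maps()]; `n_blocks` is
#'   chosen as `ceiling(n_rois^(1/3))` so each candidate ROI owns a parcel.
#' @param missing_blocks battery missingness (see [generate_scores()]).
#' @param n_timepoints,tr_seconds,r0,noise_sd,smooth_fwhm_mm generator knobs.
#' @return list of class `np_dataset`: `scores`, `gm`, `ts`, `truth`.
#' @export
simulate_dataset <- function(n_subjects, truth,
                             grid = list(dim = c(12L, 12L, 12L), voxel_mm = 3),
                             missing_blocks = NULL, n_timepoints = 480L,
                             tr_seconds = 1, r0 = 0, noise_sd = 0.1,
                             smooth_fwhm_mm = 8) {
  scores <- generate_scores(n_subjects, truth$score_model,
                            missing_blocks = missing_blocks, seed = truth$seed)
  n_blocks <- max(2L, ceiling(truth$n_rois^(1 / 3) - 1e-9))
  parc <- generate_parcellation(grid$dim, n_blocks)
  gm <- generate_gm_maps(scores, truth, grid = grid, parcellation = parc,
                         noise_sd = noise_sd, smooth_fwhm_mm = smooth_fwhm_mm)
  # one time-series column per parcel, so any discovered ROI has a signal
  ts <- generate_timeseries(scores, truth, n_rois = n_blocks^3,
                            n_timepoints = n_timepoints,
                            tr_seconds = tr_seconds, r0 = r0)
  structure(list(scores = scores, gm = gm, ts = ts, truth = truth),
            class = "np_dataset")
}

# subjects x edges feature matrix for one network component, taken from the
# connectivity stack; column names record the ROI id pairs
network_features <- function(stack, component) {
  idx_i <- match(component$edges[, 1L], stack$roi_ids)
  idx_j <- match(component$edges[, 2L], stack$roi_ids)
  if (anyNA(idx_i) || anyNA(idx_j))
    stop("alignment error: component edge ROI ids missing from the stack")
  n <- length(stack$subjects)
  X <- matrix(NA_real_, n, nrow(component$edges))
  for (s in seq_len(n)) X[s, ] <- stack$matrices[s, , ][cbind(idx_i, idx_j)]
  colnames(X) <- paste0(component$edges[, 1L], "-", component$edges[, 2L])
  X
}

#' Run the training flow end to end
#'
#' Morphometry (per-parameter voxelwise regression, small-volume FWE, ROI
#' definition, dedup) -> connectivity on the retained ROIs -> per-parameter
#' NBS with edge-count targeting -> per-network 8-class OAA-SVM with LOOCV
#' and chance comparison. Deterministic under `config$seed`.
#'
#' @param config a [pipeline_config()].
#' @param data an `np_dataset` (or compatible list with `scores`, `gm`, `ts`).
#' @param parameters score columns to process (default: all).
#' @return list of class `np_run`: `rois`, `connectivity`, `networks`,
#'   `models`, `reports`, `manifest` (per-parameter outcome data.frame),
#'   `config`.
#' @export
run_training <- function(config, data,
                         parameters = setdiff(names(data$scores), "subject")) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!identical(data$scores$subject, data$gm$subjects) ||
      !identical(data$scores$subject, data$ts$subjects))
    stop("alignment error: subject ids differ across scores, GM maps and time series")
  disc <- discover_rois(data$gm, data$scores, parameters,
                        n_perm = config$n_perm_svc, alpha_fwe = config$alpha_fwe,
                        alpha_unc = config$alpha_unc,
                        diameter_mm = config$diameter_mm,
                        seed = derive_seed(config$seed, "morph"))
  rois <- disc$rois
  if (nrow(rois) < 2L) {
    warning("fewer than 2 ROIs survived morphometry; no connectivity analysis possible")
    man <- data.frame(parameter = parameters,
                      n_rois = disc$per_parameter[parameters],
                      network_found = FALSE, network_edges = NA_integer_,
                      network_fwe_p = NA_real_, classifier_trained = FALSE,
                      classifier_significant = FALSE, accuracy = NA_real_,
                      stringsAsFactors = FALSE)
    return(structure(list(rois = rois, connectivity = NULL, networks = list(),
                          models = list(), reports = list(), manifest = man,
                          config = config),
                     class = "np_run"))
  }
  ts_sub <- data$ts
  ts_sub$series <- lapply(data$ts$series, function(m) m[, rois$parcel, drop = FALSE])
  ts_sub$roi_ids <- rois$parcel
  stack <- build_connectivity(ts_sub, config$low_hz, config$high_hz)
  networks <- list(); models <- list(); reports <- list()
  man <- data.frame(parameter = parameters, n_rois = disc$per_parameter[parameters],
                    network_found = FALSE, network_edges = NA_integer_,
                    network_fwe_p = NA_real_, classifier_trained = FALSE,
                    classifier_significant = FALSE, accuracy = NA_real_,
                    stringsAsFactors = FALSE)
  for (p in parameters) {
    sc <- data$scores[[p]]
    comp <- target_edge_count(stack, sc, target = config$target_edges,
                              p_ceiling = config$primary_p,
                              n_perm = config$n_perm_nbs,
                              seed = derive_seed(config$seed, paste0("nbs_", p)),
                              alpha_fwe = config$alpha_fwe, parameter = p)
    if (is.null(comp)) next
    networks[[p]] <- comp
    man[man$parameter == p, c("network_found", "network_edges", "network_fwe_p")] <-
      list(TRUE, comp$n_edges, comp$fwe_p)
    keep <- is.finite(sc)
    X <- network_features(stack, comp)[keep, , drop = FALSE]
    lab <- discretize(sc[keep], n_classes = config$n_classes)
    if (length(unique(lab$classes)) < 2L) next
    model <- train_oaa_svm(X, lab, config$c_grid, config$gamma_grid,
                           edge_ids = colnames(X))
    rep <- classifier_report(model$loocv_pred, lab$classes,
                             n_classes = config$n_classes,
                             alpha = config$alpha, parameter = p)
    sig <- significance_vs_chance(rep, alpha = config$alpha,
                                  n_classes = config$n_classes)
    rep$significance <- sig
    models[[p]] <- model
    reports[[p]] <- rep
    man[man$parameter == p, c("classifier_trained", "classifier_significant",
                              "accuracy")] <-
      list(TRUE, sig$significant, rep$accuracy)
  }
  structure(list(rois = rois, connectivity = stack, networks = networks,
                 models = models, reports = reports, manifest = man,
                 config = config),
            class = "np_run")
}

#' Apply trained classifiers to a new cohort
#'
#' Bypasses regression and NBS: builds connectivity for the stored ROI set,
#' extracts the stored network edges, and predicts with the stored machines.
#'
#' @param config a [pipeline_config()] (band edges are reused).
#' @param trained an `np_run` from [run_training()].
#' @param data list with `ts` (a `ts_bundle` whose columns cover the stored
#'   ROI parcels) and optionally `scores` for evaluation.
#' @return list of class `np_apply`: `predictions` (per parameter),
#'   `reports` (when scores supplied), `manifest`.
#' @export
run_apply <- function(config, trained, data) {
  rois <- trained$rois
  n_cols <- ncol(data$ts$series[[1L]])
  if (max(rois$parcel) > n_cols)
    stop("alignment error: new time series have fewer ROI columns than the stored ROI set needs")
  ts_sub <- data$ts
  ts_sub$series <- lapply(data$ts$series, function(m) m[, rois$parcel, drop = FALSE])
  ts_sub$roi_ids <- rois$parcel
  stack <- build_connectivity(ts_sub, config$low_hz, config$high_hz)
  predictions <- list(); reports <- list()
  for (p in names(trained$models)) {
    comp <- trained$networks[[p]]
    X <- network_features(stack, comp)
    truth_scores <- if (!is.null(data$scores)) data$scores[[p]] else NULL
    keep <- if (is.null(truth_scores)) rep(TRUE, nrow(X)) else is.finite(truth_scores)
    res <- apply_classifiers(X[keep, , drop = FALSE], trained$models[[p]],
                             edge_ids = colnames(X),
                             true_scores = truth_scores[keep], parameter = p)
    predictions[[p]] <- res$pred
    if (!is.null(res$report)) reports[[p]] <- res$report
  }
  man <- data.frame(parameter = names(trained$models),
                    accuracy = vapply(names(trained$models), function(p)
                      if (!is.null(reports[[p]])) reports[[p]]$accuracy else NA_real_,
                      numeric(1L)),
                    stringsAsFactors = FALSE)
  structure(list(predictions = predictions, reports = reports, manifest = man),
            class = "np_apply")
}
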