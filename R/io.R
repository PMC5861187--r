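#' Read and write psychometric score tables as TSV
#'
#' Header row `subject` plus one column per parameter; missing scores are
#' empty fields.
#'
#' @param table `psych_table` (or data.frame with a `subject` column).
#' @param path file path.
#' @return `write_scores_tsv` returns `path` invisibly; `read_scores_tsv`
#'   returns a `psych_table`.
#' @export
write_scores_tsv <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_scores_tsv
#' @export
read_scores_tsv <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", na.strings = "",
                           stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot("subject" %in% names(tab))
  class(tab) <- c("psych_table", "data.frame")
  tab
}

#' Read and write ROI sets as TSV
#'
#' Columns: id, x, y, z, radius_mm, peak_t, parameter, parcel (world
#' coordinates in MNI-convention millimeters).
#'
#' @param rois a [roi_set()].
#' @param path file path.
#' @export
write_roi_tsv <- function(rois, path) {
  utils::write.table(as.data.frame(rois), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_roi_tsv
#' @export
read_roi_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  roi_set(df[, setdiff(names(df), "id")])
}

#' Write a gray-matter stack (or any volume) as NIfTI
#'
#' One `.nii.gz` per subject plus a `tbv.tsv` table; the parcellation (when
#' present) is written as `parcellation.nii.gz`.
#'
#' @param stack a [gm_stack()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_gm_nifti <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  as_img <- function(arr) {
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- rep(stack$voxel_mm, 3L)
    RNifti::sform(img) <- structure(stack$affine, code = 2L)
    img
  }
  for (s in seq_along(stack$subjects))
    RNifti::writeNifti(as_img(stack$data[s, , , ]),
                       file.path(dir, paste0(stack$subjects[s], "_gm.nii.gz")))
  if (!is.null(stack$parcellation))
    RNifti::writeNifti(as_img(stack$parcellation),
                       file.path(dir, "parcellation.nii.gz"))
  utils::write.table(data.frame(subject = stack$subjects, tbv = stack$tbv),
                     file.path(dir, "tbv.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(dir)
}

#' Read a gray-matter stack written by [write_gm_nifti()]
#'
#' @param dir directory containing `<subject>_gm.nii.gz`, `tbv.tsv` and
#'   optionally `parcellation.nii.gz`.
#' @return a [gm_stack()].
#' @export
read_gm_nifti <- function(dir) {
  tbv <- utils::read.delim(file.path(dir, "tbv.tsv"), stringsAsFactors = FALSE)
  imgs <- lapply(tbv$subject, function(s)
    RNifti::readNifti(file.path(dir, paste0(s, "_gm.nii.gz"))))
  dims <- dim(imgs[[1L]])
  data <- array(NA_real_, c(length(imgs), dims))
  for (s in seq_along(imgs)) data[s, , , ] <- imgs[[s]]
  affine <- structure(RNifti::xform(imgs[[1L]]), class = NULL)
  parc_path <- file.path(dir, "parcellation.nii.gz")
  parc <- if (file.exists(parc_path))
    array(as.integer(round(RNifti::readNifti(parc_path))), dims) else NULL
  voxel_mm <- sqrt(sum(affine[1:3, 1L]^2))   # scale of the stored affine
  gm_stack(tbv$subject, data, voxel_mm, affine, tbv = tbv$tbv,
           parcellation = parc)
}

#' Write per-subject ROI time series as TSV
#'
#' One `<subject>_ts.tsv` (T rows x R columns) and one
#' `<subject>_confounds.tsv` per subject, plus `manifest.json` with TR and
#' ROI ids.
#'
#' @param bundle a `ts_bundle`.
#' @param dir output directory.
#' @export
write_timeseries_tsv <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in seq_along(bundle$subjects)) {
    utils::write.table(bundle$series[[s]],
                       file.path(dir, paste0(bundle$subjects[s], "_ts.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = paste0("roi", bundle$roi_ids))
    utils::write.table(bundle$confounds[[s]],
                       file.path(dir, paste0(bundle$subjects[s], "_confounds.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(list(tr = bundle$tr, roi_ids = bundle$roi_ids,
                            subjects = bundle$subjects),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a time-series bundle written by [write_timeseries_tsv()]
#' @param dir directory with the per-subject TSVs and `manifest.json`.
#' @return a `ts_bundle`.
#' @export
read_timeseries_tsv <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  read1 <- function(s, suffix) {
    f <- file.path(dir, paste0(s, suffix))
    if (!file.exists(f)) stop("missing time-series file: ", f)
    as.matrix(utils::read.delim(f))
  }
  structure(list(series = lapply(man$subjects, read1, "_ts.tsv"),
                 confounds = lapply(man$subjects, read1, "_confounds.tsv"),
                 tr = man$tr, roi_ids = man$roi_ids, subjects = man$subjects),
            class = "ts_bundle")
}

#' Write network components as an edge-list TSV and as GraphML
#'
#' TSV columns: roi_i, roi_j, t, parameter, fwe_p.
#'
#' @param components list of `network_component`s (or one).
#' @param path TSV output path.
#' @param graphml_path optional GraphML output path for graph viewers.
#' @export
write_components_tsv <- function(components, path, graphml_path = NULL) {
  if (inherits(components, "network_component")) components <- list(components)
  rows <- do.call(rbind, lapply(components, function(cm)
    data.frame(roi_i = cm$edges[, 1L], roi_j = cm$edges[, 2L], t = cm$t,
               parameter = cm$parameter, fwe_p = cm$fwe_p)))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(graphml_path)) {
    g <- igraph::graph_from_data_frame(
      rows[, c("roi_i", "roi_j", "t", "parameter")], directed = FALSE)
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  invisible(path)
}

#' Save / load a trained run
#'
#' The run (ROI set, networks, scalers, SVM weights, label min/max, config
#' and seed) is stored as an RDS next to a JSON summary of the manifest.
#'
#' @param run an `np_run`.
#' @param dir output directory.
#' @export
save_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(run, file.path(dir, "run.rds"))
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}

#' @rdname save_run
#' @export
load_run <- function(dir) {
  f <- file.path(dir, "run.rds")
  if (!file.exists(f)) stop("no saved run at ", f)
  run <- tryCatch(readRDS(f), error = function(e)
    stop("corrupted model file: ", f, " (", conditionMessage(e), ")"))
  if (!inherits(run, "np_run")) stop("corrupted model file: ", f)
  run
}

#' Write the ground truth as a JSON sidecar
#' @param truth a [ground_truth()].
#' @param path output path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
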