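#' Discretize scores into equal-width classes
#'
#' Maps a score x to `clamp(ceil(n_classes * (x - min) / (max - min)), 1,
#' n_classes)`: equal-width bins over the observed range, upper edges
#' inclusive. Products that land exactly on an integer keep that value
#' (there is no fractional part to round up); x = min, whose product is 0,
#' is clamped up to class 1. The min/max are computed on the training
#' population and stored so the same mapping can be reused on new subjects;
#' out-of-range new scores are clamped with a warning.
#'
#' @param scores numeric vector (NAs pass through as NA labels).
#' @param n_classes number of classes (default 8).
#' @param min,max range of the mapping; default the observed range.
#' @return list of class `class_labels`: `classes` (integer vector),
#'   `n_classes`, `min`, `max`.
#' @export
discretize <- function(scores, n_classes = 8L, min = NULL, max = NULL) {
  obs <- scores[is.finite(scores)]
  stored <- !is.null(min) && !is.null(max)
  min <- min %||% base::min(obs)
  max <- max %||% base::max(obs)
  if (!(max > min)) stop("degenerate scores: max must exceed min")
  if (stored && length(obs) && (any(obs < min) || any(obs > max)))
    warning("scores outside the stored [min, max] range; clamped")
  v <- n_classes * (scores - min) / (max - min)
  cls <- as.integer(ceiling(round(v, 9)))  # FP guard: 4.0000000001 is class 4
  cls <- pmin(pmax(cls, 1L), as.integer(n_classes))
  structure(list(classes = cls, n_classes = as.integer(n_classes),
                 min = min, max = max),
            class = "class_labels")
}

#' RBF kernel evaluation
#'
#' `K(x, y) = exp(-gamma * ||x - y||^2)`; K(x, x) = 1 and 0 < K <= 1.
#'
#' @param x,y numeric vectors of equal length.
#' @param gamma positive kernel width parameter.
#' @return kernel value.
#' @export
rbf_kernel <- function(x, y, gamma) {
  stopifnot(gamma > 0, length(x) == length(y))
  exp(-gamma * sum((x - y)^2))
}

#' Default dyadic hyperparameter grids
#'
#' `C = 2^-5 ... 2^15` (21 values) and `gamma = 2^-15 ... 2^15` (31 values).
#' @name svm_grids
#' @export
default_c_grid <- function() 2^(-5:15)

#' @rdname svm_grids
#' @export
default_gamma_grid <- function() 2^(-15:15)

# column standardization with stored parameters; zero-SD columns pass
# through unscaled so all-constant features stay finite
fit_scaler <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2L, stats::sd)
  sd[sd == 0] <- 1
  list(mu = mu, sd = sd)
}
apply_scaler <- function(X, scaler) sweep(sweep(X, 2L, scaler$mu), 2L, scaler$sd, "/")

# raw binary decision values w'phi(x) - rho computed directly from the
# LIBSVM support vectors: exp(-gamma ||x - sv||^2) %*% coefs - rho.
# Avoids predict() overhead inside the LOOCV loops.
svm_decision <- function(m, X, gamma) {
  d2 <- outer(rowSums(X^2), rowSums(m$SV^2), "+") - 2 * tcrossprod(X, m$SV)
  as.vector(exp(-gamma * pmax(d2, 0)) %*% m$coefs) - m$rho
}

# one binary RBF-SVM per observed class (one-against-all); orientation of
# each decision value is calibrated on the training rows so positive = the
# class (LIBSVM orients by first-seen training label)
oaa_fit <- function(X, y, cost, gamma) {
  classes <- sort(unique(y))
  if (length(classes) < 2L)
    return(list(classes = classes, fits = NULL, gamma = gamma))
  fits <- lapply(classes, function(k) {
    yk <- factor(ifelse(y == k, "pos", "neg"), levels = c("pos", "neg"))
    m <- e1071::svm(X, yk, type = "C-classification", kernel = "radial",
                    cost = cost, gamma = gamma, scale = FALSE, fitted = FALSE)
    dv <- svm_decision(m, X, gamma)
    flip <- mean(dv[y == k]) < mean(dv[y != k])
    list(model = m, flip = flip)
  })
  list(classes = classes, fits = fits, gamma = gamma)
}

# prediction = class whose binary classifier yields the highest decision
# value; exact ties resolved toward the lowest class index
oaa_predict <- function(fit, X) {
  X <- rbind(X)  # promote a single row
  if (is.null(fit$fits)) return(rep(fit$classes, nrow(X)))
  dv <- vapply(fit$fits, function(f) {
    d <- svm_decision(f$model, X, fit$gamma)
    if (f$flip) -d else d
  }, numeric(nrow(X)))
  dv <- rbind(dv)
  fit$classes[apply(dv, 1L, which.max)]  # which.max: first (= lowest class)
}

# LOOCV predictions of the OAA machine at fixed (cost, gamma); each fold
# re-estimates the feature scaler on its n-1 training rows
oaa_loocv <- function(X, y, cost, gamma) {
  n <- nrow(X)
  pred <- integer(n)
  for (i in seq_len(n)) {
    sc <- fit_scaler(X[-i, , drop = FALSE])
    fit <- oaa_fit(apply_scaler(X[-i, , drop = FALSE], sc), y[-i], cost, gamma)
    pred[i] <- oaa_predict(fit, apply_scaler(X[i, , drop = FALSE], sc))
  }
  pred
}

#' Train a one-against-all multiclass RBF-SVM with grid search
#'
#' For every (C, gamma) on the grid, the leave-one-out cross-validated
#' accuracy of the one-against-all machine is computed; the pair maximizing
#' it is selected (ties toward smaller C, then smaller gamma — the grid is
#' scanned in ascending order and only strict improvements replace the
#' incumbent). The final machine is refit on all subjects at the selected
#' pair. Features are standardized per column (training mean/SD, stored for
#' test-time reuse) before the kernel.
#'
#' @param features subjects x edges numeric matrix.
#' @param labels a `class_labels` from [discretize()] (or integer vector).
#' @param c_grid,gamma_grid hyperparameter grids (defaults: the full dyadic
#'   grids of [default_c_grid()] / [default_gamma_grid()]).
#' @param scheme `"flat"` evaluates candidates by the same LOOCV loop that
#'   is later reported (the historical design this package reproduces);
#'   `"nested"` re-runs the grid search inside every outer LOOCV fold so the
#'   reported accuracy is selection-free (much slower).
#' @return list of class `oaa_model`: `fit`, `scaler`, `best_c`,
#'   `best_gamma`, `loocv_pred`, `loocv_accuracy` (percent), `labels`,
#'   `grid_accuracy` (matrix C x gamma, percent).
#' @export
train_oaa_svm <- function(features, labels, c_grid = default_c_grid(),
                          gamma_grid = default_gamma_grid(),
                          scheme = c("flat", "nested"), edge_ids = NULL) {
  scheme <- match.arg(scheme)
  X <- as.matrix(features)
  y <- if (inherits(labels, "class_labels")) labels$classes else as.integer(labels)
  stopifnot(nrow(X) == length(y))
  if (ncol(X) == 0L) stop("empty feature matrix")
  if (length(unique(y)) < 2L) stop("need >= 2 distinct classes to train")
  c_grid <- sort(c_grid); gamma_grid <- sort(gamma_grid)
  acc <- matrix(NA_real_, length(c_grid), length(gamma_grid),
                dimnames = list(format(c_grid), format(gamma_grid)))
  best <- list(acc = -Inf, cost = NA_real_, gamma = NA_real_, pred = NULL)
  for (ci in seq_along(c_grid)) for (gi in seq_along(gamma_grid)) {
    pred <- oaa_loocv(X, y, c_grid[ci], gamma_grid[gi])
    a <- 100 * mean(pred == y)
    acc[ci, gi] <- a
    if (a > best$acc)
      best <- list(acc = a, cost = c_grid[ci], gamma = gamma_grid[gi], pred = pred)
  }
  loocv_pred <- if (scheme == "nested") {
    nested_loocv(X, y, c_grid, gamma_grid)
  } else best$pred
  scaler <- fit_scaler(X)
  fit <- oaa_fit(apply_scaler(X, scaler), y, best$cost, best$gamma)
  structure(list(fit = fit, scaler = scaler, best_c = best$cost,
                 best_gamma = best$gamma, loocv_pred = loocv_pred,
                 loocv_accuracy = 100 * mean(loocv_pred == y),
                 labels = if (inherits(labels, "class_labels")) labels else
                   structure(list(classes = y, n_classes = max(8L, max(y)),
                                  min = NA_real_, max = NA_real_),
                             class = "class_labels"),
                 truth = y, grid_accuracy = acc, scheme = scheme,
                 edge_ids = edge_ids),
            class = "oaa_model")
}

# outer LOOCV whose every fold re-runs the flat grid search on its own
# training subset; removes hyperparameter selection bias
nested_loocv <- function(X, y, c_grid, gamma_grid) {
  n <- nrow(X)
  pred <- integer(n)
  for (i in seq_len(n)) {
    inner_best <- list(acc = -Inf, cost = NA_real_, gamma = NA_real_)
    for (cost in c_grid) for (gamma in gamma_grid) {
      a <- mean(oaa_loocv(X[-i, , drop = FALSE], y[-i], cost, gamma) == y[-i])
      if (a > inner_best$acc) inner_best <- list(acc = a, cost = cost, gamma = gamma)
    }
    sc <- fit_scaler(X[-i, , drop = FALSE])
    fit <- oaa_fit(apply_scaler(X[-i, , drop = FALSE], sc), y[-i],
                   inner_best$cost, inner_best$gamma)
    pred[i] <- oaa_predict(fit, apply_scaler(X[i, , drop = FALSE], sc))
  }
  pred
}

#' Confusion-matrix report for predicted vs true classes
#'
#' Accuracy is percent correct; sensitivity and specificity are one-vs-rest
#' macro averages over the `n_classes` classes (classes absent from the
#' truth contribute no sensitivity term; classes never predicted and never
#' true contribute specificity 100).
#'
#' @param pred,truth integer class vectors.
#' @param n_classes total classes (default 8).
#' @param n_for_chance sample size used for the corrected chance level
#'   (defaults to `length(truth)`).
#' @param alpha level for the chance correction.
#' @param parameter name carried in the report.
#' @return list of class `classifier_report`: `confusion`, `accuracy`,
#'   `sensitivity`, `specificity`, `chance_theoretical`, `chance_corrected`,
#'   `correct` (per-subject logical), `n`.
#' @export
classifier_report <- function(pred, truth, n_classes = 8L,
                              n_for_chance = length(truth), alpha = 0.05,
                              parameter = "score") {
  stopifnot(length(pred) == length(truth))
  lev <- seq_len(n_classes)
  conf <- table(factor(truth, lev), factor(pred, lev), dnn = c("true", "pred"))
  tp <- diag(conf)
  sens <- ifelse(rowSums(conf) > 0, tp / rowSums(conf), NA_real_)
  tn <- sum(conf) - rowSums(conf) - colSums(conf) + tp
  spec <- tn / (sum(conf) - rowSums(conf))
  ch <- chance_levels(n_classes, n_for_chance, alpha)
  structure(list(parameter = parameter, confusion = conf,
                 accuracy = 100 * mean(pred == truth),
                 sensitivity = 100 * mean(sens, na.rm = TRUE),
                 specificity = 100 * mean(spec, na.rm = TRUE),
                 chance_theoretical = ch$theoretical,
                 chance_corrected = ch$corrected,
                 correct = pred == truth, n = length(truth)),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf(paste0("classifier_report [%s]: accuracy %.1f%% ",
                     "(chance %.1f%%, corrected %.1f%%), ",
                     "sensitivity %.1f%%, specificity %.1f%%, n = %d\n"),
              x$parameter, x$accuracy, x$chance_theoretical,
              x$chance_corrected, x$sensitivity, x$specificity, x$n))
  invisible(x)
}

#' Leave-one-out evaluation of an OAA-SVM specification
#'
#' Each subject is predicted by a machine trained on the other n - 1
#' subjects at the given (C, gamma).
#'
#' @param features subjects x edges matrix.
#' @param labels `class_labels` or integer vector.
#' @param cost,gamma hyperparameters.
#' @param parameter name carried in the report.
#' @param alpha chance-correction level.
#' @return a [classifier_report()] with `pred` attached.
#' @export
loocv_evaluate <- function(features, labels, cost, gamma, parameter = "score",
                           alpha = 0.05) {
  X <- as.matrix(features)
  y <- if (inherits(labels, "class_labels")) labels$classes else as.integer(labels)
  nc <- if (inherits(labels, "class_labels")) labels$n_classes else 8L
  if (nrow(X) < length(unique(y)))
    stop("need at least as many subjects as observed classes")
  pred <- oaa_loocv(X, y, cost, gamma)
  rep <- classifier_report(pred, y, n_classes = nc, alpha = alpha,
                           parameter = parameter)
  rep$pred <- pred
  rep
}

#' Theoretical and binomial-corrected chance levels
#'
#' Theoretical chance is `100 / n_classes`. The corrected chance is the
#' accuracy threshold that random guessing exceeds with probability < alpha
#' given the sample size: `100 * k / n_samples` with
#' `k = qbinom(1 - alpha, n_samples, 1/n_classes)` (the binomial inverse-CDF
#' convention; k = 26 at n = 150, 8 classes, alpha 0.05, i.e. 17.33%).
#' Non-increasing in `n_samples` and always >= the theoretical level.
#'
#' @param n_classes number of classes (>= 2).
#' @param n_samples sample size (>= 1).
#' @param alpha significance level.
#' @return list: `theoretical` (percent), `corrected` (percent), `k`.
#' @export
chance_levels <- function(n_classes = 8L, n_samples, alpha = 0.05) {
  stopifnot(n_classes >= 2L, n_samples >= 1L)
  k <- stats::qbinom(1 - alpha, n_samples, 1 / n_classes)
  k <- max(k, 1L)
  list(theoretical = 100 / n_classes, corrected = 100 * k / n_samples, k = k)
}

#' Test classification accuracy against chance
#'
#' Primary method: exact one-sided binomial test of the correct-prediction
#' count against p0 = 1/n_classes. A one-sample t-test on a vector of
#' accuracies (the group-level test across networks) is available as the
#' secondary method via `accuracies`.
#'
#' @param report a [classifier_report()] (primary method), or NULL.
#' @param alpha significance level.
#' @param n_classes classes defining p0.
#' @param accuracies optional numeric vector of per-network accuracies
#'   (percent) for the t-test mode.
#' @return list: `method`, `p`, `significant`.
#' @export
significance_vs_chance <- function(report = NULL, alpha = 0.05, n_classes = 8L,
                                   accuracies = NULL) {
  if (!is.null(accuracies)) {
    tt <- stats::t.test(accuracies, mu = 100 / n_classes, alternative = "greater")
    return(list(method = "t_across_networks", p = tt$p.value,
                significant = tt$p.value < alpha))
  }
  stopifnot(inherits(report, "classifier_report"))
  k <- sum(report$correct)
  p <- stats::pbinom(k - 1L, report$n, 1 / n_classes, lower.tail = FALSE)
  list(method = "exact_binomial", p = p, significant = p < alpha)
}

#' Apply trained classifiers to a new population
#'
#' Features must align with the training edge ids; scaling and the
#' discretization min/max stored at training time are reused. When true
#' scores are supplied they are discretized with the stored mapping and a
#' [classifier_report()] against the predictions is returned.
#'
#' @param new_features subjects x edges matrix (columns = training edges).
#' @param model an `oaa_model` from [train_oaa_svm()].
#' @param edge_ids optional character ids of the columns of `new_features`;
#'   checked against `model$edge_ids` when both are present.
#' @param true_scores optional numeric scores of the new subjects.
#' @param parameter name carried in the report.
#' @return list: `pred` (classes); plus `report` when `true_scores` given.
#' @export
apply_classifiers <- function(new_features, model, edge_ids = NULL,
                              true_scores = NULL, parameter = "score") {
  X <- as.matrix(new_features)
  if (!is.null(edge_ids) && !is.null(model$edge_ids) &&
      !identical(as.character(edge_ids), as.character(model$edge_ids)))
    stop("alignment error: feature edge ids do not match the trained model")
  if (ncol(X) != length(model$scaler$mu))
    stop("alignment error: feature column count does not match the trained model")
  pred <- oaa_predict(model$fit, apply_scaler(X, model$scaler))
  out <- list(pred = pred)
  if (!is.null(true_scores)) {
    lab <- discretize(true_scores, n_classes = model$labels$n_classes,
                      min = model$labels$min, max = model$labels$max)
    out$report <- classifier_report(pred, lab$classes,
                                    n_classes = model$labels$n_classes,
                                    parameter = parameter)
  }
  out
}
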