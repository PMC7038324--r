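#' Enumerate the SVM hyperparameter grid
#'
#' Cartesian product of cost, gamma and kernel axes in deterministic
#' cost-major order (cost varies slowest, kernel fastest), matching how the
#' result tables are conventionally printed. The default axes are cost
#' {1, 10, 100}, gamma {1, 0.1, 0.01} and kernels {linear, rbf}, giving 18
#' configurations.
#'
#' @param costs,gammas Numeric axes; must be non-empty.
#' @param kernels Character axis, subset of `c("linear", "radial")` aliases
#'   `"rbf"` accepted.
#' @return Data frame `cost`, `gamma`, `kernel`, one row per configuration.
#' @examples
#' nrow(enumerate_grid()) # 18
#' @export
enumerate_grid <- function(costs = c(1, 10, 100),
                           gammas = c(1, 0.1, 0.01),
                           kernels = c("linear", "rbf")) {
  if (!length(costs) || !length(gammas) || !length(kernels)) {
    stop("invalid grid: every axis must be non-empty", call. = FALSE)
  }
  g <- expand.grid(kernel = as.character(kernels), gamma = gammas,
                   cost = costs, stringsAsFactors = FALSE,
                   KEEP.OUT.ATTRS = FALSE)
  data.frame(cost = g$cost, gamma = g$gamma, kernel = g$kernel)
}

#' @keywords internal
stratified_folds <- function(labels, k, seed) {
  n <- length(labels)
  if (n < k) stop("fewer samples than folds", call. = FALSE)
  set.seed(seed)
  fold <- integer(n)
  offset <- 0L
  for (cls in unique(as.character(labels))) {
    idx <- which(labels == cls)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
    offset <- offset + length(idx)
  }
  fold
}

#' Cross-validated SVM accuracy for one configuration
#'
#' Stratified, seeded k-fold protocol: within each fold, features are
#' standardized using the training portion's mean and standard deviation,
#' an SVM with the given cost/gamma/kernel is trained, and accuracy is
#' scored on the held-out fold. Gamma only affects the RBF kernel; it is
#' accepted (and reported) for linear configurations but ignored by the
#' model, which is why linear rows of a grid share identical scores.
#'
#' @param x Feature matrix or data frame, n samples by d features.
#' @param y Class labels (factor or character), length n.
#' @param cost,gamma,kernel SVM hyperparameters; `kernel` is `"linear"` or
#'   `"rbf"`.
#' @param k Number of folds (default 8).
#' @param seed Integer seed controlling the fold assignment.
#' @param std `"population"` (divide by k; default) or `"sample"` spread of
#'   the per-fold accuracies.
#' @return List with `accuracy` (mean over folds), `std`, and
#'   `fold_accuracy`.
#' @export
cv_accuracy <- function(x, y, cost = 1, gamma = 1, kernel = "rbf",
                        k = 8, seed = 0, std = c("population", "sample")) {
  std <- match.arg(std)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- factor(y)
  n <- nrow(x)
  if (length(y) != n) stop("`x` and `y` sizes differ", call. = FALSE)
  if (any(is.na(x)) || any(is.na(y))) stop("missing values in features or labels",
                                           call. = FALSE)
  if (n < k) stop("n must be at least the number of folds", call. = FALSE)
  fold <- stratified_folds(y, k, seed)
  acc <- vapply(seq_len(k), function(f) {
    tr <- fold != f
    xtr <- x[tr, , drop = FALSE]; ytr <- droplevels(y[tr])
    xte <- x[!tr, , drop = FALSE]; yte <- y[!tr]
    if (nlevels(ytr) < nlevels(y)) {
      warning(sprintf("fold %d: training portion lacks class(es) %s; fitting on available classes",
                      f, paste(setdiff(levels(y), levels(ytr)), collapse = ", ")),
              call. = FALSE)
    }
    mu <- colMeans(xtr)
    sdv <- apply(xtr, 2L, stats::sd)
    sdv[!is.finite(sdv) | sdv == 0] <- 1
    xtr <- sweep(sweep(xtr, 2L, mu), 2L, sdv, "/")
    xte <- sweep(sweep(xte, 2L, mu), 2L, sdv, "/")
    pred <- if (nlevels(ytr) < 2L) {
      factor(rep(levels(ytr), nrow(xte)), levels = levels(y))
    } else {
      m <- e1071::svm(xtr, ytr, type = "C-classification",
                      kernel = svm_kernel(kernel), cost = cost, gamma = gamma,
                      scale = FALSE)
      stats::predict(m, xte)
    }
    mean(as.character(pred) == as.character(yte))
  }, numeric(1))
  spread <- if (std == "population") {
    sqrt(mean((acc - mean(acc))^2))
  } else {
    stats::sd(acc)
  }
  list(accuracy = mean(acc), std = spread, fold_accuracy = acc)
}

#' @keywords internal
svm_kernel <- function(kernel) {
  switch(kernel,
         linear = "linear",
         rbf = , radial = "radial",
         stop(sprintf("unsupported kernel '%s'", kernel), call. = FALSE))
}

#' Grid-search cross validation over one feature set
#'
#' Runs [cv_accuracy()] for every grid configuration with a common fold
#' assignment, so rows differ only in hyperparameters.
#'
#' @inheritParams cv_accuracy
#' @param grid Data frame from [enumerate_grid()].
#' @return Data frame `cost`, `gamma`, `kernel`, `accuracy`, `std` in grid
#'   order.
#' @export
grid_search <- function(x, y, grid = enumerate_grid(), k = 8, seed = 0,
                        std = c("population", "sample")) {
  std <- match.arg(std)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    r <- cv_accuracy(x, y, cost = grid$cost[i], gamma = grid$gamma[i],
                     kernel = grid$kernel[i], k = k, seed = seed, std = std)
    data.frame(cost = grid$cost[i], gamma = grid$gamma[i],
               kernel = grid$kernel[i], accuracy = r$accuracy, std = r$std)
  })
  do.call(rbind, res)
}

#' Best grid configuration
#'
#' Maximizes accuracy; among equally accurate configurations the one with
#' the smallest fold-to-fold standard deviation wins (a lower spread means
#' the score is the more stable estimate); any remaining tie keeps grid
#' order.
#'
#' @param results Data frame with `accuracy` and `std` columns, in grid
#'   order.
#' @return The winning row of `results`.
#' @export
best_config <- function(results) {
  stopifnot(is.data.frame(results), nrow(results) >= 1L,
            all(c("accuracy", "std") %in% names(results)))
  ord <- order(-results$accuracy, results$std)
  results[ord[1L], , drop = FALSE]
}

#' Assemble the three ripeness feature sets
#'
#' Builds the battery-only (load voltage), vision-only (R/G ratio) and
#' combined feature matrices from a per-fruit feature table.
#'
#' @param features Data frame with columns `v_l_mv`, `r_over_g` and
#'   `label`.
#' @return Named list of lists, each with `x` (matrix) and `y` (factor):
#'   `battery`, `vision`, `combined`.
#' @export
feature_sets <- function(features) {
  needed <- c("v_l_mv", "r_over_g", "label")
  if (!all(needed %in% names(features))) {
    stop("`features` must have columns v_l_mv, r_over_g, label", call. = FALSE)
  }
  y <- factor(features$label, levels = ripeness_levels())
  if (any(is.na(y))) stop("unknown ripeness labels in `features`", call. = FALSE)
  list(
    battery = list(x = cbind(v_l_mv = features$v_l_mv), y = y),
    vision = list(x = cbind(r_over_g = features$r_over_g), y = y),
    combined = list(x = cbind(v_l_mv = features$v_l_mv,
                              r_over_g = features$r_over_g), y = y)
  )
}
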