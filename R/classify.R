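#' Settings for the RBF-SVM evaluation harness
#'
#' Classification follows a repeated stratified holdout protocol: for each
#' of `n_shuffles` shuffles the data are split 70/30 (stratified by class
#' and, by default, group-aware so patches of one slide never straddle the
#' split), per-feature min-max scaling and the `(cost, gamma)` grid search
#' are fit on the training fold only, and accuracy is scored on the held
#' out 30%.
#'
#' @param c_grid,g_grid candidate SVM cost and RBF gamma values; defaults
#'   are the powers of two `2^-5 .. 2^5`.
#' @param n_shuffles number of repeated holdout shuffles (default 50).
#' @param train_fraction fraction of samples used for training (default 0.7).
#' @param seed base seed; shuffle k uses `seed + k`.
#' @param n_folds folds of the internal cross-validation of the grid search.
#' @param group_aware keep samples sharing a [patch_group()] key in the
#'   same fold (avoids patch leakage, which inflates accuracy).
#' @param search one of `"nested"` (default: grid search inside each
#'   shuffle's training fold; leak-free) or `"global"` (a single grid
#'   search on the full data, reused for every shuffle — a compatibility
#'   mode for protocols that report one `(c, g)` pair per method).
#' @return an object of class `classifier_config`.
#' @export
classifier_config <- function(c_grid = 2^(-5:5), g_grid = 2^(-5:5),
                              n_shuffles = 50L, train_fraction = 0.7,
                              seed = 1L, n_folds = 5L, group_aware = TRUE,
                              search = c("nested", "global")) {
  if (length(c_grid) == 0L || length(g_grid) == 0L)
    stop("hyperparameter grids must be non-empty")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("'train_fraction' must be in (0, 1)")
  if (n_shuffles < 1L) stop("'n_shuffles' must be >= 1")
  structure(list(c_grid = sort(c_grid), g_grid = sort(g_grid),
                 n_shuffles = as.integer(n_shuffles),
                 train_fraction = train_fraction, seed = as.integer(seed),
                 n_folds = as.integer(n_folds), group_aware = group_aware,
                 search = match.arg(search)),
            class = "classifier_config")
}

# Per-feature min-max scaler fit on the training fold; constant features
# map to 0.
fit_minmax <- function(x) {
  mins <- apply(x, 2, min)
  ranges <- apply(x, 2, max) - mins
  ranges[ranges == 0] <- 1
  list(min = mins, range = ranges)
}

apply_minmax <- function(x, scaler) {
  sweep(sweep(x, 2, scaler$min), 2, scaler$range, "/")
}

# Pairwise squared Euclidean distances (clipped at 0); computed once per
# scaled feature matrix so that every RBF kernel of the grid is a cheap
# elementwise exp of this matrix.
squared_distances <- function(x) {
  sq <- rowSums(x^2)
  pmax(outer(sq, sq, "+") - 2 * tcrossprod(x), 0)
}

# Fit an RBF C-SVM on a precomputed training kernel and predict the rows of
# a test-vs-train squared-distance block.
rbf_fit <- function(D2_tr, y_tr, cost, gamma) {
  K <- kernlab::as.kernelMatrix(exp(-gamma * D2_tr))
  kernlab::ksvm(K, y_tr, type = "C-svc", C = cost, kernel = "matrix")
}

rbf_predict <- function(fit, D2_te_tr, gamma) {
  Kte <- exp(-gamma * D2_te_tr)[, kernlab::SVindex(fit), drop = FALSE]
  kernlab::predict(fit, kernlab::as.kernelMatrix(Kte))
}

#' Grid search for RBF-SVM hyperparameters
#'
#' Evaluates every `(cost, gamma)` grid point by stratified k-fold
#' cross-validated accuracy on the supplied (training) data and returns
#' the maximizer; ties are broken toward the smallest cost, then the
#' smallest gamma.
#'
#' @param x numeric feature matrix (already scaled).
#' @param labels class labels, at least 2 classes present.
#' @param config a [classifier_config()].
#' @param seed seed for the fold assignment.
#' @return list with `cost`, `gamma` and the grid of CV accuracies
#'   (`accuracy`, a cost x gamma matrix in percent).
#' @export
grid_search <- function(x, labels, config = classifier_config(), seed = 1L) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L)
    stop("grid search needs at least 2 classes in the training data")
  x <- as.matrix(x)
  folds <- with_seed(seed, stratified_folds(labels, config$n_folds))
  D2 <- squared_distances(x)
  y <- factor(labels)
  acc <- matrix(NA_real_, length(config$c_grid), length(config$g_grid),
                dimnames = list(config$c_grid, config$g_grid))
  for (gi in seq_along(config$g_grid)) {
    g <- config$g_grid[gi]
    for (ci in seq_along(config$c_grid)) {
      correct <- 0L
      for (f in seq_len(max(folds))) {
        tr <- folds != f
        if (length(unique(labels[tr])) < 2L) next
        fit <- rbf_fit(D2[tr, tr, drop = FALSE], y[tr], config$c_grid[ci], g)
        pred <- rbf_predict(fit, D2[!tr, tr, drop = FALSE], g)
        correct <- correct + sum(pred == y[!tr])
      }
      acc[ci, gi] <- 100 * correct / length(labels)
    }
  }
  best <- which(acc == max(acc), arr.ind = TRUE)
  # ties: smallest cost first, then smallest gamma (grids are sorted)
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
  list(cost = config$c_grid[best[1]], gamma = config$g_grid[best[2]],
       accuracy = acc)
}

# Stratified fold ids 1..k (RNG must already be seeded by the caller).
stratified_folds <- function(labels, k) {
  folds <- integer(length(labels))
  for (cl in unique(labels)) {
    ix <- which(labels == cl)
    ix <- ix[sample.int(length(ix))]
    folds[ix] <- rep_len(seq_len(k), length(ix))
  }
  folds
}

# Stratified, optionally group-aware, train/test split.  Returns a logical
# train indicator.  RNG must already be seeded by the caller.
holdout_split <- function(labels, groups, fraction, group_aware) {
  train <- logical(length(labels))
  for (cl in unique(labels)) {
    ix <- which(labels == cl)
    if (length(ix) < 2L)
      stop("class '", cl, "' has fewer than 2 samples; stratified split impossible")
    if (group_aware) {
      gr <- unique(groups[ix])
      if (length(gr) < 2L)
        stop("class '", cl, "' has fewer than 2 groups; group-aware split ",
             "impossible (set group_aware = FALSE for naive splitting)")
      gr <- gr[sample.int(length(gr))]
      target <- round(fraction * length(ix))
      count <- 0L
      for (g in gr[-length(gr)]) {      # always leave >= 1 group for test
        members <- ix[groups[ix] == g]
        if (count >= target) break
        train[members] <- TRUE
        count <- count + length(members)
      }
      if (count == 0L) {                # fraction tiny: force 1 train group
        train[ix[groups[ix] == gr[1]]] <- TRUE
      }
    } else {
      n_tr <- min(max(round(fraction * length(ix)), 1L), length(ix) - 1L)
      train[ix[sample.int(length(ix))][seq_len(n_tr)]] <- TRUE
    }
  }
  train
}

#' Repeated stratified holdout evaluation with an RBF SVM
#'
#' The full protocol: for shuffle k in `1..n_shuffles` (seeded
#' `seed + k`), split the data into stratified 70/30 training and test
#' folds, fit the min-max scaler on the training fold, grid-search
#' `(cost, gamma)` by internal cross-validation on the training fold, fit
#' the SVM and score accuracy on the held-out fold.  Nothing fit on any
#' test sample ever touches the model.
#'
#' @param features a `feature_set` from [feature_matrix()], or a numeric
#'   matrix (then `labels` must be given).
#' @param labels class labels (taken from `features` if absent).
#' @param config a [classifier_config()].
#' @param groups group keys for leakage-free splitting (taken from
#'   `features` if absent; ignored when `config$group_aware` is FALSE).
#' @return an object of class `evaluation_report`: `per_shuffle_accuracy`
#'   (percent), `mean_accuracy`, `chosen_c`/`chosen_g` (the modal pair
#'   across shuffles), `per_shuffle` (list with indices, scaler and
#'   hyperparameters per shuffle, for audit), `n_train`, `n_test`,
#'   `class_names`, `config`.
#' @export
holdout_evaluate <- function(features, labels = NULL,
                             config = classifier_config(), groups = NULL) {
  if (inherits(features, "feature_set")) {
    x <- features$x
    labels <- labels %||% features$labels
    groups <- groups %||% features$groups
  } else x <- as.matrix(features)
  labels <- as.character(labels)
  if (is.null(groups)) groups <- as.character(seq_along(labels))
  stopifnot(nrow(x) == length(labels))
  if (min(table(labels)) < 2L)
    stop("every class needs at least 2 samples")
  y <- factor(labels)

  global <- NULL
  if (config$search == "global") {
    global <- grid_search(apply_minmax(x, fit_minmax(x)), labels, config,
                          seed = config$seed)
  }

  accs <- numeric(config$n_shuffles)
  shuffles <- vector("list", config$n_shuffles)
  for (k in seq_len(config$n_shuffles)) {
    sk <- config$seed + k
    train <- with_seed(sk, holdout_split(labels, groups,
                                         config$train_fraction,
                                         config$group_aware))
    scaler <- fit_minmax(x[train, , drop = FALSE])
    xs <- apply_minmax(x, scaler)
    hp <- if (is.null(global))
      grid_search(xs[train, , drop = FALSE], labels[train], config, seed = sk)
    else global
    D2 <- squared_distances(xs)
    fit <- rbf_fit(D2[train, train, drop = FALSE], y[train], hp$cost, hp$gamma)
    pred <- rbf_predict(fit, D2[!train, train, drop = FALSE], hp$gamma)
    accs[k] <- 100 * mean(pred == y[!train])
    shuffles[[k]] <- list(train = which(train), cost = hp$cost,
                          gamma = hp$gamma, scaler = scaler)
  }
  cg <- table(vapply(shuffles, function(s) paste(s$cost, s$gamma), ""))
  modal <- strsplit(names(cg)[which.max(cg)], " ")[[1]]
  structure(list(per_shuffle_accuracy = accs,
                 mean_accuracy = mean(accs),
                 chosen_c = as.numeric(modal[1]),
                 chosen_g = as.numeric(modal[2]),
                 per_shuffle = shuffles,
                 n_train = length(shuffles[[1]]$train),
                 n_test = nrow(x) - length(shuffles[[1]]$train),
                 class_names = levels(y),
                 config = config,
                 config_hash = config_hash(config)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation_report: %d shuffle(s), %d train / %d test per shuffle\n",
              length(x$per_shuffle_accuracy), x$n_train, x$n_test))
  cat(sprintf("  mean accuracy: %.2f%% (range %.2f - %.2f)\n",
              x$mean_accuracy, min(x$per_shuffle_accuracy),
              max(x$per_shuffle_accuracy)))
  cat(sprintf("  modal hyperparameters: cost %g, gamma %g\n",
              x$chosen_c, x$chosen_g))
  cat("  classes:", paste(x$class_names, collapse = ", "), "\n")
  invisible(x)
}

#' Write an evaluation report to JSON
#'
#' @param report an `evaluation_report`.
#' @param path output JSON path.
#' @export
write_report_json <- function(report, path) {
  obj <- list(mean_accuracy = report$mean_accuracy,
              per_shuffle_accuracy = report$per_shuffle_accuracy,
              chosen_c = report$chosen_c, chosen_g = report$chosen_g,
              n_train = report$n_train, n_test = report$n_test,
              class_names = report$class_names,
              config_hash = report$config_hash)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
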