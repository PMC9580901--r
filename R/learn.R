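#' @importFrom e1071 svm
#' @importFrom randomForest randomForest
NULL

#' Default hyperparameter grid for a classifier family
#'
#' SVM (RBF kernel): cost and kernel width. RF: features per split and tree
#' depth (`Inf` = unrestricted), 500 trees. NN (feed-forward, ReLU hidden
#' layers, logistic output, SGD): learning rate, epochs, hidden layers and
#' neurons per layer.
#'
#' @param kind one of `"SVM"`, `"RF"`, `"NN"`.
#' @return named list of candidate-value vectors.
#' @export
default_grid <- function(kind = c("SVM", "RF", "NN")) {
  kind <- match.arg(kind)
  switch(kind,
    SVM = list(C = c(0.1, 1, 10, 100), gamma = c(1e-3, 1e-2, 1e-1, 1)),
    RF  = list(max_features = c(2, 3, 8), depth = c(3, 5, 10, Inf)),
    NN  = list(learning_rate = c(1e-3, 1e-2, 1e-1), epochs = c(50, 200),
               hidden_layers = c(1, 2), neurons = c(8, 16))
  )
}

.standardizer <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2L, sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  list(mean = mu, sd = sdv)
}

.standardize <- function(X, std) {
  sweep(sweep(as.matrix(X), 2L, std$mean, "-"), 2L, std$sd, "/")
}

#' Stratified cross-validation folds
#'
#' @param labels vector in {-1, +1}.
#' @param k number of folds.
#' @param rng_seed integer seed.
#' @return integer vector of fold ids (1..k), one per row, with each class
#'   spread as evenly as possible across folds.
#' @export
stratified_folds <- function(labels, k = 5L, rng_seed = 1L) {
  fold <- integer(length(labels))
  set.seed(rng_seed)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < k) stop("class ", cl, " has fewer rows (", length(idx),
                              ") than folds (", k, ")")
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

## ---- feed-forward network (ReLU hidden, logistic output, SGD) ----

.mlp_init <- function(n_in, hidden_layers, neurons, rng_seed) {
  set.seed(rng_seed)
  sizes <- c(n_in, rep(neurons, hidden_layers), 1L)
  lapply(seq_len(length(sizes) - 1L), function(i) {
    list(W = matrix(stats::rnorm(sizes[i] * sizes[i + 1L],
                                 sd = sqrt(2 / sizes[i])),
                    sizes[i], sizes[i + 1L]),
         b = numeric(sizes[i + 1L]))
  })
}

.mlp_forward <- function(layers, X) {
  nl <- length(layers)
  acts <- vector("list", nl + 1L)
  zs <- vector("list", nl)
  acts[[1L]] <- X
  for (i in seq_len(nl)) {
    z <- sweep(acts[[i]] %*% layers[[i]]$W, 2L, layers[[i]]$b, "+")
    zs[[i]] <- z
    acts[[i + 1L]] <- if (i < nl) pmax(z, 0) else 1 / (1 + exp(-z))
  }
  list(acts = acts, zs = zs, out = acts[[nl + 1L]][, 1L])
}

.mlp_fit <- function(X, y01, learning_rate, epochs, hidden_layers, neurons,
                     rng_seed, batch_size = 32L) {
  n <- nrow(X)
  layers <- .mlp_init(ncol(X), hidden_layers, neurons, rng_seed)
  nl <- length(layers)
  set.seed(rng_seed + 1L)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      fw <- .mlp_forward(layers, X[idx, , drop = FALSE])
      # logistic output + cross-entropy: delta = p - y
      delta <- matrix(fw$out - y01[idx], ncol = 1L) / length(idx)
      for (i in nl:1L) {
        gW <- crossprod(fw$acts[[i]], delta)
        gb <- colSums(delta)
        if (i > 1L) {
          delta <- (delta %*% t(layers[[i]]$W)) * (fw$zs[[i - 1L]] > 0)
        }
        layers[[i]]$W <- layers[[i]]$W - learning_rate * gW
        layers[[i]]$b <- layers[[i]]$b - learning_rate * gb
      }
    }
  }
  layers
}

## ---- per-family fit / posterior-probability helpers ----

.fit_one <- function(kind, X, y, params, rng_seed) {
  yf <- factor(y, levels = c(-1L, 1L))
  switch(kind,
    SVM = {
      set.seed(rng_seed)
      e1071::svm(x = X, y = yf, kernel = "radial", cost = params$C,
                 gamma = params$gamma, probability = TRUE, scale = FALSE)
    },
    RF = {
      set.seed(rng_seed)
      maxnodes <- if (is.finite(params$depth)) {
        max(2L, min(2L^params$depth, nrow(X)))
      } else NULL
      randomForest::randomForest(
        x = X, y = yf, ntree = 500L,
        mtry = min(params$max_features, ncol(X)),
        maxnodes = maxnodes)
    },
    NN = .mlp_fit(X, as.numeric(y == 1L), params$learning_rate, params$epochs,
                  params$hidden_layers, params$neurons, rng_seed)
  )
}

# probability of the positive (+1) class
.prob_pos <- function(kind, fit, X) {
  switch(kind,
    SVM = {
      pr <- attr(predict(fit, X, probability = TRUE), "probabilities")
      unname(pr[, "1"])
    },
    RF = unname(predict(fit, X, type = "prob")[, "1"]),
    NN = unname(.mlp_forward(fit, X)$out)
  )
}

.expand_grid_list <- function(grid) {
  df <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
}

#' Train one classifier with grid search and stratified 5-fold CV
#'
#' Features are z-score standardized using training-fold statistics only;
#' every grid point is scored by mean cross-validated ROC AUC on the
#' held-out folds; the best point is refit on the full dataset. All
#' randomness (folds, fit internals) is keyed to `rng_seed`.
#'
#' @param ds a `labeled_dataset` with both classes and at least 10 rows.
#' @param kind `"SVM"`, `"RF"` or `"NN"`.
#' @param grid named list of candidate values (see [default_grid()]).
#' @param rng_seed integer seed.
#' @param n_folds number of CV folds (default 5).
#' @return object of class `model_bundle`: `classifier_kind`, `best_params`,
#'   `standardizer`, `model`, `cv_report` (per-fold metrics of the best grid
#'   point plus a `mean` row), `grid_results` (mean AUC per point),
#'   `rng_seed`.
#' @export
train_model <- function(ds, kind = c("SVM", "RF", "NN"),
                        grid = default_grid(kind), rng_seed = 1L,
                        n_folds = 5L) {
  kind <- match.arg(kind)
  stopifnot(inherits(ds, "labeled_dataset"))
  data <- ds$data
  if (nrow(data) < 10L) stop("dataset has fewer than 10 rows")
  y <- data$label
  if (length(unique(y)) < 2L) stop("dataset has a single class")
  X <- as.matrix(data[feature_names()])
  folds <- stratified_folds(y, n_folds, rng_seed)
  points <- .expand_grid_list(grid)
  fold_metrics <- function(params, record = FALSE) {
    reps <- lapply(seq_len(n_folds), function(f) {
      tr <- folds != f
      std <- .standardizer(X[tr, , drop = FALSE])
      Xtr <- .standardize(X[tr, , drop = FALSE], std)
      Xte <- .standardize(X[!tr, , drop = FALSE], std)
      fit <- .fit_one(kind, Xtr, y[tr], params, rng_seed + f)
      p <- .prob_pos(kind, fit, Xte)
      preds <- data.frame(class = ifelse(p >= 0.5, 1L, -1L),
                          posterior = pmax(p, 1 - p))
      evaluate_predictions(preds, y[!tr])
    })
    if (record) reps else mean(vapply(reps, `[[`, numeric(1L), "roc_auc"))
  }
  mean_auc <- vapply(points, fold_metrics, numeric(1L))
  best_i <- which.max(mean_auc)
  best <- points[[best_i]]
  cv <- fold_metrics(best, record = TRUE)
  cv_report <- do.call(rbind, lapply(cv, as.data.frame))
  cv_report <- cbind(fold = seq_len(n_folds), cv_report)
  cv_report <- rbind(cv_report,
                     cbind(fold = NA, as.data.frame(as.list(colMeans(cv_report[-1L])))))
  std <- .standardizer(X)
  model <- .fit_one(kind, .standardize(X, std), y, best, rng_seed)
  grid_results <- cbind(do.call(rbind, lapply(points, as.data.frame)),
                        mean_roc_auc = mean_auc)
  structure(list(classifier_kind = kind, best_params = best,
                 standardizer = std, model = model, cv_report = cv_report,
                 grid_results = grid_results, rng_seed = rng_seed,
                 adr_label = ds$adr_label, config = ds$config),
            class = "model_bundle")
}

#' Predict class and posterior for feature vectors
#'
#' Raw feature rows are standardized with the bundle's stored standardizer.
#' The posterior is the probability of the *predicted* class (always >= 0.5);
#' `p_pos` carries the positive-class probability.
#'
#' @param bundle a `model_bundle`.
#' @param features data.frame or matrix with the 8 feature columns
#'   (rownames = accession) — e.g. rows of an [assemble_features()] result.
#' @return data.frame with columns `accession`, `kind`, `class` ({-1, +1}),
#'   `posterior` (in `[0.5, 1]`), `p_pos`.
#' @export
predict_model <- function(bundle, features) {
  stopifnot(inherits(bundle, "model_bundle"))
  X <- as.matrix(as.data.frame(features)[feature_names()])
  if (!all(is.finite(X))) stop("non-finite feature value")
  Xs <- .standardize(X, bundle$standardizer)
  p <- .prob_pos(bundle$classifier_kind, bundle$model, Xs)
  data.frame(accession = if (is.null(rownames(X))) seq_len(nrow(X)) else rownames(X),
             kind = bundle$classifier_kind,
             class = ifelse(p >= 0.5, 1L, -1L),
             posterior = pmax(p, 1 - p),
             p_pos = p,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' ROC AUC by the rank (Mann-Whitney) formula
#' @param scores numeric scores, higher = more positive.
#' @param labels vector in {-1, +1}.
#' @return AUC in `[0, 1]`; `NA` if a class is absent.
#' @export
roc_auc <- function(scores, labels) {
  pos <- labels == 1L
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#' @inheritParams roc_auc
#' @return average precision in `[0, 1]`; `NA` if no positive.
#' @export
pr_auc <- function(scores, labels) {
  pos <- labels == 1L
  if (!any(pos)) return(NA_real_)
  ord <- order(-scores)
  hit <- pos[ord]
  prec <- cumsum(hit) / seq_along(hit)
  sum(prec[hit]) / sum(pos)
}

#' Evaluate predictions against known labels
#'
#' Confusion-matrix metrics (accuracy, precision, recall, MCC, NPV, PPV)
#' plus ROC AUC and AUPRC from the positive-class probabilities. Ratios
#' with a zero denominator are reported as 0 and flagged.
#'
#' @param preds data.frame with columns `class` and `posterior` (probability
#'   of the predicted class); `p_pos` used if present.
#' @param labels vector in {-1, +1}, same length.
#' @return list of class `metrics_report`: `acc`, `prec`, `rec`, `mcc`,
#'   `roc_auc`, `auprc`, `npv`, `ppv`, `undefined` (names of zero-denominator
#'   metrics).
#' @export
evaluate_predictions <- function(preds, labels) {
  preds <- as.data.frame(preds)
  if (nrow(preds) != length(labels)) stop("preds and labels length mismatch")
  if (nrow(preds) == 0L) stop("empty predictions")
  cls <- preds$class
  p_pos <- if ("p_pos" %in% names(preds)) preds$p_pos else
    ifelse(cls == 1L, preds$posterior, 1 - preds$posterior)
  tp <- sum(cls == 1L & labels == 1L)
  tn <- sum(cls == -1L & labels == -1L)
  fp <- sum(cls == 1L & labels == -1L)
  fn <- sum(cls == -1L & labels == 1L)
  undefined <- character()
  ratio <- function(num, den, name) {
    if (den == 0) { undefined <<- c(undefined, name); return(0) }
    num / den
  }
  prec <- ratio(tp, tp + fp, "prec")
  rec <- ratio(tp, tp + fn, "rec")
  npv <- ratio(tn, tn + fn, "npv")
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mcc_den == 0) { undefined <- c(undefined, "mcc"); 0 } else
    (tp * tn - fp * fn) / mcc_den
  structure(list(acc = (tp + tn) / length(labels), prec = prec, rec = rec,
                 mcc = mcc,
                 roc_auc = roc_auc(p_pos, labels),
                 auprc = pr_auc(p_pos, labels),
                 npv = npv, ppv = prec,
                 undefined = undefined),
            class = "metrics_report")
}

#' @export
as.data.frame.metrics_report <- function(x, ...) {
  data.frame(acc = x$acc, prec = x$prec, rec = x$rec, mcc = x$mcc,
             roc_auc = x$roc_auc, auprc = x$auprc, npv = x$npv, ppv = x$ppv)
}

#' Select the best training configuration by mean CV ROC AUC
#'
#' @param reports data.frame with columns `diamond_threshold`, `neg_ratio`
#'   and `mean_roc_auc` (one row per configuration).
#' @return the winning row; ties broken by smaller `neg_ratio`, then smaller
#'   `diamond_threshold`, then input order.
#' @export
select_best_model <- function(reports) {
  reports <- as.data.frame(reports)
  if (nrow(reports) == 0L) stop("no reports")
  ord <- order(-reports$mean_roc_auc, reports$neg_ratio,
               reports$diamond_threshold, seq_len(nrow(reports)))
  reports[ord[1L], , drop = FALSE]
}
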