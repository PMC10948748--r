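# Feature assembly, optimal cutpoints for one-dimensional markers, and
# leave-one-out cross-validated multimodal classification.

#' Binary labels for the two prediction tasks
#'
#' `lifetime_mdd`: positive for every MDD subject. `non_remission`:
#' positive for MDD subjects whose 17-item Hamilton score exceeds
#' `hds_cutoff` (a score of 7 or lower with a lifetime MDD history
#' defines remission).
#'
#' @param subjects Subject table with `group` and `hds17` columns.
#' @param task `"lifetime_mdd"` or `"non_remission"`.
#' @param hds_cutoff Remission cutoff on the Hamilton scale (default 7).
#' @return Integer 0/1 vector.
#' @export
make_labels <- function(subjects, task = c("lifetime_mdd", "non_remission"),
                        hds_cutoff = 7) {
  task <- match.arg(task)
  switch(task,
         lifetime_mdd = as.integer(subjects$group == "mdd"),
         non_remission = as.integer(subjects$group == "mdd" &
                                      subjects$hds17 > hds_cutoff))
}

#' Assemble a feature matrix for classification
#'
#' Joins the per-modality feature tables on subject id, selects the
#' requested modality columns (see [modality_columns()]), keeps complete
#' cases only, and attaches task labels. The fused digital set
#' (happiness + actigraphy + facial + voice + nlp) has 29 columns, 30
#' with the HADS-D score added.
#'
#' @param features Output of [extract_features()].
#' @param modalities Character vector of modality names.
#' @param include_hadsd Add the HADS-D score column.
#' @param task,hds_cutoff Passed to [make_labels()].
#' @return List of class `feature_matrix`: `X` (numeric matrix, rownames
#'   subject ids), `y` (0/1), `subject_id`, `columns`, `modalities`,
#'   `task`.
#' @export
assemble_features <- function(features,
                              modalities = c("happiness", "actigraphy",
                                             "facial", "voice", "nlp"),
                              include_hadsd = FALSE,
                              task = "lifetime_mdd", hds_cutoff = 7) {
  mc <- modality_columns()
  unknown <- setdiff(modalities, names(mc))
  if (length(unknown))
    stop("unknown modality: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cols <- unlist(mc[modalities], use.names = FALSE)
  if (include_hadsd) cols <- c(cols, mc$hadsd)

  df <- merge(features$subjects, features$actigraphy, by = "subject_id")
  df <- merge(df, features$app, by = "subject_id")
  df <- df[order(df$subject_id), ]
  keep <- stats::complete.cases(df[, cols, drop = FALSE])
  if (!any(keep)) stop("zero complete cases", call. = FALSE)
  df <- df[keep, ]
  X <- as.matrix(df[, cols, drop = FALSE])
  rownames(X) <- df$subject_id
  structure(list(X = X, y = make_labels(df, task, hds_cutoff),
                 subject_id = df$subject_id, columns = cols,
                 modalities = modalities, include_hadsd = include_hadsd,
                 task = task),
            class = "feature_matrix")
}

#' Confusion counts to evaluation metrics
#'
#' @param tp,fp,tn,fn Confusion counts.
#' @param model Optional model label.
#' @return List of class `eval_result`: counts plus `f1`
#'   (`2*tp / (2*tp + fp + fn)`), `sensitivity`, `specificity`, `ppv`,
#'   `npv`. Ratios with a zero denominator are `NA` (undefined), never 0.
#' @export
confusion_metrics <- function(tp, fp, tn, fn, model = NA_character_) {
  rat <- function(num, den) if (den == 0) NA_real_ else num / den
  structure(list(model = model, n = tp + fp + tn + fn, n_pos = tp + fn,
                 tp = tp, fp = fp, tn = tn, fn = fn,
                 f1 = rat(2 * tp, 2 * tp + fp + fn),
                 sensitivity = rat(tp, tp + fn),
                 specificity = rat(tn, tn + fp),
                 ppv = rat(tp, tp + fp),
                 npv = rat(tn, tn + fn)),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf(
    "<eval> %s n=%d (pos %d): F1 %.3f sens %.3f spec %.3f ppv %.3f npv %.3f\n",
    if (is.na(x$model)) "" else x$model, x$n, x$n_pos,
    x$f1, x$sensitivity, x$specificity, x$ppv, x$npv))
  invisible(x)
}

eval_counts <- function(pred, truth, model = NA_character_) {
  confusion_metrics(tp = sum(pred == 1 & truth == 1),
                    fp = sum(pred == 1 & truth == 0),
                    tn = sum(pred == 0 & truth == 0),
                    fn = sum(pred == 0 & truth == 1),
                    model = model)
}

#' Optimal cutpoint for a one-dimensional marker
#'
#' Exhaustive search over all candidate thresholds (midpoints of
#' adjacent sorted unique values, plus the two degenerate extremes) and
#' both directions (`">="`: high values positive; `"<="`: low values
#' positive). The balanced criterion maximises sensitivity +
#' specificity; the imbalanced criterion maximises sensitivity + PPV
#' (appropriate when positives are rare). `criterion = "auto"` selects
#' imbalanced when positive prevalence is below `imbalance_prevalence`.
#' Ties are broken toward higher specificity, then lower threshold.
#'
#' @param values Numeric marker values.
#' @param labels 0/1 labels (both classes present).
#' @param criterion `"auto"`, `"balanced"` or `"imbalanced"`.
#' @param imbalance_prevalence Prevalence below which `"auto"` switches
#'   to the imbalanced criterion (default 0.3).
#' @return List of class `cutpoint_result`: `threshold`, `direction`,
#'   `criterion`, `score`, `metrics` (an `eval_result`).
#' @export
optimal_cutpoint <- function(values, labels,
                             criterion = c("auto", "balanced",
                                           "imbalanced"),
                             imbalance_prevalence = 0.3) {
  criterion <- match.arg(criterion)
  stopifnot(length(values) == length(labels))
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2)
    stop("both classes must be present", call. = FALSE)
  if (criterion == "auto")
    criterion <- if (mean(labels) < imbalance_prevalence) "imbalanced"
                 else "balanced"
  u <- sort(unique(values))
  cand <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  best <- NULL
  for (dir in c(">=", "<=")) {
    for (th in cand) {
      pred <- if (dir == ">=") as.integer(values >= th)
              else as.integer(values <= th)
      m <- eval_counts(pred, labels)
      score <- if (criterion == "balanced")
        m$sensitivity + m$specificity else m$sensitivity + m$ppv
      if (is.na(score)) next
      better <- is.null(best) || score > best$score + 1e-12 ||
        (abs(score - best$score) <= 1e-12 &&
           (na0(m$specificity) > na0(best$metrics$specificity) + 1e-12 ||
              (abs(na0(m$specificity) -
                     na0(best$metrics$specificity)) <= 1e-12 &&
                 th < best$threshold)))
      if (better)
        best <- list(threshold = th, direction = dir,
                     criterion = criterion, score = score, metrics = m)
    }
  }
  class(best) <- "cutpoint_result"
  best
}

na0 <- function(x) if (is.na(x)) 0 else x

# ---- model registry -------------------------------------------------

#' Default hyperparameters of the seven classifiers
#'
#' Fixed, documented defaults: RF with 500 trees; KNN with k = 5; SVM
#' with a radial kernel; decision tree with rpart defaults; naive Bayes
#' with Gaussian likelihoods; single-hidden-layer neural network with 16
#' units, weight decay 0.01, 300 iterations.
#'
#' @return Named list of hyperparameter lists.
#' @export
model_defaults <- function() {
  list(rf = list(ntree = 500),
       lr = list(),
       svm = list(kernel = "radial", cost = 1),
       knn = list(k = 5),
       dt = list(),
       nb = list(),
       ann = list(size = 16, decay = 0.01, maxit = 300))
}

# Fit on training data and predict 0/1 labels for newdata. All models
# receive fold-standardised numeric matrices.
fit_predict <- function(model, Xtr, ytr, Xte, params) {
  ytr_f <- factor(ytr, levels = c(0, 1))
  tr <- as.data.frame(Xtr)
  te <- as.data.frame(Xte)
  if (length(unique(ytr)) < 2)   # degenerate fold: majority fallback
    return(rep(as.integer(names(which.max(table(ytr)))), nrow(Xte)))
  switch(model,
    lr = {
      d <- cbind(tr, .y = ytr)
      fit <- suppressWarnings(stats::glm(.y ~ ., data = d,
                                         family = stats::binomial()))
      as.integer(suppressWarnings(
        stats::predict(fit, te, type = "response")) > 0.5)
    },
    rf = {
      fit <- randomForest::randomForest(x = Xtr, y = ytr_f,
                                        ntree = params$ntree)
      as.integer(as.character(stats::predict(fit, Xte)))
    },
    svm = {
      fit <- e1071::svm(x = Xtr, y = ytr_f, kernel = params$kernel,
                        cost = params$cost, scale = FALSE)
      as.integer(as.character(stats::predict(fit, Xte)))
    },
    knn = as.integer(as.character(
      class::knn(Xtr, Xte, ytr_f, k = min(params$k, nrow(Xtr))))),
    dt = {
      d <- cbind(tr, .y = ytr_f)
      fit <- rpart::rpart(.y ~ ., data = d, method = "class")
      as.integer(as.character(stats::predict(fit, te, type = "class")))
    },
    nb = {
      fit <- e1071::naiveBayes(x = tr, y = ytr_f)
      as.integer(as.character(stats::predict(fit, te)))
    },
    ann = {
      fit <- nnet::nnet(x = Xtr, y = as.numeric(ytr), size = params$size,
                        decay = params$decay, maxit = params$maxit,
                        entropy = TRUE, trace = FALSE)
      as.integer(stats::predict(fit, Xte) > 0.5)
    },
    stop("unknown model: ", model, call. = FALSE))
}

# standardise columns using training-fold statistics only (no leakage);
# constant columns are left centred but unscaled
fold_scale <- function(Xtr, Xte) {
  mu <- colMeans(Xtr)
  sdv <- apply(Xtr, 2, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  list(tr = sweep(sweep(Xtr, 2, mu), 2, sdv, "/"),
       te = sweep(sweep(Xte, 2, mu, check.margin = FALSE), 2, sdv, "/"))
}

#' Leave-one-out cross-validated evaluation of one model
#'
#' Each subject is predicted by a model trained on the remaining
#' subjects. Feature standardisation is refitted inside every training
#' fold. Folds are seeded deterministically from the master seed and the
#' held-out subject's identifier, and subjects are processed in a
#' canonical (sorted id) order, so results are reproducible and
#' invariant to input row order. A training fold that has lost one class
#' falls back to majority-class prediction.
#'
#' @param fm A `feature_matrix` from [assemble_features()], or a list
#'   with elements `X` (matrix with rownames) and `y` (0/1).
#' @param model One of `"rf"`, `"lr"`, `"svm"`, `"knn"`, `"dt"`, `"nb"`,
#'   `"ann"`.
#' @param seed Master integer seed.
#' @param params Hyperparameters (default [model_defaults()]).
#' @return An `eval_result` (see [confusion_metrics()]) with an extra
#'   `predictions` data.frame attached as attribute `"predictions"`.
#' @export
loocv_evaluate <- function(fm, model = "ann", seed = 1,
                           params = model_defaults()[[model]]) {
  X <- fm$X
  y <- fm$y
  n <- nrow(X)
  if (n < 3) stop("need n >= 3 subjects", call. = FALSE)
  if (length(unique(y)) < 2)
    stop("both classes must be present", call. = FALSE)
  ids <- rownames(X) %||% as.character(seq_len(n))
  ord <- order(ids)
  X <- X[ord, , drop = FALSE]
  y <- y[ord]
  ids <- ids[ord]
  pred <- integer(n)
  for (i in seq_len(n)) {
    sc <- fold_scale(X[-i, , drop = FALSE], X[i, , drop = FALSE])
    set.seed((abs(seed) %% 100000L) * 17231L + fold_hash(ids[i]))
    pred[i] <- fit_predict(model, sc$tr, y[-i], sc$te, params)
  }
  out <- eval_counts(pred, y, model = model)
  attr(out, "predictions") <- data.frame(subject_id = ids, truth = y,
                                         predicted = pred)
  out
}

# small stable string hash so fold seeds follow subjects, not positions
fold_hash <- function(id) {
  sum(utf8ToInt(id) * seq_along(utf8ToInt(id))) %% 10000L
}

#' Compare the seven classifiers under shared LOOCV folds
#'
#' @param fm A `feature_matrix`.
#' @param models Character vector of model names (default all seven).
#' @param seed Master seed shared by all models.
#' @return data.frame ranked by F1: model, n, n_features, F1,
#'   sensitivity, specificity, PPV, NPV.
#' @export
compare_models <- function(fm, models = names(model_defaults()),
                           seed = 1) {
  if (length(models) == 0) stop("empty model registry", call. = FALSE)
  rows <- lapply(models, function(m) {
    ev <- loocv_evaluate(fm, model = m, seed = seed)
    data.frame(model = m, n = ev$n, n_pos = ev$n_pos,
               n_features = ncol(fm$X), f1 = ev$f1,
               sensitivity = ev$sensitivity,
               specificity = ev$specificity,
               ppv = ev$ppv, npv = ev$npv)
  })
  out <- do.call(rbind, rows)
  out[order(-out$f1), ]
}
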