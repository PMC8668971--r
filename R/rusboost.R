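## indices realizing one random undersample of the majority class to 1:1
.rusIndices <- function(labels) {
  tab <- table(labels)
  if (length(tab) < 2L || any(tab == 0L))
    stop("both classes must be present for random undersampling")
  minorityClass <- names(tab)[which.min(tab)]
  nMin <- min(tab)
  keep <- which(labels == minorityClass)
  for (cl in setdiff(names(tab), minorityClass)) {
    idx <- which(labels == cl)
    keep <- c(keep, if (length(idx) > nMin) sample(idx, nMin) else idx)
  }
  sort(keep)
}

#' Randomly undersample the majority class to a 1:1 balance
#'
#' Keeps every minority-class example and draws, without replacement, a
#' random subset of the majority class of equal size. Example weights are
#' restricted to the retained rows and renormalized to sum to 1.
#'
#' @param features data.frame (or matrix) of feature rows.
#' @param labels factor or character vector of class labels, length
#'   \code{nrow(features)}; both classes must be present.
#' @param weights optional non-negative example weights; default uniform.
#' @param seed optional integer seed for a reproducible draw.
#' @return list with elements \code{features}, \code{labels},
#'   \code{weights} (renormalized) and \code{indices} (rows retained, in
#'   increasing order).
#' @export
randomUndersample <- function(features, labels, weights = NULL,
                              seed = NULL) {
  features <- as.data.frame(features)
  if (nrow(features) != length(labels))
    stop("features and labels disagree in length")
  if (is.null(weights)) weights <- rep(1 / length(labels), length(labels))
  if (length(weights) != length(labels) || any(weights < 0))
    stop("weights must be non-negative, one per example")
  if (!is.null(seed)) set.seed(seed)
  idx <- .rusIndices(labels)
  w <- weights[idx]
  list(features = features[idx, , drop = FALSE],
       labels = labels[idx],
       weights = w / sum(w),
       indices = idx)
}

## depth-limited classification tree weak learner
.fitWeakTree <- function(features, labels, weights, depth) {
  df <- data.frame(features, .y = labels)
  rpart::rpart(.y ~ ., data = df, weights = weights / mean(weights),
               method = "class",
               control = rpart::rpart.control(maxdepth = depth,
                                              minsplit = 2L, cp = 0,
                                              xval = 0L))
}

## class-probability matrix (n x 2, columns in `classes` order)
.weakProb <- function(fit, features, classes) {
  p <- predict(fit, newdata = as.data.frame(features), type = "prob")
  out <- matrix(0, nrow(p), length(classes),
                dimnames = list(NULL, classes))
  out[, colnames(p)] <- p
  out
}

#' Train a RUSBoost ensemble
#'
#' Boosting for class-imbalanced two-class problems. Example weights start
#' at 1/n. Each iteration (t = 1..P): the majority class is randomly
#' undersampled to a 1:1 balance (weights restricted and renormalized); a
#' weak hypothesis H_t is fitted on the balanced, weighted subset; the
#' AdaBoost.M2 pseudo-loss delta_t of H_t is evaluated on the FULL weighted
#' training set; the weight-update parameter a_t = delta_t / (1 - delta_t)
#' down-weights correctly classified examples via w <- w * a_t^h_t(x, y),
#' followed by normalization. The final classifier is the vote of the weak
#' hypotheses weighted by log(1/a_t). An iteration whose pseudo-loss reaches
#' 0.5 (no better than chance, e.g. a degenerate constant hypothesis) is
#' retried with a fresh undersample up to \code{maxRetries} times; if it
#' still fails, boosting stops early and keeps the hypotheses accumulated so
#' far.
#'
#' @param features data.frame or matrix of numeric features.
#' @param labels two-class factor (or coercible), length
#'   \code{nrow(features)}.
#' @param iterations number of boosting rounds P (default 100).
#' @param weakDepth maximum depth of the decision-tree weak learner
#'   (default 2).
#' @param seed optional integer seed controlling the undersampling draws.
#' @param maxRetries fresh undersampling draws allowed per failed iteration.
#' @return a [RUSBoostModel-class].
#' @references Seiffert, C., Khoshgoftaar, T.M., Van Hulse, J. and
#'   Napolitano, A. (2010) RUSBoost: a hybrid approach to alleviating class
#'   imbalance. IEEE Trans. SMC-A 40, 185-197.
#' @export
trainRUSBoost <- function(features, labels, iterations = 100L,
                          weakDepth = 2L, seed = NULL, maxRetries = 5L) {
  features <- as.data.frame(features)
  labels <- factor(labels)
  n <- nrow(features)
  if (n < 4L) stop("need at least 4 training examples")
  if (nlevels(labels) != 2L || any(table(labels) == 0L))
    stop("training requires both classes to be present")
  if (iterations < 1L) stop("iterations must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  classes <- levels(labels)
  minority <- names(which.min(table(labels)))
  yIdx <- as.integer(labels)
  w <- rep(1 / n, n)
  hyps <- list(); votes <- numeric(0); hist <- list()
  for (t in seq_len(iterations)) {
    ok <- FALSE
    for (attempt in seq_len(maxRetries)) {
      idx <- .rusIndices(labels)
      fit <- .fitWeakTree(features[idx, , drop = FALSE], labels[idx],
                          w[idx] / sum(w[idx]), depth = weakDepth)
      h <- .weakProb(fit, features, classes)
      hy <- h[cbind(seq_len(n), yIdx)]
      delta <- sum(w * (1 - hy))
      if (delta < 0.5) { ok <- TRUE; break }
    }
    if (!ok) {
      if (length(hyps) == 0L)
        stop("boosting failed: every iteration's pseudo-loss reached 0.5")
      warning("pseudo-loss >= 0.5 after ", maxRetries,
              " undersampling retries; stopping at ", length(hyps),
              " hypotheses")
      break
    }
    delta <- max(delta, 1e-10)           # perfect hypothesis guard
    a <- delta / (1 - delta)
    w <- w * a^hy
    w <- w / sum(w)
    hyps[[length(hyps) + 1L]] <- fit
    votes <- c(votes, log(1 / a))
    hist[[t]] <- data.frame(
      iteration = t, pseudoLoss = delta, voteWeight = log(1 / a),
      weightSum = sum(w), minWeight = min(w),
      nMinorityResampled = sum(labels[idx] == minority),
      nMajorityResampled = sum(labels[idx] != minority))
  }
  new("RUSBoostModel", hypotheses = hyps, voteWeights = votes,
      classes = classes, minorityClass = minority,
      weakLearnerSpec = list(learner = "rpart", maxdepth = weakDepth),
      history = do.call(rbind, hist))
}

#' Predict with a RUSBoost ensemble
#'
#' Per-class scores are the vote-weight-weighted sums of the weak
#' hypotheses' class probabilities; the predicted class is the argmax, with
#' exact ties broken toward the minority class observed at training time.
#'
#' @param object a [RUSBoostModel-class].
#' @param newdata data.frame of feature rows with the training columns.
#' @param type \code{"class"} (default) for labels, \code{"score"} for the
#'   n x 2 matrix of summed weighted votes.
#' @param ... ignored.
#' @return factor of predicted labels, or a score matrix.
#' @export
setMethod("predict", "RUSBoostModel",
  function(object, newdata, type = c("class", "score"), ...) {
    type <- match.arg(type)
    newdata <- as.data.frame(newdata)
    scores <- matrix(0, nrow(newdata), 2L,
                     dimnames = list(NULL, object@classes))
    for (t in seq_along(object@hypotheses)) {
      scores <- scores + object@voteWeights[t] *
        .weakProb(object@hypotheses[[t]], newdata, object@classes)
    }
    if (type == "score") return(scores)
    minCol <- match(object@minorityClass, object@classes)
    pick <- apply(scores, 1L, function(s) {
      if (abs(s[1L] - s[2L]) < 1e-12) minCol else which.max(s)
    })
    factor(object@classes[pick], levels = object@classes)
  })

#' Performance metrics from a two-class confusion matrix
#'
#' Per-class precision TP/(TP+FP), recall TP/(TP+FN) and F-score (their
#' harmonic mean), plus overall accuracy. A metric whose denominator is zero
#' is reported as NA (undefined) with a warning rather than as 0.
#'
#' @param confusion 2x2 table/matrix with true classes in rows and predicted
#'   classes in columns (matching dimnames).
#' @return object of class \code{MetricsReport}: list with elements
#'   \code{confusion}, \code{perClass} (data.frame: class, precision,
#'   recall, f_score), \code{accuracy} and \code{n}.
#' @examples
#' cm <- matrix(c(9, 1, 1, 9), 2, byrow = TRUE,
#'              dimnames = list(c("a", "b"), c("a", "b")))
#' computeMetrics(cm)$accuracy  # 0.9
#' @export
computeMetrics <- function(confusion) {
  cm <- as.matrix(confusion)
  if (!identical(dim(cm), c(2L, 2L)))
    stop("confusion must be a 2x2 matrix (truth in rows)")
  if (any(cm < 0) || sum(cm) == 0)
    stop("confusion counts must be non-negative with positive total")
  classes <- rownames(cm)
  if (is.null(classes)) classes <- colnames(cm)
  if (is.null(classes)) classes <- c("class1", "class2")
  perClass <- do.call(rbind, lapply(1:2, function(k) {
    tp <- cm[k, k]; fp <- sum(cm[-k, k]); fn <- sum(cm[k, -k])
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    f <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
      2 * prec * rec / (prec + rec) else NA_real_
    data.frame(class = classes[k], precision = prec, recall = rec,
               f_score = f, stringsAsFactors = FALSE)
  }))
  if (anyNA(perClass[, -1L]))
    warning("a metric denominator was zero; reported as NA (undefined)")
  out <- list(confusion = cm, perClass = perClass,
              accuracy = sum(diag(cm)) / sum(cm), n = sum(cm))
  class(out) <- "MetricsReport"
  out
}

#' @export
print.MetricsReport <- function(x, ...) {
  cat("MetricsReport (n =", x$n, ")\n")
  cat("  accuracy:", format(x$accuracy, digits = 4))
  if (!is.null(x$auc)) cat("   AUC:", format(x$auc, digits = 4))
  cat("\n  confusion (truth in rows):\n")
  print(x$confusion)
  print(x$perClass, row.names = FALSE)
  invisible(x)
}

#' Rank-based AUC from scores
#'
#' Mann-Whitney estimate of the area under the ROC curve: the probability
#' that a random positive example scores above a random negative one (ties
#' counted half).
#'
#' @param score numeric score, higher meaning more likely positive.
#' @param labels class labels.
#' @param positive label treated as positive.
#' @return AUC in [0, 1].
#' @export
rankAUC <- function(score, labels, positive) {
  pos <- labels == positive
  nPos <- sum(pos); nNeg <- sum(!pos)
  if (nPos == 0L || nNeg == 0L) return(NA_real_)
  r <- rank(score)
  (sum(r[pos]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Stratified k-fold cross-validation of RUSBoost
#'
#' Splits each class separately into k folds (so every fold preserves the
#' class ratio as closely as possible), trains a RUSBoost ensemble on each
#' training split and predicts the held-out fold; the per-fold confusion
#' counts are pooled into a single [computeMetrics()] report, augmented with
#' the rank-based AUC of the pooled minority-class vote margins.
#'
#' @param features data.frame or matrix of numeric features.
#' @param labels two-class labels, length \code{nrow(features)}.
#' @param k number of folds (default 10); every class must have >= k
#'   members.
#' @param iterations,weakDepth passed to [trainRUSBoost()].
#' @param seed optional integer seed (fold assignment and undersampling).
#' @return a \code{MetricsReport} with extra elements \code{auc}, \code{k}
#'   and \code{predictions} (data.frame: truth, predicted, minority-margin
#'   score, fold).
#' @export
stratifiedKFoldCV <- function(features, labels, k = 10L, iterations = 100L,
                              weakDepth = 2L, seed = NULL) {
  features <- as.data.frame(features)
  labels <- factor(labels)
  if (nlevels(labels) != 2L) stop("exactly two classes are required")
  tab <- table(labels)
  if (any(tab < k))
    stop("class '", names(tab)[which.min(tab)], "' has ", min(tab),
         " members, fewer than k = ", k, "; reduce k")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(features)
  ## per-class shuffle, base allocation floor(m/k) per fold, and leftovers
  ## sent to the currently smallest folds so total fold sizes differ by at
  ## most one
  fold <- integer(n)
  foldTotal <- integer(k)
  for (cl in levels(labels)) {
    idx <- sample(which(labels == cl))
    m <- length(idx)
    base <- m %/% k; extra <- m %% k
    alloc <- rep(base, k)
    if (extra > 0) {
      target <- order(foldTotal, seq_len(k))[seq_len(extra)]
      alloc[target] <- alloc[target] + 1L
    }
    fold[idx] <- rep(seq_len(k), alloc)
    foldTotal <- foldTotal + alloc
  }
  minority <- names(which.min(tab))
  truth <- pred <- character(0); score <- numeric(0); foldId <- integer(0)
  for (f in seq_len(k)) {
    test <- fold == f
    model <- trainRUSBoost(features[!test, , drop = FALSE], labels[!test],
                           iterations = iterations, weakDepth = weakDepth)
    s <- predict(model, features[test, , drop = FALSE], type = "score")
    p <- predict(model, features[test, , drop = FALSE], type = "class")
    truth <- c(truth, as.character(labels[test]))
    pred <- c(pred, as.character(p))
    score <- c(score, s[, minority] - s[, setdiff(levels(labels), minority)])
    foldId <- c(foldId, rep(f, sum(test)))
  }
  cm <- table(factor(truth, levels = levels(labels)),
              factor(pred, levels = levels(labels)))
  rep <- computeMetrics(unclass(as.matrix(cm)))
  rep$auc <- rankAUC(score, truth, positive = minority)
  rep$k <- k
  rep$predictions <- data.frame(truth = truth, predicted = pred,
                                score = score, fold = foldId,
                                stringsAsFactors = FALSE)
  rep
}
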