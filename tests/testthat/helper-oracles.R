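# Independent oracles and small fixture builders shared across tests.

# literal quadruple-loop evaluation of C(i,j) = sum_mn X(m,n) Y(m-i, n-j)
# (0-based indices; out-of-range Y terms are zero)
oracleCrossCorrelation <- function(X, Y) {
  M <- nrow(X); N <- ncol(X)
  C <- matrix(0, 2 * M - 1, 2 * N - 1)
  for (i in -(M - 1):(M - 1)) {
    for (j in -(N - 1):(N - 1)) {
      acc <- 0
      for (m in 0:(M - 1)) {
        for (n in 0:(N - 1)) {
          mi <- m - i; nj <- n - j
          if (mi >= 0 && mi <= M - 1 && nj >= 0 && nj <= N - 1)
            acc <- acc + X[m + 1, n + 1] * Y[mi + 1, nj + 1]
        }
      }
      C[i + M, j + N] <- acc
    }
  }
  C
}

# textbook per-column sample variance by direct summation
oracleColumnVariance <- function(C) {
  apply(C, 2, function(col) {
    m <- sum(col) / length(col)
    sum((col - m)^2) / (length(col) - 1)
  })
}

# least-squares sinusoid fit at one frequency: raw Lomb power is half the
# fitted sum of squares of a*cos(2*pi*f*t) + b*sin(2*pi*f*t) on the
# mean-centered signal
oracleLombPower <- function(x, f, t = seq_along(x)) {
  xc <- x - mean(x)
  fit <- lm(xc ~ 0 + cos(2 * pi * f * t) + sin(2 * pi * f * t))
  0.5 * sum(fitted(fit)^2)
}

# plain AdaBoost.M2 (no undersampling), rpart weak learner; independent
# reference for the balanced-data comparison
oracleAdaBoostM2 <- function(features, labels, iterations, depth = 2) {
  features <- as.data.frame(features)
  labels <- factor(labels)
  n <- nrow(features)
  w <- rep(1 / n, n)
  yIdx <- as.integer(labels)
  fits <- list(); alphas <- numeric(0)
  for (t in seq_len(iterations)) {
    df <- data.frame(features, .y = labels)
    fit <- rpart::rpart(.y ~ ., data = df, weights = w / mean(w),
                        method = "class",
                        control = rpart::rpart.control(maxdepth = depth,
                                                       minsplit = 2, cp = 0,
                                                       xval = 0))
    p <- predict(fit, df, type = "prob")
    hy <- p[cbind(seq_len(n), yIdx)]
    delta <- max(sum(w * (1 - hy)), 1e-10)
    if (delta >= 0.5) break
    a <- delta / (1 - delta)
    w <- w * a^hy
    w <- w / sum(w)
    fits[[length(fits) + 1]] <- fit
    alphas <- c(alphas, log(1 / a))
  }
  list(fits = fits, alphas = alphas, classes = levels(labels))
}

predictOracleBoost <- function(model, features) {
  features <- as.data.frame(features)
  scores <- matrix(0, nrow(features), length(model$classes))
  colnames(scores) <- model$classes
  for (t in seq_along(model$fits)) {
    p <- predict(model$fits[[t]], features, type = "prob")
    scores[, colnames(p)] <- scores[, colnames(p)] + model$alphas[t] * p
  }
  factor(model$classes[apply(scores, 1, which.max)],
         levels = model$classes)
}

# linearly separable 2-feature data with a 2:1 class imbalance
separableData <- function(n = 60, gap = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nMaj <- round(2 * n / 3); nMin <- n - nMaj
  x <- rbind(cbind(rnorm(nMaj), rnorm(nMaj)),
             cbind(rnorm(nMin) + gap, rnorm(nMin) + gap))
  data.frame(f1 = x[, 1], f2 = x[, 2],
             y = rep(c("non-deleted", "co-deleted"), c(nMaj, nMin)))
}

# small rectangular-plus-noise image and a connected random blob mask
randomMaskedImage <- function(M = 10, N = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  img <- matrix(rnorm(M * N), M, N)
  mask <- matrix(0, M, N)
  r <- sort(sample(seq_len(M), 2)); c <- sort(sample(seq_len(N), 2))
  mask[r[1]:r[2], c[1]:c[2]] <- 1
  list(image = img, mask = mask)
}
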