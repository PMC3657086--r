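# Learner registry and uniform fit/predict interface.
#
# Categorical learners return a positive-class score (for ROC) and a hard
# label; continuous learners return a numeric prediction. Every fit is
# wrapped so exceptions surface as model-matrix failures, never aborts.
# Defaults are declared, not tuned: each learner runs at its library
# defaults apart from the documented values below.

#' Learner registry
#'
#' The seven available statistical learners with their endpoint
#' capabilities and default parameters. `pp_bayes` (Laplacian-modified
#' naive Bayes on binary features), `rp_tree` (recursive-partitioning
#' tree, rpart), `rp_forest` (random forest, 100 trees) support
#' categorical endpoints only; `nn` (single-hidden-layer neural network,
#' nnet) and `svm` (RBF support vector machine, e1071) support both;
#' `pls_nipals` and `pls_simpls` (partial least squares, components by
#' internal cross-validation capped at 10) support continuous only.
#'
#' @return tibble with columns `name`, `supports_categorical`,
#'   `supports_continuous`, `defaults` (list).
#' @export
learner_registry <- function() {
  tibble(
    name = c("pp_bayes", "rp_tree", "rp_forest", "nn", "svm",
      "pls_nipals", "pls_simpls"),
    supports_categorical = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
    supports_continuous = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE),
    defaults = list(
      list(laplace_k = 1),
      list(),
      list(ntree = 100),
      list(size = 3, decay = 0.01, maxit = 100),
      list(),
      list(max_ncomp = 10, cv_folds = 5),
      list(max_ncomp = 10, cv_folds = 5)
    )
  )
}

learners_supporting <- function(endpoint_type) {
  reg <- learner_registry()
  if (endpoint_type == "categorical") reg$name[reg$supports_categorical]
  else reg$name[reg$supports_continuous]
}

# range-scale columns to [0, 1] on training ranges; constant columns -> 0
fit_range_scaler <- function(X) {
  lo <- apply(X, 2, min); hi <- apply(X, 2, max)
  span <- hi - lo
  span[span == 0] <- 1
  list(lo = lo, span = span, constant = hi == lo)
}

apply_range_scaler <- function(scaler, X) {
  Xs <- sweep(sweep(X, 2, scaler$lo), 2, scaler$span, "/")
  Xs[, scaler$constant] <- 0
  Xs
}

# ---- PLS1 (authored: NIPALS and SIMPLS) ---------------------------------

pls_fit_core <- function(X, y, ncomp, algorithm) {
  n <- nrow(X); p <- ncol(X)
  mx <- colMeans(X); my <- mean(y)
  sx <- apply(X, 2, stats::sd); sx[sx == 0] <- 1
  Xc <- sweep(sweep(X, 2, mx), 2, sx, "/")
  yc <- y - my
  ncomp <- min(ncomp, n - 1, p)
  assert_that(ncomp >= 1, "cannot fit PLS: no usable components")
  if (algorithm == "nipals") {
    W <- P <- matrix(0, p, ncomp); q <- numeric(ncomp)
    E <- Xc; f <- yc
    a_used <- 0
    for (a in seq_len(ncomp)) {
      w <- crossprod(E, f)
      nw <- sqrt(sum(w^2))
      if (nw < 1e-12) break
      w <- w / nw
      t <- E %*% w
      tt <- sum(t^2)
      if (tt < 1e-12) break
      pvec <- crossprod(E, t) / tt
      qa <- sum(f * t) / tt
      E <- E - t %*% t(pvec)
      f <- f - qa * t
      W[, a] <- w; P[, a] <- pvec; q[a] <- qa
      a_used <- a
    }
    assert_that(a_used >= 1, "PLS failed: no descriptor variance")
    W <- W[, 1:a_used, drop = FALSE]; P <- P[, 1:a_used, drop = FALSE]
    q <- q[1:a_used]
    B <- W %*% solve(crossprod(P, W), q)
  } else {
    # SIMPLS (de Jong), univariate response
    R <- matrix(0, p, ncomp); q <- numeric(ncomp)
    V <- matrix(0, p, 0)
    s <- crossprod(Xc, yc)
    a_used <- 0
    for (a in seq_len(ncomp)) {
      r <- s
      if (ncol(V) > 0) r <- r - V %*% crossprod(V, s)
      if (sqrt(sum(r^2)) < 1e-12) break
      t <- Xc %*% r
      nt <- sqrt(sum(t^2))
      if (nt < 1e-12) break
      t <- t / nt; r <- r / nt
      pvec <- crossprod(Xc, t)
      qa <- sum(yc * t)
      v <- pvec
      if (ncol(V) > 0) v <- v - V %*% crossprod(V, pvec)
      v <- v / sqrt(sum(v^2))
      V <- cbind(V, v)
      R[, a] <- r; q[a] <- qa
      a_used <- a
      s <- s - v %*% crossprod(v, s)
    }
    assert_that(a_used >= 1, "PLS failed: no descriptor variance")
    R <- R[, 1:a_used, drop = FALSE]; q <- q[1:a_used]
    B <- R %*% q
  }
  list(B = as.numeric(B), mx = mx, sx = sx, my = my, ncomp = a_used)
}

pls_predict_core <- function(fit, X) {
  Xc <- sweep(sweep(X, 2, fit$mx), 2, fit$sx, "/")
  as.numeric(Xc %*% fit$B + fit$my)
}

# choose ncomp by k-fold CV on the training data
pls_fit <- function(X, y, algorithm, max_ncomp = 10, cv_folds = 5, seed = 1) {
  n <- nrow(X)
  cap <- min(max_ncomp, n - 2, ncol(X))
  assert_that(cap >= 1, "too few records for PLS")
  folds <- withr::with_seed(seed, sample(rep_len(seq_len(cv_folds), n)))
  press <- numeric(cap)
  for (k in seq_len(cv_folds)) {
    tr <- folds != k
    if (sum(tr) < 3 || sum(!tr) < 1) next
    for (a in seq_len(cap)) {
      fa <- tryCatch(pls_fit_core(X[tr, , drop = FALSE], y[tr], a, algorithm),
        error = function(e) NULL)
      if (is.null(fa)) next
      pred <- pls_predict_core(fa, X[!tr, , drop = FALSE])
      press[a] <- press[a] + sum((y[!tr] - pred)^2)
    }
  }
  ncomp <- if (all(press == 0)) cap else which.min(replace(press, press == 0, Inf))
  fit <- pls_fit_core(X, y, ncomp, algorithm)
  fit$algorithm <- algorithm
  fit
}

# ---- Laplacian-modified naive Bayes (pp_bayes) --------------------------

# Binary-feature Bayes scorer of the kind popular in fingerprint-based
# virtual screening: features are
# presence bits (numeric columns binarised at the training median); each
# present feature contributes log((A_f + 1) / ((N_f + 1/p) * p)) where
# A_f = positives with the feature, N_f = records with the feature and
# p = training positive fraction. The decision threshold maximises
# Youden's J on the training scores.
ppbayes_fit <- function(X, y, positive_class, laplace_k = 1) {
  cut <- apply(X, 2, stats::median)
  bits <- sweep(X, 2, cut, ">")
  pos <- y == positive_class
  p <- mean(pos)
  assert_that(p > 0 && p < 1, "pp_bayes needs both classes in training data")
  A <- colSums(bits[pos, , drop = FALSE])
  N <- colSums(bits)
  w <- log((A + laplace_k) / ((N + laplace_k / p) * p))
  scores <- as.numeric(bits %*% w)
  thr <- ppbayes_threshold(scores, pos)
  list(cut = cut, w = w, threshold = thr, positive_class = positive_class,
    classes = unique(as.character(y)))
}

ppbayes_threshold <- function(scores, pos) {
  cand <- sort(unique(scores))
  if (length(cand) == 1) return(cand[1])
  mids <- (cand[-1] + cand[-length(cand)]) / 2
  j <- vapply(mids, function(t) {
    mean(scores[pos] > t) - mean(scores[!pos] > t)
  }, numeric(1))
  mids[which.max(j)]
}

ppbayes_score <- function(fit, X) {
  bits <- sweep(X, 2, fit$cut, ">")
  as.numeric(bits %*% fit$w)
}

# ---- uniform fit/predict -------------------------------------------------

#' Fit a learner
#'
#' Uniform interface over the learner registry. Categorical endpoints
#' require binary labels and a declared positive class. Stochastic
#' learners are made reproducible through `seed`.
#'
#' @param learner learner name from [learner_registry()].
#' @param X numeric training matrix (records x descriptors).
#' @param y response vector (character labels or numeric).
#' @param endpoint_type `"categorical"` or `"continuous"`.
#' @param positive_class positive label for categorical endpoints.
#' @param params named list overriding the registry defaults.
#' @param seed integer seed.
#' @return a `qsar_fit` object usable with [predict_learner()].
#' @export
fit_learner <- function(learner, X, y, endpoint_type,
                        positive_class = NULL, params = list(), seed = 1) {
  reg <- learner_registry()
  assert_that(learner %in% reg$name, sprintf("unknown learner: %s", learner))
  row <- which(reg$name == learner)
  supported <- if (endpoint_type == "categorical")
    reg$supports_categorical[row] else reg$supports_continuous[row]
  assert_that(supported,
    sprintf("learner %s does not support %s endpoints", learner, endpoint_type))
  p <- utils::modifyList(reg$defaults[[row]], params)
  if (endpoint_type == "categorical") {
    y <- as.character(y)
    classes <- sort(unique(y))
    assert_that(length(classes) == 2,
      "categorical model building requires binary labels")
    positive_class <- positive_class %||% classes[2]
    assert_that(positive_class %in% classes,
      "positive_class absent from training labels")
  }
  fit <- withr::with_seed(derive_seed(seed, learner), {
    switch(learner,
      pp_bayes = ppbayes_fit(X, y, positive_class, p$laplace_k),
      rp_tree = {
        df <- data.frame(.y = factor(y), X, check.names = FALSE)
        rpart::rpart(.y ~ ., data = df, method = "class")
      },
      rp_forest = randomForest::randomForest(
        x = X, y = factor(y), ntree = p$ntree),
      nn = {
        scaler <- fit_range_scaler(X)
        Xs <- apply_range_scaler(scaler, X)
        if (endpoint_type == "categorical") {
          y01 <- as.numeric(y == positive_class)
          net <- nnet::nnet(Xs, y01, size = p$size, decay = p$decay,
            maxit = p$maxit, entropy = TRUE, trace = FALSE, MaxNWts = 1e6)
          list(net = net, scaler = scaler, classes = classes)
        } else {
          my <- mean(y); sy <- stats::sd(y); if (sy == 0) sy <- 1
          net <- nnet::nnet(Xs, (y - my) / sy, size = p$size, decay = p$decay,
            maxit = p$maxit, linout = TRUE, trace = FALSE, MaxNWts = 1e6)
          list(net = net, scaler = scaler, my = my, sy = sy)
        }
      },
      svm = {
        scaler <- fit_range_scaler(X)
        Xs <- apply_range_scaler(scaler, X)
        if (endpoint_type == "categorical") {
          m <- e1071::svm(Xs, factor(y), scale = FALSE)
          list(svm = m, scaler = scaler)
        } else {
          m <- e1071::svm(Xs, y, scale = FALSE)
          list(svm = m, scaler = scaler)
        }
      },
      pls_nipals = pls_fit(X, y, "nipals", p$max_ncomp, p$cv_folds,
        derive_seed(seed, "plscv")),
      pls_simpls = pls_fit(X, y, "simpls", p$max_ncomp, p$cv_folds,
        derive_seed(seed, "plscv"))
    )
  })
  structure(
    list(learner = learner, fit = fit, endpoint_type = endpoint_type,
      positive_class = positive_class, columns = colnames(X),
      params = p, seed = seed),
    class = "qsar_fit"
  )
}

#' Predict from a fitted learner
#'
#' @param model a `qsar_fit` from [fit_learner()].
#' @param X numeric matrix with the training descriptor columns.
#' @return list with `pred` (labels or numeric) and, for categorical
#'   models, `score` (positive-class score used for ROC).
#' @export
predict_learner <- function(model, X) {
  assert_that(identical(colnames(X), model$columns),
    "descriptor columns do not match the fitted model")
  f <- model$fit
  cat_ep <- model$endpoint_type == "categorical"
  pos <- model$positive_class
  switch(model$learner,
    pp_bayes = {
      s <- ppbayes_score(f, X)
      neg <- setdiff(f$classes, pos)
      list(pred = ifelse(s > f$threshold, pos, neg), score = s)
    },
    rp_tree = {
      df <- data.frame(X, check.names = FALSE)
      pr <- stats::predict(f, df, type = "prob")
      s <- pr[, pos]
      lab <- colnames(pr)[max.col(pr, ties.method = "first")]
      list(pred = lab, score = as.numeric(s))
    },
    rp_forest = {
      pr <- stats::predict(f, X, type = "prob")
      s <- pr[, pos]
      list(pred = as.character(stats::predict(f, X)), score = as.numeric(s))
    },
    nn = {
      Xs <- apply_range_scaler(f$scaler, X)
      out <- as.numeric(stats::predict(f$net, Xs))
      if (cat_ep) {
        neg <- setdiff(f$classes, pos)
        lab <- ifelse(out > 0.5, pos, neg)
        list(pred = lab, score = out)
      } else {
        list(pred = out * f$sy + f$my)
      }
    },
    svm = {
      Xs <- apply_range_scaler(f$scaler, X)
      if (cat_ep) {
        pr <- stats::predict(f$svm, Xs, decision.values = TRUE)
        dv <- attr(pr, "decision.values")
        lab <- as.character(pr)
        nm <- colnames(dv)[1]
        first <- strsplit(nm, "/", fixed = TRUE)[[1]][1]
        s <- if (identical(first, pos)) dv[, 1] else -dv[, 1]
        list(pred = lab, score = as.numeric(s))
      } else {
        list(pred = as.numeric(stats::predict(f$svm, Xs)))
      }
    },
    pls_nipals = list(pred = pls_predict_core(f, X)),
    pls_simpls = list(pred = pls_predict_core(f, X))
  )
}
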