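#' Multi-class classification metrics
#'
#' Computes the full evaluation suite from true and predicted labels:
#' confusion matrix (rows = truth, columns = prediction), accuracy,
#' balanced accuracy, support-weighted precision / recall / F1,
#' multi-class Matthews correlation coefficient, Cohen's kappa, a
#' chi-squared goodness-of-fit test of the correct/incorrect split
#' against the 50% null, and (when posteriors are supplied) per-class
#' one-vs-rest AUROC.
#'
#' Undefined per-class ratios (zero predicted positives) contribute 0, so
#' weighted metrics are always finite.
#'
#' @param y_true,y_pred Label vectors of equal length.
#' @param posteriors Optional matrix / data frame of class posteriors
#'   with one column per class (plain class names or `.prob_<class>`).
#' @param labels Optional explicit class set; defaults to the union of
#'   observed labels (or factor levels).
#' @return An object of class `metric_report`.
#' @export
compute_metrics <- function(y_true, y_pred, posteriors = NULL,
                            labels = NULL) {
  if (length(y_true) == 0) abort("empty inputs")
  if (length(y_true) != length(y_pred)) abort("y_true and y_pred lengths differ")
  labels <- labels %||%
    (if (is.factor(y_true)) levels(y_true) else sort(unique(c(as.character(y_true), as.character(y_pred)))))
  yt <- factor(y_true, levels = labels)
  yp <- factor(y_pred, levels = labels)
  cm <- table(true = yt, predicted = yp)
  n <- sum(cm)

  tp <- diag(cm)
  support <- rowSums(cm)   # truth counts t_k
  predded <- colSums(cm)   # prediction counts p_k

  accuracy <- sum(tp) / n
  recall_c <- ifelse(support > 0, tp / support, NA_real_)
  precision_c <- ifelse(predded > 0, tp / predded, 0)
  f1_c <- ifelse(precision_c + recall_c > 0 & !is.na(recall_c),
                 2 * precision_c * recall_c / (precision_c + recall_c), 0)
  balanced_accuracy <- mean(recall_c, na.rm = TRUE)
  w <- support / n
  precision_w <- sum(w * precision_c, na.rm = TRUE)
  recall_w <- sum(w * ifelse(is.na(recall_c), 0, recall_c))
  f1_w <- sum(w * ifelse(is.na(f1_c), 0, f1_c))

  # multi-class MCC from the contingency counts
  s <- n
  c_ok <- sum(tp)
  num <- c_ok * s - sum(predded * support)
  den <- sqrt(s^2 - sum(predded^2)) * sqrt(s^2 - sum(support^2))
  mcc <- if (den > 0) num / den else 0

  po <- accuracy
  pe <- sum(predded * support) / n^2
  kappa <- if (pe < 1) (po - pe) / (1 - pe) else 1

  correct <- sum(tp)
  chisq <- suppressWarnings(chisq.test(c(correct, n - correct),
                                       p = c(0.5, 0.5)))

  auroc <- NULL
  if (!is.null(posteriors)) {
    post <- .posterior_matrix(posteriors, labels)
    auroc <- vapply(labels, function(cl) {
      if (!any(yt == cl) || all(yt == cl)) return(NA_real_)
      .auc_rank(post[, cl], yt == cl)
    }, numeric(1))
  }

  structure(
    list(confusion = cm, labels = labels, n = n,
         accuracy = accuracy, balanced_accuracy = balanced_accuracy,
         precision_w = precision_w, recall_w = recall_w, f1_w = f1_w,
         mcc = mcc, kappa = kappa,
         chisq_stat = unname(chisq$statistic), chisq_p = unname(chisq$p.value),
         per_class = tibble(class = labels, support = as.numeric(support),
                            precision = as.numeric(precision_c),
                            recall = as.numeric(recall_c),
                            f1 = as.numeric(f1_c),
                            auroc = if (is.null(auroc)) NA_real_ else as.numeric(auroc))),
    class = "metric_report"
  )
}

# accept posterior columns named either "<class>" or ".prob_<class>"
.posterior_matrix <- function(posteriors, labels) {
  post <- as.data.frame(posteriors)
  prefixed <- paste0(".prob_", labels)
  if (all(prefixed %in% names(post))) {
    post <- post[prefixed]
    names(post) <- labels
  } else if (!all(labels %in% names(post))) {
    abort("posterior columns do not cover all classes")
  } else {
    post <- post[labels]
  }
  as.matrix(post)
}

# AUROC by the rank (Mann-Whitney) statistic == trapezoid on the ROC
.auc_rank <- function(scores, positive) {
  r <- rank(scores, ties.method = "average")
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' @export
print.metric_report <- function(x, ...) {
  cat("Classification metrics (n =", x$n, ")\n")
  print(x$confusion)
  cat(sprintf("accuracy %.4f | balanced %.4f | precision_w %.4f | recall_w %.4f | F1_w %.4f\n",
              x$accuracy, x$balanced_accuracy, x$precision_w, x$recall_w,
              x$f1_w))
  cat(sprintf("MCC %.4f | kappa %.4f | chi-squared vs 50%%: %.2f (p = %.3g)\n",
              x$mcc, x$kappa, x$chisq_stat, x$chisq_p))
  invisible(x)
}

#' @export
tidy.metric_report <- function(x, ...) x$per_class

#' @export
glance.metric_report <- function(x, ...) {
  tibble(n = x$n, accuracy = x$accuracy,
         balanced_accuracy = x$balanced_accuracy,
         precision_w = x$precision_w, recall_w = x$recall_w, f1_w = x$f1_w,
         mcc = x$mcc, kappa = x$kappa,
         auroc_macro = mean(x$per_class$auroc, na.rm = TRUE),
         chisq_stat = x$chisq_stat, chisq_p = x$chisq_p)
}

#' @export
autoplot.metric_report <- function(object, ...) {
  df <- as.data.frame(object$confusion)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$Freq)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$Freq)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::scale_y_discrete(limits = rev(object$labels)) +
    ggplot2::labs(x = "predicted", y = "true", fill = "count")
}

# stratified fold assignment: per class, shuffled, cyclic fold ids
.stratified_folds <- function(y, k) {
  y <- factor(y)
  if (any(table(y) < k)) {
    abort(paste0("every class needs >= k members for k = ", k, "-fold CV"))
  }
  folds <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Stratified k-fold cross-validation of the LDA classifier
#'
#' Splits the data into `k` folds that preserve class proportions (with
#' `k = 5` each validation fold is a 0.2 fraction), fits the shrinkage
#' LDA on each training portion and scores the held-out fold, so every
#' sample is validated exactly once. Metrics are computed on the pooled
#' out-of-fold predictions.
#'
#' @param x Feature data frame / matrix (see [fit_lda()]).
#' @param y Class labels.
#' @param k Number of folds (default 5).
#' @param seed Optional integer seed controlling the fold assignment.
#' @param shrinkage,priors,tol Passed to [fit_lda()].
#' @return An object of class `cv_result`: list with `report` (a
#'   [compute_metrics()] report on pooled predictions), `predictions`
#'   (tibble of out-of-fold truth, prediction, posteriors, fold), and
#'   `folds` (the assignment).
#' @export
stratified_kfold_cv <- function(x, y, k = 5, seed = NULL,
                                shrinkage = "auto", priors = "empirical",
                                tol = 1e-4) {
  y <- factor(y)
  X <- .feature_matrix(x)
  folds <- .run_seeded(seed, function() .stratified_folds(y, k))
  labels <- levels(y)
  pred <- factor(rep(labels[1], length(y)), levels = labels)
  post <- matrix(NA_real_, length(y), length(labels),
                 dimnames = list(NULL, labels))
  for (f in seq_len(k)) {
    tr <- folds != f
    fit <- fit_lda(X[tr, , drop = FALSE], y[tr], shrinkage = shrinkage,
                   priors = priors, tol = tol)
    pr <- predict(fit, X[!tr, , drop = FALSE])
    pred[!tr] <- factor(as.character(pr$label), levels = labels)
    post[!tr, ] <- as.matrix(pr[paste0(".prob_", labels)])
  }
  report <- compute_metrics(y, pred, posteriors = post, labels = labels)
  structure(
    list(report = report,
         predictions = tibble(fold = folds, truth = y, pred = pred,
                              as_tibble(post)),
         folds = folds, k = k),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat("Stratified", x$k, "fold cross-validation\n")
  print(x$report)
  invisible(x)
}

#' @export
glance.cv_result <- function(x, ...) glance(x$report)

#' @export
tidy.cv_result <- function(x, ...) tidy(x$report)

#' One-vs-rest ROC and precision-recall curves with bootstrap bands
#'
#' For every class, scores are that class's posterior and positives are
#' the samples truly in the class. ROC and precision-recall curves are
#' built from the ranked scores (ties merged), AUCs by trapezoid, and 95%
#' confidence bands from bootstrap resamples of the (label, score) pairs,
#' evaluated on a fixed grid. A class absent from `y_true` is flagged
#' `defined = FALSE` rather than silently computed.
#'
#' @param y_true True labels.
#' @param posteriors Posterior matrix / data frame, one column per class.
#' @param n_boot Bootstrap resamples for the bands (default 1000).
#' @param seed Optional integer seed.
#' @param grid_size Number of grid points for the bands (default 101).
#' @return An object of class `ovr_curves`: list with `auc` (per-class
#'   AUROC / AUPRC with CIs and a `defined` flag), `roc` and `pr`
#'   (per-class curve tibbles with `lower` / `upper` band columns).
#' @export
ovr_curves <- function(y_true, posteriors, n_boot = 1000, seed = NULL,
                       grid_size = 101) {
  yt <- as.character(y_true)
  post <- as.data.frame(posteriors)
  classes <- sub("^\\.prob_", "", names(post))
  names(post) <- classes
  grid <- seq(0, 1, length.out = grid_size)

  .run_seeded(seed, function() {
    res <- lapply(classes, function(cl) {
      pos <- yt == cl
      if (!any(pos) || all(pos)) {
        return(list(auc = tibble(class = cl, auroc = NA_real_,
                                 auroc_lo = NA_real_, auroc_hi = NA_real_,
                                 auprc = NA_real_, auprc_lo = NA_real_,
                                 auprc_hi = NA_real_, defined = FALSE),
                    roc = NULL, pr = NULL))
      }
      s <- post[[cl]]
      roc <- .roc_points(s, pos)
      pr <- .pr_points(s, pos)
      auroc <- .auc_rank(s, pos)
      auprc <- .trapezoid(pr$recall, pr$precision)

      n <- length(s)
      boot_roc <- matrix(NA_real_, n_boot, grid_size)
      boot_pr <- matrix(NA_real_, n_boot, grid_size)
      boot_auroc <- numeric(n_boot)
      boot_auprc <- numeric(n_boot)
      for (b in seq_len(n_boot)) {
        i <- sample.int(n, n, replace = TRUE)
        if (!any(pos[i]) || all(pos[i])) {
          boot_auroc[b] <- NA
          boot_auprc[b] <- NA
          next
        }
        rb <- .roc_points(s[i], pos[i])
        pb <- .pr_points(s[i], pos[i])
        boot_auroc[b] <- .auc_rank(s[i], pos[i])
        boot_auprc[b] <- .trapezoid(pb$recall, pb$precision)
        boot_roc[b, ] <- approx(rb$fpr, rb$tpr, xout = grid, ties = "ordered",
                                rule = 2)$y
        boot_pr[b, ] <- approx(pb$recall, pb$precision, xout = grid,
                               ties = "ordered", rule = 2)$y
      }
      qs <- function(m) apply(m, 2, quantile, probs = c(0.025, 0.975),
                              na.rm = TRUE)
      qroc <- qs(boot_roc)
      qpr <- qs(boot_pr)
      ci <- function(v) quantile(v, c(0.025, 0.975), na.rm = TRUE)
      list(
        auc = tibble(class = cl, auroc = auroc,
                     auroc_lo = ci(boot_auroc)[1], auroc_hi = ci(boot_auroc)[2],
                     auprc = auprc,
                     auprc_lo = ci(boot_auprc)[1], auprc_hi = ci(boot_auprc)[2],
                     defined = TRUE),
        roc = tibble(class = cl, fpr = grid,
                     tpr = approx(roc$fpr, roc$tpr, xout = grid,
                                  ties = "ordered", rule = 2)$y,
                     lower = qroc[1, ], upper = qroc[2, ]),
        pr = tibble(class = cl, recall = grid,
                    precision = approx(pr$recall, pr$precision, xout = grid,
                                       ties = "ordered", rule = 2)$y,
                    lower = qpr[1, ], upper = qpr[2, ])
      )
    })
    structure(
      list(auc = list_rbind(map(res, "auc")),
           roc = list_rbind(map(res, "roc")),
           pr = list_rbind(map(res, "pr")),
           n_boot = n_boot),
      class = "ovr_curves"
    )
  })
}

# ROC points with tied scores merged, from (0,0) to (1,1)
.roc_points <- function(s, pos) {
  ord <- order(s, decreasing = TRUE)
  s <- s[ord]
  pos <- pos[ord]
  last <- !duplicated(s, fromLast = TRUE) # last index of each tie group
  tpr <- cumsum(pos)[last] / sum(pos)
  fpr <- cumsum(!pos)[last] / sum(!pos)
  tibble(fpr = c(0, fpr), tpr = c(0, tpr))
}

# precision-recall points at each distinct score threshold
.pr_points <- function(s, pos) {
  ord <- order(s, decreasing = TRUE)
  s <- s[ord]
  pos <- pos[ord]
  last <- which(!duplicated(s, fromLast = TRUE))
  tp <- cumsum(pos)[last]
  prec <- tp / last
  rec <- tp / sum(pos)
  tibble(recall = c(0, rec), precision = c(prec[1], prec))
}

.trapezoid <- function(x, y) {
  ord <- order(x)
  x <- x[ord]
  y <- y[ord]
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

#' @export
print.ovr_curves <- function(x, ...) {
  cat("One-vs-rest curves (", x$n_boot, "bootstrap resamples )\n")
  print(x$auc)
  invisible(x)
}

#' @export
autoplot.ovr_curves <- function(object, curve = c("roc", "pr"), ...) {
  curve <- match.arg(curve)
  if (curve == "roc") {
    ggplot2::ggplot(object$roc,
                    ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                 colour = .data$class, fill = .data$class)) +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower,
                                        ymax = .data$upper),
                           alpha = 0.2, colour = NA) +
      ggplot2::geom_line() +
      ggplot2::geom_abline(linetype = "dashed", colour = "grey50") +
      ggplot2::labs(x = "false positive rate", y = "true positive rate")
  } else {
    ggplot2::ggplot(object$pr,
                    ggplot2::aes(x = .data$recall, y = .data$precision,
                                 colour = .data$class, fill = .data$class)) +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower,
                                        ymax = .data$upper),
                           alpha = 0.2, colour = NA) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "recall", y = "precision")
  }
}

#' Compare baseline classifiers under identical folds
#'
#' Runs the shrinkage LDA next to standard baselines (multinomial
#' logistic regression, ridge-penalised multinomial regression, random
#' forest, naive Bayes) under one shared stratified fold assignment and
#' reports the pooled out-of-fold metric suite per model. Only the LDA is
#' this package's own implementation; baselines are delegated to their
#' canonical packages.
#'
#' @param x Feature data frame / matrix.
#' @param y Class labels.
#' @param folds Number of folds (default 10).
#' @param seed Optional integer seed (folds and forest).
#' @param models Subset of
#'   `c("lda", "logistic", "ridge", "random_forest", "naive_bayes")`.
#' @return A tibble with one row per model: `model`, `accuracy`, `auc`
#'   (macro one-vs-rest), `recall`, `precision`, `f1`, `kappa`, `mcc`.
#' @export
compare_classifiers <- function(x, y, folds = 10, seed = NULL,
                                models = c("lda", "logistic", "ridge",
                                           "random_forest", "naive_bayes")) {
  y <- factor(y)
  X <- .feature_matrix(x)
  labels <- levels(y)
  fold_id <- .run_seeded(seed, function() .stratified_folds(y, folds))
  rf_seed <- if (is.null(seed)) 1L else as.integer(seed)

  fitters <- list(
    lda = function(Xtr, ytr, Xte) {
      fit <- fit_lda(Xtr, ytr, shrinkage = "auto")
      pr <- predict(fit, Xte)
      list(pred = as.character(pr$label),
           post = as.matrix(pr[paste0(".prob_", labels)]))
    },
    logistic = function(Xtr, ytr, Xte) {
      d <- data.frame(Xtr)
      d$.y <- ytr
      fit <- nnet::multinom(.y ~ ., data = d, trace = FALSE, maxit = 300)
      p <- predict(fit, newdata = data.frame(Xte), type = "probs")
      if (is.null(dim(p))) p <- cbind(1 - p, p)
      colnames(p) <- labels
      list(pred = labels[max.col(p, ties.method = "first")], post = p)
    },
    ridge = function(Xtr, ytr, Xte) {
      fit <- glmnet::glmnet(Xtr, ytr, family = "multinomial", alpha = 0,
                            lambda = 0.01)
      p <- predict(fit, newx = Xte, type = "response")[, , 1]
      if (is.null(dim(p))) p <- matrix(p, nrow = 1, dimnames = list(NULL, names(p)))
      p <- p[, labels, drop = FALSE]
      list(pred = labels[max.col(p, ties.method = "first")], post = p)
    },
    random_forest = function(Xtr, ytr, Xte) {
      d <- data.frame(Xtr)
      d$.y <- ytr
      fit <- ranger::ranger(.y ~ ., data = d, probability = TRUE,
                            num.trees = 300, seed = rf_seed)
      p <- predict(fit, data = data.frame(Xte))$predictions
      p <- p[, labels, drop = FALSE]
      list(pred = labels[max.col(p, ties.method = "first")], post = p)
    },
    naive_bayes = function(Xtr, ytr, Xte) {
      fit <- e1071::naiveBayes(Xtr, ytr)
      p <- predict(fit, Xte, type = "raw")
      p <- p[, labels, drop = FALSE]
      list(pred = labels[max.col(p, ties.method = "first")], post = p)
    }
  )

  rows <- lapply(models, function(mname) {
    fitter <- fitters[[mname]]
    pred <- character(length(y))
    post <- matrix(NA_real_, length(y), length(labels),
                   dimnames = list(NULL, labels))
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      out <- fitter(X[tr, , drop = FALSE], y[tr], X[!tr, , drop = FALSE])
      pred[!tr] <- out$pred
      post[!tr, ] <- out$post
    }
    rep <- compute_metrics(y, pred, posteriors = post, labels = labels)
    tibble(model = mname, accuracy = rep$accuracy,
           auc = mean(rep$per_class$auroc, na.rm = TRUE),
           recall = rep$recall_w, precision = rep$precision_w,
           f1 = rep$f1_w, kappa = rep$kappa, mcc = rep$mcc)
  })
  list_rbind(rows)
}
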