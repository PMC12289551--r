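#' Fit a shrinkage linear discriminant classifier
#'
#' Gaussian equal-covariance LDA on ancestry-profile features. Class
#' means are per-class sample means; the pooled within-class covariance
#' `S` is shrunk toward a scaled identity,
#' `Sigma = (1 - gamma) S + gamma (tr(S) / K) I`, with the intensity
#' `gamma` chosen by a Ledoit-Wolf estimator when `shrinkage = "auto"`.
#' Shrinkage guarantees an invertible covariance even when profiles are
#' sparse after thresholding (many exact zeros) or classes are small.
#' Discriminant scores are
#' `d_c(x) = x' Sigma^-1 mu_c - mu_c' Sigma^-1 mu_c / 2 + log pi_c` and
#' posteriors are the softmax over scores.
#'
#' @param x A data frame or matrix of numeric features, one row per
#'   individual (non-numeric columns such as `sample` are dropped with a
#'   record kept for prediction).
#' @param y Class labels (factor or character), one per row of `x`.
#' @param shrinkage `"auto"` for the Ledoit-Wolf intensity, or a fixed
#'   value in `[0, 1]` (`0` is classical LDA and errors on singular
#'   covariance).
#' @param priors `"empirical"` for class frequencies, or a numeric vector
#'   of prior probabilities named by class.
#' @param tol Numerical tolerance: the smallest acceptable eigenvalue of
#'   the (shrunk) covariance relative to the largest. Default `1e-4`.
#' @return An object of class `shrinkage_lda`.
#' @export
fit_lda <- function(x, y, shrinkage = "auto", priors = "empirical",
                    tol = 1e-4) {
  X <- .feature_matrix(x)
  y <- factor(y)
  labels <- levels(y)
  C <- length(labels)
  n <- nrow(X)
  p <- ncol(X)
  if (n != length(y)) abort("x and y lengths differ")
  if (n < C + 1) abort("need at least C + 1 observations")
  cnt <- table(y)
  if (any(cnt < 2)) {
    abort(paste0("every class needs >= 2 members; too small: ",
                 paste(names(cnt)[cnt < 2], collapse = ", ")))
  }

  means <- do.call(rbind, lapply(labels, function(cl) {
    colMeans(X[y == cl, , drop = FALSE])
  }))
  rownames(means) <- labels
  Xc <- X - means[as.integer(y), , drop = FALSE]
  S <- crossprod(Xc) / (n - C)

  gamma <- if (identical(shrinkage, "auto")) {
    .ledoit_wolf_gamma(Xc)
  } else {
    g <- as.numeric(shrinkage)
    if (is.na(g) || g < 0 || g > 1) abort("shrinkage must be 'auto' or in [0, 1]")
    g
  }
  mu_tr <- sum(diag(S)) / p
  if (gamma > 0 && mu_tr <= .Machine$double.eps) {
    # classes are internally constant: fall back to the total scatter so
    # the shrunk covariance is still a positive multiple of the identity
    # (the classifier degrades to nearest class mean)
    tot <- scale(X, center = TRUE, scale = FALSE)
    mu_tr <- sum(tot^2) / (max(n - 1, 1) * p)
    if (mu_tr <= .Machine$double.eps) mu_tr <- 1
  }
  Sigma <- (1 - gamma) * S + gamma * mu_tr * diag(p)

  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (max(ev) <= 0 || min(ev) <= tol * max(ev)) {
    abort(paste0("covariance is numerically singular (relative eigenvalue ",
                 format(min(ev) / max(ev), digits = 3),
                 " <= tol); increase shrinkage"))
  }
  Sigma_inv <- chol2inv(chol(Sigma))

  pri <- if (identical(priors, "empirical")) {
    as.numeric(cnt) / n
  } else {
    pv <- as.numeric(priors[labels])
    if (anyNA(pv) || abs(sum(pv) - 1) > 1e-8) {
      abort("priors must be named by class and sum to 1")
    }
    pv
  }

  W <- Sigma_inv %*% t(means)                         # p x C
  b <- -0.5 * colSums(t(means) * W) + log(pri)        # length C

  structure(
    list(labels = labels, means = means, pooled_cov = Sigma,
         shrinkage = gamma, priors = setNames(pri, labels), tol = tol,
         features = colnames(X), coef = W, intercept = b, n = n),
    class = "shrinkage_lda"
  )
}

# Ledoit-Wolf intensity toward the scaled identity, computed on the
# within-class-centred observations
.ledoit_wolf_gamma <- function(Xc) {
  n <- nrow(Xc)
  p <- ncol(Xc)
  Sn <- crossprod(Xc) / n
  m <- sum(diag(Sn)) / p
  d2 <- sum((Sn - m * diag(p))^2) / p
  # S already (numerically) a multiple of the identity: shrinking toward
  # the target is a no-op direction, so take it fully
  if (d2 <= .Machine$double.eps) return(1)
  xx <- rowSums(Xc^2)
  b2bar <- (sum(xx^2) / n - sum(Sn^2)) / (n * p)
  b2 <- min(max(b2bar, 0), d2)
  b2 / d2
}

.feature_matrix <- function(x) {
  if (is.matrix(x)) {
    if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
    return(x)
  }
  x <- as.data.frame(x)
  num <- vapply(x, is.numeric, logical(1))
  drop <- intersect(names(x), c("loglik", "n_iter", "converged",
                                "applied_threshold"))
  keep <- setdiff(names(x)[num], drop)
  as.matrix(x[keep])
}

#' Predict continental groups from ancestry profiles
#'
#' @param object A fitted [fit_lda()] model.
#' @param newdata Data frame or matrix containing the model's feature
#'   columns; a `sample` column, if present, is carried through.
#' @param ... Unused.
#' @return A tibble with one row per observation: `sample` (when
#'   available), the predicted `label`, one posterior column per class
#'   (`.prob_<class>`), and `top1`/`top1_prob`/`top2`/`top2_prob`. Ties in
#'   posterior are broken by lexicographic class order.
#' @export
predict.shrinkage_lda <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) {
    missing <- setdiff(object$features, names(newdata))
    if (length(missing)) {
      abort(paste0("newdata lacks feature columns: ",
                   paste(missing, collapse = ", ")))
    }
    X <- as.matrix(as.data.frame(newdata)[object$features])
    smp <- if ("sample" %in% names(newdata)) newdata[["sample"]] else NULL
  } else {
    if (ncol(newdata) != length(object$features)) {
      abort("newdata has the wrong number of feature columns")
    }
    X <- newdata
    smp <- rownames(newdata)
  }
  scores <- X %*% object$coef +
    matrix(object$intercept, nrow(X), length(object$labels), byrow = TRUE)
  post <- exp(scores - apply(scores, 1, max))
  post <- post / rowSums(post)
  colnames(post) <- object$labels

  # argmax with lexicographic tie-break (labels are sorted factor levels)
  rank2 <- t(apply(post, 1, function(pr) order(-pr, object$labels)[1:2]))
  if (nrow(X) == 1) rank2 <- matrix(rank2, nrow = 1)

  out <- tibble(.rows = nrow(X))
  if (!is.null(smp)) out$sample <- smp
  out$label <- factor(object$labels[rank2[, 1]], levels = object$labels)
  for (cl in object$labels) out[[paste0(".prob_", cl)]] <- unname(post[, cl])
  out$top1 <- object$labels[rank2[, 1]]
  out$top1_prob <- post[cbind(seq_len(nrow(post)), rank2[, 1])]
  out$top2 <- object$labels[rank2[, 2]]
  out$top2_prob <- post[cbind(seq_len(nrow(post)), rank2[, 2])]
  out
}

#' @export
print.shrinkage_lda <- function(x, ...) {
  cat("Shrinkage LDA:", length(x$labels), "classes,",
      length(x$features), "features, n =", x$n, "\n")
  cat("shrinkage gamma =", format(x$shrinkage, digits = 4),
      " priors:", paste(sprintf("%s=%.3f", x$labels, x$priors),
                        collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.shrinkage_lda <- function(x, ...) {
  means <- as_tibble(x$means)
  means$class <- x$labels
  tidyr::pivot_longer(means, cols = -dplyr::all_of("class"),
                      names_to = "term", values_to = "mean")
}

#' @export
glance.shrinkage_lda <- function(x, ...) {
  tibble(n = x$n, n_classes = length(x$labels),
         n_features = length(x$features), shrinkage = x$shrinkage,
         tol = x$tol)
}

#' Serialize / restore a fitted LDA model as JSON
#'
#' @param model A `shrinkage_lda` object.
#' @param path Output (input) file path.
#' @return `write_lda_json()` returns `path` invisibly; `read_lda_json()`
#'   returns the restored model.
#' @export
write_lda_json <- function(model, path) {
  payload <- list(
    labels = model$labels, features = model$features,
    means = model$means, pooled_cov = model$pooled_cov,
    shrinkage = model$shrinkage, priors = as.numeric(model$priors),
    tol = model$tol, n = model$n
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_lda_json
#' @export
read_lda_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  means <- matrix(as.numeric(x$means), nrow = length(x$labels))
  colnames(means) <- x$features
  rownames(means) <- x$labels
  Sigma <- matrix(as.numeric(x$pooled_cov), nrow = length(x$features))
  Sigma_inv <- chol2inv(chol(Sigma))
  W <- Sigma_inv %*% t(means)
  b <- -0.5 * colSums(t(means) * W) + log(x$priors)
  structure(
    list(labels = x$labels, means = means, pooled_cov = Sigma,
         shrinkage = x$shrinkage, priors = setNames(x$priors, x$labels),
         tol = x$tol, features = x$features, coef = W, intercept = b,
         n = x$n),
    class = "shrinkage_lda"
  )
}
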