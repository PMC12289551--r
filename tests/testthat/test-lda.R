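test_that("two symmetric classes put the boundary at the midpoint", {
  withr::with_seed(1, {
    x <- matrix(c(rnorm(200, -1, 0.5), rnorm(200, 1, 0.5)), ncol = 1)
    colnames(x) <- "f"
    y <- rep(c("neg", "pos"), each = 200)
  })
  fit <- fit_lda(x, y, shrinkage = 0)
  pr <- predict(fit, matrix(c(0.5, -0.5), ncol = 1,
                            dimnames = list(NULL, "f")))
  expect_equal(as.character(pr$label), c("pos", "neg"))
})

test_that("full shrinkage reduces to nearest class mean under equal priors", {
  withr::with_seed(2, {
    x <- matrix(rnorm(300), ncol = 3)
    colnames(x) <- c("a", "b", "c")
    y <- rep(c("u", "v"), each = 50)
    x[y == "v", ] <- x[y == "v", ] + 2
  })
  fit <- fit_lda(x, y, shrinkage = 1, priors = c(u = 0.5, v = 0.5))
  expect_equal(fit$shrinkage, 1)
  pr <- predict(fit, x)
  d_u <- rowSums((x - matrix(fit$means["u", ], nrow(x), 3, byrow = TRUE))^2)
  d_v <- rowSums((x - matrix(fit$means["v", ], nrow(x), 3, byrow = TRUE))^2)
  expect_equal(as.character(pr$label), ifelse(d_u < d_v, "u", "v"))
})

test_that("unshrunk LDA posteriors match the classical reference", {
  skip_if_not_installed("MASS")
  withr::with_seed(3, {
    n <- 150
    x <- matrix(rnorm(3 * n * 2), ncol = 2)
    colnames(x) <- c("a", "b")
    y <- rep(c("A", "B", "C"), each = n)
    x[y == "B", 1] <- x[y == "B", 1] + 2.5
    x[y == "C", 2] <- x[y == "C", 2] + 2.5
  })
  ours <- fit_lda(x, y, shrinkage = 0)
  ref <- MASS::lda(x, grouping = y)
  post_ref <- predict(ref, x)$posterior
  post_ours <- as.matrix(predict(ours, x)[paste0(".prob_", c("A", "B", "C"))])
  expect_lt(max(abs(post_ours - post_ref)), 1e-6)
})

test_that("two-class Gaussian error rate matches the closed-form Bayes rate", {
  mu1 <- c(0, 0)
  mu2 <- c(1.2, 0.8)
  A <- matrix(c(1, 0.3, 0.3, 0.8), 2)  # shared covariance
  L <- chol(A)
  delta <- sqrt(mahalanobis(mu2, mu1, A))
  bayes <- pnorm(-delta / 2)
  withr::with_seed(4, {
    n <- 2000
    x1 <- matrix(rnorm(2 * n), ncol = 2) %*% L
    x2 <- sweep(matrix(rnorm(2 * n), ncol = 2) %*% L, 2, mu2 - mu1, "+")
    x <- rbind(x1, x2)
    colnames(x) <- c("a", "b")
    y <- rep(c("one", "two"), each = n)
    xt1 <- matrix(rnorm(2 * n), ncol = 2) %*% L
    xt2 <- sweep(matrix(rnorm(2 * n), ncol = 2) %*% L, 2, mu2 - mu1, "+")
    xt <- rbind(xt1, xt2)
    colnames(xt) <- c("a", "b")
  })
  fit <- fit_lda(x, y, shrinkage = 0)
  pr <- predict(fit, xt)
  err <- mean(as.character(pr$label) != y)
  expect_lt(abs(err - bayes), 0.02)
})

test_that("prediction at a class mean of a separated model is confident", {
  means <- rbind(a = c(10, 0), b = c(0, 10), c = c(-10, -10))
  withr::with_seed(5, {
    x <- means[rep(1:3, each = 30), ] + matrix(rnorm(180, sd = 0.5), ncol = 2)
    colnames(x) <- c("f1", "f2")
    y <- rep(c("a", "b", "c"), each = 30)
  })
  fit <- fit_lda(x, y)
  pr <- predict(fit, matrix(means["b", ], ncol = 2,
                            dimnames = list(NULL, c("f1", "f2"))))
  expect_equal(as.character(pr$label), "b")
  expect_gt(pr$.prob_b, 0.99)
  expect_gte(pr$top1_prob, pr$top2_prob)
})

test_that("exact posterior ties break lexicographically", {
  # identical class means and priors: posteriors are exactly 0.5/0.5
  x <- matrix(c(-1, 1, -1, 1), ncol = 1)
  colnames(x) <- "f"
  y <- c("zeta", "zeta", "alpha", "alpha")
  fit <- fit_lda(x, y, shrinkage = 1, priors = c(alpha = 0.5, zeta = 0.5))
  pr <- predict(fit, matrix(0, ncol = 1, dimnames = list(NULL, "f")))
  expect_equal(pr$.prob_alpha, 0.5)
  expect_equal(as.character(pr$label), "alpha")
  # posteriors always sum to one
  withr::with_seed(6, {
    xr <- matrix(rnorm(20), ncol = 1, dimnames = list(NULL, "f"))
  })
  prr <- predict(fit, xr)
  expect_equal(prr$.prob_alpha + prr$.prob_zeta, rep(1, 20))
})

test_that("degenerate inputs raise informative errors", {
  x <- matrix(rnorm(20), ncol = 2, dimnames = list(NULL, c("a", "b")))
  expect_error(fit_lda(x, rep(c("u", "v"), c(9, 1))), ">= 2 members")
  # perfectly collinear features are singular without shrinkage
  xc <- cbind(a = rnorm(20), b = 0)
  xc[, 2] <- xc[, 1]
  expect_error(fit_lda(xc, rep(c("u", "v"), each = 10), shrinkage = 0),
               "shrinkage")
  fit <- fit_lda(x, rep(c("u", "v"), each = 5))
  expect_error(predict(fit, matrix(1, ncol = 3)), "wrong number")
})

test_that("relabelling classes permutes predictions consistently", {
  withr::with_seed(7, {
    x <- matrix(rnorm(120), ncol = 2, dimnames = list(NULL, c("a", "b")))
    y <- rep(c("g1", "g2", "g3"), each = 20)
    x[y == "g2", ] <- x[y == "g2", ] + 3
    x[y == "g3", 1] <- x[y == "g3", 1] - 3
  })
  ren <- c(g1 = "zz", g2 = "mm", g3 = "aa")
  fit1 <- fit_lda(x, y)
  fit2 <- fit_lda(x, ren[y])
  p1 <- predict(fit1, x)
  p2 <- predict(fit2, x)
  expect_equal(as.character(p2$label), unname(ren[as.character(p1$label)]))
  expect_equal(p2$.prob_mm, p1$.prob_g2, tolerance = 1e-12)
})

test_that("JSON serialisation round-trips the model", {
  withr::with_seed(8, {
    x <- matrix(rnorm(120), ncol = 3,
                dimnames = list(NULL, c("a", "b", "c")))
    y <- rep(c("u", "v"), each = 20)
    x[y == "v", ] <- x[y == "v", ] + 1
  })
  fit <- fit_lda(x, y)
  path <- withr::local_tempfile(fileext = ".json")
  write_lda_json(fit, path)
  back <- read_lda_json(path)
  expect_equal(back$shrinkage, fit$shrinkage)
  p1 <- predict(fit, x)
  p2 <- predict(back, x)
  expect_equal(p2$.prob_u, p1$.prob_u, tolerance = 1e-12)
})

test_that("tidy and glance expose means and hyperparameters", {
  withr::with_seed(9, {
    x <- matrix(rnorm(80), ncol = 2, dimnames = list(NULL, c("a", "b")))
    y <- rep(c("u", "v"), each = 20)
  })
  fit <- fit_lda(x, y)
  td <- tidy(fit)
  expect_equal(nrow(td), 4)  # 2 classes x 2 features
  gl <- glance(fit)
  expect_equal(gl$n, 40)
  expect_true(gl$shrinkage >= 0 && gl$shrinkage <= 1)
})
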