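test_that("log-likelihood matches direct evaluation of the model sum", {
  # flat frequencies: f_j = 0.5 whatever q is
  P <- matrix(0.5, 2, 8)
  q <- c(0.3, 0.7)
  g <- c(0, 1, 2, 1, 0, 2, 1, 1)
  expect_equal(admixture_loglik(q, P, g), 16 * log(0.5))

  # K = 1 with frequencies equal to g / 2 at homozygous sites: every term
  # is log(1) up to the clamp
  g2 <- c(0, 2, 2, 0)
  P2 <- matrix(pmin(pmax(g2 / 2, 1e-6), 1 - 1e-6), 1, 4)
  expect_equal(admixture_loglik(1, P2, g2), 0, tolerance = 1e-4)

  # K = 2, M = 4 worked example against an independent scalar evaluation
  P3 <- rbind(rep(0.9, 4), rep(0.1, 4))
  q3 <- c(0.5, 0.5)
  g3 <- c(2, 2, 1, 1)
  f <- 0.5 * 0.9 + 0.5 * 0.1
  by_hand <- 2 * log(f) + 2 * log(f) +
    (log(f) + log(1 - f)) + (log(f) + log(1 - f))
  expect_equal(admixture_loglik(q3, P3, g3), by_hand)

  # missing sites are skipped
  g4 <- c(2, NA, 1, NA)
  expect_equal(admixture_loglik(q3, P3, g4),
               2 * log(f) + log(f) + log(1 - f))

  expect_error(admixture_loglik(c(1, 0), P3, c(1, 1)), "panel sites")
})

test_that("supervised EM finds the boundary optima of degenerate panels", {
  eps <- 1e-6
  P <- rbind(rep(1 - eps, 20), rep(eps, 20))
  gm <- tibble::tibble(chrom = "1", pos = 1:20 * 10L, id = NA_character_,
                       ref = "A", alt = "G", qual = 50)
  panel <- gm
  panel$pool1 <- P[1, ]
  panel$pool2 <- P[2, ]
  gm$all2 <- rep(2L, 20)
  gm$all1 <- rep(1L, 20)
  q <- fit_supervised_q(gm, panel)
  expect_equal(unlist(q[q$sample == "all2", c("pool1", "pool2")]),
               c(pool1 = 1, pool2 = 0), tolerance = 1e-3)
  # heterozygous everywhere: P(g = 1) = 2 f (1 - f) peaks at f = 0.5
  expect_equal(unlist(q[q$sample == "all1", c("pool1", "pool2")]),
               c(pool1 = 0.5, pool2 = 0.5), tolerance = 1e-2)
})

test_that("supervised EM agrees with the simplex grid-search oracle", {
  # worked K = 2, M = 4 instance
  P <- rbind(rep(0.9, 4), rep(0.1, 4))
  g <- c(2, 2, 1, 1)
  oracle <- grid_search_q(P, g)
  em <- admixclass:::.fit_q_em(g, P, tol = 1e-10, max_iter = 10000)
  expect_lt(max(abs(em$q - oracle$q)), 1e-3)
  expect_gte(em$loglik, oracle$loglik - 1e-6)

  # random instances at K in {2, 3}
  for (seed in 1:6) {
    K <- 2 + seed %% 2
    inst <- random_instance(K, 50, seed)
    oracle <- grid_search_q(inst$P, inst$g)
    em <- admixclass:::.fit_q_em(inst$g, inst$P, tol = 1e-10, max_iter = 10000)
    expect_lte(max(abs(em$q - oracle$q)), 0.01)
    expect_gte(em$loglik, oracle$loglik - 1e-6)
  }
})

test_that("EM log-likelihood traces never decrease", {
  for (seed in 1:20) {
    inst <- random_instance(2 + seed %% 3, 40, seed)
    em <- admixclass:::.fit_q_em(inst$g, inst$P)
    expect_true(all(diff(em$trace) >= -1e-8))
  }
})

test_that("component permutation of the panel permutes q identically", {
  sim <- small_sim(K = 3, M = 200, n_per_group = 4, seed = 21)
  q1 <- fit_supervised_q(sim$genotypes, sim$panel)
  perm_panel <- sim$panel[c("chrom", "pos", "id", "ref", "alt", "qual",
                            "pool3", "pool1", "pool2")]
  q2 <- fit_supervised_q(sim$genotypes, perm_panel)
  expect_equal(q2$pool1, q1$pool1, tolerance = 1e-9)
  expect_equal(q2$pool3, q1$pool3, tolerance = 1e-9)
})

test_that("masking uninformative sites leaves q essentially unchanged", {
  sim <- small_sim(K = 3, M = 400, n_per_group = 3, seed = 31)
  panel <- sim$panel
  # make the last 100 sites carry identical frequencies in every pool
  flat <- runif(100, 0.2, 0.8)
  for (k in c("pool1", "pool2", "pool3")) panel[[k]][301:400] <- flat
  cfg <- sim$cfg
  coh <- simulate_cohort(panel, cfg)
  gm_mask <- coh$genotypes
  for (s in geno_samples(gm_mask)) gm_mask[[s]][301:400] <- NA_integer_
  q_full <- fit_supervised_q(coh$genotypes, panel)
  q_mask <- fit_supervised_q(gm_mask, panel)
  comps <- attr(q_full, "components")
  expect_lt(max(abs(as.matrix(q_full[comps]) - as.matrix(q_mask[comps]))),
            0.02)
})

test_that("all-missing genotypes raise an error", {
  sim <- small_sim(K = 2, M = 20, n_per_group = 1, seed = 41)
  gm <- sim$genotypes
  gm[[geno_samples(gm)[1]]] <- NA_integer_
  expect_error(fit_supervised_q(gm, sim$panel), "missing")
})

test_that("unsupervised K = 1 reduces to the closed form", {
  sim <- small_sim(K = 2, M = 100, n_per_group = 5, seed = 51)
  fit <- fit_unsupervised(sim$genotypes, K = 1, seed = 1)
  expect_equal(fit$q$pool1, rep(1, 10))
  G <- t(as.matrix(sim$genotypes[geno_samples(sim$genotypes)]))
  expected <- pmin(pmax(colMeans(G) / 2, 1e-6), 1 - 1e-6)
  expect_equal(fit$p$pool1, unname(expected), tolerance = 1e-6)
})

test_that("unsupervised fit separates two differentiated populations", {
  sim <- small_sim(K = 2, M = 500, F = 0.3, n_per_group = 20, seed = 61)
  fit <- fit_unsupervised(sim$genotypes, K = 2, seed = 3, max_iter = 300)
  expect_true(all(diff(fit$loglik_trace) >= -1e-8))
  qm <- as.matrix(fit$q[c("pool1", "pool2")])
  truth <- sim$truth$group
  # best label permutation (K = 2: identity or swap)
  acc1 <- mean((qm[, 1] > 0.5) == (truth == "pool1"))
  acc2 <- mean((qm[, 2] > 0.5) == (truth == "pool1"))
  expect_gte(max(acc1, acc2), 0.95)
  expect_gte(mean(apply(qm, 1, max)), 0.9)
})

test_that("unsupervised traces are monotone on random instances", {
  for (seed in 1:5) {
    gm <- random_gm(n_samples = 8, M = 60, seed = seed, missing_rate = 0.1)
    fit <- fit_unsupervised(gm, K = 2, seed = seed, max_iter = 60)
    expect_true(all(diff(fit$loglik_trace) >= -1e-8))
  }
  expect_error(fit_unsupervised(random_gm(3, 10, 1), K = 5), "exceeds")
})

test_that("synthetic reference individuals follow their pool frequencies", {
  # degenerate pool: all frequencies at the upper clamp -> all dosage 2
  panel <- tibble::tibble(chrom = "1", pos = 1:100 * 5L, id = NA_character_,
                          ref = "A", alt = "G", qual = 50,
                          pure = rep(1 - 1e-6, 100))
  syn <- generate_synthetic_individuals(panel, n_per_component = 3, seed = 2)
  expect_equal(nrow(syn$labels), 3)
  expect_true(all(as.matrix(syn$genotypes[syn$labels$sample]) == 2))

  # intermediate pool: mean dosage concentrates at 2p = 1
  panel$pure <- 0.5
  syn2 <- generate_synthetic_individuals(panel, n_per_component = 2, seed = 3)
  g <- as.matrix(syn2$genotypes[syn2$labels$sample])
  expect_equal(mean(g), 1, tolerance = 0.1)

  # reproducible per seed
  syn3 <- generate_synthetic_individuals(panel, n_per_component = 2, seed = 3)
  expect_identical(syn2$genotypes, syn3$genotypes)
})

test_that("supervised projection recovers the source pool of synthetic anchors", {
  sim <- small_sim(K = 3, M = 1000, F = 0.2, n_per_group = 1, seed = 71)
  syn <- generate_synthetic_individuals(sim$panel, n_per_component = 4,
                                        seed = 5)
  q <- fit_supervised_q(syn$genotypes, sim$panel)
  for (i in seq_len(nrow(q))) {
    k <- syn$labels$component[syn$labels$sample == q$sample[i]]
    expect_gte(q[[k]][i], 0.9)
  }
})
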