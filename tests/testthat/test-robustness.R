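test_that("down-sampling correlation is exactly 1 at the full size", {
  sim <- small_sim(K = 3, M = 250, n_per_group = 8, seed = 111)
  tab <- downsample_correlation_experiment(sim$genotypes, sim$panel,
                                           sizes = c(250, 50), seed = 1)
  full <- tab[tab$size == 250, ]
  expect_true(all(full$defined))
  expect_equal(full$r, rep(1, 3), tolerance = 1e-12)
  expect_true(all(full$p_value < 1e-12))
  expect_true(all(tab$r >= -1 & tab$r <= 1))
  expect_error(downsample_correlation_experiment(sim$genotypes, sim$panel,
                                                 sizes = 9999))
})

test_that("a constant component is flagged undefined, not silently dropped", {
  # single-pool panel: q is identically 1 for every sample
  sim <- small_sim(K = 1, M = 100, n_per_group = 6, seed = 121)
  tab <- downsample_correlation_experiment(sim$genotypes, sim$panel,
                                           sizes = c(50), seed = 2)
  expect_false(tab$defined[1])
  expect_true(is.na(tab$r[1]))
})

test_that("smaller subsets correlate less with the full estimate", {
  sim <- small_sim(K = 3, M = 1000, F = 0.1, n_per_group = 12, seed = 131)
  tab <- downsample_correlation_experiment(sim$genotypes, sim$panel,
                                           sizes = c(500, 25), seed = 3)
  r_hi <- mean(tab$r[tab$size == 500])
  r_lo <- mean(tab$r[tab$size == 25])
  expect_gt(r_hi, r_lo)
})

split_cohort <- function(gm) {
  vc <- c("chrom", "pos", "id", "ref", "alt", "qual")
  out <- lapply(geno_samples(gm), function(s) gm[c(vc, s)])
  names(out) <- geno_samples(gm)
  out
}

test_that("the union SNP list keeps the highest-QUAL duplicate", {
  base <- tibble::tibble(chrom = "1", pos = c(10L, 20L), id = NA_character_,
                         ref = "A", alt = "G", qual = c(50, 70))
  a <- base
  a$s_a <- c(1L, 2L)
  b <- base[1, ]
  b$qual <- 60
  b$s_b <- 0L
  u <- build_union_snp_list(list(s_a = a, s_b = b))
  expect_equal(nrow(u), 2)
  shared <- u[u$pos == 10, ]
  expect_equal(shared$qual, 60)
  expect_equal(shared$donor, "s_b")
  expect_equal(shared$donor_dosage, 0L)
})

test_that("disjoint site sets union to the sum of sizes; QUAL ties keep the first donor", {
  a <- tibble::tibble(chrom = "1", pos = c(1L, 2L), id = NA_character_,
                      ref = "A", alt = "G", qual = 50, sA = 1L)
  b <- tibble::tibble(chrom = "1", pos = c(3L, 4L), id = NA_character_,
                      ref = "A", alt = "G", qual = 50, sB = 2L)
  expect_equal(nrow(build_union_snp_list(list(sA = a, sB = b))), 4)
  b2 <- a
  names(b2)[7] <- "sB"
  b2$sB <- 0L
  u <- build_union_snp_list(list(sA = a, sB = b2))
  expect_equal(u$donor, c("sA", "sA"))
  expect_error(build_union_snp_list(list(sA = a)), "at least 2")
})

test_that("perturbation appends the exact per-chromosome count, never touching own sites", {
  gm <- random_gm(n_samples = 4, M = 1000, seed = 141, missing_rate = 0)
  gm$chrom <- "1"
  gm$pos <- seq_len(1000) * 7L
  cohort <- split_cohort(gm)
  union <- build_union_snp_list(cohort)
  target <- cohort[[1]]
  # make the sample miss 300 union sites so there is an eligible pool
  target <- target[1:700, ]
  pert <- perturb_sample(target, union, level = 0.05, seed = 9)
  expect_equal(nrow(pert), 700 + round(0.05 * 700))
  added <- setdiff(variant_key(pert), variant_key(target))
  expect_equal(length(added), 35)
  expect_true(all(!added %in% variant_key(target)))
  # original rows are present and unchanged
  orig <- pert[variant_key(pert) %in% variant_key(target), ]
  orig <- orig[order(orig$pos), ]
  expect_equal(as.data.frame(orig), as.data.frame(target[order(target$pos), ]),
               ignore_attr = TRUE)
  # deterministic per seed
  pert2 <- perturb_sample(target, union, level = 0.05, seed = 9)
  expect_identical(pert, pert2)
})

test_that("a zero-count perturbation level returns the input bit-exactly", {
  gm <- random_gm(n_samples = 3, M = 40, seed = 151, missing_rate = 0)
  cohort <- split_cohort(gm)
  union <- build_union_snp_list(cohort)
  tiny <- perturb_sample(cohort[[1]], union, level = 0.001, seed = 1)
  expect_identical(tiny, cohort[[1]])
})

test_that("an exhausted eligible pool warns and takes the whole pool", {
  gm <- random_gm(n_samples = 2, M = 20, seed = 161, missing_rate = 0)
  gm$chrom <- "1"
  cohort <- split_cohort(gm)
  union <- build_union_snp_list(cohort)
  # sample 1 already carries every union site -> pool empty
  expect_warning(out <- perturb_sample(cohort[[1]], union, level = 0.5,
                                       seed = 2),
                 "eligible pool")
  expect_equal(nrow(out), 20)
})

test_that("metric trajectories stay flat for well-separated groups", {
  sim <- small_sim(K = 3, M = 400, F = 0.3, n_per_group = 6, seed = 171)
  gm <- sim$genotypes
  cohort <- split_cohort(gm)
  withr::with_seed(21, {
    cohort <- lapply(cohort, function(x) x[sort(sample.int(nrow(x), 320)), ])
  })
  labels <- tibble::tibble(sample = names(cohort), group = sim$truth$group)
  q <- fit_supervised_q(gm, sim$panel)
  prof <- threshold_normalize(q)
  model <- fit_lda(prof[attr(prof, "components")], labels$group)
  sw <- suppressWarnings(
    perturbation_sweep_evaluate(cohort, labels, model, sim$panel,
                                levels = c(0.03, 0.06, 0.10), seed = 6)
  )
  expect_equal(sw$level, c("orig", "f0", "f1", "f2"))
  expect_equal(nrow(sw), 4)
  expect_true(all(c("accuracy", "f1_w", "auroc_ovr", "mcc", "kappa",
                    "precision_w", "recall_w") %in% names(sw)))
  lv <- sw[sw$level != "orig", ]
  expect_lte(max(lv$accuracy) - min(lv$accuracy), 0.05)
  expect_error(
    perturbation_sweep_evaluate(cohort, labels, model, sim$panel,
                                levels = c(0.2, 0.1)),
    "increasing")
})

test_that("averaging profiles yields midpoints with canonical pair labels", {
  profiles <- tibble::tibble(
    sample = c("x1", "x2", "y1"),
    A = c(1, 0, 0.5), B = c(0, 1, 0.5)
  )
  groups <- tibble::tibble(sample = c("x1", "x2", "y1"),
                           group = c("Africa", "Europe", "Africa"))
  pairs <- tibble::tibble(sample1 = c("x1", "x2", "x1"),
                          sample2 = c("x2", "x1", "x1"))
  adm <- make_synthetic_admixed(profiles, groups, pairs,
                                components = c("A", "B"))
  expect_equal(adm$A, c(0.5, 0.5, 1))
  expect_equal(adm$B, c(0.5, 0.5, 0))
  # unordered pair: both orders give the same canonical label
  expect_equal(adm$pair_label,
               c("Africa-Europe", "Africa-Europe", "Africa-Africa"))
  expect_equal(rowSums(adm[c("A", "B")]), rep(1, 3), ignore_attr = TRUE)
  bad <- pairs
  bad$sample1[1] <- "nope"
  expect_error(make_synthetic_admixed(profiles, groups, bad,
                                      components = c("A", "B")))
})

test_that("admixed classification reports confident calls and flags weak ones", {
  withr::with_seed(31, {
    # three synthetic pair categories in a 2-D component space
    mk <- function(center, n) {
      sweep(matrix(rnorm(2 * n, sd = 0.02), ncol = 2), 2, center, "+")
    }
    X <- rbind(mk(c(1, 0), 30), mk(c(0, 1), 30), mk(c(0.5, 0.5), 30))
    colnames(X) <- c("A", "B")
    y <- rep(c("Africa-Africa", "Europe-Europe", "Africa-Europe"), each = 30)
  })
  model <- fit_lda(X, y)
  adm <- tibble::tibble(sample = c("h1", "m1"),
                        A = c(1, 0.5), B = c(0, 0.5),
                        pair_label = c("Africa-Africa", "Africa-Europe"))
  rep_ <- admixture_classification_report(adm, model)
  expect_equal(rep_$accuracy, 1)
  # homogeneous sample at its class mean: near-certain top-1
  h <- rep_$calls[rep_$calls$sample == "h1", ]
  expect_gt(h$top1_prob, 0.99)
  expect_true(all(rep_$calls$top1_prob + rep_$calls$top2_prob <= 1 + 1e-9))
  expect_equal(glance(rep_)$n, 2)
})
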