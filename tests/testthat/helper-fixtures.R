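# fixtures are built in code at test time; nothing binary is shipped

# a small differentiated panel + labelled cohort
small_sim <- function(K = 3, M = 300, F = 0.2, n_per_group = 10, seed = 7,
                      ...) {
  cfg <- sim_config(K = K, M = M, F = F, n_per_group = n_per_group,
                    seed = seed, ...)
  panel <- simulate_panel(cfg)
  cohort <- simulate_cohort(panel, cfg)
  list(cfg = cfg, panel = panel, genotypes = cohort$genotypes,
       truth = cohort$truth)
}

# a hand-written five-record toy VCF: one multi-allelic, one low-QUAL,
# one non-PASS, two records that pass everything
write_toy_vcf <- function(path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", sep = "\t"),
    paste("1", "100", ".", "A", "C,T", "90", "PASS", ".", "GT", "0/1", "1/1", sep = "\t"),
    paste("1", "200", "rs1", "G", "T", "30", "PASS", ".", "GT", "0/0", "0/1", sep = "\t"),
    paste("1", "300", ".", "C", "G", "80", "LowQual", ".", "GT", "1/1", "0/0", sep = "\t"),
    paste("1", "400", "rs2", "T", "A", "55", "PASS", ".", "GT", "0/1", "./.", sep = "\t"),
    paste("2", "150", ".", "A", "G", "40", "PASS", ".", "GT", "1/1", "0|1", sep = "\t")
  )
  writeLines(lines, path)
  path
}

# a random genotype tibble without any simulation structure
random_gm <- function(n_samples = 10, M = 50, seed = 1,
                      missing_rate = 0.05) {
  withr::with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, M, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
    gm <- tibble::tibble(
      chrom = as.character(rep_len(1:2, M)),
      pos = as.integer(seq_len(M) * 10L),
      id = NA_character_,
      ref = unname(ref), alt = unname(alt),
      qual = round(runif(M, 40, 99), 1)
    )
    for (s in paste0("smp", seq_len(n_samples))) {
      g <- sample(0:2, M, replace = TRUE)
      g[runif(M) < missing_rate] <- NA_integer_
      gm[[s]] <- g
    }
    gm
  })
}

# --- independent oracle: exhaustive simplex grid search -------------------
# The admixture log-likelihood is concave in q (log of an affine function
# of q), so a coarse global grid plus a fine local grid around the coarse
# optimum finds the global maximiser to fine-grid resolution.

loglik_direct <- function(q, P, g) {
  obs <- !is.na(g)
  f <- pmin(pmax(as.numeric(q %*% P[, obs, drop = FALSE]), 1e-6), 1 - 1e-6)
  sum(g[obs] * log(f) + (2 - g[obs]) * log1p(-f))
}

# all simplex grid points with resolution `step` (K = 2 or 3)
simplex_grid <- function(K, step) {
  s <- seq(0, 1, by = step)
  if (K == 2) {
    cbind(s, 1 - s)
  } else if (K == 3) {
    grid <- expand.grid(q1 = s, q2 = s)
    grid <- grid[grid$q1 + grid$q2 <= 1 + 1e-12, ]
    cbind(grid$q1, grid$q2, pmax(1 - grid$q1 - grid$q2, 0))
  } else {
    stop("oracle supports K in {2, 3}")
  }
}

grid_best <- function(qs, P, g) {
  obs <- !is.na(g)
  Po <- P[, obs, drop = FALSE]
  go <- g[obs]
  f <- qs %*% Po
  f <- pmin(pmax(f, 1e-6), 1 - 1e-6)
  ll <- as.numeric(log(f) %*% go + log1p(-f) %*% (2 - go))
  list(q = qs[which.max(ll), ], loglik = max(ll))
}

grid_search_q <- function(P, g, coarse = 0.01, fine = 1e-3) {
  K <- nrow(P)
  best <- grid_best(simplex_grid(K, coarse), P, g)
  lo <- pmax(best$q - 2 * coarse, 0)
  hi <- pmin(best$q + 2 * coarse, 1)
  s <- seq(0, 1, by = fine)
  if (K == 2) {
    s1 <- s[s >= lo[1] & s <= hi[1]]
    qs <- cbind(s1, 1 - s1)
  } else {
    g1 <- s[s >= lo[1] & s <= hi[1]]
    g2 <- s[s >= lo[2] & s <= hi[2]]
    grid <- expand.grid(q1 = g1, q2 = g2)
    grid <- grid[grid$q1 + grid$q2 <= 1 + 1e-12, ]
    qs <- cbind(grid$q1, grid$q2, pmax(1 - grid$q1 - grid$q2, 0))
  }
  grid_best(qs, P, g)
}

# random supervised instance for the oracle comparisons
random_instance <- function(K, M, seed) {
  withr::with_seed(seed, {
    P <- matrix(runif(K * M, 0.05, 0.95), nrow = K)
    q_true <- as.numeric(rgamma(K, 1))
    q_true <- q_true / sum(q_true)
    f <- as.numeric(q_true %*% P)
    g <- rbinom(M, 2, f)
    list(P = P, g = g, q_true = q_true)
  })
}

expect_simplex <- function(x, tol = 1e-9) {
  expect_true(all(x >= -tol))
  expect_equal(sum(x), 1, tolerance = tol)
}
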