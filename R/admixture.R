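#' Admixture log-likelihood of one individual
#'
#' For an individual with admixture proportions `q` over K gene pools with
#' allele frequencies `p`, the expected alternate-allele frequency at site
#' j is `f_j = sum_k q_k p_kj`, and each observed diploid dosage `g_j`
#' contributes `g_j * log(f_j) + (2 - g_j) * log(1 - f_j)`. Missing sites
#' are skipped. The binomial coefficient `choose(2, g)` is constant in the
#' parameters and omitted, so traces are comparable across fits but not
#' with tools that include it.
#'
#' @param q Numeric vector of K proportions on the simplex.
#' @param p A panel tibble or a K x M frequency matrix.
#' @param g Numeric vector of M dosages in `{0, 1, 2}` with `NA` for
#'   missing sites, in the same variant order as `p`.
#' @return The log-likelihood (finite; frequencies are clamped).
#' @export
admixture_loglik <- function(q, p, g) {
  P <- .as_freq_matrix(p)
  if (length(q) != nrow(P)) abort("length(q) must equal the number of components")
  if (length(g) != ncol(P)) abort("length(g) must equal the number of panel sites")
  obs <- !is.na(g)
  if (!any(obs)) abort("all genotypes are missing")
  f <- .clamp(as.numeric(q %*% P[, obs, drop = FALSE]))
  sum(g[obs] * log(f) + (2 - g[obs]) * log1p(-f))
}

# one-individual EM on fixed frequencies P (K x M), dosage vector g
.fit_q_em <- function(g, P, tol = 1e-6, max_iter = 2000) {
  fit <- .fit_q_em_batch(matrix(g, nrow = 1), P, tol = tol,
                         max_iter = max_iter)
  list(q = fit$q[1, ], loglik = fit$loglik[1], trace = fit$traces[[1]],
       converged = fit$converged[1], n_iter = fit$n_iter[1])
}

# all individuals at once; the compiled loop carries the EM
.fit_q_em_batch <- function(G, P, tol = 1e-6, max_iter = 2000) {
  storage.mode(G) <- "double"
  storage.mode(P) <- "double"
  if (any(rowSums(!is.na(G)) == 0)) {
    abort(paste0("all genotypes missing for sample(s): ",
                 paste(rownames(G)[rowSums(!is.na(G)) == 0], collapse = ", ")))
  }
  .em_fit_q_cpp(G, .clamp(P), tol, as.integer(max_iter), .EPS)
}

#' Supervised admixture projection
#'
#' Estimates each individual's admixture proportions `q` by maximising the
#' admixture log-likelihood over the simplex with the gene-pool allele
#' frequencies held fixed (the supervised mode used to project new samples
#' onto an existing panel). The EM update is
#' `q_k <- q_k / (2 M_obs) * sum_j [ g_j p_kj / f_j +
#' (2 - g_j)(1 - p_kj) / (1 - f_j) ]`, iterated from a uniform start until
#' the log-likelihood improves by less than `tol`. Individuals are fitted
#' independently, so sample order never affects results.
#'
#' @param gm A genotype tibble whose variants are all present in `panel`
#'   (use [intersect_with_panel()] first when reading arbitrary VCFs).
#' @param panel A panel tibble.
#' @param tol Absolute log-likelihood improvement below which the EM
#'   stops. Default `1e-6`.
#' @param max_iter Maximum EM iterations per individual. Default 2000.
#' @return A tibble with one row per sample: `sample`, one proportion
#'   column per component, `loglik`, `n_iter`, `converged`. The attribute
#'   `"components"` names the component columns and `"traces"` holds the
#'   per-individual log-likelihood traces.
#' @export
fit_supervised_q <- function(gm, panel, tol = 1e-6, max_iter = 2000) {
  idx <- match(variant_key(gm), variant_key(panel))
  if (anyNA(idx)) {
    abort(paste0(sum(is.na(idx)), " genotype sites are absent from the ",
                 "panel; run intersect_with_panel() first"))
  }
  P <- .freq_matrix(panel)[, idx, drop = FALSE]
  G <- .dosage_matrix(gm)
  comps <- rownames(P)
  fit <- .fit_q_em_batch(G, P, tol = tol, max_iter = max_iter)
  out <- tibble(sample = rownames(G))
  for (j in seq_along(comps)) out[[comps[j]]] <- fit$q[, j]
  out$loglik <- fit$loglik
  out$n_iter <- fit$n_iter
  out$converged <- fit$converged
  attr(out, "components") <- comps
  attr(out, "traces") <- setNames(fit$traces, out$sample)
  out
}

#' Unsupervised admixture fit
#'
#' Jointly estimates admixture proportions Q and gene-pool allele
#' frequencies P for a cohort by alternating EM: the Q-step applies the
#' supervised update per individual with the current P, and the P-step
#' sets `p_kj <- sum_i a_ikj / (sum_i a_ikj + sum_i b_ikj)` where
#' `a_ikj = g_ij q_ik p_kj / f_ij` and
#' `b_ikj = (2 - g_ij) q_ik (1 - p_kj) / (1 - f_ij)`, both restricted to
#' observed genotypes. Q is initialised from flat Dirichlet draws and P
#' from jittered per-site observed frequencies; the total log-likelihood
#' is non-decreasing across iterations. Components are anonymous
#' (`pool1 ... poolK`): naming them after geography is a post-hoc, human
#' step done by inspecting population-mean profiles.
#'
#' @param gm A genotype tibble of the training cohort.
#' @param K Number of components; must not exceed the number of samples.
#' @param seed Integer seed for the random initialisation.
#' @param tol,max_iter Convergence settings (absolute log-likelihood
#'   improvement; default `1e-6`, 500 iterations).
#' @return An object of class `admixture_fit`: a list with `q` (tibble,
#'   one row per sample), `p` (panel tibble of the fitted frequencies),
#'   `loglik_trace`, `converged`, `n_iter`, `K`.
#' @export
fit_unsupervised <- function(gm, K, seed = NULL, tol = 1e-6, max_iter = 500) {
  G <- .dosage_matrix(gm)
  n <- nrow(G)
  m <- ncol(G)
  if (K > n) abort("K exceeds the number of individuals")
  obs <- !is.na(G)
  G0 <- ifelse(obs, G, 0)

  init <- .run_seeded(seed, function() {
    Q <- .rdirichlet(n, rep(1, K))
    site_freq <- colSums(G0) / (2 * colSums(obs))
    P <- matrix(rep(site_freq, each = K), nrow = K) +
      matrix(rnorm(K * m, sd = 0.05), nrow = K)
    list(Q = Q, P = .clamp(P))
  })
  Q <- init$Q
  P <- init$P
  mobs_i <- rowSums(obs)

  total_ll <- function(Q, P) {
    f <- .clamp(Q %*% P)
    sum((G0 * log(f) + (2 - G) * log1p(-f))[obs])
  }

  trace <- total_ll(Q, P)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    f <- .clamp(Q %*% P)
    U <- ifelse(obs, G / f, 0)            # g_ij / f_ij
    V <- ifelse(obs, (2 - G) / (1 - f), 0) # (2 - g_ij) / (1 - f_ij)
    # simultaneous M-step from the same responsibilities
    Qn <- Q * (U %*% t(P) + V %*% t(1 - P)) / (2 * mobs_i)
    Qn <- Qn / rowSums(Qn)
    A <- P * t(crossprod(U, Q))           # K x M: sum_i a_ikj
    B <- (1 - P) * t(crossprod(V, Q))     # K x M: sum_i b_ikj
    Pn <- .clamp(A / (A + B))
    Q <- Qn
    P <- Pn
    cur <- total_ll(Q, P)
    trace <- c(trace, cur)
    if (abs(cur - trace[length(trace) - 1]) < tol) {
      converged <- TRUE
      break
    }
  }

  comps <- paste0("pool", seq_len(K))
  qt <- tibble(sample = rownames(G))
  for (j in seq_len(K)) qt[[comps[j]]] <- unname(Q[, j])
  attr(qt, "components") <- comps
  pt <- gm[intersect(.variant_cols, names(gm))]
  for (j in seq_len(K)) pt[[comps[j]]] <- unname(P[j, ])
  structure(
    list(q = qt, p = as_tibble(pt), loglik_trace = trace,
         converged = converged, n_iter = iter, K = K),
    class = "admixture_fit"
  )
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat("Unsupervised admixture fit: K =", x$K, ", n =", nrow(x$q),
      ", M =", nrow(x$p), "\n")
  cat("log-likelihood", format(x$loglik_trace[length(x$loglik_trace)]),
      "after", x$n_iter, "iterations",
      if (x$converged) "(converged)" else "(not converged)", "\n")
  invisible(x)
}

#' @export
tidy.admixture_fit <- function(x, ...) {
  tidyr::pivot_longer(x$q, cols = dplyr::all_of(attr(x$q, "components")),
                      names_to = "component", values_to = "proportion")
}

#' @export
glance.admixture_fit <- function(x, ...) {
  tibble(K = x$K, n = nrow(x$q), m = nrow(x$p),
         loglik = x$loglik_trace[length(x$loglik_trace)],
         n_iter = x$n_iter, converged = x$converged)
}

#' Generate pure-ancestry synthetic reference individuals
#'
#' Draws, for every gene-pool component, `n_per_component` synthetic
#' diploid individuals whose dosage at each site is
#' `Binomial(2, p_kj)` — the in-silico anchors that make supervised
#' projection possible without shipping reference genotypes.
#'
#' @param panel A panel tibble.
#' @param n_per_component Synthetic individuals per component (default 15).
#' @param seed Optional integer seed.
#' @return A list with `genotypes` (genotype tibble; samples named
#'   `<component>_syn<i>`) and `labels` (tibble `sample`, `component`).
#' @export
generate_synthetic_individuals <- function(panel, n_per_component = 15,
                                           seed = NULL) {
  P <- .freq_matrix(panel)
  comps <- rownames(P)
  m <- ncol(P)
  .run_seeded(seed, function() {
    gm <- panel[intersect(.variant_cols, names(panel))]
    if (all(is.na(gm$qual))) gm$qual <- round(runif(m, 40, 99), 1)
    labels <- list()
    for (k in comps) {
      for (i in seq_len(n_per_component)) {
        nm <- sprintf("%s_syn%02d", gsub("[^A-Za-z0-9]", "_", k), i)
        gm[[nm]] <- rbinom(m, 2, P[k, ])
        labels[[nm]] <- k
      }
    }
    list(genotypes = as_tibble(gm),
         labels = tibble(sample = names(labels),
                         component = unlist(labels, use.names = FALSE)))
  })
}
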