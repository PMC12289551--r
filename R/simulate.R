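#' Simulation settings for synthetic cohorts
#'
#' Bundles the parameters of the Balding-Nichols style generator that
#' stands in for real reference data: `K` differentiated gene pools, `M`
#' SNPs, differentiation `F`, cohort size per group, optional Dirichlet
#' admixture and missingness, and a single seed from which all
#' randomness flows.
#'
#' @param K Number of gene pools (default 5).
#' @param M Number of SNPs (default 2000).
#' @param F Differentiation parameter in `(0, 1)` (default 0.15).
#' @param n_per_group Individuals per group (default 40).
#' @param alpha `NULL` for vertex truth (each individual drawn purely
#'   from its own pool), or `c(self =, other =)` Dirichlet concentrations
#'   for admixed truth.
#' @param missing_rate Fraction of genotypes masked as missing, in
#'   `[0, 1)` (default 0).
#' @param seed Integer seed (default 1).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(K = 5, M = 2000, F = 0.15, n_per_group = 40,
                       alpha = NULL, missing_rate = 0, seed = 1) {
  stopifnot(K >= 1, M >= 1, n_per_group >= 1)
  if (!(F > 0 && F < 1)) abort("F must be in (0, 1)")
  if (!(missing_rate >= 0 && missing_rate < 1)) abort("missing_rate must be in [0, 1)")
  if (!is.null(alpha) && !all(c("self", "other") %in% names(alpha))) {
    abort("alpha must be NULL or c(self =, other =)")
  }
  structure(list(K = K, M = M, F = F, n_per_group = n_per_group,
                 alpha = alpha, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a differentiated gene-pool panel
#'
#' Balding-Nichols frequencies: an ancestral frequency
#' `p0_j ~ Uniform(0.05, 0.95)` per site, and per gene pool
#' `p_kj ~ Beta(p0_j (1 - F) / F, (1 - p0_j)(1 - F) / F)`, so
#' `E[p_kj] = p0_j` and `Var[p_kj] = p0_j (1 - p0_j) F`. Sites are laid
#' out round-robin over 22 autosomes with distinct ref/alt bases.
#'
#' @param cfg A [sim_config()].
#' @return A panel tibble with components `pool1 ... poolK`; the
#'   ancestral frequencies are kept in attribute `"p0"`.
#' @export
simulate_panel <- function(cfg) {
  withr::with_seed(cfg$seed, {
    m <- cfg$M
    p0 <- runif(m, 0.05, 0.95)
    shape_scale <- (1 - cfg$F) / cfg$F
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, m, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
    chrom <- as.character(rep_len(1:22, m))
    panel <- tibble(
      chrom = chrom,
      pos = as.integer(seq_len(m) * 101L),
      id = sprintf("v%06d", seq_len(m)),
      ref = unname(ref), alt = unname(alt),
      qual = NA_real_
    )
    for (k in seq_len(cfg$K)) {
      panel[[paste0("pool", k)]] <-
        .clamp(rbeta(m, p0 * shape_scale, (1 - p0) * shape_scale))
    }
    attr(panel, "p0") <- p0
    panel
  })
}

#' Simulate a labelled cohort from a gene-pool panel
#'
#' For each gene pool k, draws `n_per_group` individuals with true
#' ancestry `q` at the vertex of pool k (or Dirichlet-concentrated on it
#' when `cfg$alpha` is set), then genotype dosages
#' `g_j ~ Binomial(2, sum_k q_k p_kj)` with optional missingness.
#' Synthetic QUAL values are drawn from `Uniform(40, 99)` so the
#' PASS/QUAL filters get exercised on emitted fixtures.
#'
#' @param panel A panel tibble (typically [simulate_panel()]).
#' @param cfg The matching [sim_config()].
#' @return A list with `genotypes` (genotype tibble) and `truth` (tibble
#'   `sample`, `group`, plus the true `q` per component).
#' @export
simulate_cohort <- function(panel, cfg) {
  comps <- .panel_components(panel)
  P <- .freq_matrix(panel)
  K <- length(comps)
  m <- ncol(P)
  withr::with_seed(cfg$seed + 1L, {
    gm <- panel[intersect(.variant_cols, names(panel))]
    attr(gm, "p0") <- NULL
    gm$qual <- round(runif(m, 40, 99), 1)
    truth <- list()
    for (k in seq_len(K)) {
      for (i in seq_len(cfg$n_per_group)) {
        nm <- sprintf("%s_ind%03d", comps[k], i)
        q <- if (is.null(cfg$alpha)) {
          as.numeric(seq_len(K) == k)
        } else {
          a <- rep(cfg$alpha[["other"]], K)
          a[k] <- cfg$alpha[["self"]]
          as.numeric(.rdirichlet(1, a))
        }
        f <- .clamp(as.numeric(q %*% P))
        g <- rbinom(m, 2, f)
        if (cfg$missing_rate > 0) {
          g[runif(m) < cfg$missing_rate] <- NA_integer_
        }
        gm[[nm]] <- g
        truth[[nm]] <- c(list(sample = nm, group = comps[k]),
                         setNames(as.list(q), comps))
      }
    }
    list(genotypes = as_tibble(gm),
         truth = list_rbind(lapply(truth, as_tibble)))
  })
}

#' Write a simulated cohort to disk as plain-text fixtures
#'
#' Emits the cohort VCF (via [write_vcf_genotypes()]), the truth table
#' and the panel as TSV, and a JSON manifest with the configuration and
#' seed so the fixture can be regenerated byte-identically. Optionally
#' appends records that deliberately fail the filters (multi-allelic,
#' low-QUAL, non-PASS) to exercise VCF filtering.
#'
#' @param gm Genotype tibble.
#' @param truth Truth tibble.
#' @param outdir Output directory (created if needed).
#' @param panel Optional panel tibble to write alongside.
#' @param cfg Optional [sim_config()] recorded in the manifest.
#' @param decoys Number of deliberately failing records to append to the
#'   VCF (default 0; cycled over the three failure modes).
#' @return Named character vector of the written paths, invisibly.
#' @export
emit_fixture <- function(gm, truth, outdir, panel = NULL, cfg = NULL,
                         decoys = 0) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  vcf <- file.path(outdir, "cohort.vcf")
  write_vcf_genotypes(gm, vcf)
  if (decoys > 0) .append_decoys(gm, vcf, decoys)
  truth_path <- file.path(outdir, "truth.tsv")
  readr::write_tsv(truth, truth_path)
  paths <- c(vcf = vcf, truth = truth_path)
  if (!is.null(panel)) {
    paths[["panel"]] <- file.path(outdir, "panel.tsv")
    write_panel(panel, paths[["panel"]])
  }
  manifest <- file.path(outdir, "manifest.json")
  jsonlite::write_json(
    list(config = if (is.null(cfg)) NULL else unclass(cfg),
         n_samples = length(geno_samples(gm)), n_variants = nrow(gm),
         decoys = decoys, files = as.list(paths)),
    manifest, auto_unbox = TRUE, digits = NA, null = "null")
  paths[["manifest"]] <- manifest
  invisible(paths)
}

# records guaranteed to be dropped by the default filters
.append_decoys <- function(gm, vcf, decoys) {
  smp <- geno_samples(gm)
  max_pos <- max(gm$pos)
  gts <- paste(rep("0/0", length(smp)), collapse = "\t")
  mk <- function(i, alt, qual, filter) {
    paste(c(gm$chrom[1], max_pos + i * 13L, ".", "A", alt, qual, filter, ".",
            "GT", gts), collapse = "\t")
  }
  types <- rep_len(c("multi", "lowqual", "fail"), decoys)
  lines <- vapply(seq_len(decoys), function(i) {
    switch(types[i],
           multi = mk(i, "C,T", "80", "PASS"),
           lowqual = mk(i, "C", "30", "PASS"),
           fail = mk(i, "C", "80", "LowQual"))
  }, character(1))
  cat(paste0(lines, "\n"), file = vcf, sep = "", append = TRUE)
}
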