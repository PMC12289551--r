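#' SNP down-sampling correlation study
#'
#' Re-estimates ancestry on random SNP subsets of decreasing size and
#' correlates, component by component, the subset estimates with the
#' full-set estimates across samples. Reports Pearson's r with the
#' Student's t p-value (`t = r * sqrt(n - 2) / sqrt(1 - r^2)`, n - 2 df).
#' A component that is constant across samples in either run has no
#' defined correlation and is flagged rather than silently dropped.
#'
#' @param gm A genotype tibble restricted to panel sites.
#' @param panel A panel tibble.
#' @param sizes Integer vector of SNP subset sizes (each `<=` the number
#'   of sites).
#' @param seed Optional integer seed for the subsampling.
#' @param tol,max_iter Passed to [fit_supervised_q()].
#' @return A tibble with one row per (size, component): `size`,
#'   `component`, `r`, `p_value`, `defined`.
#' @export
downsample_correlation_experiment <- function(gm, panel, sizes, seed = NULL,
                                              tol = 1e-6, max_iter = 2000) {
  m <- nrow(gm)
  if (any(sizes > m)) abort("a requested size exceeds the number of SNPs")
  q_full <- fit_supervised_q(gm, panel, tol = tol, max_iter = max_iter)
  comps <- attr(q_full, "components")
  n <- nrow(q_full)

  .run_seeded(seed, function() {
    rows <- lapply(sizes, function(sz) {
      sub <- subsample_snps(gm, sz)
      q_sub <- fit_supervised_q(sub, panel, tol = tol, max_iter = max_iter)
      list_rbind(lapply(comps, function(k) {
        a <- q_full[[k]]
        b <- q_sub[[k]]
        if (stats::sd(a) == 0 || stats::sd(b) == 0) {
          return(tibble(size = sz, component = k, r = NA_real_,
                        p_value = NA_real_, defined = FALSE))
        }
        r <- cor(a, b)
        p <- if (abs(r) >= 1) {
          0
        } else {
          tstat <- r * sqrt(n - 2) / sqrt(1 - r^2)
          2 * pt(-abs(tstat), df = n - 2)
        }
        tibble(size = sz, component = k, r = r, p_value = p, defined = TRUE)
      }))
    })
    list_rbind(rows)
  })
}

#' Build the union SNP list of a cohort
#'
#' Combines the variant sets of all samples into one list of unique
#' sites. When a site was called in several samples, the call with the
#' highest QUAL is retained (ties keep the first-encountered donor, in
#' cohort order). Each retained site carries the donor sample's genotype
#' and QUAL — the pool from which foreign SNPs are drawn during
#' perturbation.
#'
#' @param cohort A named list of single-sample genotype tibbles.
#' @return A tibble with columns `chrom, pos, id, ref, alt, qual, donor,
#'   donor_dosage`, sorted by chromosome and position.
#' @export
build_union_snp_list <- function(cohort) {
  if (length(cohort) < 2) abort("need a cohort of at least 2 samples")
  if (is.null(names(cohort))) names(cohort) <- paste0("sample", seq_along(cohort))
  all <- list_rbind(imap(cohort, function(gm, nm) {
    smp <- geno_samples(gm)
    if (length(smp) != 1) {
      abort(paste0("cohort entries must be single-sample tables; '", nm,
                   "' has ", length(smp)))
    }
    tibble(chrom = gm$chrom, pos = gm$pos, id = gm$id, ref = gm$ref,
           alt = gm$alt, qual = gm$qual, donor = nm,
           donor_dosage = gm[[smp]])
  }))
  # stable sort by descending QUAL keeps first-encountered donor on ties
  ord <- order(-ifelse(is.na(all$qual), -Inf, all$qual))
  all <- all[ord, ]
  all <- all[!duplicated(variant_key(all)), ]
  chrom_levels <- unique(all$chrom)
  all[order(match(all$chrom, chrom_levels), all$pos), ]
}

#' Inject foreign SNPs into one sample
#'
#' Per chromosome, draws `round(level * <sample's site count on that
#' chromosome>)` sites from the union list restricted to that chromosome,
#' excluding sites the sample already carries, and appends them with the
#' donor sample's genotype. Original sites are never removed or altered.
#' If the eligible pool is smaller than the requested count, the whole
#' pool is taken with a warning. A level whose rounded count is zero on
#' every chromosome returns the input unchanged.
#'
#' @param sample_gm A single-sample genotype tibble.
#' @param union The union list from [build_union_snp_list()].
#' @param level Perturbation fraction in `(0, 1)`.
#' @param seed Optional integer seed.
#' @return The perturbed genotype tibble, position-sorted per chromosome.
#' @export
perturb_sample <- function(sample_gm, union, level, seed = NULL) {
  smp <- geno_samples(sample_gm)
  if (length(smp) != 1) abort("perturb_sample() expects a single-sample table")
  own_keys <- variant_key(sample_gm)

  added <- .run_seeded(seed, function() {
    per_chrom <- lapply(unique(sample_gm$chrom), function(ch) {
      n_add <- .round_half_up(level * sum(sample_gm$chrom == ch))
      if (n_add == 0) return(NULL)
      pool <- union[union$chrom == ch & !(variant_key(union) %in% own_keys), ]
      if (nrow(pool) < n_add) {
        warn(paste0("chromosome ", ch, ": eligible pool (", nrow(pool),
                    ") smaller than requested ", n_add, " sites; taking all"))
        return(pool)
      }
      pool[sample.int(nrow(pool), n_add), ]
    })
    list_rbind(per_chrom[!vapply(per_chrom, is.null, logical(1))])
  })
  if (is.null(added) || nrow(added) == 0) return(sample_gm)

  new_rows <- tibble(chrom = added$chrom, pos = added$pos, id = added$id,
                     ref = added$ref, alt = added$alt, qual = added$qual)
  new_rows[[smp]] <- added$donor_dosage
  out <- dplyr::bind_rows(sample_gm, new_rows)
  chrom_levels <- unique(out$chrom)
  out[order(match(out$chrom, chrom_levels), out$pos), ]
}

#' Metric trajectories across the perturbation spectrum
#'
#' Runs the full inference chain (supervised projection, threshold
#' normalisation, classification) on the unperturbed cohort and on each
#' perturbation level, and tracks the multi-metric suite. Levels are
#' labelled `f0 ... f9` for the 1%-10% fractions; the unperturbed run is
#' reported separately as level `"orig"`.
#'
#' @param cohort A named list of single-sample genotype tibbles.
#' @param labels A tibble with columns `sample` and `group` (the truth).
#' @param model A fitted `shrinkage_lda` whose features are the panel's
#'   component names.
#' @param panel A panel tibble.
#' @param levels Perturbation fractions (default `seq(0.01, 0.10, 0.01)`).
#' @param seed Optional integer seed (drives all level draws).
#' @param tau,step Threshold-normalisation settings.
#' @param exclude_classes Optional class labels to drop from evaluation.
#' @return An object of class `perturbation_sweep`: a tibble with one row
#'   per level (`orig` first): `level`, `fraction`, `n`, `accuracy`,
#'   `precision_w`, `recall_w`, `f1_w`, `auroc_ovr`, `mcc`, `kappa`.
#' @export
perturbation_sweep_evaluate <- function(cohort, labels, model, panel,
                                        levels = seq(0.01, 0.10, by = 0.01),
                                        seed = NULL, tau = 0.1, step = 0.01,
                                        exclude_classes = NULL) {
  if (any(diff(levels) <= 0) || any(levels <= 0) || any(levels >= 1)) {
    abort("levels must be strictly increasing fractions in (0, 1)")
  }
  union <- build_union_snp_list(cohort)

  eval_cohort <- function(samples) {
    profs <- list_rbind(imap(samples, function(gm, nm) {
      sub <- intersect_with_panel(gm, panel)
      q <- fit_supervised_q(sub, panel)
      q$sample <- nm
      threshold_normalize(q, tau = tau, step = step)
    }))
    truth <- labels$group[match(profs$sample, labels$sample)]
    keep <- !(truth %in% (exclude_classes %||% character()))
    profs <- profs[keep, ]
    truth <- factor(truth[keep], levels = model$labels)
    pr <- predict(model, profs)
    rep <- compute_metrics(truth, pr$label,
                           posteriors = pr[paste0(".prob_", model$labels)],
                           labels = model$labels)
    g <- glance(rep)
    tibble(n = g$n, accuracy = g$accuracy, precision_w = g$precision_w,
           recall_w = g$recall_w, f1_w = g$f1_w, auroc_ovr = g$auroc_macro,
           mcc = g$mcc, kappa = g$kappa)
  }

  out <- .run_seeded(seed, function() {
    rows <- list(dplyr::bind_cols(tibble(level = "orig", fraction = 0),
                                  eval_cohort(cohort)))
    for (i in seq_along(levels)) {
      perturbed <- lapply(cohort, perturb_sample, union = union,
                          level = levels[i])
      rows[[i + 1]] <- dplyr::bind_cols(
        tibble(level = paste0("f", i - 1), fraction = levels[i]),
        eval_cohort(perturbed)
      )
    }
    list_rbind(rows)
  })
  class(out) <- c("perturbation_sweep", class(out))
  out
}

#' @export
autoplot.perturbation_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object)[c("level", "accuracy", "precision_w", "recall_w",
                        "f1_w", "auroc_ovr", "mcc", "kappa")],
    cols = -dplyr::all_of("level"), names_to = "metric", values_to = "value")
  long$level <- factor(long$level, levels = unique(object$level))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$level, y = .data$value,
                                     colour = .data$metric,
                                     group = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "perturbation level", y = "metric value")
}

#' Synthetic two-way admixed profiles
#'
#' Builds admixed individuals by averaging, component by component, the
#' ancestry profiles of paired source individuals. The label of each
#' admixed sample is the canonical (alphabetically sorted) pair of the
#' sources' group labels, e.g. `Africa-Europe`; homogeneous pairs
#' (`Europe-Europe`) are allowed. By construction the admixed profile
#' lies on the midpoint of the segment between its parents and still
#' sums to one.
#'
#' @param profiles A tibble of profiles with a `sample` column and one
#'   column per component.
#' @param groups A tibble with columns `sample` and `group` for the
#'   source individuals.
#' @param pairs A tibble with columns `sample1` and `sample2`.
#' @param components Optional component column names.
#' @return A tibble: `sample` (`<s1>_<s2>`), the averaged component
#'   columns, and `pair_label`.
#' @export
make_synthetic_admixed <- function(profiles, groups, pairs,
                                   components = NULL) {
  comps <- .component_cols(profiles, components)
  i1 <- match(pairs$sample1, profiles$sample)
  i2 <- match(pairs$sample2, profiles$sample)
  if (anyNA(i1) || anyNA(i2)) abort("a paired sample is missing from profiles")
  g1 <- groups$group[match(pairs$sample1, groups$sample)]
  g2 <- groups$group[match(pairs$sample2, groups$sample)]
  if (anyNA(g1) || anyNA(g2)) abort("a paired sample is missing from groups")

  v1 <- as.matrix(profiles[i1, comps])
  v2 <- as.matrix(profiles[i2, comps])
  out <- tibble(sample = paste(pairs$sample1, pairs$sample2, sep = "_"))
  avg <- (v1 + v2) / 2
  for (j in seq_along(comps)) out[[comps[j]]] <- avg[, j]
  out$pair_label <- canonical_pair(g1, g2)
  attr(out, "components") <- comps
  out
}

#' Canonical unordered pair label
#'
#' @param a,b Group label vectors.
#' @return `"<min>-<max>"` per element pair.
#' @export
canonical_pair <- function(a, b) {
  paste(pmin(as.character(a), as.character(b)),
        pmax(as.character(a), as.character(b)), sep = "-")
}

#' Draw random source pairs per admixed group
#'
#' Convenience sampler for the admixture study: for each requested pair
#' category, draws `n_per_group` random (distinct where possible) source
#' individuals from the two groups.
#'
#' @param groups A tibble with columns `sample` and `group`.
#' @param pair_labels Character vector like `"Africa-Europe"` (group
#'   names joined by `-`; both halves must exist in `groups`).
#' @param n_per_group Pairs to draw per category (default 10).
#' @param seed Optional integer seed.
#' @return A tibble with columns `sample1`, `sample2`.
#' @export
sample_admix_pairs <- function(groups, pair_labels, n_per_group = 10,
                               seed = NULL) {
  .run_seeded(seed, function() {
    rows <- lapply(pair_labels, function(lab) {
      gs <- strsplit(lab, "-", fixed = TRUE)[[1]]
      if (length(gs) != 2) abort(paste0("bad pair label: ", lab))
      s1 <- groups$sample[groups$group == gs[1]]
      s2 <- groups$sample[groups$group == gs[2]]
      if (!length(s1) || !length(s2)) {
        abort(paste0("no samples for a group in pair ", lab))
      }
      a <- sample(s1, n_per_group, replace = n_per_group > length(s1))
      b <- vapply(seq_len(n_per_group), function(i) {
        cand <- setdiff(s2, a[i])
        if (!length(cand)) s2[1] else sample(cand, 1)
      }, character(1))
      tibble(sample1 = a, sample2 = b)
    })
    list_rbind(rows)
  })
}

#' Classify synthetic admixed samples and report confidence
#'
#' Scores an admixed profile set with a model trained on pair-category
#' labels, reporting per-sample top-1 / top-2 labels and probabilities,
#' flagging low-confidence calls (top-1 posterior below `threshold`,
#' default 0.85), and summarising overall and per-category accuracy.
#'
#' @param admixed Output of [make_synthetic_admixed()] (needs
#'   `pair_label`).
#' @param model A `shrinkage_lda` trained on pair-category labels.
#' @param threshold Low-confidence flag threshold on the top-1
#'   posterior. Default 0.85.
#' @return An object of class `admix_report`: list with `calls` (per
#'   sample), `accuracy`, `per_group` (accuracy per true category) and
#'   `low_confidence` (the flagged subset of `calls`).
#' @export
admixture_classification_report <- function(admixed, model,
                                            threshold = 0.85) {
  pr <- predict(model, admixed)
  calls <- tibble(
    sample = admixed$sample,
    true = admixed$pair_label,
    predicted = as.character(pr$label),
    top1 = pr$top1, top1_prob = pr$top1_prob,
    top2 = pr$top2, top2_prob = pr$top2_prob,
    low_confidence = pr$top1_prob < threshold,
    correct = as.character(pr$label) == admixed$pair_label
  )
  per_group <- calls |>
    group_by(.data$true) |>
    summarise(n = dplyr::n(), accuracy = mean(.data$correct),
              .groups = "drop")
  structure(
    list(calls = calls, accuracy = mean(calls$correct),
         per_group = per_group,
         low_confidence = calls[calls$low_confidence, ],
         threshold = threshold),
    class = "admix_report"
  )
}

#' @export
print.admix_report <- function(x, ...) {
  cat(sprintf("Admixed classification: accuracy %.4f over %d samples (%d categories)\n",
              x$accuracy, nrow(x$calls), nrow(x$per_group)))
  cat(sprintf("%d low-confidence calls (top-1 < %.2f)\n",
              nrow(x$low_confidence), x$threshold))
  invisible(x)
}

#' @export
tidy.admix_report <- function(x, ...) x$calls

#' @export
glance.admix_report <- function(x, ...) {
  tibble(n = nrow(x$calls), accuracy = x$accuracy,
         n_low_confidence = nrow(x$low_confidence),
         threshold = x$threshold)
}
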