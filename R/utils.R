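# shared internal helpers

# columns that describe a variant rather than a sample / component
.variant_cols <- c("chrom", "pos", "id", "ref", "alt", "qual")

# frequencies are clamped into [EPS, 1 - EPS] so log terms stay finite
.EPS <- 1e-6

.clamp <- function(x, eps = .EPS) pmin(pmax(x, eps), 1 - eps)

# run `fn()` under a fixed seed when one is supplied, otherwise in the
# ambient RNG stream (so callers can seed a whole experiment once)
.run_seeded <- function(seed, fn) {
  if (is.null(seed)) fn() else withr::with_seed(as.integer(seed), fn())
}

#' Canonical variant key
#'
#' Builds the `chrom:pos:ref:alt` string used everywhere in the package to
#' match variants. Matching is exact: no strand flipping or ref/alt
#' swapping is ever attempted.
#'
#' @param x A data frame with `chrom`, `pos`, `ref`, `alt` columns.
#' @return Character vector of keys, one per row.
#' @export
variant_key <- function(x) {
  paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")
}

#' Sample columns of a genotype table
#'
#' A genotype table stores one row per variant: the columns
#' `chrom, pos, id, ref, alt, qual` describe the site and every remaining
#' column is one sample's alternate-allele dosage (0, 1, 2 or `NA`).
#'
#' @param gm A genotype tibble.
#' @return Character vector of sample names.
#' @export
geno_samples <- function(gm) {
  setdiff(names(gm), .variant_cols)
}

# samples x variants dosage matrix from a genotype tibble
.dosage_matrix <- function(gm) {
  smp <- geno_samples(gm)
  m <- t(as.matrix(gm[smp]))
  storage.mode(m) <- "double"
  rownames(m) <- smp
  colnames(m) <- variant_key(gm)
  m
}

# component (frequency) columns of a panel tibble
.panel_components <- function(panel) {
  setdiff(names(panel), .variant_cols)
}

# K x M frequency matrix from a panel tibble, clamped
.freq_matrix <- function(panel) {
  comps <- .panel_components(panel)
  m <- t(as.matrix(panel[comps]))
  storage.mode(m) <- "double"
  m <- .clamp(m)
  rownames(m) <- comps
  colnames(m) <- variant_key(panel)
  m
}

# accept either a panel tibble or an already-built K x M matrix
.as_freq_matrix <- function(p) {
  if (is.matrix(p)) .clamp(p) else .freq_matrix(p)
}

# columns of a profile/Q tibble that hold component proportions
.component_cols <- function(data, components = NULL) {
  if (!is.null(components)) return(components)
  comps <- attr(data, "components")
  if (!is.null(comps)) return(comps)
  reserved <- c("sample", "group", "label", "loglik", "n_iter", "converged",
                "applied_threshold", "pair_label", "fold")
  nm <- setdiff(names(data), reserved)
  nm[vapply(data[nm], is.numeric, logical(1))]
}

# Dirichlet draws, one row per observation
.rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  g / rowSums(g)
}

# round half up (used for perturbation site counts)
.round_half_up <- function(x) floor(x + 0.5)
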