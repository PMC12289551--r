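#' Read / write a gene-pool allele-frequency panel
#'
#' A panel holds, for each of K gene-pool components, the alternate-allele
#' frequency at each panel SNP. On disk it is a TSV with the variant
#' columns `chrom, pos, ref, alt` (optionally `id`) followed by one
#' frequency column per component. Frequencies are clamped into
#' `[1e-6, 1 - 1e-6]` on read so the admixture log-likelihood is always
#' finite.
#'
#' @param path File path.
#' @return A panel tibble.
#' @export
read_panel <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("chrom", "pos", "ref", "alt") %in% names(x))) {
    abort("panel TSV needs chrom, pos, ref, alt columns")
  }
  if (!"id" %in% names(x)) x$id <- NA_character_
  if (!"qual" %in% names(x)) x$qual <- NA_real_
  x$chrom <- as.character(x$chrom)
  x$pos <- as.integer(x$pos)
  comps <- setdiff(names(x), .variant_cols)
  if (length(comps) == 0) abort("panel has no component columns")
  for (k in comps) x[[k]] <- .clamp(as.numeric(x[[k]]))
  if (anyDuplicated(variant_key(x))) abort("panel has duplicate variants")
  as_tibble(x[c(.variant_cols, comps)])
}

#' @rdname read_panel
#' @param panel A panel tibble.
#' @export
write_panel <- function(panel, path) {
  readr::write_tsv(panel, path)
  invisible(path)
}

#' Read an ADMIXTURE-style P file
#'
#' Reads a whitespace-delimited allele-frequency file (one row per
#' variant, one column per component, no header) together with a variant
#' list giving the site coordinates, and assembles a panel tibble.
#'
#' @param p_path Path to the whitespace-delimited frequency file.
#' @param variants_path Path to a TSV with `chrom, pos, ref, alt` columns,
#'   one row per variant, in the same order as `p_path`.
#' @param components Optional component names; defaults to
#'   `pool1 ... poolK`.
#' @return A panel tibble.
#' @export
read_admixture_p <- function(p_path, variants_path, components = NULL) {
  p <- as.matrix(readr::read_table(p_path, col_names = FALSE,
                                   show_col_types = FALSE))
  v <- readr::read_tsv(variants_path, show_col_types = FALSE)
  if (nrow(p) != nrow(v)) {
    abort("frequency file and variant list have different row counts")
  }
  k <- ncol(p)
  components <- components %||% paste0("pool", seq_len(k))
  if (length(components) != k) abort("wrong number of component names")
  out <- tibble(
    chrom = as.character(v$chrom), pos = as.integer(v$pos),
    id = if ("id" %in% names(v)) as.character(v$id) else NA_character_,
    qual = NA_real_, ref = v$ref, alt = v$alt
  )[, c("chrom", "pos", "id", "ref", "alt", "qual")]
  for (j in seq_len(k)) out[[components[j]]] <- .clamp(as.numeric(p[, j]))
  out
}
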