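#' Read and filter SNP genotypes from a VCF file
#'
#' Parses a VCF (v4.x, plain or gzipped), keeps bi-allelic SNPs only, and
#' applies the quality filters used throughout the pipeline: records must
#' carry `FILTER == "PASS"` (when `require_pass`) and a `QUAL` of at least
#' `min_qual` (default 40). Genotypes are converted to alternate-allele
#' dosages: `0/0 -> 0`, `0/1 -> 1`, `1/1 -> 2`, anything incomplete
#' (`./.`, half-calls such as `./1`) becomes `NA`. Phased and unphased
#' calls are treated identically. Duplicate `(chrom, pos, ref, alt)`
#' records keep the copy with the highest `QUAL`.
#'
#' @param path Path to the VCF file.
#' @param min_qual Minimum `QUAL` to keep a record. Records with missing
#'   `QUAL` are dropped whenever `min_qual > 0`. Default 40.
#' @param require_pass Keep only records whose `FILTER` is exactly
#'   `"PASS"`. Default `TRUE`.
#' @return A genotype tibble: columns `chrom, pos, id, ref, alt, qual`
#'   plus one integer dosage column per sample. The attribute
#'   `"filter_stats"` records, per filter, how many records were dropped;
#'   retrieve it with [filter_stats()].
#' @seealso [write_vcf_genotypes()], [intersect_with_panel()]
#' @export
read_vcf_genotypes <- function(path, min_qual = 40, require_pass = TRUE) {
  if (!file.exists(path)) abort(paste0("VCF not found: ", path))
  v <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) abort(paste0("failed to parse VCF '", path, "': ",
                                     conditionMessage(e)))
  )
  fix <- vcfR::getFIX(v, getINFO = FALSE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  if (is.null(fix) || nrow(fix) == 0) {
    abort(paste0("no records in VCF: ", path), class = "admixclass_empty_result")
  }
  fix <- as_tibble(fix)
  n_read <- nrow(fix)
  qual <- suppressWarnings(as.numeric(fix$QUAL))

  bases <- c("A", "C", "G", "T")
  is_snp <- fix$REF %in% bases & fix$ALT %in% bases & fix$REF != fix$ALT
  drop_biallelic <- sum(!is_snp)

  qual_ok <- is_snp & (min_qual <= 0 | (!is.na(qual) & qual >= min_qual))
  drop_qual <- sum(is_snp) - sum(qual_ok)

  if (require_pass) {
    pass_ok <- qual_ok & !is.na(fix$FILTER) & fix$FILTER == "PASS"
  } else {
    pass_ok <- qual_ok
  }
  drop_pass <- sum(qual_ok) - sum(pass_ok)

  keep <- which(pass_ok)
  if (length(keep) == 0) {
    abort(paste0("no records in '", path, "' survive the filters ",
                 "(bi-allelic SNP, QUAL >= ", min_qual,
                 if (require_pass) ", FILTER == PASS" else "", ")"),
          class = "admixclass_empty_result")
  }

  # duplicate (chrom,pos,ref,alt): retain the highest-QUAL copy
  key <- variant_key(data.frame(chrom = fix$CHROM[keep],
                                pos = fix$POS[keep],
                                ref = fix$REF[keep],
                                alt = fix$ALT[keep]))
  ord <- order(-ifelse(is.na(qual[keep]), -Inf, qual[keep]))
  dup <- keep[ord][duplicated(key[ord])]
  drop_dup <- length(dup)
  keep <- setdiff(keep, dup)

  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) abort(paste0("VCF has no GT field: ", path))
  gt <- gt[keep, , drop = FALSE]
  dos <- apply(gt, 2, .gt_to_dosage)
  if (length(keep) == 1) dos <- matrix(dos, nrow = 1, dimnames = list(NULL, colnames(gt)))

  out <- tibble(
    chrom = fix$CHROM[keep],
    pos = as.integer(fix$POS[keep]),
    id = ifelse(fix$ID[keep] %in% c(".", ""), NA_character_, fix$ID[keep]),
    ref = fix$REF[keep],
    alt = fix$ALT[keep],
    qual = qual[keep]
  )
  for (s in colnames(dos)) out[[s]] <- unname(dos[, s])

  attr(out, "filter_stats") <- tibble(
    filter = c("read", "not_biallelic_snp", "low_qual", "not_pass",
               "duplicate_site", "kept"),
    records = c(n_read, drop_biallelic, drop_qual, drop_pass, drop_dup,
                nrow(out))
  )
  out
}

# GT strings -> dosage; anything that is not two called 0/1 alleles is NA
.gt_to_dosage <- function(g) {
  g <- sub(":.*$", "", g)
  out <- rep(NA_integer_, length(g))
  known <- !is.na(g)
  al <- strsplit(g[known], "[/|]")
  out[known] <- vapply(al, function(x) {
    if (length(x) != 2 || !all(x %in% c("0", "1"))) return(NA_integer_)
    sum(x == "1")
  }, integer(1))
  out
}

#' Per-filter drop counts of a genotype read
#'
#' @param gm A genotype tibble returned by [read_vcf_genotypes()].
#' @return A tibble with columns `filter` and `records`.
#' @export
filter_stats <- function(gm) attr(gm, "filter_stats")

#' Write a genotype table as a minimal VCF v4.2
#'
#' Emits a GT-only VCF that [read_vcf_genotypes()] reads back into the
#' identical table (all records are written with `FILTER = PASS`).
#' Missing dosages become `./.`.
#'
#' @param gm A genotype tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf_genotypes <- function(gm, path) {
  smp <- geno_samples(gm)
  if (length(smp) == 0) abort("genotype table has no sample columns")
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=admixclass",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", smp), collapse = "\t")
  )
  gt_code <- c("0/0", "0/1", "1/1")
  gt_cols <- lapply(smp, function(s) {
    d <- gm[[s]]
    ifelse(is.na(d), "./.", gt_code[d + 1])
  })
  qual <- ifelse(is.na(gm$qual), ".",
                 format(gm$qual, digits = 15, scientific = FALSE, trim = TRUE))
  body <- do.call(paste, c(
    list(gm$chrom, gm$pos, ifelse(is.na(gm$id), ".", gm$id), gm$ref, gm$alt,
         qual, "PASS", ".", "GT"),
    gt_cols, sep = "\t"
  ))
  con <- tryCatch(file(path, "w"),
                  error = function(e) abort(paste0("cannot write ", path)))
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}

#' Read / write the tabular genotype format
#'
#' The secondary exchange format: a TSV with columns
#' `chrom, pos, ref, alt` (optionally `id`, `qual`) followed by one dosage
#' column per sample.
#'
#' @param path File path.
#' @return `read_genotype_tsv()` returns a genotype tibble.
#' @export
read_genotype_tsv <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("chrom", "pos", "ref", "alt") %in% names(x))) {
    abort("genotype TSV needs chrom, pos, ref, alt columns")
  }
  if (!"id" %in% names(x)) x$id <- NA_character_
  if (!"qual" %in% names(x)) x$qual <- NA_real_
  x$id <- as.character(x$id)
  x$qual <- as.numeric(x$qual)
  x$chrom <- as.character(x$chrom)
  x$pos <- as.integer(x$pos)
  smp <- setdiff(names(x), .variant_cols)
  for (s in smp) x[[s]] <- as.integer(x[[s]])
  as_tibble(x[c(.variant_cols, smp)])
}

#' @rdname read_genotype_tsv
#' @param gm A genotype tibble.
#' @export
write_genotype_tsv <- function(gm, path) {
  readr::write_tsv(gm, path)
  invisible(path)
}

#' Restrict a genotype table to the reference-panel SNP set
#'
#' Keeps the variants present in both the genotype table and the panel, in
#' panel order. A variant matches only on identical
#' `(chrom, pos, ref, alt)`; a site with swapped ref/alt does not match.
#'
#' @param gm A genotype tibble.
#' @param panel A panel tibble (see [read_panel()]) or any data frame with
#'   `chrom, pos, ref, alt` columns.
#' @return The genotype sub-table in panel order, with attribute
#'   `"n_matched"` giving the overlap size.
#' @export
intersect_with_panel <- function(gm, panel) {
  if (nrow(gm) == 0 || nrow(panel) == 0) abort("empty input")
  idx <- match(variant_key(panel), variant_key(gm))
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0) {
    abort("no overlap between genotype sites and panel sites",
          class = "admixclass_empty_overlap")
  }
  out <- gm[idx, ]
  attr(out, "n_matched") <- length(idx)
  out
}

#' Randomly down-sample the SNPs of a genotype table
#'
#' Draws a uniform subset of variants without replacement, reproducibly
#' for a fixed seed, preserving the original relative variant order.
#'
#' @param gm A genotype tibble.
#' @param n_snps Number of SNPs to keep; must not exceed the number of
#'   variants.
#' @param seed Optional integer seed. `NULL` uses the ambient RNG stream.
#' @return The down-sampled genotype tibble.
#' @export
subsample_snps <- function(gm, n_snps, seed = NULL) {
  m <- nrow(gm)
  if (n_snps > m) abort(paste0("n_snps (", n_snps, ") exceeds available SNPs (", m, ")"))
  idx <- .run_seeded(seed, function() sort(sample.int(m, n_snps)))
  gm[idx, ]
}
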