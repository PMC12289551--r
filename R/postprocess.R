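#' Threshold-normalise ancestry proportions
#'
#' Zeroes every component strictly below the threshold `tau` (a value
#' exactly at the threshold survives) and renormalises the survivors to
#' sum to one. If *all* components fall below `tau`, the threshold is
#' lowered by `step` and the rule re-applied, repeatedly, until at least
#' one component survives; the threshold actually applied is recorded so
#' the adaptive rule is auditable per sample. The threshold never drops
#' below `step`; in the degenerate case where nothing survives even
#' there, the maximal component(s) are kept. The operation is idempotent.
#'
#' @param q Either a numeric ancestry vector or a tibble of ancestry
#'   vectors (e.g. the output of [fit_supervised_q()]) with one component
#'   column per gene pool.
#' @param tau Initial threshold, in `(0, 0.1]`. Default 0.1.
#' @param step Fallback decrement, `0 < step <= tau`. Default 0.01.
#' @param components For the data-frame method: names of the component
#'   columns. Defaults to the `"components"` attribute, else every
#'   numeric column not reserved for metadata.
#' @return For a vector: the normalised vector with attribute
#'   `"applied_threshold"`. For a data frame: a tibble with the component
#'   columns replaced and an `applied_threshold` column appended.
#' @export
threshold_normalize <- function(q, tau = 0.1, step = 0.01, components = NULL) {
  if (!(step > 0 && step <= tau && tau <= 0.1 + 1e-12)) {
    abort("need 0 < step <= tau <= 0.1")
  }
  if (is.numeric(q) && is.null(dim(q))) {
    res <- .threshold_one(q, tau, step)
    out <- res$values
    attr(out, "applied_threshold") <- res$applied
    return(out)
  }
  comps <- .component_cols(q, components)
  qm <- as.matrix(q[comps])
  res <- apply(qm, 1, .threshold_one, tau = tau, step = step)
  out <- as_tibble(q)
  vals <- t(vapply(res, `[[`, numeric(length(comps)), "values"))
  for (j in seq_along(comps)) out[[comps[j]]] <- vals[, j]
  out$applied_threshold <- vapply(res, `[[`, numeric(1), "applied")
  attr(out, "components") <- comps
  out
}

.threshold_one <- function(q, tau, step) {
  if (any(is.na(q)) || any(q < 0) || sum(q) <= 0) {
    abort("invalid ancestry vector: needs non-negative entries summing to a positive value")
  }
  i <- 0L
  repeat {
    t_cur <- round(tau - i * step, 10)
    if (t_cur <= step) {
      t_cur <- step
      break
    }
    if (any(q >= t_cur)) break
    i <- i + 1L
  }
  keep <- q >= t_cur
  if (!any(keep)) keep <- q == max(q)  # floor reached and still nothing
  v <- ifelse(keep, q, 0)
  list(values = v / sum(v), applied = t_cur)
}

#' Default mapping of the 12 gene-pool components to continental groups
#'
#' The shipped 12-to-5 mapping (Africa A/B to Africa; Central, South and
#' Western Europe plus Scandinavia to Europe; East, Far East and
#' Southeast Asia to East Asia; Central Asia and India to Central Asia;
#' Native America to America). It is a configuration default, not a
#' constraint: pass any two-column mapping to [collapse_to_groups()] or
#' edit the copy in `system.file("extdata", "component_groups.tsv",
#' package = "admixclass")`.
#'
#' @return A tibble with columns `component` and `group`.
#' @export
default_group_map <- function() {
  tibble(
    component = c("Africa A", "Africa B",
                  "Central Europe", "South Europe", "Western Europe",
                  "Scandinavia",
                  "East Asia", "Far East Asia", "Southeast Asia",
                  "Central Asia", "India",
                  "Native America"),
    group = c("Africa", "Africa",
              "Europe", "Europe", "Europe", "Europe",
              "East Asia", "East Asia", "East Asia",
              "Central Asia", "Central Asia",
              "America")
  )
}

#' Read a component-to-group map
#'
#' @param path A two-column TSV (`component`, `group`).
#' @return A tibble with columns `component` and `group`.
#' @export
read_group_map <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("component", "group") %in% names(x))) {
    abort("group map needs 'component' and 'group' columns")
  }
  if (anyDuplicated(x$component)) abort("a component is mapped more than once")
  as_tibble(x[c("component", "group")])
}

#' Collapse gene-pool components into continental groups
#'
#' Sums the component proportions within each group of the mapping; total
#' mass is conserved. Groups appear in the order of their first mention
#' in the map.
#'
#' @param profile A numeric named vector, or a tibble of profiles with one
#'   column per component (other columns are carried through).
#' @param map A tibble mapping `component` to `group`
#'   (default [default_group_map()]).
#' @param components For the data-frame method: component column names
#'   (defaults as in [threshold_normalize()]).
#' @return A group profile: named vector, or tibble with one column per
#'   group.
#' @export
collapse_to_groups <- function(profile, map = default_group_map(),
                               components = NULL) {
  groups <- unique(map$group)
  if (is.numeric(profile) && is.null(dim(profile))) {
    comps <- names(profile)
    .check_mapped(comps, profile, map)
    out <- vapply(groups, function(g) {
      sum(profile[intersect(comps, map$component[map$group == g])])
    }, numeric(1))
    return(out)
  }
  comps <- .component_cols(profile, components)
  vals <- as.matrix(profile[comps])
  .check_mapped(comps, colSums(abs(vals)), map)
  keep <- profile[setdiff(names(profile), comps)]
  out <- as_tibble(keep)
  for (g in groups) {
    member <- intersect(comps, map$component[map$group == g])
    out[[g]] <- if (length(member)) rowSums(vals[, member, drop = FALSE]) else 0
  }
  attr(out, "groups") <- groups
  out
}

.check_mapped <- function(comps, mass, map) {
  unmapped <- setdiff(comps, map$component)
  bad <- unmapped[mass[match(unmapped, comps)] > 0]
  if (length(bad)) {
    abort(paste0("components with non-zero mass are not in the group map: ",
                 paste(bad, collapse = ", ")))
  }
}
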