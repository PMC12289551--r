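#' End-to-end ancestry inference over a set of VCFs
#'
#' The full per-sample chain: read and filter the VCF, intersect with the
#' panel SNP set, estimate admixture proportions by supervised
#' projection, threshold-normalise, and collapse to continental groups
#' (when a map is supplied). A failing input is logged and skipped — the
#' run continues for the remaining files — and the run log records the
#' stage counts and the applied threshold per sample so the adaptive
#' rule stays auditable.
#'
#' @param config A named list (or path to a YAML file) with fields:
#'   `inputs` (character vector of VCF paths, optionally named by
#'   sample), `panel` (panel tibble or TSV path), `map` (optional group
#'   map tibble or TSV path), `min_qual` (default 40), `require_pass`
#'   (default `TRUE`), `tau` (default 0.1), `step` (default 0.01),
#'   `tol`, `max_iter` (EM settings), `out` (optional output directory).
#' @return An object of class `infer_run`: list with `profiles`
#'   (component profiles, one row per sample), `group_profiles` (or
#'   `NULL` without a map), `log` (per-input tibble of stage counts and
#'   status), `failures` (subset of the log).
#' @export
run_infer <- function(config) {
  cfg <- .load_config(config)
  panel <- .load_panel(cfg$panel)
  map <- .load_map(cfg$map)
  min_qual <- cfg$min_qual %||% 40
  require_pass <- cfg$require_pass %||% TRUE
  tau <- cfg$tau %||% 0.1
  step <- cfg$step %||% 0.01
  tol <- cfg$tol %||% 1e-6
  max_iter <- cfg$max_iter %||% 2000
  inputs <- cfg$inputs
  if (is.null(inputs)) abort("config needs 'inputs'")

  logs <- list()
  profiles <- list()
  for (i in seq_along(inputs)) {
    path <- inputs[[i]]
    nm <- names(inputs)[i] %||% ""
    if (!nzchar(nm)) nm <- sub("\\.vcf(\\.gz)?$", "", basename(path))
    rec <- tibble(input = nm, path = path, n_read = NA_integer_,
                  n_kept = NA_integer_, n_matched = NA_integer_,
                  status = "ok", message = NA_character_)
    res <- tryCatch({
      gm <- read_vcf_genotypes(path, min_qual = min_qual,
                               require_pass = require_pass)
      st <- filter_stats(gm)
      rec$n_read <- st$records[st$filter == "read"]
      rec$n_kept <- nrow(gm)
      sub <- intersect_with_panel(gm, panel)
      rec$n_matched <- attr(sub, "n_matched")
      q <- fit_supervised_q(sub, panel, tol = tol, max_iter = max_iter)
      prof <- threshold_normalize(q, tau = tau, step = step)
      if (length(geno_samples(gm)) == 1) prof$sample <- nm
      prof
    }, error = function(e) {
      rec$status <<- "failed"
      rec$message <<- conditionMessage(e)
      NULL
    })
    logs[[i]] <- rec
    if (!is.null(res)) profiles[[i]] <- res
  }
  log <- list_rbind(logs)
  profiles <- if (length(profiles)) list_rbind(profiles) else NULL
  group_profiles <- NULL
  if (!is.null(profiles)) {
    attr(profiles, "components") <- .panel_components(panel)
    if (!is.null(map)) {
      group_profiles <- collapse_to_groups(
        profiles[c("sample", .panel_components(panel), "applied_threshold")],
        map = map, components = .panel_components(panel))
    }
  }
  out <- structure(
    list(profiles = profiles, group_profiles = group_profiles, log = log,
         failures = log[log$status == "failed", ]),
    class = "infer_run"
  )
  if (!is.null(cfg$out)) .write_infer_run(out, cfg)
  out
}

.write_infer_run <- function(run, cfg) {
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(run$profiles)) {
    readr::write_tsv(run$profiles, file.path(cfg$out, "profiles.tsv"))
  }
  if (!is.null(run$group_profiles)) {
    readr::write_tsv(run$group_profiles,
                     file.path(cfg$out, "group_profiles.tsv"))
  }
  readr::write_tsv(run$log, file.path(cfg$out, "run_log.tsv"))
  cfg_rec <- cfg
  cfg_rec$panel <- if (is.character(cfg$panel)) cfg$panel else "<in-memory>"
  cfg_rec$map <- if (is.character(cfg$map)) cfg$map else
    if (is.null(cfg$map)) NULL else "<in-memory>"
  jsonlite::write_json(cfg_rec, file.path(cfg$out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(run)
}

#' @export
print.infer_run <- function(x, ...) {
  cat("Inference run:", nrow(x$log), "inputs,",
      sum(x$log$status == "ok"), "ok,", nrow(x$failures), "failed\n")
  if (!is.null(x$profiles)) {
    cat("profiles:", nrow(x$profiles), "samples x",
        length(attr(x$profiles, "components")), "components\n")
  }
  invisible(x)
}

#' Train and/or apply the continental-group classifier
#'
#' With training data (`profiles` + `labels`), fits the shrinkage LDA,
#' reports stratified cross-validation metrics, and scores any
#' additional `predict_profiles`. With a pre-trained `model` (object or
#' JSON path), only predicts.
#'
#' @param config A named list (or YAML path) with fields: `profiles`
#'   (tibble or TSV path of training profiles), `labels` (tibble with
#'   `sample`, `group`, or TSV path), `model` (optional `shrinkage_lda`
#'   or JSON path), `predict_profiles` (optional tibble or TSV path),
#'   `cv` (folds, default 5), `seed`, `shrinkage` (default `"auto"`),
#'   `tol` (default 1e-4), `out` (optional output directory).
#' @return An object of class `classify_run`: list with `model`,
#'   `cv` (a `cv_result` or `NULL`), `predictions` (tibble or `NULL`).
#' @export
run_classify <- function(config) {
  cfg <- .load_config(config)
  model <- cfg$model
  if (is.character(model)) model <- read_lda_json(model)
  cv <- NULL
  if (is.null(model)) {
    if (is.null(cfg$profiles) || is.null(cfg$labels)) {
      abort("need either a 'model' or training 'profiles' + 'labels'")
    }
    profiles <- .load_table(cfg$profiles)
    labels <- .load_table(cfg$labels)
    y <- labels$group[match(profiles$sample, labels$sample)]
    if (anyNA(y)) abort("labels are missing for some profile samples")
    feats <- .component_cols(profiles)
    model <- fit_lda(profiles[feats], y, shrinkage = cfg$shrinkage %||% "auto",
                     tol = cfg$tol %||% 1e-4)
    cv <- stratified_kfold_cv(profiles[feats], y, k = cfg$cv %||% 5,
                              seed = cfg$seed,
                              shrinkage = cfg$shrinkage %||% "auto",
                              tol = cfg$tol %||% 1e-4)
  }
  predictions <- NULL
  target <- cfg$predict_profiles %||% cfg$profiles
  if (!is.null(target)) {
    predictions <- predict(model, .load_table(target))
  }
  out <- structure(list(model = model, cv = cv, predictions = predictions),
                   class = "classify_run")
  if (!is.null(cfg$out)) {
    dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
    write_lda_json(model, file.path(cfg$out, "model.json"))
    if (!is.null(predictions)) {
      readr::write_tsv(predictions, file.path(cfg$out, "predictions.tsv"))
    }
    if (!is.null(cv)) {
      readr::write_tsv(glance(cv), file.path(cfg$out, "cv_metrics.tsv"))
    }
  }
  out
}

#' @export
print.classify_run <- function(x, ...) {
  print(x$model)
  if (!is.null(x$cv)) print(glance(x$cv))
  if (!is.null(x$predictions)) {
    cat("predictions:", nrow(x$predictions), "samples\n")
  }
  invisible(x)
}

.load_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(paste0("config file not found: ", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("config must be a named list or a YAML path")
  config
}

.load_panel <- function(x) {
  if (is.null(x)) abort("config needs 'panel'")
  if (is.character(x)) read_panel(x) else x
}

.load_map <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.character(x)) read_group_map(x) else x
}

.load_table <- function(x) {
  if (is.character(x)) readr::read_tsv(x, show_col_types = FALSE) else x
}

#' Stacked-bar plot of ancestry profiles
#'
#' @param profiles Profile tibble with `sample` and component columns.
#' @param components Optional component column names.
#' @return A ggplot object.
#' @export
plot_ancestry <- function(profiles, components = NULL) {
  comps <- .component_cols(profiles, components)
  long <- tidyr::pivot_longer(profiles[c("sample", comps)],
                              cols = dplyr::all_of(comps),
                              names_to = "component",
                              values_to = "proportion")
  long$sample <- factor(long$sample, levels = unique(profiles$sample))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample,
                                     y = .data$proportion,
                                     fill = .data$component)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(x = NULL, y = "ancestry proportion") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 6))
}
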