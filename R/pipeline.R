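#' Pipeline configuration
#'
#' Thresholds and estimator settings for [run_pipeline()], all in one
#' place so a run is reproducible from its manifest.
#'
#' @param reverse_threshold correlation below which an item is flagged as
#'   a reverse-coding candidate (default -0.2).
#' @param min_cell sparse-cell threshold (default 5).
#' @param min_overlap minimum pairwise-complete observations for a
#'   correlation (default 20).
#' @param dichotomize_all truncate remaining ordinal items to 0/1 before
#'   model fitting (default `TRUE`).
#' @param fit_irt run the per-study 2PL stage (default `TRUE`).
#' @param n_quad,tol,max_iter estimator settings passed to [fit_2pl()].
#' @param resid_cor_threshold,resid_z_threshold residual flag thresholds
#'   passed to [residual_report()] (defaults 0.3 and 3).
#' @param seed seed recorded in the manifest (the pipeline itself is
#'   deterministic; the seed covers any stochastic pre-processing such as
#'   [select_random_visit()]).
#' @return a named list of class `pipeline_config`.
#' @export
pipeline_config <- function(reverse_threshold = -0.2, min_cell = 5L,
                            min_overlap = 20L, dichotomize_all = TRUE,
                            fit_irt = TRUE, n_quad = 41L, tol = 1e-6,
                            max_iter = 500L, resid_cor_threshold = 0.3,
                            resid_z_threshold = 3, seed = 1L) {
  structure(list(reverse_threshold = reverse_threshold, min_cell = min_cell,
                 min_overlap = min_overlap, dichotomize_all = dichotomize_all,
                 fit_irt = fit_irt, n_quad = n_quad, tol = tol,
                 max_iter = max_iter,
                 resid_cor_threshold = resid_cor_threshold,
                 resid_z_threshold = resid_z_threshold, seed = seed),
            class = "pipeline_config")
}

# raw study data with declared missing codes masked and columns keyed by
# construct; the view used by the raw-code comparability checks
mask_missing_codes <- function(ds, cw) {
  maps <- Filter(function(m) m$study_id == ds$study_id &&
                   !isTRUE(m$is_summary_score), cw$mappings)
  out <- list()
  for (m in maps) {
    if (!m$source_variable %in% names(ds$data)) next
    v <- ds$data[[m$source_variable]]
    v[v %in% m$missing_codes] <- NA
    out[[m$construct_id]] <- v
  }
  study_dataset(ds$study_id,
                as.data.frame(c(list(respondent_id = ds$data[[1]]), out),
                              stringsAsFactors = FALSE, check.names = FALSE))
}

#' Run the pre-statistical harmonization pipeline
#'
#' Executes the full checklist in a fixed stage order over one crosswalk
#' and a set of raw study files:
#' 1. read and validate the crosswalk against the data;
#' 2. sentinel and cross-study range QC on raw codes (declared missing
#'    codes masked for the range cross-tab);
#' 3. recode / standardize every mapped item (summary scores excluded);
#' 4. exclude conditional (gated) items;
#' 5. drop no-variability items; sparse-cell collapsing happened during
#'    standardization;
#' 6. directionality check -- reverse-coding candidates are reported
#'    only; reversal requires an explicit crosswalk recode, because an
#'    anti-correlated item can be substantively, not artifactually,
#'    reversed;
#' 7. per-study 2PL fit with fit statistics and residual flags;
#' 8. reports: QC flag table, standardization audit log, per-study fit
#'    report, run manifest.
#'
#' The pipeline never mutates its inputs; all outputs go to `out_dir`.
#' Two runs with equal inputs, config and seed produce byte-identical
#' reports (the manifest records input digests so this is checkable).
#'
#' @param crosswalk_path path to the crosswalk TSV.
#' @param data_paths named character vector: `study_id -> path` of raw
#'   study tables.
#' @param out_dir output directory, created if needed.
#' @param config a [pipeline_config()].
#' @return the run manifest (invisibly a list, also written as JSON):
#'   config snapshot, input digests, stage ordering, per-stage flag
#'   counts, fits, flags, and output paths.
#' @export
run_pipeline <- function(crosswalk_path, data_paths, out_dir,
                         config = pipeline_config()) {
  stopifnot(length(data_paths) >= 1L, !is.null(names(data_paths)))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- c("read_validate", "raw_qc", "standardize",
              "exclude_conditional", "variability", "directionality",
              "irt_fit", "reports")

  # stage 1: read and validate
  cw <- read_crosswalk(crosswalk_path)
  datasets <- lapply(names(data_paths), function(s) {
    read_study_data(data_paths[[s]], s)
  })
  names(datasets) <- names(data_paths)
  flags <- list(validate_crosswalk(cw, datasets))
  stage_counts <- c(read_validate = nrow(flags[[1]]))

  # stage 2: raw-code QC -- sentinels, then range cross-tab on masked raw
  raw_flags <- list()
  for (m in cw$mappings) {
    if (isTRUE(m$is_summary_score)) next
    ds <- datasets[[m$study_id]]
    if (is.null(ds) || !m$source_variable %in% names(ds$data)) next
    f <- detect_missing_codes(ds$data[[m$source_variable]],
                              m$construct_id, m$study_id)
    if (!is.null(f)) raw_flags[[length(raw_flags) + 1L]] <- f
  }
  masked <- lapply(datasets, mask_missing_codes, cw = cw)
  ct <- crosstab_ranges(masked, cw)
  raw_flags <- bind_flags(c(raw_flags, list(ct$flags)))
  flags[[length(flags) + 1L]] <- raw_flags
  stage_counts["raw_qc"] <- nrow(raw_flags)

  # stage 3: standardize
  audit <- list(); harmonized <- list(); std_flags <- list()
  for (s in names(datasets)) {
    st <- standardize_study(datasets[[s]], cw, min_cell = config$min_cell,
                            dichotomize_all = config$dichotomize_all)
    harmonized[[s]] <- st$dataset
    audit[[s]] <- st$log
    std_flags[[length(std_flags) + 1L]] <- st$flags
  }
  std_flags <- bind_flags(std_flags)
  flags[[length(flags) + 1L]] <- std_flags
  stage_counts["standardize"] <- nrow(std_flags)

  # stage 4: conditional exclusion
  cond_flags <- list()
  for (s in names(harmonized)) {
    ex <- exclude_conditional(harmonized[[s]], cw)
    harmonized[[s]] <- ex$dataset
    cond_flags[[length(cond_flags) + 1L]] <- ex$flags
  }
  cond_flags <- bind_flags(cond_flags)
  flags[[length(flags) + 1L]] <- cond_flags
  stage_counts["exclude_conditional"] <- nrow(cond_flags)

  # stage 5: no-variability exclusion
  var_flags <- list()
  for (s in names(harmonized)) {
    ds <- harmonized[[s]]
    keep <- character(0)
    for (j in item_columns(ds)) {
      f <- detect_no_variability(ds$data[[j]], j, s)
      if (is.null(f)) keep <- c(keep, j) else {
        var_flags[[length(var_flags) + 1L]] <- f
      }
    }
    harmonized[[s]] <- study_dataset(
      s, ds$data[, c(names(ds$data)[1], keep), drop = FALSE])
  }
  var_flags <- bind_flags(var_flags)
  flags[[length(flags) + 1L]] <- var_flags
  stage_counts["variability"] <- nrow(var_flags)

  # stage 6: directionality (report-only)
  dir_flags <- list()
  for (s in names(harmonized)) {
    if (length(item_columns(harmonized[[s]])) >= 2L) {
      dir_flags[[length(dir_flags) + 1L]] <-
        detect_reverse_candidates(harmonized[[s]],
                                  threshold = config$reverse_threshold,
                                  min_overlap = config$min_overlap)
    }
  }
  dir_flags <- bind_flags(dir_flags)
  flags[[length(flags) + 1L]] <- dir_flags
  stage_counts["directionality"] <- nrow(dir_flags)

  # stage 7: per-study 2PL
  fits <- list()
  if (isTRUE(config$fit_irt)) {
    for (s in names(harmonized)) {
      items <- item_columns(harmonized[[s]])
      if (length(items) < 3L) next
      y <- as.matrix(harmonized[[s]]$data[, items, drop = FALSE])
      fit <- fit_2pl(y, n_quad = config$n_quad, tol = config$tol,
                     max_iter = config$max_iter, study_id = s)
      fs <- fit_statistics(fit, y)
      rr <- residual_report(fit, y,
                            cor_threshold = config$resid_cor_threshold,
                            z_threshold = config$resid_z_threshold)
      fits[[s]] <- list(fit = fit, stats = fs, residuals = rr)
    }
  }
  stage_counts["irt_fit"] <- length(fits)

  all_flags <- bind_flags(flags)
  endorse <- do.call(rbind, lapply(harmonized, function(ds) {
    rep <- endorsement_report(ds)
    if (nrow(rep)) cbind(study_id = ds$study_id, rep) else NULL
  }))

  # stage 8: reports
  paths <- list(qc_report = file.path(out_dir, "qc_report.tsv"),
                audit_log = file.path(out_dir, "audit_log.tsv"),
                fit_report = file.path(out_dir, "fit_report.tsv"),
                endorsement = file.path(out_dir, "endorsement.tsv"),
                manifest = file.path(out_dir, "manifest.json"))
  write_tsv_plain(all_flags, paths$qc_report)
  write_tsv_plain(do.call(rbind, audit), paths$audit_log)
  write_tsv_plain(fit_report_table(fits), paths$fit_report)
  write_tsv_plain(endorse, paths$endorsement)

  manifest <- list(
    config = unclass(config),
    inputs = c(crosswalk = unname(tools::md5sum(crosswalk_path)),
               stats::setNames(unname(tools::md5sum(unlist(data_paths))),
                               names(data_paths))),
    stage_order = stages,
    seed = config$seed,
    flag_counts = as.list(stage_counts),
    outputs = lapply(paths, basename))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest$flags <- all_flags
  manifest$fits <- fits
  manifest$harmonized <- harmonized
  manifest$paths <- paths
  invisible(manifest)
}

write_tsv_plain <- function(df, path) {
  if (is.null(df)) {
    df <- data.frame()
  }
  utils::write.table(format(df, digits = 15, scientific = FALSE,
                            trim = TRUE),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

fit_report_table <- function(fits) {
  if (!length(fits)) {
    return(data.frame(study_id = character(0), n = integer(0),
                      n_items = integer(0), converged = logical(0),
                      loglik = numeric(0), m2 = numeric(0), df = integer(0),
                      rmsea = numeric(0), rmsea_label = character(0),
                      cfi = numeric(0), cfi_label = character(0),
                      srmr = numeric(0), srmr_label = character(0),
                      n_flagged_pairs = integer(0),
                      flagged_pairs = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(fits, function(f) {
    fp <- f$residuals$flagged_pairs
    data.frame(
      study_id = f$fit$study_id, n = f$fit$n,
      n_items = length(f$fit$a), converged = f$fit$converged,
      loglik = round(f$fit$loglik, 4),
      m2 = round(f$stats$m2, 4), df = f$stats$df,
      rmsea = round(f$stats$rmsea, 4),
      rmsea_label = f$stats$labels[["rmsea"]],
      cfi = round(f$stats$cfi, 4), cfi_label = f$stats$labels[["cfi"]],
      srmr = round(f$stats$srmr, 4), srmr_label = f$stats$labels[["srmr"]],
      n_flagged_pairs = nrow(fp),
      flagged_pairs = if (nrow(fp)) {
        paste(paste0(fp$item_i, "/", fp$item_j), collapse = " ")
      } else "",
      stringsAsFactors = FALSE)
  }))
}

#' Reduce longitudinal data to one random visit per respondent
#'
#' Statistical linking needs a single record per participant; for
#' longitudinal sources this selects one visit per respondent uniformly
#' at random, reproducibly from the seed.
#'
#' @param data data frame with one row per visit.
#' @param id_col respondent identifier column name.
#' @param seed integer seed (recorded by the caller's manifest).
#' @return data frame with one row per respondent, in order of first
#'   appearance.
#' @export
select_random_visit <- function(data, id_col, seed = 1L) {
  stopifnot(id_col %in% names(data))
  set.seed(seed)
  ids <- unique(data[[id_col]])
  rows <- vapply(ids, function(id) {
    idx <- which(data[[id_col]] == id)
    if (length(idx) == 1L) idx else sample(idx, 1L)
  }, integer(1))
  data[rows, , drop = FALSE]
}
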