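#' Reverse-code an item
#'
#' Flips a 0-based harmonized item so that high scores point the other
#' way: each non-missing value `v` becomes `max_level - v`. Used to bring
#' every item in a pooled construct to the shared convention that higher
#' values indicate a worse / more severe symptom. Reversal is an
#' involution: applying it twice restores the input.
#'
#' @param values 0-based integer vector (may contain `NA`).
#' @param max_level highest level of the item's declared range.
#' @return integer vector with non-missing entries reflected; `NA`
#'   unchanged.
#' @export
reverse_code <- function(values, max_level) {
  v <- as.integer(values)
  max_level <- as.integer(max_level)
  nm <- v[!is.na(v)]
  if (length(nm) && (any(nm < 0L) || any(nm > max_level))) {
    stop("values outside [0, ", max_level, "] cannot be reverse-coded",
         call. = FALSE)
  }
  ifelse(is.na(v), NA_integer_, max_level - v)
}

#' Shift a 1-based item down to 0
#'
#' Some studies code the lowest response option as 1 rather than 0; this
#' subtracts exactly 1 from every non-missing value so scales align at 0.
#' Applying it to an item whose minimum is already 0 is refused as a
#' no-op with a warning, which guards against accidental double shifts.
#'
#' @param values integer vector whose declared minimum is 1.
#' @return integer vector shifted down by one.
#' @export
shift_to_zero <- function(values) {
  v <- as.integer(values)
  nm <- v[!is.na(v)]
  if (length(nm) && min(nm) == 0L) {
    warning("minimum is already 0; shift_to_zero is a no-op", call. = FALSE)
    return(v)
  }
  ifelse(is.na(v), NA_integer_, v - 1L)
}

#' Dichotomize an ordinal item
#'
#' Keeps the 0 option and truncates every non-missing score of 1 or more
#' to 1, the "presence" coding used when studies score the same behavior
#' on different granularities. Idempotent; `NA` propagates.
#'
#' @param values 0-based integer vector.
#' @return integer vector of 0/1/`NA`.
#' @export
dichotomize <- function(values) {
  v <- as.integer(values)
  ifelse(is.na(v), NA_integer_, as.integer(v >= 1L))
}

#' Collapse an ordinal item with sparse cells to binary
#'
#' If any non-extreme category (a level other than 0 and the observed
#' maximum) has fewer than `min_cell` responses, the item is dichotomized
#' via [dichotomize()]; otherwise it is returned unchanged. Small interior
#' cells create outlier-driven instability in item response models, so
#' they are folded into the presence coding. The decision is reported so
#' it can be audited.
#'
#' @param values 0-based integer vector.
#' @param min_cell minimum acceptable count per non-extreme category
#'   (default 5, the conventional small-cell criterion).
#' @param construct_id,study_id identifiers carried into the flag.
#' @return a list with `values` (possibly collapsed), `collapsed`
#'   (logical), and `flag` (a one-row QC flag data frame when collapsed or
#'   degenerate, else `NULL`).
#' @export
collapse_sparse <- function(values, min_cell = 5L, construct_id = NA_character_,
                            study_id = NA_character_) {
  stopifnot(min_cell >= 1L)
  v <- as.integer(values)
  nm <- v[!is.na(v)]
  if (!length(nm)) {
    return(list(values = v, collapsed = FALSE,
                flag = qc_flag("sparse_cell", construct_id, study_id,
                               "all values missing; left unchanged")))
  }
  counts <- table(nm)
  levels_obs <- as.integer(names(counts))
  # the 0 option is always kept; any higher category can be truncated
  interior <- levels_obs > 0L
  if (any(interior & as.integer(counts) < min_cell)) {
    bad <- levels_obs[interior & as.integer(counts) < min_cell]
    list(values = dichotomize(v), collapsed = TRUE,
         flag = qc_flag("sparse_cell", construct_id, study_id,
                        paste0("category ", paste(bad, collapse = ","),
                               " below min_cell=", min_cell,
                               "; item dichotomized"),
                        value = min(as.integer(counts)[interior])))
  } else {
    list(values = v, collapsed = FALSE, flag = NULL)
  }
}

#' Standardize one study against the crosswalk
#'
#' Applies the deterministic standardization sequence to every mapped
#' item of a raw study table, in the fixed order: recode (sentinel
#' masking and any reversal encoded in the crosswalk's recode map), then
#' shift-to-zero when the recoded minimum of the declared range is 1,
#' then sparse-cell collapsing, then (optionally) dichotomization of all
#' remaining ordinal items. Summary-score items are flagged and dropped
#' before any transformation. Every applied transform is logged.
#'
#' @param ds a [study_dataset()] holding raw codes.
#' @param cw a [crosswalk()].
#' @param min_cell sparse-cell threshold passed to [collapse_sparse()].
#' @param dichotomize_all if `TRUE` (default), ordinal items are truncated
#'   to presence/absence after collapsing, the lowest-common-denominator
#'   coding needed for a binary IRT stage.
#' @return list with `dataset` (a harmonized [study_dataset()] keyed by
#'   construct), `log` (data frame: study, construct, operation,
#'   parameters), and `flags` (QC flag data frame).
#' @export
standardize_study <- function(ds, cw, min_cell = 5L, dichotomize_all = TRUE) {
  stopifnot(inherits(ds, "study_dataset"), inherits(cw, "crosswalk"))
  maps <- Filter(function(m) m$study_id == ds$study_id, cw$mappings)
  log <- list(); flags <- list(); out <- list()
  for (m in maps) {
    if (isTRUE(m$is_summary_score)) {
      flags[[length(flags) + 1L]] <-
        qc_flag("summary_score", m$construct_id, ds$study_id,
                paste0("summary score '", m$source_variable,
                       "' excluded in favor of item-level data"))
      next
    }
    if (!m$source_variable %in% names(ds$data)) next  # validate_crosswalk flags this
    v <- apply_recode(ds$data[[m$source_variable]], m$recode)
    log[[length(log) + 1L]] <- data.frame(
      study_id = ds$study_id, construct_id = m$construct_id,
      operation = "apply_recode", parameters = format_recode(m$recode),
      stringsAsFactors = FALSE)
    rng <- m$recode$declared_range
    if (!is.na(rng[1]) && rng[1] == 1L) {
      # recode maps are required to land at 0, so this is unreachable via
      # recode_rule; kept for directly supplied vectors
      v <- shift_to_zero(v)
      log[[length(log) + 1L]] <- data.frame(
        study_id = ds$study_id, construct_id = m$construct_id,
        operation = "shift_to_zero", parameters = "",
        stringsAsFactors = FALSE)
    }
    nlev <- length(unique(v[!is.na(v)]))
    if (nlev > 2L) {
      cs <- collapse_sparse(v, min_cell, m$construct_id, ds$study_id)
      if (!is.null(cs$flag)) flags[[length(flags) + 1L]] <- cs$flag
      if (cs$collapsed) {
        v <- cs$values
        log[[length(log) + 1L]] <- data.frame(
          study_id = ds$study_id, construct_id = m$construct_id,
          operation = "collapse_sparse",
          parameters = paste0("min_cell=", min_cell),
          stringsAsFactors = FALSE)
      } else if (dichotomize_all) {
        v <- dichotomize(v)
        log[[length(log) + 1L]] <- data.frame(
          study_id = ds$study_id, construct_id = m$construct_id,
          operation = "dichotomize", parameters = "",
          stringsAsFactors = FALSE)
      }
    }
    out[[m$construct_id]] <- v
  }
  data <- if (length(out)) {
    as.data.frame(c(list(respondent_id = ds$data[[1]]), out),
                  stringsAsFactors = FALSE, check.names = FALSE)
  } else {
    data.frame(respondent_id = ds$data[[1]], stringsAsFactors = FALSE)
  }
  list(dataset = study_dataset(ds$study_id, data),
       log = if (length(log)) do.call(rbind, log) else empty_audit_log(),
       flags = bind_flags(flags))
}

empty_audit_log <- function() {
  data.frame(study_id = character(0), construct_id = character(0),
             operation = character(0), parameters = character(0),
             stringsAsFactors = FALSE)
}
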