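#' Item mappings
#'
#' One row of a crosswalk: the link between a harmonized item construct
#' and the variable that measures it in a specific study, together with
#' everything needed to recode that variable deterministically --
#' response options, declared missing codes, an optional gate variable
#' (skip pattern), a summary-score marker, and the recode rule itself.
#'
#' @param construct_id stable identifier of the harmonized behavioral
#'   attribute (e.g. `"delusion_danger"`).
#' @param study_id source study label.
#' @param source_variable raw variable name in the study file.
#' @param instrument instrument name/version (e.g. `"NPI"`, `"DEMQOL"`).
#' @param question_stem free text of the question.
#' @param response_options named integer vector: raw codes named by their
#'   labels (e.g. `c(Yes = 1L, No = 5L)`).
#' @param missing_codes integer codes denoting non-response.
#' @param gate_variable source variable this item is conditional on, or
#'   `""` if unconditional.
#' @param is_summary_score logical; summary scores are excluded from QC
#'   and IRT stages.
#' @param recode a [recode_rule()] total over
#'   `response_options` and `missing_codes`.
#' @return an object of class `item_mapping`.
#' @export
item_mapping <- function(construct_id, study_id, source_variable,
                         instrument = "", question_stem = "",
                         response_options = integer(0),
                         missing_codes = integer(0),
                         gate_variable = "", is_summary_score = FALSE,
                         recode) {
  stopifnot(is.character(construct_id), is.character(study_id),
            is.character(source_variable), inherits(recode, "recode_rule"))
  response_options <- as.integer(response_options)
  missing_codes <- as.integer(missing_codes)
  all_codes <- c(response_options, missing_codes)
  if (anyDuplicated(all_codes)) {
    stop("raw code(s) declared more than once across response_options and ",
         "missing_codes for (", construct_id, ", ", study_id, "): ",
         paste(unique(all_codes[duplicated(all_codes)]), collapse = ", "),
         call. = FALSE)
  }
  undeclared <- setdiff(all_codes, recode$raw)
  if (length(undeclared)) {
    stop("recode rule for (", construct_id, ", ", study_id,
         ") is not total: code(s) ", paste(undeclared, collapse = ", "),
         " have no recode target", call. = FALSE)
  }
  structure(list(construct_id = construct_id, study_id = study_id,
                 source_variable = source_variable, instrument = instrument,
                 question_stem = question_stem,
                 response_options = response_options,
                 missing_codes = missing_codes,
                 gate_variable = gate_variable,
                 is_summary_score = isTRUE(is_summary_score),
                 recode = recode),
            class = "item_mapping")
}

#' Crosswalks
#'
#' A crosswalk is the table that maps common elements between studies:
#' one [item_mapping()] per (construct, study) pair, with the pair unique
#' across the table. It is the single place where recode decisions,
#' skip-pattern declarations and summary-score exclusions live, so that
#' every downstream transformation is reproducible from the crosswalk
#' plus the raw data alone.
#'
#' @param mappings list of [item_mapping()] objects.
#' @return an object of class `crosswalk` with elements `mappings`,
#'   `constructs` and `studies`.
#' @export
crosswalk <- function(mappings) {
  stopifnot(is.list(mappings),
            all(vapply(mappings, inherits, logical(1), "item_mapping")))
  keys <- vapply(mappings, function(m) paste0(m$construct_id, "\r", m$study_id),
                 character(1))
  if (anyDuplicated(keys)) {
    dup <- keys[duplicated(keys)][1]
    rows <- which(keys == dup)
    parts <- strsplit(dup, "\r", fixed = TRUE)[[1]]
    stop("duplicate (construct_id, study_id) pair (", parts[1], ", ",
         parts[2], ") at rows ", paste(rows, collapse = " and "),
         call. = FALSE)
  }
  structure(list(
    mappings = mappings,
    constructs = unique(vapply(mappings, `[[`, character(1), "construct_id")),
    studies = unique(vapply(mappings, `[[`, character(1), "study_id"))
  ), class = "crosswalk")
}

#' @export
print.crosswalk <- function(x, ...) {
  cat("<crosswalk> ", length(x$mappings), " mappings, ",
      length(x$constructs), " constructs, ",
      length(x$studies), " studies\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.crosswalk <- function(x, ...) {
  do.call(rbind, lapply(x$mappings, function(m) {
    data.frame(
      construct_id = m$construct_id, study_id = m$study_id,
      source_variable = m$source_variable, instrument = m$instrument,
      question_stem = m$question_stem,
      response_options = format_options(m$response_options),
      missing_codes = paste(m$missing_codes, collapse = ","),
      gate_variable = m$gate_variable,
      is_summary_score = m$is_summary_score,
      recode = format_recode(m$recode),
      stringsAsFactors = FALSE)
  }))
}

format_options <- function(opts) {
  if (!length(opts)) return("")
  labels <- names(opts)
  if (is.null(labels)) labels <- rep("", length(opts))
  paste(paste0(opts, "=", labels), collapse = ";")
}

parse_options <- function(text) {
  if (is.na(text) || !nzchar(trimws(text))) return(integer(0))
  parts <- strsplit(trimws(text), ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  codes <- suppressWarnings(as.integer(vapply(kv, `[[`, character(1), 1)))
  if (anyNA(codes)) stop("non-integer raw code in response_options '", text,
                         "'", call. = FALSE)
  names(codes) <- vapply(kv, function(p) if (length(p) > 1) p[[2]] else "",
                         character(1))
  codes
}

parse_code_set <- function(text) {
  if (is.na(text) || !nzchar(trimws(text))) return(integer(0))
  codes <- suppressWarnings(
    as.integer(trimws(strsplit(trimws(text), ",", fixed = TRUE)[[1]])))
  if (anyNA(codes)) stop("non-integer missing code in '", text, "'",
                         call. = FALSE)
  codes
}

cw_columns <- c("construct_id", "study_id", "source_variable", "instrument",
                "question_stem", "response_options", "missing_codes",
                "gate_variable", "is_summary_score", "recode")

#' Read a crosswalk from delimited text
#'
#' Reads a TSV (or other delimited) crosswalk with the canonical columns
#' `construct_id, study_id, source_variable, instrument, question_stem,
#' response_options, missing_codes, gate_variable, is_summary_score,
#' recode`, parses the compact recode and response-option encodings, and
#' validates the result. Parse failures report the offending cell.
#'
#' @param path file path.
#' @param delim field delimiter (default tab).
#' @return a [crosswalk()].
#' @export
read_crosswalk <- function(path, delim = "\t") {
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, sep = delim, stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE,
                          na.strings = NULL)
  missing_cols <- setdiff(cw_columns, names(df))
  if (length(missing_cols)) {
    stop("crosswalk file lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  mappings <- lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    rule <- tryCatch(parse_recode(row$recode), error = function(e) {
      stop("row ", i, ", column 'recode': ", conditionMessage(e),
           call. = FALSE)
    })
    opts <- tryCatch(parse_options(row$response_options), error = function(e) {
      stop("row ", i, ", column 'response_options': ", conditionMessage(e),
           call. = FALSE)
    })
    item_mapping(
      construct_id = row$construct_id, study_id = row$study_id,
      source_variable = row$source_variable, instrument = row$instrument,
      question_stem = row$question_stem, response_options = opts,
      missing_codes = parse_code_set(row$missing_codes),
      gate_variable = row$gate_variable,
      is_summary_score = toupper(trimws(row$is_summary_score)) %in%
        c("TRUE", "T", "1", "YES"),
      recode = rule)
  })
  crosswalk(mappings)
}

#' Write a crosswalk to delimited text
#'
#' Inverse of [read_crosswalk()]: `read_crosswalk(write_crosswalk(cw, f))`
#' reproduces the crosswalk field for field.
#'
#' @param cw a [crosswalk()].
#' @param path output file path.
#' @param delim field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_crosswalk <- function(cw, path, delim = "\t") {
  stopifnot(inherits(cw, "crosswalk"))
  utils::write.table(as.data.frame(cw), path, sep = delim, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Tabulate construct prevalence across studies
#'
#' Counts, for each number of studies `k`, how many constructs appear in
#' exactly `k` studies -- the "k-study overlap" summary that shows how
#' much linking information a pooled analysis will have.
#'
#' @param cw a [crosswalk()].
#' @return data frame with columns `n_studies` and `n_constructs`; the
#'   counts sum to the number of distinct constructs.
#' @export
item_prevalence <- function(cw) {
  stopifnot(inherits(cw, "crosswalk"))
  per <- table(vapply(cw$mappings, `[[`, character(1), "construct_id"))
  tab <- table(factor(as.integer(per), levels = seq_along(cw$studies)))
  data.frame(n_studies = as.integer(names(tab)),
             n_constructs = as.integer(tab))
}

#' Validate a crosswalk against study data
#'
#' Cross-checks the crosswalk's claims against the actual study tables:
#' flags mappings whose `source_variable` or `gate_variable` is absent
#' from the named study's columns (`missing_variable`), and raw codes
#' observed in the data but declared nowhere in the mapping's response
#' options or missing codes (`undeclared_code`). Findings are flags, not
#' exceptions: the crosswalk is corrected by its curator, not by code.
#'
#' @param cw a [crosswalk()].
#' @param datasets list of [study_dataset()] covering every study the
#'   crosswalk references.
#' @return QC flag data frame (zero rows when fully consistent).
#' @export
validate_crosswalk <- function(cw, datasets) {
  stopifnot(inherits(cw, "crosswalk"))
  by_study <- stats::setNames(datasets,
                              vapply(datasets, `[[`, character(1), "study_id"))
  missing_ds <- setdiff(cw$studies, names(by_study))
  if (length(missing_ds)) {
    stop("no dataset supplied for study(ies): ",
         paste(missing_ds, collapse = ", "), call. = FALSE)
  }
  flags <- list()
  for (m in cw$mappings) {
    ds <- by_study[[m$study_id]]
    cols <- names(ds$data)
    if (!m$source_variable %in% cols) {
      flags[[length(flags) + 1L]] <-
        qc_flag("missing_variable", m$construct_id, m$study_id,
                paste0("source variable '", m$source_variable,
                       "' not found in study columns"))
      next
    }
    if (nzchar(m$gate_variable) && !m$gate_variable %in% cols) {
      flags[[length(flags) + 1L]] <-
        qc_flag("missing_variable", m$construct_id, m$study_id,
                paste0("gate variable '", m$gate_variable,
                       "' not found in study columns"))
    }
    obs <- unique(ds$data[[m$source_variable]])
    obs <- obs[!is.na(obs)]
    undeclared <- setdiff(obs, c(m$response_options, m$missing_codes))
    if (length(undeclared)) {
      flags[[length(flags) + 1L]] <-
        qc_flag("undeclared_code", m$construct_id, m$study_id,
                paste0("observed raw code(s) ",
                       paste(sort(undeclared), collapse = ","),
                       " not declared in response_options or missing_codes"),
                value = length(undeclared))
    }
  }
  bind_flags(flags)
}

#' Study datasets
#'
#' One study's respondent-by-item table: the first column is the
#' respondent id, remaining columns are item variables (raw codes before
#' standardization, harmonized scores after). All item vectors share the
#' respondent dimension by construction.
#'
#' @param study_id source study label.
#' @param data data frame; first column respondent id.
#' @return an object of class `study_dataset`.
#' @export
study_dataset <- function(study_id, data) {
  stopifnot(is.character(study_id), length(study_id) == 1L,
            is.data.frame(data), ncol(data) >= 1L)
  structure(list(study_id = study_id, data = data), class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  cat("<study_dataset> ", x$study_id, ": ", nrow(x$data), " respondents x ",
      ncol(x$data) - 1L, " items\n", sep = "")
  invisible(x)
}

#' Read study data from delimited text
#'
#' @param path file path; first column respondent id, remaining columns
#'   raw item variables.
#' @param study_id label for the study.
#' @param delim field delimiter (default tab).
#' @return a [study_dataset()].
#' @export
read_study_data <- function(path, study_id, delim = "\t") {
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, sep = delim, stringsAsFactors = FALSE,
                          check.names = FALSE)
  study_dataset(study_id, df)
}

#' Write study data to delimited text
#'
#' @param ds a [study_dataset()].
#' @param path output file path.
#' @param delim field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_study_data <- function(ds, path, delim = "\t") {
  stopifnot(inherits(ds, "study_dataset"))
  utils::write.table(ds$data, path, sep = delim, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

item_columns <- function(ds) names(ds$data)[-1L]
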