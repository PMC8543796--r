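#' QC flags
#'
#' Every comparability problem the automated battery detects is recorded
#' as one flag: a kind, the construct and study concerned, a free-text
#' evidence string, and a numeric payload (e.g. the offending
#' correlation) sufficient to recompute the finding from the inputs.
#'
#' @param kind one of `missing_code`, `no_variability`,
#'   `scale_discrepancy`, `reverse_candidate`, `conditional_item`,
#'   `summary_score`, `sparse_cell`, `undeclared_code`,
#'   `missing_variable`.
#' @param construct_id,study_id identifiers (`study_id` may be
#'   `"pooled"` for cross-study findings).
#' @param evidence free-text description of the finding.
#' @param value optional numeric payload.
#' @return a one-row data frame of class `qc_flags`.
#' @export
qc_flag <- function(kind, construct_id, study_id, evidence,
                    value = NA_real_) {
  kinds <- c("missing_code", "no_variability", "scale_discrepancy",
             "reverse_candidate", "conditional_item", "summary_score",
             "sparse_cell", "undeclared_code", "missing_variable")
  kind <- match.arg(kind, kinds)
  structure(data.frame(kind = kind, construct_id = construct_id,
                       study_id = study_id, evidence = evidence,
                       value = as.numeric(value), stringsAsFactors = FALSE),
            class = c("qc_flags", "data.frame"))
}

bind_flags <- function(flags) {
  flags <- Filter(Negate(is.null), flags)
  if (!length(flags)) {
    return(structure(
      data.frame(kind = character(0), construct_id = character(0),
                 study_id = character(0), evidence = character(0),
                 value = numeric(0), stringsAsFactors = FALSE),
      class = c("qc_flags", "data.frame")))
  }
  structure(do.call(rbind, lapply(flags, as.data.frame)),
            class = c("qc_flags", "data.frame"))
}

#' Detect sentinel missing codes in a raw item
#'
#' Raw (pre-recode) values whose maximum lies in [90, 100] or that
#' contain negative values are, on the small behavioral scales handled
#' here, missing-data sentinels (96 = skipped, -5 = can't answer, and so
#' on) that must be masked by the crosswalk's recode map rather than
#' analyzed as scores. This check runs on raw codes only; harmonized
#' ranges are small by construction so the rule is never re-applied
#' downstream.
#'
#' @param raw_item raw integer vector for one item.
#' @param construct_id,study_id identifiers carried into the flag.
#' @return a one-row flag of kind `missing_code`, or `NULL` if clean.
#' @export
detect_missing_codes <- function(raw_item, construct_id = NA_character_,
                                 study_id = NA_character_) {
  v <- raw_item[!is.na(raw_item)]
  if (!length(v)) return(NULL)
  suspects <- integer(0)
  if (max(v) >= 90 && max(v) <= 100) {
    suspects <- c(suspects, unique(v[v >= 90 & v <= 100]))
  }
  if (any(v < 0)) suspects <- c(suspects, unique(v[v < 0]))
  if (!length(suspects)) return(NULL)
  qc_flag("missing_code", construct_id, study_id,
          paste0("suspect sentinel code(s): ",
                 paste(sort(unique(suspects)), collapse = ",")),
          value = length(unique(suspects)))
}

#' Detect items with no variability
#'
#' Flags an item whose non-missing minimum equals its maximum (a
#' constant item carries no information for a latent-trait model), or
#' that is entirely missing.
#'
#' @param item value vector (raw or harmonized).
#' @param construct_id,study_id identifiers carried into the flag.
#' @return a one-row flag of kind `no_variability`, or `NULL`.
#' @export
detect_no_variability <- function(item, construct_id = NA_character_,
                                  study_id = NA_character_) {
  v <- item[!is.na(item)]
  if (!length(v)) {
    return(qc_flag("no_variability", construct_id, study_id, "all missing"))
  }
  if (min(v) == max(v)) {
    return(qc_flag("no_variability", construct_id, study_id,
                   paste0("constant value ", v[1], " across ", length(v),
                          " non-missing responses"), value = v[1]))
  }
  NULL
}

#' Cross-tabulate item ranges across studies
#'
#' For every construct carried by two or more studies, tabulates the
#' observed (min, max) per study and flags the construct when the pair
#' is not identical across all studies carrying it -- the signature of
#' differential scoring (e.g. a 0-3 severity scale in one study against
#' a 0/1 presence code in another, or a 1-based scale).
#'
#' @param datasets list of [study_dataset()] (harmonized or raw).
#' @param cw a [crosswalk()]; constructs and membership are taken from it.
#' @return list with `table` (construct, study, min, max) and `flags`
#'   (kind `scale_discrepancy`, study `"pooled"`, one per discrepant
#'   construct).
#' @export
crosstab_ranges <- function(datasets, cw) {
  stopifnot(inherits(cw, "crosswalk"))
  by_study <- stats::setNames(datasets,
                              vapply(datasets, `[[`, character(1), "study_id"))
  rows <- list()
  for (m in cw$mappings) {
    if (isTRUE(m$is_summary_score)) next
    ds <- by_study[[m$study_id]]
    if (is.null(ds)) next
    col <- if (m$construct_id %in% names(ds$data)) m$construct_id
           else m$source_variable
    if (!col %in% names(ds$data)) next
    v <- ds$data[[col]]
    v <- v[!is.na(v)]
    if (!length(v)) next
    rows[[length(rows) + 1L]] <- data.frame(
      construct_id = m$construct_id, study_id = m$study_id,
      min = min(v), max = max(v), stringsAsFactors = FALSE)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(construct_id = character(0), study_id = character(0),
               min = numeric(0), max = numeric(0), stringsAsFactors = FALSE)
  flags <- list()
  for (con in unique(tab$construct_id)) {
    sub <- tab[tab$construct_id == con, ]
    if (nrow(sub) < 2L) next
    if (length(unique(paste(sub$min, sub$max))) > 1L) {
      ev <- paste(sprintf("%s:[%g,%g]", sub$study_id, sub$min, sub$max),
                  collapse = " ")
      flags[[length(flags) + 1L]] <-
        qc_flag("scale_discrepancy", con, "pooled",
                paste0("(min,max) differs across studies: ", ev))
    }
  }
  list(table = tab, flags = bind_flags(flags))
}

pairwise_cor <- function(mat, min_overlap) {
  obs <- !is.na(mat)
  n_pair <- crossprod(obs)
  r <- suppressWarnings(stats::cor(mat, use = "pairwise.complete.obs"))
  r[n_pair < min_overlap] <- NA
  diag(r) <- NA
  list(r = r, n = n_pair)
}

#' Flag reverse-coding candidates
#'
#' Computes the within-study item intercorrelation matrix (Pearson,
#' pairwise-complete) and flags any item whose correlation with at least
#' one other item falls below `threshold` (default -0.2). If not by
#' chance, a sizable negative correlation indicates an item coded in the
#' opposite direction from the rest of the battery. Pairs with fewer
#' than `min_overlap` complete observations are skipped (skip patterns
#' create blockwise missingness). The flag reports the most negative
#' partner, the correlation, and the pair count; reversal itself is a
#' curator decision recorded in the crosswalk, never automatic.
#'
#' @param ds a [study_dataset()] of harmonized items.
#' @param threshold correlation below which an item is flagged.
#' @param min_overlap minimum pairwise-complete observations per pair.
#' @return QC flag data frame (kind `reverse_candidate`).
#' @export
detect_reverse_candidates <- function(ds, threshold = -0.2,
                                      min_overlap = 20L) {
  stopifnot(inherits(ds, "study_dataset"))
  items <- item_columns(ds)
  mat <- as.matrix(ds$data[, items, drop = FALSE])
  storage.mode(mat) <- "double"
  varying <- vapply(items, function(j) {
    v <- mat[, j]; v <- v[!is.na(v)]
    length(v) > 0L && min(v) != max(v)
  }, logical(1))
  mat <- mat[, varying, drop = FALSE]
  if (ncol(mat) < 2L) {
    warning("fewer than 2 items with variability; no correlations computed",
            call. = FALSE)
    return(bind_flags(list()))
  }
  pc <- pairwise_cor(mat, min_overlap)
  flags <- list()
  for (j in colnames(pc$r)) {
    rj <- pc$r[j, ]
    if (all(is.na(rj))) next
    rmin <- min(rj, na.rm = TRUE)
    if (rmin < threshold) {
      partner <- names(which.min(rj))
      flags[[length(flags) + 1L]] <-
        qc_flag("reverse_candidate", j, ds$study_id,
                paste0("r(", j, ", ", partner, ") = ",
                       formatC(rmin, digits = 3, format = "f"), " over ",
                       pc$n[j, partner], " pairs"),
                value = rmin)
    }
  }
  bind_flags(flags)
}

#' Exclude conditional (gated) items
#'
#' Removes every item whose crosswalk mapping declares a gate variable.
#' Items administered only given a particular response to another item
#' (severity or frequency follow-ups behind a presence screener) are
#' logically dependent on their gate: they duplicate its information and
#' inflate apparent reliability, so they are excluded before model
#' fitting. Gate cycles are a structural error in the crosswalk.
#'
#' @param ds a [study_dataset()].
#' @param cw a [crosswalk()].
#' @return list with `dataset` (gated items removed) and `flags` (one
#'   `conditional_item` flag per removed item).
#' @export
exclude_conditional <- function(ds, cw) {
  stopifnot(inherits(ds, "study_dataset"), inherits(cw, "crosswalk"))
  maps <- Filter(function(m) m$study_id == ds$study_id, cw$mappings)
  src <- vapply(maps, `[[`, character(1), "source_variable")
  gate <- vapply(maps, `[[`, character(1), "gate_variable")
  con <- vapply(maps, `[[`, character(1), "construct_id")
  # cycle check on the gate graph (edges follow-up -> gate)
  edge_from <- src[nzchar(gate)]
  edge_to <- gate[nzchar(gate)]
  if (length(edge_from)) {
    for (start in edge_from) {
      seen <- character(0); cur <- start
      while (cur %in% edge_from) {
        if (cur %in% seen) {
          stop("gate cycle detected involving variable '", cur, "'",
               call. = FALSE)
        }
        seen <- c(seen, cur)
        cur <- edge_to[match(cur, edge_from)]
      }
    }
  }
  gated <- nzchar(gate)
  flags <- lapply(which(gated), function(i) {
    qc_flag("conditional_item", con[i], ds$study_id,
            paste0("item '", src[i], "' conditional on gate '", gate[i],
                   "'; excluded as redundant"))
  })
  drop_cols <- intersect(c(src[gated], con[gated]), names(ds$data)[-1L])
  data <- ds$data[, !(names(ds$data) %in% drop_cols), drop = FALSE]
  list(dataset = study_dataset(ds$study_id, data), flags = bind_flags(flags))
}

#' Per-item endorsement and frequency report
#'
#' Tabulates, for every item in a study, the exact category counts, the
#' missing proportion, and (for the non-missing values) the endorsement
#' rate -- the mean, which for binary items is the proportion endorsed.
#' Used to spot skewness, rare symptoms, and excess missingness before
#' model fitting.
#'
#' @param ds a [study_dataset()].
#' @return data frame with one row per item: `construct_id`, `n`,
#'   `n_missing`, `prop_missing`, `endorsement`, `counts` (text
#'   `value:count` pairs).
#' @export
endorsement_report <- function(ds) {
  stopifnot(inherits(ds, "study_dataset"))
  items <- item_columns(ds)
  n <- nrow(ds$data)
  do.call(rbind, lapply(items, function(j) {
    v <- ds$data[[j]]
    nm <- v[!is.na(v)]
    counts <- table(nm)
    data.frame(
      construct_id = j, n = n, n_missing = n - length(nm),
      prop_missing = (n - length(nm)) / n,
      endorsement = if (length(nm)) mean(nm) else NA_real_,
      counts = paste(paste0(names(counts), ":", as.integer(counts)),
                     collapse = " "),
      stringsAsFactors = FALSE)
  }))
}

#' Summarize flags per study and kind
#'
#' @param flags a QC flag data frame (e.g. the `flags` element of a
#'   [run_pipeline()] manifest).
#' @return data frame with columns `study_id`, `kind`, `n`, `constructs`.
#' @export
summarize_flags <- function(flags) {
  if (!nrow(flags)) {
    return(data.frame(study_id = character(0), kind = character(0),
                      n = integer(0), constructs = character(0),
                      stringsAsFactors = FALSE))
  }
  key <- paste(flags$study_id, flags$kind, sep = "\r")
  out <- do.call(rbind, lapply(unique(key), function(k) {
    sub <- flags[key == k, ]
    data.frame(study_id = sub$study_id[1], kind = sub$kind[1],
               n = nrow(sub),
               constructs = paste(sort(unique(sub$construct_id)),
                                  collapse = ","),
               stringsAsFactors = FALSE)
  }))
  out[order(out$study_id, out$kind), , drop = FALSE]
}
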