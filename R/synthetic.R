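#' Generator configuration for synthetic multi-study item banks
#'
#' Describes a bank of latent-trait items administered across several
#' studies, plus the planted cross-study pathologies the QC battery is
#' meant to catch. Responses follow a unidimensional logistic
#' latent-trait model: binary items are 2PL, ordinal items follow the
#' graded mechanism (a logistic latent response cut at evenly spaced
#' thresholds around the item difficulty). Defects are applied after
#' response generation, so every defect has an exact truth record.
#'
#' @param studies data frame with columns `study_id`, `n`.
#' @param items data frame with columns `construct_id`, `a`
#'   (discrimination, > 0), `b` (difficulty), `n_levels` (2 = binary,
#'   k > 2 = k-level ordinal).
#' @param membership named list: `construct_id` -> character vector of
#'   the studies carrying the item. Defaults to every item in every
#'   study.
#' @param defects list with any of:
#' * `reversed`: data frame (`construct_id`, `study_id`) -- the study
#'   stores the item with flipped polarity;
#' * `sentinels`: named list `study_id -> list(codes, rate)` -- a
#'   fraction `rate` of responses is replaced by a sentinel code;
#' * `one_based`: character vector of studies whose raw codes start at 1;
#' * `gated`: data frame (`gate_construct`, `follow_construct`,
#'   `study_id`) -- the follow-up is missing whenever the gate is 0, and
#'   the crosswalk declares the skip pattern;
#' * `constant`: data frame (`construct_id`, `study_id`, `value`) -- the
#'   item is overwritten with a constant;
#' * `couplets`: data frame (`construct_1`, `construct_2`, `loading`,
#'   `study_id`) -- the pair shares a specific factor with the given
#'   standardized loading on the latent-response scale (local
#'   dependence);
#' * `scale_override`: data frame (`construct_id`, `study_id`,
#'   `n_levels`) -- the study scores the item on a different number of
#'   levels (a planted scale discrepancy);
#' * `summary_scores`: data frame (`construct_id`, `study_id`) -- an
#'   extra column holding the row sum of the study's items, marked
#'   `is_summary_score` in the crosswalk.
#' @param seed integer seed; generation is fully reproducible from it.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(studies, items, membership = NULL,
                             defects = list(), seed = 1L) {
  stopifnot(is.data.frame(studies), all(c("study_id", "n") %in% names(studies)),
            is.data.frame(items),
            all(c("construct_id", "a", "b", "n_levels") %in% names(items)))
  if (any(items$a <= 0)) stop("discriminations must be positive", call. = FALSE)
  if (is.null(membership)) {
    membership <- stats::setNames(
      rep(list(studies$study_id), nrow(items)), items$construct_id)
  }
  stopifnot(all(names(membership) %in% items$construct_id))
  known <- list(reversed = NULL, sentinels = NULL, one_based = NULL,
                gated = NULL, constant = NULL, couplets = NULL,
                scale_override = NULL, summary_scores = NULL)
  bad <- setdiff(names(defects), names(known))
  if (length(bad)) stop("unknown defect class(es): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  check_ref <- function(df, what) {
    if (is.null(df)) return()
    if ("construct_id" %in% names(df) &&
        !all(df$construct_id %in% items$construct_id)) {
      stop(what, " references unknown construct(s)", call. = FALSE)
    }
    if ("study_id" %in% names(df) && !all(df$study_id %in% studies$study_id)) {
      stop(what, " references unknown study(ies)", call. = FALSE)
    }
  }
  check_ref(defects$reversed, "reversed")
  check_ref(defects$constant, "constant")
  check_ref(defects$scale_override, "scale_override")
  if (!is.null(defects$one_based) &&
      !all(defects$one_based %in% studies$study_id)) {
    stop("one_based references unknown study(ies)", call. = FALSE)
  }
  if (!is.null(defects$sentinels) &&
      !all(names(defects$sentinels) %in% studies$study_id)) {
    stop("sentinels references unknown study(ies)", call. = FALSE)
  }
  if (!is.null(defects$gated)) {
    g <- defects$gated
    if (!all(c(g$gate_construct, g$follow_construct) %in% items$construct_id) ||
        !all(g$study_id %in% studies$study_id)) {
      stop("gated references unknown construct(s) or study(ies)",
           call. = FALSE)
    }
  }
  if (!is.null(defects$couplets)) {
    cp <- defects$couplets
    if (!all(c(cp$construct_1, cp$construct_2) %in% items$construct_id)) {
      stop("couplets reference unknown construct(s)", call. = FALSE)
    }
    if (any(cp$loading <= 0 | cp$loading >= 1)) {
      stop("couplet loadings must lie in (0, 1)", call. = FALSE)
    }
  }
  if (!is.null(defects$reversed) && !is.null(defects$constant)) {
    clash <- merge(defects$reversed, defects$constant,
                   by = c("construct_id", "study_id"))
    if (nrow(clash)) {
      stop("impossible defect combination: item(s) both constant and ",
           "reversed in the same study: ",
           paste(clash$construct_id, clash$study_id, sep = "/",
                 collapse = ", "), call. = FALSE)
    }
  }
  structure(list(studies = studies, items = items, membership = membership,
                 defects = defects, seed = as.integer(seed)),
            class = "generator_config")
}

df_or_empty <- function(df, cols) {
  if (is.null(df)) {
    as.data.frame(stats::setNames(rep(list(character(0)), length(cols)), cols),
                  stringsAsFactors = FALSE)
  } else df
}

#' Generate a synthetic multi-study item bank
#'
#' Draws a standard-normal latent trait per respondent per study,
#' generates item responses from the configured 2PL / graded model (with
#' couplet pairs sharing an extra specific factor), then applies planted
#' defects to the raw coding: reversal flips codes, one-based studies
#' shift codes up by 1, sentinel codes replace a configured fraction of
#' responses, gated follow-ups are missing-coded when the gate is 0,
#' constant items are overwritten. Alongside the raw-coded study tables
#' it emits two crosswalks and the truth record.
#'
#' The `crosswalk` element is the fully curated crosswalk: its recode
#' maps mask sentinels, shift one-based codes down, and undo planted
#' reversals, so standardizing with it recovers the model-scale
#' responses (the pipeline round-trip used for parameter recovery). The
#' `naive_crosswalk` is the pre-curation counterpart -- sentinel masking
#' and zero-basing only, reversals left in place -- emulating a first
#' documentation pass before directionality review; QC on naively
#' standardized data should recover the planted reversals.
#'
#' @param config a [generator_config()].
#' @return list with `datasets` (raw-coded [study_dataset()]s),
#'   `crosswalk`, `naive_crosswalk`, and `truth` (the planted-defect
#'   record plus the generating item parameters).
#' @export
generate_item_bank <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  items <- config$items
  d <- config$defects
  gated <- df_or_empty(d$gated, c("gate_construct", "follow_construct",
                                  "study_id"))
  reversed <- df_or_empty(d$reversed, c("construct_id", "study_id"))
  constant <- df_or_empty(d$constant, c("construct_id", "study_id", "value"))
  couplets <- df_or_empty(d$couplets, c("construct_1", "construct_2",
                                        "loading", "study_id"))
  override <- df_or_empty(d$scale_override,
                          c("construct_id", "study_id", "n_levels"))
  summaries <- df_or_empty(d$summary_scores, c("construct_id", "study_id"))
  one_based <- d$one_based %||% character(0)
  sentinels <- d$sentinels %||% list()

  datasets <- list()
  cw_rows_truth <- list()
  cw_rows_naive <- list()

  for (si in seq_len(nrow(config$studies))) {
    study <- config$studies$study_id[si]
    n <- config$studies$n[si]
    theta <- stats::rnorm(n)
    in_study <- vapply(items$construct_id, function(cid) {
      study %in% config$membership[[cid]]
    }, logical(1))
    study_items <- items[in_study, , drop = FALSE]
    follows <- gated$follow_construct[gated$study_id == study]
    # generation order: regular items first, gated follow-ups after
    ord <- order(study_items$construct_id %in% follows)
    study_items <- study_items[ord, , drop = FALSE]

    # shared specific factors for couplet pairs active in this study
    cp <- couplets[couplets$study_id == study | is.na(couplets$study_id), ,
                   drop = FALSE]
    u <- if (nrow(cp)) {
      matrix(stats::rnorm(n * nrow(cp)), n, nrow(cp))
    } else matrix(0, n, 0)
    couplet_slope <- function(cid, a) {
      hit <- which(cp$construct_1 == cid | cp$construct_2 == cid)
      if (!length(hit)) return(list(idx = 0L, gamma = 0))
      lam <- cp$loading[hit[1]]
      # standardized loading lam on the logistic latent-response scale
      gamma <- sqrt(lam^2 * (a^2 + pi^2 / 3) / (1 - lam^2))
      list(idx = hit[1], gamma = gamma)
    }

    harm <- list()   # model-scale (harmonized-truth) values
    for (k in seq_len(nrow(study_items))) {
      cid <- study_items$construct_id[k]
      a <- study_items$a[k]; b <- study_items$b[k]
      nl <- study_items$n_levels[k]
      ov <- override[override$construct_id == cid &
                       override$study_id == study, , drop = FALSE]
      if (nrow(ov)) nl <- ov$n_levels[1]
      cs <- couplet_slope(cid, a)
      z <- a * theta + stats::rlogis(n)
      if (cs$idx > 0L) z <- z + cs$gamma * u[, cs$idx]
      taus <- b + ((seq_len(nl - 1L)) - nl / 2) * 0.8
      v <- rowSums(outer(z, a * taus, ">"))
      gi <- which(gated$follow_construct == cid & gated$study_id == study)
      if (length(gi)) {
        gate_v <- harm[[gated$gate_construct[gi[1]]]]
        v[is.na(gate_v) | gate_v == 0L] <- NA_integer_
      }
      if (nrow(constant[constant$construct_id == cid &
                          constant$study_id == study, , drop = FALSE])) {
        v <- rep(as.integer(constant$value[constant$construct_id == cid &
                                             constant$study_id == study][1]),
                 n)
      }
      harm[[cid]] <- as.integer(v)
    }

    # raw coding: reversal, then one-based shift, then sentinel injection
    shift <- as.integer(study %in% one_based)
    sent <- sentinels[[study]]
    raw <- list()
    maxlev <- integer(0)
    for (cid in names(harm)) {
      nl <- study_items$n_levels[match(cid, study_items$construct_id)]
      ov <- override[override$construct_id == cid &
                       override$study_id == study, , drop = FALSE]
      if (nrow(ov)) nl <- ov$n_levels[1]
      L <- nl - 1L
      v <- harm[[cid]]
      rev_here <- nrow(reversed[reversed$construct_id == cid &
                                  reversed$study_id == study, ,
                                drop = FALSE]) > 0L
      r <- if (rev_here) L - v else v
      r <- r + shift
      if (!is.null(sent) && sent$rate > 0) {
        hit <- stats::runif(n) < sent$rate
        hit[is.na(r)] <- FALSE   # skip-pattern blanks stay blank
        r[hit] <- sample(as.integer(sent$codes), sum(hit), replace = TRUE)
      }
      raw[[cid]] <- r
      maxlev[cid] <- L
    }

    # summary-score columns: row sums of the study's item-level values
    for (cid in summaries$construct_id[summaries$study_id == study]) {
      mat <- do.call(cbind, harm)
      raw[[cid]] <- as.integer(rowSums(mat, na.rm = TRUE))
      maxlev[cid] <- sum(maxlev[names(harm)])
    }

    src <- stats::setNames(sprintf("v%02d", seq_along(raw)), names(raw))
    data <- as.data.frame(c(list(respondent_id = sprintf("%s_%04d", study,
                                                         seq_len(n))),
                            stats::setNames(raw, src[names(raw)])),
                          stringsAsFactors = FALSE, check.names = FALSE)
    datasets[[study]] <- study_dataset(study, data)

    # crosswalk rows
    for (cid in names(raw)) {
      is_sum <- cid %in% summaries$construct_id[summaries$study_id == study]
      L <- maxlev[cid]
      codes <- (0:L) + if (is_sum) 0L else shift
      rev_here <- !is_sum &&
        nrow(reversed[reversed$construct_id == cid &
                        reversed$study_id == study, , drop = FALSE]) > 0L
      harm_truth <- if (is_sum) codes else {
        h <- codes - shift
        if (rev_here) L - h else h
      }
      harm_naive <- if (is_sum) codes else codes - shift
      scodes <- if (!is_sum && !is.null(sent)) as.integer(sent$codes)
                else integer(0)
      gi <- which(gated$follow_construct == cid & gated$study_id == study)
      gv <- if (length(gi)) {
        src[[gated$gate_construct[gi[1]]]]
      } else ""
      mk_row <- function(harm_target) {
        item_mapping(
          construct_id = cid, study_id = study,
          source_variable = src[[cid]],
          instrument = "SYNTH",
          question_stem = paste0("synthetic item ", cid),
          response_options = stats::setNames(codes, paste0("lvl", harm_target)),
          missing_codes = scodes,
          gate_variable = gv,
          is_summary_score = is_sum,
          recode = recode_rule(c(codes, scodes),
                               c(harm_target,
                                 rep(NA_integer_, length(scodes)))))
      }
      cw_rows_truth[[length(cw_rows_truth) + 1L]] <- mk_row(harm_truth)
      cw_rows_naive[[length(cw_rows_naive) + 1L]] <- mk_row(harm_naive)
    }
  }

  list(datasets = datasets,
       crosswalk = crosswalk(cw_rows_truth),
       naive_crosswalk = crosswalk(cw_rows_naive),
       truth = list(items = items, membership = config$membership,
                    reversed = reversed, sentinels = sentinels,
                    one_based = one_based, gated = gated,
                    constant = constant, couplets = couplets,
                    scale_override = override, summary_scores = summaries,
                    seed = config$seed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default multi-study bank configuration
#'
#' The standard synthetic study conditions used throughout the package's
#' validation: three studies of equal size, sixteen binary 2PL items
#' with discriminations spread over [1, 2.5] and difficulties over
#' [-1.5, 1.5], one ordinal item scored on 4 levels in one study but
#' binary in another (a scale discrepancy), and one planted defect of
#' every remaining class -- four reversed items and ADAMS-style sentinel
#' codes 96-99 in study_a, a DEMQOL-style -5 sentinel, one-based coding
#' and a constant item in study_b, three gated severity follow-ups and a
#' local-dependence couplet (standardized specific loading 0.6) in
#' study_c, and a summary-score column in study_a. Sentinels replace 5%
#' of responses.
#'
#' @param seed integer seed.
#' @param n_per_study respondents per study (default 1000).
#' @return a [generator_config()].
#' @export
default_bank_config <- function(seed = 1L, n_per_study = 1000L) {
  core <- sprintf("bsx%02d", 1:16)
  scramble <- (seq_along(core) * 7L) %% 16L + 1L
  items <- data.frame(
    construct_id = c(core, "lik01", sprintf("f%02d", 1:3)),
    a = c(seq(1, 2.5, length.out = 16), 1.6, rep(1.4, 3)),
    b = c(seq(-1.5, 1.5, length.out = 16)[scramble], 0.3, rep(0.2, 3)),
    n_levels = c(rep(2L, 16), 4L, rep(3L, 3)),
    stringsAsFactors = FALSE)
  studies <- data.frame(study_id = c("study_a", "study_b", "study_c"),
                        n = rep(as.integer(n_per_study), 3),
                        stringsAsFactors = FALSE)
  membership <- c(
    stats::setNames(rep(list(studies$study_id), 16), core),
    list(lik01 = c("study_a", "study_c"),
         f01 = "study_c", f02 = "study_c", f03 = "study_c"))
  defects <- list(
    reversed = data.frame(construct_id = c("bsx02", "bsx04", "bsx07", "bsx09"),
                          study_id = "study_a", stringsAsFactors = FALSE),
    sentinels = list(study_a = list(codes = 96:99, rate = 0.05),
                     study_b = list(codes = -5L, rate = 0.05)),
    one_based = "study_b",
    gated = data.frame(gate_construct = c("bsx01", "bsx02", "bsx03"),
                       follow_construct = c("f01", "f02", "f03"),
                       study_id = "study_c", stringsAsFactors = FALSE),
    constant = data.frame(construct_id = "bsx11", study_id = "study_b",
                          value = 0L, stringsAsFactors = FALSE),
    couplets = data.frame(construct_1 = "bsx05", construct_2 = "bsx06",
                          loading = 0.6, study_id = "study_c",
                          stringsAsFactors = FALSE),
    scale_override = data.frame(construct_id = "lik01", study_id = "study_a",
                                n_levels = 2L, stringsAsFactors = FALSE),
    summary_scores = data.frame(construct_id = "summary01",
                                study_id = "study_a",
                                stringsAsFactors = FALSE))
  generator_config(studies, items, membership, defects, seed)
}

#' Write an item bank to disk in the formats the crosswalk module reads
#'
#' @param bank result of [generate_item_bank()].
#' @param dir output directory (created if needed).
#' @return named list of written paths, invisibly.
#' @export
write_item_bank <- function(bank, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(crosswalk = file.path(dir, "crosswalk.tsv"),
                naive_crosswalk = file.path(dir, "crosswalk_naive.tsv"),
                truth = file.path(dir, "truth.json"))
  write_crosswalk(bank$crosswalk, paths$crosswalk)
  write_crosswalk(bank$naive_crosswalk, paths$naive_crosswalk)
  jsonlite::write_json(bank$truth, paths$truth, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  for (ds in bank$datasets) {
    p <- file.path(dir, paste0(ds$study_id, ".tsv"))
    write_study_data(ds, p)
    paths[[ds$study_id]] <- p
  }
  invisible(paths)
}
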