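#' Recode rules
#'
#' A recode rule is a finite, total map from the raw integer codes a study
#' uses for an item to harmonized non-negative integer scores, with a
#' dedicated missing marker (`NA`) for codes that denote non-response.
#' Rules are the declarative equivalent of per-item recode syntax: applying
#' one is deterministic and auditable, and sentinel codes such as 96--99 or
#' -5 can never leak into analysis as numbers because they map to `NA`
#' at the boundary.
#'
#' @param raw integer vector of raw codes (no duplicates).
#' @param harmonized integer vector of the same length; `NA` marks codes
#'   that mean "missing". Non-missing targets must be non-negative and,
#'   when any exist, include 0 as the minimum.
#' @return An object of class `recode_rule` with elements `raw`,
#'   `harmonized` and `declared_range` (the `(min, max)` of non-missing
#'   harmonized scores, or `c(NA, NA)` if all codes map to missing).
#' @examples
#' r <- recode_rule(c(1L, 5L, 6L, 96L, 97L, 98L, 99L),
#'                  c(1L, 0L, NA, NA, NA, NA, NA))
#' apply_recode(c(1, 5, 96, 98), r)
#' @export
recode_rule <- function(raw, harmonized) {
  raw <- as.integer(raw)
  harmonized <- as.integer(harmonized)
  if (length(raw) != length(harmonized)) {
    stop("`raw` and `harmonized` must have the same length", call. = FALSE)
  }
  if (anyNA(raw)) stop("raw codes must be integers, not NA", call. = FALSE)
  if (anyDuplicated(raw)) {
    stop("duplicate raw code(s) in recode rule: ",
         paste(unique(raw[duplicated(raw)]), collapse = ", "), call. = FALSE)
  }
  hs <- harmonized[!is.na(harmonized)]
  if (length(hs)) {
    if (any(hs < 0L)) stop("harmonized scores must be non-negative", call. = FALSE)
    if (min(hs) != 0L) {
      stop("harmonized scores must start at 0 (got minimum ", min(hs), ")",
           call. = FALSE)
    }
    rng <- c(0L, max(hs))
  } else {
    rng <- c(NA_integer_, NA_integer_)
  }
  ord <- order(raw)   # canonical order, so round-trips are field-identical
  structure(list(raw = raw[ord], harmonized = harmonized[ord],
                 declared_range = rng),
            class = "recode_rule")
}

#' Parse the compact recode mini-grammar
#'
#' Recode maps travel in crosswalk cells as text of the form
#' `"1->1;5->0;6,96,97,98,99->NA"`: semicolon-separated clauses, each
#' mapping a comma-separated list of raw integer codes to one harmonized
#' integer score or to the missing token `NA`.
#'
#' @param text a single recode string.
#' @return a [recode_rule()].
#' @seealso [format_recode()] for the inverse.
#' @export
parse_recode <- function(text) {
  if (length(text) != 1L || is.na(text) || !nzchar(trimws(text))) {
    stop("recode string is empty", call. = FALSE)
  }
  clauses <- strsplit(trimws(text), ";", fixed = TRUE)[[1]]
  raw <- integer(0)
  harm <- integer(0)
  for (cl in clauses) {
    parts <- strsplit(trimws(cl), "->", fixed = TRUE)[[1]]
    if (length(parts) != 2L) {
      stop("unparseable recode clause '", cl, "' in \"", text, "\"",
           call. = FALSE)
    }
    codes <- trimws(strsplit(parts[1], ",", fixed = TRUE)[[1]])
    tgt <- trimws(parts[2])
    codes_i <- suppressWarnings(as.integer(codes))
    if (anyNA(codes_i) || any(codes_i != suppressWarnings(as.numeric(codes)))) {
      stop("non-integer raw code in recode clause '", cl, "'", call. = FALSE)
    }
    if (identical(toupper(tgt), "NA")) {
      tgt_i <- NA_integer_
    } else {
      tgt_i <- suppressWarnings(as.integer(tgt))
      if (is.na(tgt_i) || tgt_i != suppressWarnings(as.numeric(tgt))) {
        stop("non-integer harmonized target in recode clause '", cl, "'",
             call. = FALSE)
      }
    }
    raw <- c(raw, codes_i)
    harm <- c(harm, rep(tgt_i, length(codes_i)))
  }
  recode_rule(raw, harm)
}

#' Serialize a recode rule to the compact text form
#'
#' Codes are grouped by harmonized target and targets emitted in
#' ascending order with `NA` last, so the representation is canonical:
#' `parse_recode(format_recode(r))` reproduces `r` up to code order.
#'
#' @param rule a [recode_rule()].
#' @return a single string in the recode mini-grammar.
#' @export
format_recode <- function(rule) {
  stopifnot(inherits(rule, "recode_rule"))
  key <- ifelse(is.na(rule$harmonized), "NA", as.character(rule$harmonized))
  ord <- order(is.na(rule$harmonized), rule$harmonized, method = "radix")
  raw <- rule$raw[ord]
  key <- key[ord]
  clauses <- vapply(unique(key), function(k) {
    paste0(paste(sort(raw[key == k]), collapse = ","), "->", k)
  }, character(1))
  paste(clauses, collapse = ";")
}

#' @export
print.recode_rule <- function(x, ...) {
  cat("<recode_rule> ", format_recode(x), "\n", sep = "")
  invisible(x)
}

#' Apply a recode rule to raw values
#'
#' Element-wise, deterministic application of a [recode_rule()]. Raw `NA`
#' (a truly absent response) stays `NA`; sentinel codes become `NA` via
#' the rule. Any observed raw code outside the rule's domain is an error
#' (the crosswalk must be corrected, not the data coerced).
#'
#' @param raw_values vector of raw integer codes (may contain `NA`).
#' @param rule a [recode_rule()].
#' @return integer vector of harmonized scores, same length as input.
#' @export
apply_recode <- function(raw_values, rule) {
  stopifnot(inherits(rule, "recode_rule"))
  v <- as.integer(raw_values)
  obs <- v[!is.na(v)]
  bad <- setdiff(unique(obs), rule$raw)
  if (length(bad)) {
    freq <- table(obs[obs %in% bad])
    stop("raw code(s) outside recode domain: ",
         paste(sprintf("%s (n=%d)", names(freq), as.integer(freq)),
               collapse = ", "), call. = FALSE)
  }
  out <- rep(NA_integer_, length(v))
  ok <- !is.na(v)
  out[ok] <- rule$harmonized[match(v[ok], rule$raw)]
  out
}
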