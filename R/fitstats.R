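# Limited-information fit machinery for binary items.
#
# Full-information Pearson chi-square over the 2^J response-pattern table
# is degenerate at realistic sample sizes, so model fit is assessed on the
# univariate and bivariate margins: the M2-type quadratic form
#   M2 = n (p - pi)' C2 (p - pi)
# with p the stacked sample proportions (J univariate + J(J-1)/2
# bivariate), pi the model-implied values, and
#   C2 = Xi^-1 - Xi^-1 D (D' Xi^-1 D)^-1 D' Xi^-1
# where Xi is the asymptotic covariance of sqrt(n) p under the model
# (Xi_rs = pi_{r u s} - pi_r pi_s, a union of at most four items, computed
# by quadrature) and D is the Jacobian of the margins with respect to the
# item parameters. M2 is asymptotically chi-square with
# df = J + J(J-1)/2 - (number of parameters).

margin_sets <- function(J) {
  uni <- lapply(seq_len(J), function(j) j)
  pairs <- utils::combn(J, 2, simplify = FALSE)
  c(uni, pairs)
}

# model-implied probability that all items in `set` are 1, by quadrature
pi_union <- function(set, logP, w) {
  sum(w * exp(colSums(logP[set, , drop = FALSE])))
}

margin_moments <- function(P, w) {
  # P: J x K item curves at the quadrature nodes; returns pi (length s),
  # Xi (s x s) for the stacked univariate + bivariate margins
  J <- nrow(P); K <- ncol(P)
  sets <- margin_sets(J)
  s <- length(sets)
  logP <- log(pmin(pmax(P, 1e-300), 1))
  pi <- vapply(sets, pi_union, numeric(1), logP = logP, w = w)
  # disjoint margins: pi_{r u s} = sum_k w C_r C_s with C the margin curves
  Cmat <- exp(do.call(rbind, lapply(sets, function(st) {
    colSums(logP[st, , drop = FALSE])
  })))
  U <- Cmat %*% (w * t(Cmat))
  # overlapping margins need the shared items counted once, not twice
  for (r in seq_len(s)) {
    for (q in r:s) {
      shared <- intersect(sets[[r]], sets[[q]])
      if (length(shared)) {
        un <- union(sets[[r]], sets[[q]])
        U[r, q] <- U[q, r] <- pi_union(un, logP, w)
      }
    }
  }
  list(pi = pi, Xi = U - tcrossprod(pi), sets = sets)
}

jacobian_2pl <- function(a, b, nodes, w) {
  J <- length(a)
  P <- irf_2pl(nodes, a, b)
  pq <- P * (1 - P)
  Da <- sweep(pq, 2, nodes, "*") - b * pq       # dP/da = (theta - b) P(1-P)
  Db <- -a * pq                                 # dP/db = -a P(1-P)
  sets <- margin_sets(J)
  s <- length(sets)
  Delta <- matrix(0, s, 2L * J)
  for (r in seq_len(s)) {
    st <- sets[[r]]
    for (j in st) {
      others <- setdiff(st, j)
      base <- if (length(others)) P[others, ] else rep(1, ncol(P))
      Delta[r, j] <- sum(w * base * Da[j, ])
      Delta[r, J + j] <- sum(w * base * Db[j, ])
    }
  }
  Delta
}

sample_margins <- function(y) {
  # univariate means and pairwise-complete joint endorsement proportions
  J <- ncol(y)
  O <- !is.na(y); Y0 <- y; Y0[!O] <- 0
  p1 <- colSums(Y0) / colSums(O)
  n11 <- crossprod(Y0)
  npair <- crossprod(O)
  sets <- margin_sets(J)
  p <- numeric(length(sets))
  p[seq_len(J)] <- p1
  for (r in (J + 1L):length(sets)) {
    ij <- sets[[r]]
    p[r] <- n11[ij[1], ij[2]] / npair[ij[1], ij[2]]
  }
  list(p = p, n_eff = stats::median(npair[upper.tri(npair)]))
}

m2_quadform <- function(e, Xi, Delta, n) {
  solve_pd <- function(A, x) {
    tryCatch(solve(A, x), error = function(err) {
      solve(A + diag(1e-10 * mean(diag(A)), nrow(A)), x)
    })
  }
  Xie <- solve_pd(Xi, e)
  XiD <- solve_pd(Xi, Delta)
  middle <- crossprod(Delta, XiD)
  rhs <- crossprod(Delta, Xie)
  n * (sum(e * Xie) - sum(rhs * solve_pd(middle, rhs)))
}

#' Limited-information fit statistics for a 2PL fit
#'
#' Computes the M2 statistic over univariate and bivariate margins, and
#' from it RMSEA, CFI and SRMR:
#' * `rmsea = sqrt(max(M2 - df, 0) / (df * n))`;
#' * `cfi = 1 - max(M2 - df, 0) / max(M2_b - df_b, 0)`, with the mutual
#'   independence model (free per-item thresholds, no latent trait) as
#'   baseline -- `NA` when the baseline itself fits (denominator 0);
#' * `srmr` = root mean square of the residual inter-item correlations
#'   (observed minus model-implied Pearson correlations of the binary
#'   items).
#' With missing data, margins are pairwise-complete and the effective n
#' is the median pairwise count.
#'
#' @param fit an [fit_2pl()] result.
#' @param responses the binary response matrix the model was fit to.
#' @return an object of class `fit_stats`: `m2`, `df`, `m2_baseline`,
#'   `df_baseline`, `rmsea`, `cfi`, `srmr`, `n`, plus `labels` from
#'   [classify_fit()].
#' @export
fit_statistics <- function(fit, responses) {
  stopifnot(inherits(fit, "irt_fit"))
  y <- as.matrix(responses); storage.mode(y) <- "double"
  J <- ncol(y)
  if (J < 3L) {
    stop("fit statistics need at least 2 item pairs (3 items)",
         call. = FALSE)
  }
  sm <- sample_margins(y)
  n <- sm$n_eff
  P <- irf_2pl(fit$nodes, fit$a, fit$b)
  mm <- margin_moments(P, fit$weights)
  Delta <- jacobian_2pl(fit$a, fit$b, fit$nodes, fit$weights)
  e <- sm$p - mm$pi
  m2 <- m2_quadform(e, mm$Xi, Delta, n)
  df <- length(sm$p) - 2L * J

  # baseline: independence with free thresholds, fitted at sample means
  p1 <- sm$p[seq_len(J)]
  Pb <- matrix(p1, J, 1)
  mmb <- margin_moments(Pb, 1)
  sets <- mmb$sets
  Db <- matrix(0, length(sets), J)
  for (r in seq_along(sets)) {
    st <- sets[[r]]
    for (j in st) {
      others <- setdiff(st, j)
      Db[r, j] <- if (length(others)) prod(p1[others]) else 1
    }
  }
  m2_b <- m2_quadform(sm$p - mmb$pi, mmb$Xi, Db, n)
  df_b <- length(sm$p) - J

  rmsea <- if (df > 0) sqrt(max(m2 - df, 0) / (df * n)) else NA_real_
  denom <- max(m2_b - df_b, 0)
  cfi <- if (df > 0 && denom > 0) 1 - max(m2 - df, 0) / denom else NA_real_
  rc <- residual_correlations(fit, y)
  srmr <- sqrt(mean(rc$residual[upper.tri(rc$residual)]^2, na.rm = TRUE))

  out <- list(m2 = m2, df = df, m2_baseline = m2_b, df_baseline = df_b,
              rmsea = rmsea, cfi = cfi, srmr = srmr, n = n)
  out$labels <- classify_fit(out)
  structure(out, class = "fit_stats")
}

#' @export
print.fit_stats <- function(x, ...) {
  cat("<fit_stats> M2 = ", formatC(x$m2, format = "f", digits = 2),
      " on ", x$df, " df (n = ", x$n, ")\n",
      "  RMSEA = ", formatC(x$rmsea, format = "f", digits = 3),
      " [", x$labels["rmsea"], "]",
      "  CFI = ", formatC(x$cfi, format = "f", digits = 3),
      " [", x$labels["cfi"], "]",
      "  SRMR = ", formatC(x$srmr, format = "f", digits = 3),
      " [", x$labels["srmr"], "]\n", sep = "")
  invisible(x)
}

#' Classify fit statistics against conventional cutoffs
#'
#' RMSEA below 0.05 is labelled `excellent`, from 0.05 to 0.08
#' (boundaries inclusive) `mediocre`, above 0.08 `poor`. CFI of 0.90 or
#' more is `good`, below `poor`. SRMR below 0.08 is `good`, otherwise
#' `poor`. A statistic that could not be computed (e.g. CFI when the
#' independence baseline already fits) is labelled `not computable`.
#'
#' @param fit a `fit_stats` object, or a list/vector with elements
#'   `rmsea`, `cfi`, `srmr`.
#' @return named character vector of labels for `rmsea`, `cfi`, `srmr`.
#' @export
classify_fit <- function(fit) {
  rmsea <- fit[["rmsea"]]; cfi <- fit[["cfi"]]; srmr <- fit[["srmr"]]
  lab_rmsea <- if (is.null(rmsea) || is.na(rmsea)) "not computable"
    else if (rmsea < 0.05) "excellent"
    else if (rmsea <= 0.08) "mediocre"
    else "poor"
  lab_cfi <- if (is.null(cfi) || is.na(cfi)) "not computable"
    else if (cfi >= 0.90) "good" else "poor"
  lab_srmr <- if (is.null(srmr) || is.na(srmr)) "not computable"
    else if (srmr < 0.08) "good" else "poor"
  c(rmsea = lab_rmsea, cfi = lab_cfi, srmr = lab_srmr)
}
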