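# Residual diagnostics: where does a unidimensional 2PL disagree with the
# observed pairwise behavior of the items? Two complementary views:
# residual correlations (observed minus model-implied inter-item Pearson
# correlation) and standardized residuals of the 2x2 observed-vs-expected
# cross-tables. Pairs crossing either threshold are "couplet" candidates:
# locally dependent item pairs (shared wording, skip-pattern leakage, a
# shared specific factor) that violate the model's conditional
# independence assumption.

residual_correlations <- function(fit, y) {
  J <- ncol(y)
  P <- irf_2pl(fit$nodes, fit$a, fit$b)
  w <- fit$weights
  pi1 <- as.vector(P %*% w)
  pi11 <- P %*% (w * t(P))
  diag(pi11) <- pi1
  sd1 <- sqrt(pi1 * (1 - pi1))
  implied <- (pi11 - tcrossprod(pi1)) / tcrossprod(sd1)
  diag(implied) <- 1
  observed <- suppressWarnings(stats::cor(y, use = "pairwise.complete.obs"))
  res <- observed - implied
  diag(res) <- 0
  dimnames(res) <- dimnames(implied) <- list(fit$items, fit$items)
  list(observed = observed, implied = implied, residual = res,
       pi1 = pi1, pi11 = pi11)
}

#' Residual report for a 2PL fit
#'
#' For every item pair, computes (i) the residual correlation -- observed
#' minus model-implied Pearson correlation of the binary items -- and
#' (ii) the bivariate standardized residuals of the 2x2 observed versus
#' model-expected cross-table, `z = (O - E) / sqrt(n pi (1 - pi))` per
#' cell, summarized by the largest absolute cell residual. Pairs with
#' `|residual correlation| > cor_threshold` (default 0.3) or
#' `|standardized residual| > z_threshold` (default 3) are listed as
#' couplet candidates for curator review (exclude one item, or model the
#' residual covariance); nothing is excluded automatically.
#'
#' @param fit an [fit_2pl()] result.
#' @param responses the binary response matrix the model was fit to.
#' @param cor_threshold flag threshold on `|residual correlation|`.
#' @param z_threshold flag threshold on `|bivariate standardized
#'   residual|`.
#' @return an object of class `residual_report`: `residual_cor` (J x J),
#'   `std_residual` (J x J, max |z| over the four cells), `pairs` (data
#'   frame per pair), `flagged_pairs` (subset crossing a threshold).
#' @export
residual_report <- function(fit, responses, cor_threshold = 0.3,
                            z_threshold = 3) {
  stopifnot(inherits(fit, "irt_fit"))
  y <- as.matrix(responses); storage.mode(y) <- "double"
  J <- ncol(y)
  rc <- residual_correlations(fit, y)
  O <- !is.na(y); Y0 <- y; Y0[!O] <- 0
  npair <- crossprod(O)
  n11 <- crossprod(Y0)
  n10 <- crossprod(Y0, O) - n11      # item i = 1, item j = 0
  n01 <- t(n10)
  n00 <- npair - n11 - n10 - n01
  zmat <- matrix(0, J, J, dimnames = list(fit$items, fit$items))
  pairs <- list()
  for (i in seq_len(J - 1L)) {
    for (j in (i + 1L):J) {
      np <- npair[i, j]
      p11 <- rc$pi11[i, j]
      p1i <- rc$pi1[i]; p1j <- rc$pi1[j]
      pcell <- c(p11, p1i - p11, p1j - p11, 1 - p1i - p1j + p11)
      ocell <- c(n11[i, j], n10[i, j], n01[i, j], n00[i, j])
      z <- (ocell - np * pcell) / sqrt(pmax(np * pcell * (1 - pcell), 1e-12))
      zmax <- max(abs(z))
      zmat[i, j] <- zmat[j, i] <- zmax
      pairs[[length(pairs) + 1L]] <- data.frame(
        item_i = fit$items[i], item_j = fit$items[j],
        residual_cor = rc$residual[i, j], std_residual = zmax,
        n_pair = np, stringsAsFactors = FALSE)
    }
  }
  pairs <- do.call(rbind, pairs)
  pairs$flagged <- abs(pairs$residual_cor) > cor_threshold |
    pairs$std_residual > z_threshold
  structure(list(residual_cor = rc$residual, std_residual = zmat,
                 pairs = pairs,
                 flagged_pairs = pairs[pairs$flagged, , drop = FALSE],
                 cor_threshold = cor_threshold, z_threshold = z_threshold),
            class = "residual_report")
}

#' @export
print.residual_report <- function(x, ...) {
  cat("<residual_report> ", nrow(x$pairs), " pairs, ",
      nrow(x$flagged_pairs), " flagged (|res cor| > ", x$cor_threshold,
      " or |std resid| > ", x$z_threshold, ")\n", sep = "")
  if (nrow(x$flagged_pairs)) print(x$flagged_pairs, row.names = FALSE)
  invisible(x)
}

# P(Z1 <= h, Z2 <= k) for standard bivariate normal with correlation rho,
# by conditioning: integral of phi(x) Phi((k - rho x)/sqrt(1-rho^2)) dx.
pbvnorm <- function(h, k, rho) {
  if (abs(rho) >= 1 - 1e-12) {
    return(if (rho > 0) stats::pnorm(min(h, k))
           else max(stats::pnorm(h) - stats::pnorm(-k), 0))
  }
  s <- sqrt(1 - rho^2)
  stats::integrate(function(x) {
    stats::dnorm(x) * stats::pnorm((k - rho * x) / s)
  }, -Inf, h, rel.tol = 1e-10)$value
}

#' Tetrachoric correlation of a 2x2 table
#'
#' Maximum-likelihood estimate of the correlation of the latent bivariate
#' normal assumed to underlie a 2x2 cross-table of two binary items:
#' thresholds are fixed at the normal quantiles of the margins and the
#' table multinomial likelihood is maximized over the correlation. Zero
#' cells receive a continuity correction of 0.5.
#'
#' @param tab 2x2 table of counts, rows item 1 (0, 1), columns item 2
#'   (0, 1); or a vector `c(n00, n01, n10, n11)`.
#' @return the estimated correlation in (-1, 1).
#' @export
tetrachoric <- function(tab) {
  tab <- matrix(as.numeric(tab), 2, 2)
  if (any(tab < 0)) stop("negative cell count", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("degenerate 2x2 table: empty margin", call. = FALSE)
  }
  if (any(tab == 0)) tab <- tab + 0.5
  n <- sum(tab)
  p1 <- sum(tab[2, ]) / n     # P(item1 = 1)
  p2 <- sum(tab[, 2]) / n
  t1 <- stats::qnorm(1 - p1)
  t2 <- stats::qnorm(1 - p2)
  negll <- function(rho) {
    p00 <- pbvnorm(t1, t2, rho)
    p0x <- stats::pnorm(t1); px0 <- stats::pnorm(t2)
    p <- c(p00, px0 - p00, p0x - p00, 1 - p0x - px0 + p00)
    p <- pmax(p, 1e-12)
    -sum(c(tab[1, 1], tab[2, 1], tab[1, 2], tab[2, 2]) * log(p))
  }
  stats::optimize(negll, c(-0.9999, 0.9999), tol = 1e-7)$minimum
}

#' Pairwise tetrachoric correlation matrix
#'
#' Applies [tetrachoric()] to every item pair of a binary matrix,
#' pairwise-complete. Pairs with fewer than `min_overlap` complete
#' observations, or with a degenerate 2x2 table (an empty margin), get
#' `NA` and a message in the `skipped` attribute.
#'
#' @param responses respondent-by-item matrix of 0/1/`NA`.
#' @param min_overlap minimum pairwise-complete observations.
#' @return J x J correlation matrix with unit diagonal; attribute
#'   `skipped` lists pairs that could not be estimated.
#' @export
tetrachoric_matrix <- function(responses, min_overlap = 20L) {
  y <- as.matrix(responses); storage.mode(y) <- "double"
  J <- ncol(y)
  if (is.null(colnames(y))) colnames(y) <- paste0("item", seq_len(J))
  out <- diag(1, J)
  dimnames(out) <- list(colnames(y), colnames(y))
  skipped <- character(0)
  for (i in seq_len(J - 1L)) {
    for (j in (i + 1L):J) {
      ok <- !is.na(y[, i]) & !is.na(y[, j])
      if (sum(ok) < min_overlap) {
        out[i, j] <- out[j, i] <- NA
        skipped <- c(skipped, paste0(colnames(y)[i], "/", colnames(y)[j],
                                     " (overlap ", sum(ok), ")"))
        next
      }
      tab <- table(factor(y[ok, i], levels = 0:1),
                   factor(y[ok, j], levels = 0:1))
      r <- tryCatch(tetrachoric(tab), error = function(e) NA_real_)
      if (is.na(r)) {
        skipped <- c(skipped, paste0(colnames(y)[i], "/", colnames(y)[j],
                                     " (degenerate table)"))
      }
      out[i, j] <- out[j, i] <- r
    }
  }
  attr(out, "skipped") <- skipped
  out
}
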