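#' Gauss-Hermite quadrature on a standard-normal prior
#'
#' Nodes and weights for integrating smooth functions against N(0, 1):
#' physicists' Gauss-Hermite rules rescaled by sqrt(2) and 1/sqrt(pi).
#'
#' @param n number of nodes.
#' @return list with `nodes` and `weights` (weights sum to 1).
#' @keywords internal
normal_quadrature <- function(n) {
  gh <- pracma::gaussHermite(n)
  list(nodes = gh$x * sqrt(2), weights = gh$w / sqrt(pi))
}

irf_2pl <- function(theta, a, b) {
  # P(x = 1 | theta) = 1 / (1 + exp(-a (theta - b))), vectorized J x K
  stats::plogis(outer(a, theta) - a * b)
}

#' Fit a two-parameter logistic IRT model
#'
#' Marginal maximum likelihood estimation of the 2PL model for binary
#' items by the EM algorithm over a fixed Gaussian quadrature grid, with
#' a standard-normal prior on the latent trait. The item response
#' function is `P(x = 1 | theta) = 1 / (1 + exp(-a (theta - b)))`:
#' discrimination `a` plays the role of a factor loading, difficulty `b`
#' is the trait level at which endorsement probability is 50%. Missing
#' responses contribute nothing to their item's likelihood term. The
#' E-step computes posterior weights over the quadrature nodes per
#' respondent; the M-step solves one weighted logistic regression per
#' item by Newton steps with step-halving, so the recorded marginal
#' log-likelihood trace is non-decreasing.
#'
#' Identification: the trait is oriented so that the mean discrimination
#' is positive. Standard errors come from the inverse of the
#' cross-product of per-respondent scores of the marginal likelihood
#' (the full 2J x 2J block), mapped to the (a, b) parameterization by
#' the delta method.
#'
#' @param responses respondent-by-item matrix of 0/1/`NA`.
#' @param n_quad number of quadrature nodes (default 41).
#' @param tol convergence tolerance on the marginal log-likelihood
#'   (default 1e-6).
#' @param max_iter maximum EM iterations (default 500).
#' @param a_max bound on the discrimination magnitude (default 3.5).
#'   Small samples can send a slope to infinity (a Heywood case); the
#'   bound keeps the estimate finite and the quadrature accurate, and
#'   binds only when the data carry almost no information about the
#'   slope.
#' @param study_id optional label stored in the result.
#' @return an object of class `irt_fit`: `a`, `b`, `se_a`, `se_b`
#'   (named per item), `alpha`/`beta` (slope-intercept form), `loglik`,
#'   `trace` (per-iteration log-likelihood), `n_iter`, `converged`,
#'   `nodes`, `weights`, `n`, `items`, `study_id`.
#' @export
fit_2pl <- function(responses, n_quad = 41L, tol = 1e-6, max_iter = 500L,
                    a_max = 3.5, study_id = NA_character_) {
  y <- as.matrix(responses)
  storage.mode(y) <- "double"
  if (is.null(colnames(y))) colnames(y) <- paste0("item", seq_len(ncol(y)))
  vals <- unique(y[!is.na(y)])
  if (!all(vals %in% c(0, 1))) {
    stop("responses must be binary 0/1 (ordinal items must be ",
         "dichotomized upstream); found values: ",
         paste(sort(setdiff(vals, c(0, 1))), collapse = ", "), call. = FALSE)
  }
  p_obs <- colMeans(y, na.rm = TRUE)
  degenerate <- !is.na(p_obs) & (p_obs == 0 | p_obs == 1)
  if (any(degenerate)) {
    stop("item(s) with 0% or 100% endorsement: ",
         paste(colnames(y)[degenerate], collapse = ", "),
         "; remove them with the qc filters (detect_no_variability) ",
         "before fitting", call. = FALSE)
  }
  J <- ncol(y); n <- nrow(y)
  if (J < 3L) stop("need at least 3 items with variability", call. = FALSE)
  q <- normal_quadrature(n_quad)
  theta <- q$nodes; w <- q$weights; K <- length(theta)

  O <- !is.na(y)                 # observed indicator
  Y0 <- y; Y0[!O] <- 0           # NA -> 0 for matrix products
  alpha <- stats::qlogis(pmin(pmax(p_obs, 0.02), 0.98))
  beta <- rep(1, J)

  estep <- function(alpha, beta) {
    eta <- outer(beta, theta) + alpha          # J x K
    logP <- stats::plogis(eta, log.p = TRUE)
    log1mP <- stats::plogis(-eta, log.p = TRUE)
    LL <- Y0 %*% logP + (O - Y0) %*% log1mP    # n x K
    LL <- sweep(LL, 2, log(w), "+")
    m <- apply(LL, 1, max)
    W <- exp(LL - m)
    rs <- rowSums(W)
    list(W = W / rs, loglik = sum(log(rs) + m))
  }

  trace <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    es <- estep(alpha, beta)
    trace <- c(trace, es$loglik)
    if (iter > 1L && abs(trace[iter] - trace[iter - 1L]) < tol) {
      converged <- TRUE
      break
    }
    njk <- crossprod(O, es$W)                  # J x K expected counts
    rjk <- crossprod(Y0, es$W)
    # M-step: per-item weighted logistic Newton with step-halving
    for (j in seq_len(J)) {
      par <- c(alpha[j], beta[j])
      nj <- njk[j, ]; rj <- rjk[j, ]
      obj <- function(p) {
        eta <- p[1] + p[2] * theta
        sum(rj * stats::plogis(eta, log.p = TRUE) +
            (nj - rj) * stats::plogis(-eta, log.p = TRUE))
      }
      f0 <- obj(par)
      for (it in 1:50) {
        eta <- par[1] + par[2] * theta
        pk <- stats::plogis(eta)
        g <- c(sum(rj - nj * pk), sum((rj - nj * pk) * theta))
        if (max(abs(g)) < 1e-9) break
        wgt <- nj * pk * (1 - pk)
        H <- matrix(c(sum(wgt), sum(wgt * theta), sum(wgt * theta),
                      sum(wgt * theta^2)), 2, 2)
        step <- tryCatch(solve(H, g), error = function(e) g * 0)
        if (all(step == 0)) break
        lam <- 1
        moved <- FALSE
        repeat {
          cand <- par + lam * step
          cand[1] <- min(max(cand[1], -20), 20)
          cand[2] <- min(max(cand[2], -a_max), a_max)
          f1 <- obj(cand)
          if (f1 >= f0 - 1e-12 && any(cand != par)) {
            par <- cand; f0 <- f1; moved <- TRUE; break
          }
          lam <- lam / 2
          if (lam < 1e-8) break
        }
        if (!moved) break
      }
      alpha[j] <- par[1]; beta[j] <- par[2]
    }
  }
  if (!converged) {
    es <- estep(alpha, beta)
    trace <- c(trace, es$loglik)
  }
  # orientation: trait pointed so mean discrimination is positive
  if (mean(beta) < 0) beta <- -beta
  es <- estep(alpha, beta)

  # observed-information SEs via score cross-products
  eta <- outer(beta, theta) + alpha
  P <- stats::plogis(eta)                      # J x K
  EP <- es$W %*% t(P)                          # n x J posterior E[p_j]
  EPt <- es$W %*% t(P * rep(theta, each = J))  # n x J posterior E[p_j theta]
  Et <- as.vector(es$W %*% theta)              # n
  S_alpha <- O * (Y0 - EP)
  S_beta <- O * (Y0 * Et - EPt)
  G <- cbind(S_alpha, S_beta)                  # n x 2J, order (alpha, beta)
  info <- crossprod(G)
  cov_ab <- tryCatch(solve(info), error = function(e) {
    MASSlike <- info + diag(1e-8, nrow(info)); solve(MASSlike)
  })
  a <- beta
  b <- -alpha / beta
  se_a <- sqrt(pmax(diag(cov_ab)[J + seq_len(J)], 0))
  se_b <- vapply(seq_len(J), function(j) {
    idx <- c(j, J + j)
    V <- cov_ab[idx, idx]
    gr <- c(-1 / beta[j], alpha[j] / beta[j]^2)
    sqrt(max(drop(t(gr) %*% V %*% gr), 0))
  }, numeric(1))
  names(a) <- names(b) <- names(se_a) <- names(se_b) <- colnames(y)

  structure(list(a = a, b = b, se_a = se_a, se_b = se_b,
                 alpha = alpha, beta = beta,
                 loglik = es$loglik, trace = trace,
                 n_iter = length(trace), converged = converged,
                 nodes = theta, weights = w, n = n, items = colnames(y),
                 study_id = study_id),
            class = "irt_fit")
}

#' @export
print.irt_fit <- function(x, ...) {
  cat("<irt_fit>", if (!is.na(x$study_id)) paste0(" study ", x$study_id),
      ": ", length(x$a), " items, n = ", x$n,
      ", loglik = ", formatC(x$loglik, format = "f", digits = 2),
      ", ", if (x$converged) "converged" else "NOT converged",
      " in ", x$n_iter, " iterations\n", sep = "")
  df <- data.frame(a = x$a, se_a = x$se_a, b = x$b, se_b = x$se_b)
  print(round(df, 3))
  invisible(x)
}

#' @export
logLik.irt_fit <- function(object, ...) {
  structure(object$loglik, df = 2L * length(object$a), class = "logLik")
}

#' Marginal log-likelihood of a 2PL model at given parameters
#'
#' Evaluates the marginal log-likelihood of a binary response matrix
#' under the 2PL model with a standard-normal trait prior, integrating
#' over the trait with the supplied quadrature rule. Used for oracle
#' comparisons and convergence diagnostics.
#'
#' @param responses respondent-by-item matrix of 0/1/`NA`.
#' @param a,b item parameter vectors.
#' @param nodes,weights quadrature rule (defaults to 41-node
#'   Gauss-Hermite via [normal_quadrature()]).
#' @return total log-likelihood (scalar).
#' @export
marginal_loglik_2pl <- function(responses, a, b, nodes = NULL,
                                weights = NULL) {
  if (is.null(nodes)) {
    q <- normal_quadrature(41L); nodes <- q$nodes; weights <- q$weights
  }
  y <- as.matrix(responses)
  storage.mode(y) <- "double"
  O <- !is.na(y); Y0 <- y; Y0[!O] <- 0
  eta <- outer(a, nodes) - a * b
  logP <- stats::plogis(eta, log.p = TRUE)
  log1mP <- stats::plogis(-eta, log.p = TRUE)
  LL <- Y0 %*% logP + (O - Y0) %*% log1mP
  LL <- sweep(LL, 2, log(weights), "+")
  m <- apply(LL, 1, max)
  sum(log(rowSums(exp(LL - m))) + m)
}
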