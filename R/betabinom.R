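#' Beta-binomial probability mass function
#'
#' Density of the beta-binomial distribution in its mean/dispersion
#' parameterisation: with shape parameters
#' \eqn{\alpha = \pi(1/\gamma - 1)}, \eqn{\beta = (1-\pi)(1/\gamma - 1)},
#' \deqn{\Pr(M = m \mid n) = \binom{n}{m} B(m+\alpha, n-m+\beta)/B(\alpha,\beta).}
#' Here \eqn{\pi \in (0,1)} is the mean methylation level across replicates
#' and \eqn{\gamma \in [0,1)} the dispersion; \eqn{\gamma = 0} recovers the
#' binomial exactly.
#'
#' @param m,n counts, `0 <= m <= n`.
#' @param pi mean level in (0, 1).
#' @param gamma dispersion in \[0, 1).
#' @param log if `TRUE`, return log-probabilities.
#' @return probability (or log-probability), vectorised over the arguments.
#' @examples
#' dBetaBinom(1, 1, pi = 0.5, gamma = 1/3)          # 0.5 (uniform level)
#' dBetaBinom(2, 5, pi = 0.4, gamma = 1/6)          # 5/21
#' dBetaBinom(3, 10, 0.3, 0) == dbinom(3, 10, 0.3)  # binomial special case
#' @export
dBetaBinom <- function(m, n, pi, gamma, log = FALSE) {
  len <- max(length(m), length(n), length(pi), length(gamma))
  m <- rep_len(m, len); n <- rep_len(n, len)
  pi <- rep_len(pi, len); gamma <- rep_len(gamma, len)
  if (any(!is.finite(m)) || any(!is.finite(n)) || any(m < 0) || any(m > n))
    stop("counts must satisfy 0 <= m <= n")
  if (any(m != round(m)) || any(n != round(n)))
    stop("m and n must be integers")
  if (any(pi <= 0) || any(pi >= 1))
    stop("pi must lie strictly in (0, 1)")
  if (any(gamma < 0) || any(gamma >= 1))
    stop("gamma must lie in [0, 1)")
  out <- numeric(len)
  bin <- gamma == 0
  if (any(bin))
    out[bin] <- dbinom(m[bin], n[bin], pi[bin], log = TRUE)
  if (any(!bin)) {
    s <- 1 / gamma[!bin] - 1
    a <- pi[!bin] * s
    b <- (1 - pi[!bin]) * s
    mm <- m[!bin]; nn <- n[!bin]
    out[!bin] <- lchoose(nn, mm) + lbeta(mm + a, nn - mm + b) - lbeta(a, b)
  }
  if (log) out else exp(out)
}

#' Beta-binomial mean and variance
#'
#' For `M ~ BetaBinomial(n, pi, gamma)`: `E(M) = n*pi` and
#' `Var(M) = n*pi*(1-pi)*(1 + (n-1)*gamma)`. At `n = 1` the dispersion has
#' no effect; at `gamma = 0` the binomial moments are recovered.
#'
#' @inheritParams dBetaBinom
#' @return a list with components `mean` and `variance`.
#' @examples
#' betaBinomMoments(10, 0.5, 0.2)  # mean 5, variance 7
#' @export
betaBinomMoments <- function(n, pi, gamma) {
  if (any(n < 0)) stop("n must be nonnegative")
  if (any(pi <= 0) || any(pi >= 1)) stop("pi must lie strictly in (0, 1)")
  if (any(gamma < 0) || any(gamma >= 1)) stop("gamma must lie in [0, 1)")
  list(mean = n * pi,
       variance = n * pi * (1 - pi) * (1 + (n - 1) * gamma))
}

#' Beta-binomial regression log-likelihood
#'
#' Log-likelihood of the per-site regression model
#' `M_i ~ BetaBinomial(n_i, pi_i, gamma)` with logit link
#' `pi_i = plogis(X[i, ] %*% eta)` and a common dispersion `gamma`.
#' Samples with zero coverage carry no information and are excluded from
#' the sum.
#'
#' @param eta regression parameter vector (log-odds scale), one entry per
#'   column of `X`.
#' @param gamma common dispersion in \[0, 1).
#' @param X model matrix, samples x parameters.
#' @param totals,meths per-sample read counts at the site.
#' @return the log-likelihood (a nonpositive number).
#' @export
betaBinomLogLik <- function(eta, gamma, X, totals, meths) {
  X <- as.matrix(X)
  if (length(eta) != ncol(X))
    stop("length(eta) must equal ncol(X)")
  keep <- totals > 0
  if (!any(keep)) stop("site has no covered samples")
  pii <- plogis(drop(X[keep, , drop = FALSE] %*% eta))
  pii <- pmin(pmax(pii, 1e-12), 1 - 1e-12)
  sum(dBetaBinom(meths[keep], totals[keep], pii, gamma, log = TRUE))
}

.checkDesign <- function(X) {
  X <- as.matrix(X)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  X
}

#' Fit the beta-binomial regression at one site
#'
#' Maximises the likelihood of [betaBinomLogLik()] over `eta` (unbounded)
#' and `gamma` (constrained to \[1e-6, 1 - 1e-6\] through a logit
#' transform) with a quasi-Newton optimiser started from a pooled binomial
#' logistic fit (`gamma` start 0.05), falling back to Nelder-Mead on
#' failure. Zero-coverage samples are dropped first; if the design then
#' loses full column rank the site is untestable and the fit is returned
#' with `NA` entries rather than an error.
#'
#' @param X model matrix, samples x parameters (binary factor columns,
#'   first column the intercept).
#' @param totals,meths per-sample read counts at the site.
#' @return a list with components `eta`, `gamma`, `logLik`, `converged`,
#'   and `nUsed` (samples with nonzero coverage).
#' @examples
#' X <- matrix(1, 6, 1, dimnames = list(NULL, "base"))
#' fit <- fitBetaBinom(X, totals = rep(6L, 6), meths = rep(3L, 6))
#' plogis(fit$eta)   # ~0.5
#' @export
fitBetaBinom <- function(X, totals, meths) {
  X <- .checkDesign(X)
  stopifnot(nrow(X) == length(totals), length(totals) == length(meths))
  res <- .fitSitesCpp(matrix(as.integer(totals), nrow = 1L),
                      matrix(as.integer(meths), nrow = 1L),
                      X, integer(0))
  eta <- drop(res$etaFull)
  names(eta) <- colnames(X)
  list(eta = eta, gamma = res$gammaFull[1L], logLik = res$llFull[1L],
       converged = isTRUE(res$convFull[1L]), nUsed = res$nUsed[1L])
}

.dropColsFor <- function(X, testFactor) {
  idx <- match(testFactor, colnames(X))
  if (anyNA(idx))
    stop("unknown test factor: ",
         paste(testFactor[is.na(idx)], collapse = ", "))
  if (any(idx == 1L))
    stop("the intercept ('", colnames(X)[1L], "') cannot be the test factor")
  as.integer(idx)
}

#' Likelihood-ratio test for one site
#'
#' Fits the full model and the reduced model without the test factor and
#' compares them with a log-likelihood ratio test: the statistic
#' `2 * (logLik_full - logLik_reduced)` (clamped at 0 against numerical
#' noise) is referred to a chi-squared distribution with one degree of
#' freedom per dropped column. A site is untestable -- `pRaw = NA` -- when
#' dropping zero-coverage samples leaves the design rank deficient or
#' leaves some level of the test factor without coverage.
#'
#' @param X model matrix with named columns; the first column is the
#'   intercept.
#' @param testFactor name(s) of the column(s) to drop in the reduced model.
#' @param totals,meths per-sample read counts at the site.
#' @return a list with components `full` and `reduced` (each as returned by
#'   [fitBetaBinom()]), `df`, and `pRaw`.
#' @examples
#' X <- cbind(base = 1, case = rep(0:1, each = 3))
#' testSite(X, "case", totals = rep(10L, 6),
#'          meths = c(1L, 2L, 1L, 8L, 9L, 8L))$pRaw
#' @export
testSite <- function(X, testFactor, totals, meths) {
  X <- .checkDesign(X)
  stopifnot(nrow(X) == length(totals), length(totals) == length(meths))
  drop <- .dropColsFor(X, testFactor)
  res <- .fitSitesCpp(matrix(as.integer(totals), nrow = 1L),
                      matrix(as.integer(meths), nrow = 1L),
                      X, drop)
  keep <- setdiff(seq_len(ncol(X)), drop)
  full <- list(eta = stats::setNames(drop(res$etaFull), colnames(X)),
               gamma = res$gammaFull[1L], logLik = res$llFull[1L],
               converged = isTRUE(res$convFull[1L]), nUsed = res$nUsed[1L])
  reduced <- list(eta = stats::setNames(drop(res$etaRed)[seq_along(keep)],
                                        colnames(X)[keep]),
                  gamma = res$gammaRed[1L], logLik = res$llRed[1L],
                  converged = isTRUE(res$convRed[1L]), nUsed = res$nUsed[1L])
  df <- length(drop)
  p <- NA_real_
  if (isTRUE(res$testable[1L]) &&
      is.finite(full$logLik) && is.finite(reduced$logLik)) {
    stat <- max(0, 2 * (full$logLik - reduced$logLik))
    p <- pchisq(stat, df = df, lower.tail = FALSE)
  }
  list(full = full, reduced = reduced, df = df, pRaw = p)
}
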