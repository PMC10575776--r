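#' Firth penalized logistic regression
#'
#' Maximises the Jeffreys-prior penalized log-likelihood
#' \eqn{\ell(\beta) + \frac{1}{2}\log\det I(\beta)} by Newton iteration on the
#' modified score \eqn{X'(y - p + h(1/2 - p))} with step-halving, where `h`
#' are the hat-diagonals of the weighted design. The penalty removes the
#' first-order bias of the maximum-likelihood estimate and yields finite
#' coefficients even under complete separation, which makes it the standard
#' choice for sparse case-control burden tests (a handful of carriers against
#' hundreds of non-carriers).
#'
#' @param y binary outcome vector (0/1).
#' @param X numeric design matrix; an intercept column is prepended unless one
#'   is already present (a column of ones).
#' @param p_method `"plr"` (default) for penalized-likelihood-ratio p-values,
#'   obtained by refitting with each coefficient constrained to zero, or
#'   `"wald"`.
#' @param level confidence level for the Wald intervals.
#' @param maxit,score_tol,step_tol iteration controls; convergence is declared
#'   when the largest component of the penalized score falls below
#'   `score_tol` or the parameter change falls below `step_tol`.
#' @param plr_terms column names for which penalized-LR p-values are
#'   computed (default all); other terms get Wald p-values. Each PLR p-value
#'   costs one constrained refit, so restricting to the term of interest
#'   speeds up covariate-heavy scans.
#' @return an object of class `"trio_fit"`: a list with `coef`, `se`, `or`,
#'   `ci` (matrix, columns lower/upper on the OR scale), `p`, `loglik`
#'   (unpenalized, at the estimate), `penalized_loglik`, `converged`, `n`,
#'   `method`.
#' @export
firth_logistic <- function(y, X, p_method = c("plr", "wald"), level = 0.95,
                           maxit = 100L, score_tol = 1e-6, step_tol = 1e-8,
                           plr_terms = NULL) {
  p_method <- match.arg(p_method)
  dat <- check_glm_inputs(y, X)
  y <- dat$y; X <- dat$X
  fit <- firth_engine(y, X, free = seq_len(ncol(X)), maxit = maxit,
                      score_tol = score_tol, step_tol = step_tol)
  se <- sqrt(diag(solve(fit$info)))
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(lower = exp(fit$beta - z * se), upper = exp(fit$beta + z * se))
  p <- 2 * stats::pnorm(-abs(fit$beta / se))
  if (p_method == "plr") {
    cols <- if (is.null(plr_terms)) seq_len(ncol(X)) else
      match(plr_terms, colnames(X))
    if (anyNA(cols)) stop("plr_terms not found in the design matrix")
    p[cols] <- vapply(cols, function(j) {
      red <- firth_engine(y, X, free = setdiff(seq_len(ncol(X)), j),
                          maxit = maxit, score_tol = score_tol,
                          step_tol = step_tol)
      lr <- 2 * (fit$pen_loglik - red$pen_loglik)
      stats::pchisq(max(lr, 0), df = 1, lower.tail = FALSE)
    }, numeric(1))
  }
  names(p) <- names(fit$beta)
  structure(list(coef = fit$beta, se = se, or = exp(fit$beta), ci = ci, p = p,
                 loglik = fit$loglik, penalized_loglik = fit$pen_loglik,
                 converged = fit$converged, n = length(y), iter = fit$iter,
                 method = "firth"),
            class = "trio_fit")
}

# Core Firth iteration; `free` gives the coefficient indices allowed to move
# (the rest stay at zero), which is how the penalized-LR reduced fits are run.
firth_engine <- function(y, X, free, maxit, score_tol, step_tol) {
  beta <- numeric(ncol(X))
  names(beta) <- colnames(X)
  state <- firth_state(y, X, beta)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(maxit)) {
    if (max(abs(state$score[free])) < score_tol) { converged <- TRUE; break }
    delta <- numeric(ncol(X))
    delta[free] <- solve(state$info[free, free, drop = FALSE],
                         state$score[free])
    # step-halving on the penalized log-likelihood
    step <- 1
    repeat {
      cand <- beta + step * delta
      cand_state <- firth_state(y, X, cand)
      if (cand_state$pen_loglik >= state$pen_loglik - 1e-12 || step < 1e-4) break
      step <- step / 2
    }
    moved <- max(abs(step * delta))
    beta <- beta + step * delta
    state <- cand_state
    if (moved < step_tol) { converged <- TRUE; break }
  }
  if (max(abs(state$score[free])) < score_tol) converged <- TRUE
  list(beta = beta, info = state$info, score = state$score,
       loglik = state$loglik, pen_loglik = state$pen_loglik,
       converged = converged, iter = iter)
}

firth_state <- function(y, X, beta) {
  eta <- drop(X %*% beta)
  p <- clip_prob(stats::plogis(eta))
  w <- p * (1 - p)
  XW <- X * w
  info <- crossprod(X, XW)
  # hat diagonals of W^(1/2) X I^(-1) X' W^(1/2)
  h <- rowSums((X %*% solve(info)) * XW)
  score <- drop(crossprod(X, y - p + h * (0.5 - p)))
  loglik <- sum(y * log(p) + (1 - y) * log1p(-p))
  pen_loglik <- loglik + 0.5 * determinant(info, logarithm = TRUE)$modulus
  list(score = score, info = info, loglik = loglik,
       pen_loglik = as.numeric(pen_loglik))
}

clip_prob <- function(p) pmin(pmax(p, 1e-12), 1 - 1e-12)

check_glm_inputs <- function(y, X) {
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("outcome must be coded 0/1")
  X <- as.matrix(X)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (!any(apply(X, 2, function(col) all(col == 1))))
    X <- cbind(`(Intercept)` = 1, X)
  if (!all(is.finite(X))) stop("design matrix contains non-finite values")
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank-deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  list(y = y, X = X)
}

#' Binomial (maximum-likelihood) logistic regression
#'
#' Standard logistic fit via [stats::glm()], returned in the same shape as
#' [firth_logistic()] so the two can be swapped in the association pipeline.
#' If the fit shows signs of separation (fitted probabilities numerically 0 or
#' 1) the function refits with [firth_logistic()] and flags the fallback in
#' `method`.
#'
#' @inheritParams firth_logistic
#' @return a `"trio_fit"` object; `method` is `"binomial"` or
#'   `"firth_fallback"`.
#' @export
binomial_logistic <- function(y, X, level = 0.95) {
  dat <- check_glm_inputs(y, X)
  y <- dat$y; X <- dat$X
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(X, y, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  p_fit <- fit$fitted.values
  if (!separated &&
      (fit$boundary || max(abs(fit$coefficients)) > 15 ||
         any(p_fit < 1e-8) || any(p_fit > 1 - 1e-8)))
    separated <- TRUE
  if (separated || !fit$converged) {
    warning("possible separation in binomial fit; falling back to Firth")
    out <- firth_logistic(y, X, level = level)
    out$method <- "firth_fallback"
    return(out)
  }
  beta <- stats::setNames(fit$coefficients, colnames(X))
  p_hat <- clip_prob(fit$fitted.values)
  info <- crossprod(X, X * (p_hat * (1 - p_hat)))
  se <- sqrt(diag(solve(info)))
  z <- stats::qnorm(1 - (1 - level) / 2)
  structure(list(coef = beta, se = se, or = exp(beta),
                 ci = cbind(lower = exp(beta - z * se),
                            upper = exp(beta + z * se)),
                 p = 2 * stats::pnorm(-abs(beta / se)),
                 loglik = sum(y * log(p_hat) + (1 - y) * log1p(-p_hat)),
                 penalized_loglik = NA_real_,
                 converged = fit$converged, n = length(y), iter = fit$iter,
                 method = "binomial"),
            class = "trio_fit")
}

#' @export
print.trio_fit <- function(x, ...) {
  cat(sprintf("%s logistic fit (n = %d, converged = %s)\n",
              x$method, x$n, x$converged))
  print(data.frame(beta = x$coef, se = x$se, OR = x$or,
                   lower = x$ci[, "lower"], upper = x$ci[, "upper"],
                   p = x$p))
  invisible(x)
}

#' Nagelkerke pseudo-R-squared difference between nested logistic models
#'
#' Nagelkerke's R² for a model with log-likelihood \eqn{\ell_m} against the
#' intercept-only log-likelihood \eqn{\ell_0} is
#' \deqn{R^2_N = \frac{1 - \exp\{2(\ell_0 - \ell_m)/n\}}{1 - \exp\{2\ell_0/n\}}.}
#' The difference between a full model and a reduced model that omits one
#' genetic factor measures the variance in the binary outcome attributable to
#' that factor.
#'
#' @param full,reduced `"trio_fit"` objects on the same outcome (the reduced
#'   model's predictors must be a subset of the full model's).
#' @param loglik_null intercept-only log-likelihood; computed from `y` if
#'   `y` is supplied instead.
#' @param y optional outcome vector used to compute the null log-likelihood.
#' @return the scalar \eqn{R^2_N(\mathrm{full}) - R^2_N(\mathrm{reduced})}.
#' @export
nagelkerke_delta_r2 <- function(full, reduced, y = NULL, loglik_null = NULL) {
  if (full$n != reduced$n) stop("models were fitted on different n")
  if (is.null(loglik_null)) {
    if (is.null(y)) stop("supply y or loglik_null")
    loglik_null <- null_loglik(y)
  }
  nagelkerke_r2(full$loglik, loglik_null, full$n) -
    nagelkerke_r2(reduced$loglik, loglik_null, reduced$n)
}

#' @rdname nagelkerke_delta_r2
#' @param loglik model log-likelihood.
#' @param n number of observations.
#' @export
nagelkerke_r2 <- function(loglik, loglik_null, n) {
  (1 - exp(2 * (loglik_null - loglik) / n)) / (1 - exp(2 * loglik_null / n))
}

null_loglik <- function(y) {
  p <- mean(y)
  if (p == 0 || p == 1) return(0)
  sum(y) * log(p) + sum(1 - y) * log(1 - p)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Bounds from the beta-quantile characterisation of the inverted binomial
#' tail tests: the lower bound is the `alpha/2` quantile of Beta(k, n-k+1)
#' (0 when k = 0) and the upper bound the `1-alpha/2` quantile of
#' Beta(k+1, n-k) (1 when k = n).
#'
#' @param k successes, `0 <= k <= n`.
#' @param n trials, `n >= 1`.
#' @param level confidence level.
#' @return list with `estimate` (k/n), `lower`, `upper`, `k`, `n`, `level`.
#' @export
clopper_pearson <- function(k, n, level = 0.95) {
  if (n < 1) stop("n must be at least 1")
  if (k < 0 || k > n) stop("k must lie in [0, n]")
  alpha <- 1 - level
  lower <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
  upper <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  list(estimate = k / n, lower = lower, upper = upper, k = k, n = n,
       level = level)
}

#' Fisher's exact test with conditional-MLE odds ratio
#'
#' Two-tailed p-value by summing the hypergeometric probabilities of all
#' tables (with the observed margins) no more probable than the observed
#' table; the odds ratio is the conditional maximum-likelihood estimate under
#' the noncentral hypergeometric distribution, and the confidence interval is
#' obtained by inverting the one-sided conditional tests. Implemented
#' directly from the conditional likelihood (log-space) rather than wrapping
#' an existing routine, so the enumeration can be checked independently.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @param level confidence level for the exact interval.
#' @return list with `p.value`, `or` (conditional MLE; 0 or Inf at the
#'   support boundary), `lower`, `upper`.
#' @export
fisher_exact <- function(tab, level = 0.95) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("tab must be 2x2")
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be non-negative integers")
  m1 <- sum(tab[1, ]); m2 <- sum(tab[2, ]); n1 <- sum(tab[, 1])
  if (m1 == 0 || m2 == 0 || sum(tab[, 1]) == 0 || sum(tab[, 2]) == 0)
    stop("zero margin: odds ratio undefined")
  x <- tab[1, 1]
  support <- max(0, n1 - m2):min(n1, m1)
  logdc <- stats::dhyper(support, m1, m2, n1, log = TRUE)

  dens <- function(log_psi) {
    logw <- logdc + support * log_psi
    w <- exp(logw - max(logw))
    w / sum(w)
  }
  cond_mean <- function(log_psi) sum(support * dens(log_psi))

  # two-sided p: central hypergeometric masses <= observed (with slack)
  d0 <- exp(logdc - max(logdc)); d0 <- d0 / sum(d0)
  p.value <- sum(d0[d0 <= d0[support == x] * (1 + 1e-7)])

  solve_log_psi <- function(f, target) {
    # monotone in log_psi; bracket then uniroot
    lo <- -1; hi <- 1
    while (f(lo) > target && lo > -745) lo <- lo * 2
    while (f(hi) < target && hi < 745) hi <- hi * 2
    stats::uniroot(function(lp) f(lp) - target, c(lo, hi), tol = 1e-10)$root
  }
  or <- if (x == min(support)) 0
        else if (x == max(support)) Inf
        else exp(solve_log_psi(cond_mean, x))

  alpha <- 1 - level
  p_upper_tail <- function(log_psi) { d <- dens(log_psi); sum(d[support >= x]) }
  p_lower_tail <- function(log_psi) { d <- dens(log_psi); sum(d[support <= x]) }
  lower <- if (x == min(support)) 0
           else exp(solve_log_psi(p_upper_tail, alpha / 2))
  upper <- if (x == max(support)) Inf
           else exp(solve_log_psi(function(lp) -p_lower_tail(lp), -alpha / 2))
  list(p.value = p.value, or = or, lower = lower, upper = upper)
}

#' Transmission disequilibrium chi-square test
#'
#' Asymptotic test of the transmitted vs non-transmitted count of an allele
#' class against the chance rate of 1/2:
#' \eqn{\chi^2 = (T - NT)^2 / (T + NT)} on 1 degree of freedom.
#'
#' @param transmitted,non_transmitted non-negative counts with
#'   `transmitted + non_transmitted >= 1`.
#' @return list with `statistic`, `p.value`, `transmitted`,
#'   `non_transmitted`.
#' @export
tdt_chisq <- function(transmitted, non_transmitted) {
  if (transmitted < 0 || non_transmitted < 0) stop("counts must be non-negative")
  tot <- transmitted + non_transmitted
  if (tot == 0) stop("transmitted + non_transmitted must be at least 1")
  stat <- (transmitted - non_transmitted)^2 / tot
  list(statistic = stat,
       p.value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       transmitted = transmitted, non_transmitted = non_transmitted)
}

#' Two-sample t-test (pooled variance by default)
#'
#' Thin wrapper over [stats::t.test()] with `var.equal = TRUE` as the default,
#' matching the construction of the liability power simulation, where the two
#' truncated-normal groups have near-equal variance.
#'
#' @param a,b numeric vectors, each of length at least 2.
#' @param var_equal pooled (`TRUE`, default) or Welch (`FALSE`) variance.
#' @return list with `statistic`, `df`, `p.value`, `mean_diff`.
#' @export
two_sample_t <- function(a, b, var_equal = TRUE) {
  if (length(a) < 2 || length(b) < 2) stop("each group needs n >= 2")
  if (stats::var(c(a - mean(a), b - mean(b))) == 0) stop("zero pooled variance")
  tt <- stats::t.test(a, b, var.equal = var_equal)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p.value = tt$p.value, mean_diff = mean(a) - mean(b))
}
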