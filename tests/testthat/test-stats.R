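make_2x2_data <- function(exposed_case, exposed_ctrl, unexposed_case,
                          unexposed_ctrl) {
  y <- c(rep(1, exposed_case), rep(0, exposed_ctrl),
         rep(1, unexposed_case), rep(0, unexposed_ctrl))
  x <- c(rep(1, exposed_case + exposed_ctrl),
         rep(0, unexposed_case + unexposed_ctrl))
  list(y = y, x = x)
}

test_that("Firth estimate for a single binary covariate equals the add-half closed form", {
  # carriers of a damaging DD de novo variant by phenotype group
  d <- make_2x2_data(12, 1, 281, 368)
  fit <- firth_logistic(d$y, cbind(carrier = d$x))
  expect_true(fit$converged)
  expect_equal(fit$or[["carrier"]], (12.5 * 368.5) / (1.5 * 281.5),
               tolerance = 1e-6)
  # penalized score is solved to tolerance at the optimum
  expect_lt(abs(fit$or[["carrier"]] - 10.90882), 1e-4)
})

test_that("Firth stays finite under complete separation", {
  d <- make_2x2_data(8, 0, 0, 12)  # all carriers are cases
  fit <- firth_logistic(d$y, cbind(carrier = d$x))
  expect_true(fit$converged)
  expect_true(all(is.finite(fit$coef)))
  expect_true(all(is.finite(fit$ci)))
  expect_gt(fit$or[["carrier"]], 1)
})

test_that("Firth agrees with unpenalized ML on well-conditioned large samples", {
  set.seed(401)
  n <- 10000
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.5 + 0.4 * x))
  firth <- firth_logistic(y, cbind(x = x), p_method = "wald")
  ml <- glm(y ~ x, family = binomial())
  expect_lt(abs(firth$or[["x"]] / exp(coef(ml)[["x"]]) - 1), 0.01)
})

test_that("Firth rejects rank-deficient designs naming the collinear column", {
  set.seed(402)
  x <- rnorm(50)
  expect_error(firth_logistic(rbinom(50, 1, 0.5), cbind(a = x, b = 2 * x)),
               "collinear.*b")
})

test_that("binomial_logistic recovers generating coefficients and falls back under separation", {
  set.seed(403)
  n <- 5000
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(0.3 * x))
  fit <- binomial_logistic(y, cbind(x = x))
  expect_equal(fit$method, "binomial")
  expect_lt(abs(fit$coef[["x"]] - 0.3), 0.1)
  # balanced intercept-only fit
  y0 <- rep(c(0, 1), 25)
  fit0 <- binomial_logistic(y0, matrix(1, 50, 1,
                                       dimnames = list(NULL, "(Intercept)")))
  expect_equal(unname(fit0$coef[1]), 0, tolerance = 1e-8)
  # perfectly separated data
  ysep <- c(rep(0, 10), rep(1, 10))
  xsep <- c(rep(-1, 10), rep(1, 10))
  expect_warning(fsep <- binomial_logistic(ysep, cbind(x = xsep)),
                 "separation")
  expect_equal(fsep$method, "firth_fallback")
  expect_true(all(is.finite(fsep$coef)))
})

test_that("Nagelkerke delta-R2 matches a direct recomputation and is 0 for identical models", {
  set.seed(404)
  n <- 400
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- rbinom(n, 1, plogis(0.8 * x1 + 0.3 * x2))
  full <- binomial_logistic(y, cbind(x1 = x1, x2 = x2))
  reduced <- binomial_logistic(y, cbind(x1 = x1))
  expect_equal(nagelkerke_delta_r2(full, full, y = y), 0)
  # independent recomputation from glm log-likelihoods
  ll_full <- as.numeric(logLik(glm(y ~ x1 + x2, family = binomial())))
  ll_red <- as.numeric(logLik(glm(y ~ x1, family = binomial())))
  ll_0 <- as.numeric(logLik(glm(y ~ 1, family = binomial())))
  r2 <- function(ll) (1 - exp(2 * (ll_0 - ll) / n)) / (1 - exp(2 * ll_0 / n))
  expect_equal(nagelkerke_delta_r2(full, reduced, y = y),
               r2(ll_full) - r2(ll_red), tolerance = 1e-6)
  dr2 <- nagelkerke_delta_r2(full, reduced, y = y)
  expect_gte(dr2, 0)
  expect_lte(dr2, 1)
})

null_loglik_for_test <- function(y) {
  p <- mean(y)
  sum(y) * log(p) + sum(1 - y) * log(1 - p)
}

test_that("Nagelkerke R2 approaches 1 for a near-perfect predictor", {
  set.seed(405)
  n <- 500
  x <- rnorm(n)
  y <- as.integer(x + rnorm(n, 0, 0.05) > 0)
  fit <- suppressWarnings(binomial_logistic(y, cbind(x = x)))
  expect_gt(nagelkerke_r2(fit$loglik, null_loglik_for_test(y), n), 0.9)
})

test_that("Clopper-Pearson intervals match the exact binomial test", {
  for (case in list(c(12, 13), c(40, 66), c(3, 50), c(0, 10), c(10, 10))) {
    k <- case[1]; n <- case[2]
    ours <- clopper_pearson(k, n)
    ref <- binom.test(k, n)$conf.int
    expect_equal(c(ours$lower, ours$upper), as.numeric(ref),
                 tolerance = 1e-10)
  }
  expect_identical(clopper_pearson(0, 10)$lower, 0)
  expect_identical(clopper_pearson(10, 10)$upper, 1)
  expect_error(clopper_pearson(2, 0), "n")
})

test_that("fisher_exact matches the reference implementation across random tables", {
  set.seed(406)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 6) + 1, 2, 2)
    ours <- fisher_exact(tab)
    ref <- fisher.test(tab)
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-7)
    # fisher.test solves its CMLE/CI with coarser root-finding tolerances
    expect_equal(ours$or, unname(ref$estimate), tolerance = 1e-3)
    expect_equal(c(ours$lower, ours$upper), as.numeric(ref$conf.int),
                 tolerance = 1e-3)
  }
})

test_that("fisher_exact p is transpose-invariant and the OR inverts on column swap", {
  tab <- matrix(c(5, 12, 7, 269), 2, 2)
  a <- fisher_exact(tab)
  expect_equal(a$p.value, fisher_exact(t(tab))$p.value, tolerance = 1e-12)
  swapped <- fisher_exact(tab[, 2:1])
  expect_equal(a$or, 1 / swapped$or, tolerance = 1e-6)
  flat <- fisher_exact(matrix(c(5, 5, 5, 5), 2, 2))
  expect_equal(flat$or, 1, tolerance = 1e-8)
  expect_equal(flat$p.value, 1, tolerance = 1e-12)
  expect_error(fisher_exact(matrix(c(0, 0, 3, 4), 2, 2)), "margin")
})

test_that("TDT chi-square matches the closed form and its tail probability", {
  even <- tdt_chisq(50, 50)
  expect_equal(even$statistic, 0)
  expect_equal(even$p.value, 1)
  skew <- tdt_chisq(10, 0)
  expect_equal(skew$statistic, 10)
  expect_equal(skew$p.value, pchisq(10, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(skew$p.value, 0.001565402, tolerance = 1e-6)
  expect_error(tdt_chisq(0, 0), "at least 1")
})

test_that("two_sample_t matches a hand-computed pooled t and is antisymmetric", {
  a <- c(4.1, 5.0, 6.2, 5.5, 4.8)
  b <- c(3.2, 4.1, 3.9, 4.6, 3.5)
  res <- two_sample_t(a, b)
  sp2 <- (4 * var(a) + 4 * var(b)) / 8
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (2 / 5))
  expect_equal(res$statistic, t_hand, tolerance = 1e-10)
  expect_equal(res$p.value, 2 * pt(-abs(t_hand), df = 8), tolerance = 1e-10)
  expect_equal(two_sample_t(b, a)$statistic, -res$statistic)
  same <- two_sample_t(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
})
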