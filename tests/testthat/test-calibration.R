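clamp01 <- function(x) pmin(1, pmax(0, x))

sim_scores <- function(n, mu = c(0.2, 0.8), sd = 0.05, seed = 1) {
  set.seed(seed)
  clamp01(c(rnorm(n / 2, mu[1], sd), rnorm(n / 2, mu[2], sd)))
}

test_that("the EM fit recovers planted mixture components", {
  scores <- sim_scores(2000, seed = 31)
  fit <- fit_score_mixture(scores, seed = 5)
  expect_lt(abs(fit$mu[["B"]] - 0.2), 0.02)
  expect_lt(abs(fit$mu[["P"]] - 0.8), 0.02)
  expect_gt(fit$mu[["P"]], fit$mu[["B"]])  # label-order contract
  expect_equal(sum(fit$weight), 1)
  expect_true(all(fit$sigma2 > 0))
  # deterministic given the seed
  fit2 <- fit_score_mixture(scores, seed = 5)
  expect_equal(fit$mu, fit2$mu)
  expect_equal(fit$loglik, fit2$loglik)
  expect_error(fit_score_mixture(rep(0.5, 50)), "identical")
  expect_error(fit_score_mixture(c(0.1, 0.9)), "at least 10")
})

test_that("the EM fit agrees with an independent mixture implementation", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")  # Mclust resolves helpers unqualified
  scores <- sim_scores(1500, mu = c(0.25, 0.75), sd = 0.08, seed = 17)
  fit <- fit_score_mixture(scores, seed = 2)
  mc <- mclust::Mclust(scores, G = 2, modelNames = "V", verbose = FALSE)
  mc_mu <- sort(mc$parameters$mean)
  expect_lt(abs(fit$mu[["B"]] - mc_mu[1]), 0.01)
  expect_lt(abs(fit$mu[["P"]] - mc_mu[2]), 0.01)
  expect_lt(abs(fit$loglik - mc$loglik), 1)
})

equal_var_fit <- function(muB = 0.2, muP = 0.8, s2 = 0.01) {
  scores <- sim_scores(200, mu = c(muB, muP), sd = sqrt(s2), seed = 4)
  fit <- fit_score_mixture(scores, seed = 4)
  fit$mu <- stats::setNames(c(muB, muP), c("B", "P"))
  fit$sigma2 <- stats::setNames(c(s2, s2), c("B", "P"))
  fit$weight <- stats::setNames(c(0.5, 0.5), c("B", "P"))
  fit
}

test_that("likelihood ratio follows the component-density formula", {
  fit <- equal_var_fit()
  # midpoint of equal-variance components: LR = 1
  expect_equal(likelihood_ratio(0.5, fit), 1)
  # closed form at the pathogenic mean: exp(gap^2 / (2 sigma^2))
  expect_equal(likelihood_ratio(0.8, fit), exp(0.6^2 / (2 * 0.01)))
  # monotone increasing between the means under equal variances
  xs <- seq(0.2, 0.8, by = 0.01)
  expect_true(all(diff(likelihood_ratio(xs, fit)) > 0))
  # weighted mode multiplies by the mixing-odds
  fit$weight <- stats::setNames(c(0.75, 0.25), c("B", "P"))
  expect_equal(likelihood_ratio(0.5, fit, weighted = TRUE), 1 / 3)
})

test_that("threshold solving matches the closed form and a numeric root-finder", {
  fit <- equal_var_fit()
  th <- solve_thresholds(fit, ratio = 9)
  closed_upper <- 0.5 + 0.01 * log(9) / 0.6
  expect_equal(th[["upper"]], closed_upper, tolerance = 1e-9)
  expect_equal(th[["lower"]], 1 - closed_upper, tolerance = 1e-9)
  # self-consistency: LR at the solved thresholds is exactly the ratio
  expect_lt(abs(likelihood_ratio(th[["upper"]], fit) - 9), 1e-9)
  expect_lt(abs(likelihood_ratio(th[["lower"]], fit) - 1 / 9), 1e-9)
  # ratio = 1 collapses both thresholds to the equal-density point
  th1 <- solve_thresholds(fit, ratio = 1)
  expect_equal(th1[["lower"]], th1[["upper"]])
  expect_equal(th1[["upper"]], 0.5)

  # unequal variances: quadratic root agrees with numeric root-finding
  fit$sigma2 <- stats::setNames(c(0.012, 0.006), c("B", "P"))
  th2 <- solve_thresholds(fit, ratio = 9)
  for (side in c("lower", "upper")) {
    target <- if (side == "upper") log(9) else -log(9)
    root <- stats::uniroot(function(x) stoplossr:::log_lr(x, fit) - target,
                           c(fit$mu[["B"]], fit$mu[["P"]]), tol = 1e-12)$root
    expect_equal(th2[[side]], root, tolerance = 1e-9)
  }
  expect_lt(abs(likelihood_ratio(th2[["upper"]], fit) - 9), 1e-9)
})

test_that("score classification uses inclusive decisive boundaries", {
  th <- default_thresholds()
  expect_identical(classify_score(0.75, th), "potentially_PLP")
  expect_identical(classify_score(0.70, th), "potentially_PLP")
  expect_identical(classify_score(0.30, th), "potentially_BLB")
  expect_identical(classify_score(0.50, th), "uncertain")
  expect_identical(classify_score(c(0.1, 0.5, 0.9), th),
                   c("potentially_BLB", "uncertain", "potentially_PLP"))
})

test_that("the pathogenic-bin fraction converges to the component mass above threshold", {
  scores <- sim_scores(10000, seed = 99)
  fit <- fit_score_mixture(scores, seed = 3)
  th <- solve_thresholds(fit, 9)
  observed <- mean(classify_score(scores, th) == "potentially_PLP")
  expected <- fit$weight[["P"]] *
    stats::pnorm(th[["upper"]], fit$mu[["P"]], sqrt(fit$sigma2[["P"]]),
                 lower.tail = FALSE) +
    fit$weight[["B"]] *
    stats::pnorm(th[["upper"]], fit$mu[["B"]], sqrt(fit$sigma2[["B"]]),
                 lower.tail = FALSE)
  expect_lt(abs(observed - expected), 0.02)
})

test_that("calibration reports serialize to JSON", {
  scores <- sim_scores(500, seed = 12)
  fit <- fit_score_mixture(scores, seed = 1)
  th <- solve_thresholds(fit, 9)
  path <- withr::local_tempfile(fileext = ".json")
  write_calibration_json(fit, th, 9, path)
  rep <- jsonlite::read_json(path)
  expect_equal(rep$thresholds$upper, th[["upper"]])
  expect_equal(rep$components$P$mu, fit$mu[["P"]])
  expect_equal(rep$n, 500)
})
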