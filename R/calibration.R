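#' Published operating thresholds
#'
#' The operating score cutoffs shipped with the framework (0.30 benign-side,
#' 0.70 pathogenic-side), derived from a Gaussian-mixture likelihood-ratio
#' rule at LR = 1/9 and 9 on the full score distribution of all possible
#' stop-loss substitutions. Use [solve_thresholds()] to calibrate fresh
#' thresholds on your own score distribution.
#'
#' @return Named numeric vector `c(lower = 0.30, upper = 0.70)`.
#' @export
default_thresholds <- function() c(lower = 0.30, upper = 0.70)

new_mixture_fit <- function(mu, sigma2, weight, loglik, n, seed) {
  # Components are labeled by mean order: the larger-mean component is P/LP.
  ord <- order(mu)
  structure(list(
    mu = setNames(mu[ord], c("B", "P")),
    sigma2 = setNames(sigma2[ord], c("B", "P")),
    weight = setNames(weight[ord], c("B", "P")),
    loglik = loglik, n = n, seed = seed),
    class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf(
    "<mixture_fit: B ~ N(%.3f, %.3f^2) w=%.2f | P ~ N(%.3f, %.3f^2) w=%.2f | logL %.2f, n %d>\n",
    x$mu["B"], sqrt(x$sigma2["B"]), x$weight["B"],
    x$mu["P"], sqrt(x$sigma2["P"]), x$weight["P"], x$loglik, x$n))
  invisible(x)
}

em_run <- function(x, mu, sigma2, weight, max_iter = 500L, tol = 1e-10) {
  n <- length(x)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- weight[1] * dnorm(x, mu[1], sqrt(sigma2[1]))
    d2 <- weight[2] * dnorm(x, mu[2], sqrt(sigma2[2]))
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    r2 <- d2 / tot
    r1 <- 1 - r2
    ll <- sum(log(tot))
    n1 <- sum(r1); n2 <- sum(r2)
    if (n1 < 1e-8 || n2 < 1e-8) break  # degenerate responsibility split
    mu <- c(sum(r1 * x) / n1, sum(r2 * x) / n2)
    sigma2 <- pmax(c(sum(r1 * (x - mu[1])^2) / n1,
                     sum(r2 * (x - mu[2])^2) / n2), 1e-8)
    weight <- c(n1, n2) / n
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  list(mu = mu, sigma2 = sigma2, weight = weight, loglik = ll)
}

#' Fit a two-component Gaussian mixture to classifier scores
#'
#' Expectation-maximization with k-means initialization, ten seeded
#' restarts, keeping the run with the best log-likelihood. The component
#' with the larger mean is labeled P/LP, the other B/LB.
#'
#' @param scores Numeric scores in `[0, 1]`, `n >= 10`.
#' @param seed Integer seed (initialization randomness).
#' @param restarts Number of seeded k-means restarts.
#' @return An object of class `"mixture_fit"`.
#' @export
fit_score_mixture <- function(scores, seed = 1L, restarts = 10L) {
  stopifnot(is.numeric(scores))
  if (length(scores) < 10L)
    stop("need at least 10 scores to fit a mixture", call. = FALSE)
  if (any(scores < 0 | scores > 1))
    stop("scores must lie in [0, 1]", call. = FALSE)
  if (length(unique(scores)) < 2L)
    stop("degenerate data: all scores identical", call. = FALSE)
  best <- NULL
  for (r in seq_len(restarts)) {
    set.seed(seed + r - 1L)
    km <- suppressWarnings(kmeans(scores, centers = 2L, nstart = 1L))
    mu0 <- as.numeric(km$centers)
    s0 <- vapply(1:2, function(k) {
      v <- var_or(scores[km$cluster == k], fallback = stats::var(scores))
      max(v, 1e-6)
    }, numeric(1))
    w0 <- as.numeric(table(factor(km$cluster, levels = 1:2))) / length(scores)
    w0 <- pmax(w0, 1e-3); w0 <- w0 / sum(w0)
    run <- em_run(scores, mu0, s0, w0)
    if (is.null(best) || run$loglik > best$loglik) best <- run
  }
  new_mixture_fit(best$mu, best$sigma2, best$weight, best$loglik,
                  length(scores), seed)
}

var_or <- function(x, fallback) {
  if (length(x) < 2L) return(fallback)
  v <- stats::var(x)
  if (!is.finite(v) || v == 0) fallback else v
}

#' Likelihood ratio of the pathogenic over the benign component density
#'
#' `LR(x) = P(x | P/LP) / P(x | B/LB)`, the ratio of the two component
#' normal densities at `x`. Mixing weights are deliberately not applied
#' (that is the published rule); set `weighted = TRUE` for posterior odds
#' instead.
#'
#' @param x Score(s).
#' @param fit A `mixture_fit`.
#' @param weighted Multiply by the mixing-weight ratio (posterior odds).
#' @return Positive likelihood ratio(s).
#' @export
likelihood_ratio <- function(x, fit, weighted = FALSE) {
  stopifnot(inherits(fit, "mixture_fit"))
  lr <- exp(log_lr(x, fit))
  if (weighted) lr * fit$weight[["P"]] / fit$weight[["B"]] else lr
}

log_lr <- function(x, fit) {
  dnorm(x, fit$mu[["P"]], sqrt(fit$sigma2[["P"]]), log = TRUE) -
    dnorm(x, fit$mu[["B"]], sqrt(fit$sigma2[["B"]]), log = TRUE)
}

#' Solve likelihood-ratio score thresholds
#'
#' Finds the scores at which the component-density likelihood ratio equals
#' `ratio` (pathogenic-side, "upper") and `1/ratio` (benign-side, "lower");
#' the default `ratio = 9` corresponds to 90% likelihood of the favored
#' class. With unequal variances `log LR(x) = +/- log(ratio)` is quadratic
#' in `x` and the root strictly between the component means is selected;
#' with equal variances the closed form
#' `x = (mu_B + mu_P)/2 + sigma^2 log(ratio) / (mu_P - mu_B)` applies.
#'
#' @param fit A `mixture_fit`.
#' @param ratio Likelihood ratio (> 1 for a proper band; `ratio = 1` gives
#'   the equal-density point for both thresholds).
#' @return Named numeric vector `c(lower = , upper = )` with
#'   `lower <= upper`.
#' @export
solve_thresholds <- function(fit, ratio = 9) {
  stopifnot(inherits(fit, "mixture_fit"), ratio >= 1)
  upper <- solve_one_lr(fit, log(ratio))
  lower <- solve_one_lr(fit, -log(ratio))
  if (lower > upper)
    stop("pathological fit: benign-side threshold above pathogenic-side ",
         sprintf("(lower %.4f > upper %.4f)", lower, upper), call. = FALSE)
  c(lower = lower, upper = upper)
}

# Root of log LR(x) = target with x strictly between the component means.
solve_one_lr <- function(fit, target) {
  muB <- fit$mu[["B"]]; muP <- fit$mu[["P"]]
  s2B <- fit$sigma2[["B"]]; s2P <- fit$sigma2[["P"]]
  # log LR(x) = a x^2 + b x + c
  a <- 1 / (2 * s2B) - 1 / (2 * s2P)
  b <- muP / s2P - muB / s2B
  cc <- muB^2 / (2 * s2B) - muP^2 / (2 * s2P) + 0.5 * log(s2B / s2P)
  if (abs(a) < 1e-12) {
    root <- (target - cc) / b
  } else {
    disc <- b^2 - 4 * a * (cc - target)
    if (disc < 0)
      stop("pathological fit: no real likelihood-ratio root ",
           sprintf("(target log LR %.3f, components N(%.3f, %.4f) / N(%.3f, %.4f))",
                   target, muB, s2B, muP, s2P), call. = FALSE)
    roots <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
    inside <- roots[roots > muB & roots < muP]
    if (length(inside) == 0L)
      stop("pathological fit: no likelihood-ratio root between the ",
           sprintf("component means (roots %.4f, %.4f; means %.4f, %.4f)",
                   roots[1], roots[2], muB, muP), call. = FALSE)
    # If both roots fall between the means, keep the one on the matching
    # side of the midpoint (larger for the pathogenic-side threshold).
    root <- if (target >= 0) max(inside) else min(inside)
  }
  unname(root)
}

#' Classify a score against calibrated thresholds
#'
#' Boundaries are inclusive toward the decisive bins: `score >= upper` is
#' potentially pathogenic, `score <= lower` potentially benign, anything
#' strictly between is uncertain.
#'
#' @param score Numeric score(s).
#' @param thresholds Named vector `c(lower = , upper = )`, e.g.
#'   [default_thresholds()] or [solve_thresholds()] output.
#' @return Character vector over \{`"potentially_PLP"`, `"uncertain"`,
#'   `"potentially_BLB"`\}.
#' @export
classify_score <- function(score, thresholds = default_thresholds()) {
  stopifnot(all(c("lower", "upper") %in% names(thresholds)),
            thresholds[["lower"]] <= thresholds[["upper"]])
  ifelse(score >= thresholds[["upper"]], "potentially_PLP",
         ifelse(score <= thresholds[["lower"]], "potentially_BLB",
                "uncertain"))
}

#' Write a calibration report as JSON
#' @param fit A `mixture_fit`.
#' @param thresholds Output of [solve_thresholds()].
#' @param ratio The likelihood ratio used.
#' @param path Output path.
#' @export
write_calibration_json <- function(fit, thresholds, ratio, path) {
  jsonlite::write_json(list(
    components = list(
      B = list(mu = fit$mu[["B"]], sigma2 = fit$sigma2[["B"]],
               weight = fit$weight[["B"]]),
      P = list(mu = fit$mu[["P"]], sigma2 = fit$sigma2[["P"]],
               weight = fit$weight[["P"]])),
    thresholds = as.list(thresholds),
    ratio = ratio, loglik = fit$loglik, n = fit$n, seed = fit$seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
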