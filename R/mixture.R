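#' Two-component Gaussian mixture fit of peak summit heights
#'
#' Recruitment foci are detected by modeling summit heights as a mixture of
#' two normal components: one for the bulk of binding sites with low summit
#' coverage, one for the small set with extremely high coverage. Parameters
#' are estimated by expectation-maximization. Initialization comes from the
#' 25th/90th percentile split of the data: points at or below the 25th
#' percentile seed the low component, points at or above the 90th percentile
#' seed the high component, and the remainder are assigned to the nearer
#' seed mean. Components are relabeled on return so that
#' `mu["high"] > mu["low"]`; foci are the observations with posterior
#' probability of the high component above 0.5.
#'
#' @param heights Numeric vector of summit heights (>= 4 values with nonzero
#'   variance).
#' @param tol Convergence tolerance on the log-likelihood change.
#' @param max_iter Maximum EM iterations; non-convergence is flagged and the
#'   best estimate returned.
#' @return An object of class `foci_model`: `mu`, `sigma`, `lambda` (mixing
#'   weights summing to 1), `posterior_high` per observation, `foci` logical
#'   vector (posterior strictly above 0.5), `loglik` trace, `converged`,
#'   `iterations`.
#' @export
fit_foci_mixture <- function(heights, tol = 1e-8, max_iter = 1000L) {
  x <- as.numeric(heights)
  .assert(length(x) >= 4, "need at least 4 summit heights, got %d", length(x))
  .assert(all(is.finite(x)), "non-finite summit heights")
  .assert(stats::var(x) > 0,
          "degenerate data: all summit heights are equal, no mixture to fit")
  n <- length(x)
  sd_floor <- max(stats::sd(x) * 1e-6, 1e-12)

  q <- stats::quantile(x, c(0.25, 0.90), names = FALSE)
  lo_seed <- x[x <= q[1]]
  hi_seed <- x[x >= q[2]]
  mu <- c(mean(lo_seed), mean(hi_seed))
  if (mu[1] == mu[2]) mu <- range(x)
  assign_hi <- abs(x - mu[2]) < abs(x - mu[1])
  sigma <- c(max(stats::sd(x[!assign_hi]), sd_floor, na.rm = TRUE),
             max(stats::sd(x[assign_hi]), sd_floor, na.rm = TRUE))
  sigma[!is.finite(sigma)] <- sd_floor
  lambda <- c(mean(!assign_hi), mean(assign_hi))
  lambda <- .clip(lambda, 1 / n, 1 - 1 / n)
  lambda <- lambda / sum(lambda)

  loglik <- numeric(0)
  converged <- FALSE
  iter <- 0L
  post_hi <- rep(0, n)
  repeat {
    iter <- iter + 1L
    l1 <- log(lambda[1]) + stats::dnorm(x, mu[1], sigma[1], log = TRUE)
    l2 <- log(lambda[2]) + stats::dnorm(x, mu[2], sigma[2], log = TRUE)
    m <- pmax(l1, l2)
    ll <- sum(m + log(exp(l1 - m) + exp(l2 - m)))
    loglik <- c(loglik, ll)
    post_hi <- 1 / (1 + exp(l1 - l2))
    if (iter > 1 && abs(ll - loglik[iter - 1L]) < tol) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    w2 <- post_hi
    w1 <- 1 - post_hi
    lambda <- c(sum(w1), sum(w2)) / n
    mu <- c(sum(w1 * x) / sum(w1), sum(w2 * x) / sum(w2))
    sigma <- c(sqrt(sum(w1 * (x - mu[1])^2) / sum(w1)),
               sqrt(sum(w2 * (x - mu[2])^2) / sum(w2)))
    sigma <- pmax(sigma, sd_floor)
  }
  if (!converged) {
    warning("EM did not converge in ", max_iter,
            " iterations; returning best estimate")
  }
  # Relabel so the second component is the high one.
  if (mu[1] > mu[2]) {
    mu <- rev(mu); sigma <- rev(sigma); lambda <- rev(lambda)
    post_hi <- 1 - post_hi
  }
  structure(list(
    mu = c(low = mu[1], high = mu[2]),
    sigma = c(low = sigma[1], high = sigma[2]),
    lambda = c(low = lambda[1], high = lambda[2]),
    posterior_high = post_hi,
    foci = post_hi > 0.5,
    loglik = loglik,
    converged = converged,
    iterations = iter), class = "foci_model")
}

#' @export
print.foci_model <- function(x, ...) {
  cat(sprintf(
    "foci_model: mu = (%.3g, %.3g), sigma = (%.3g, %.3g), weights = (%.3g, %.3g)\n",
    x$mu[1], x$mu[2], x$sigma[1], x$sigma[2], x$lambda[1], x$lambda[2]))
  cat(sprintf("  %d foci of %d observations; %sconverged in %d iterations\n",
              sum(x$foci), length(x$foci), if (x$converged) "" else "NOT ",
              x$iterations))
  invisible(x)
}
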