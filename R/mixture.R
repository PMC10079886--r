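#' Normal probability density
#'
#' Thin, domain-checked wrapper around [stats::dnorm()]: the density
#' `(1/sqrt(2*pi*sigma^2)) * exp(-(x - mu)^2 / (2*sigma^2))`.
#'
#' @param x Numeric vector of evaluation points (G).
#' @param mu Mean (G).
#' @param sigma Standard deviation (G), strictly positive.
#' @return Densities (per G).
#' @export
normal_pdf <- function(x, mu, sigma) {
  if (!is_scalar_num(sigma) || sigma <= 0)
    abort("sigma must be a positive number", "accelmix_domain_error")
  dnorm(x, mean = mu, sd = sigma)
}

#' Two-component Gaussian mixture density
#'
#' `(1 - w_high) * N(x | mu_low, sigma_low^2) + w_high * N(x | mu_high,
#' sigma_high^2)`; accepts a fitted [fit_gmm_em()] object, a
#' [mixture_truth()] or any list carrying the five parameter fields.
#'
#' @param x Numeric vector of evaluation points (G).
#' @param fit List-like with fields `mu_low`, `sigma_low`, `mu_high`,
#'   `sigma_high`, `w_high`.
#' @return Densities (per G).
#' @export
mixture_pdf <- function(x, fit) {
  p <- as.list(fit)[c("mu_low", "sigma_low", "mu_high", "sigma_high",
                      "w_high")]
  if (any(vapply(p, is.null, logical(1))))
    abort("fit must carry mu_low, sigma_low, mu_high, sigma_high, w_high",
          "accelmix_domain_error")
  if (!is_scalar_num(p$w_high) || p$w_high < 0 || p$w_high > 1)
    abort("w_high must lie in [0, 1]", "accelmix_domain_error")
  (1 - p$w_high) * normal_pdf(x, p$mu_low, p$sigma_low) +
    p$w_high * normal_pdf(x, p$mu_high, p$sigma_high)
}

#' Fit a two-component Gaussian mixture by EM
#'
#' Maximum-likelihood fit of a univariate two-component normal mixture to
#' pooled in-play acceleration-index samples. Each EM iteration computes
#' responsibilities (E-step) and weighted means, variances and mixing
#' weights (M-step); the run stops when the mean per-sample log-likelihood
#' improves by less than `cfg$em_tol` or after `cfg$em_max_iter` iterations.
#' `cfg$em_n_init` initializations are tried -- the first a deterministic
#' median split of the data, the rest seeded random responsibility draws --
#' and the run with the highest final log-likelihood wins. Components are
#' then relabeled so that `mu_low <= mu_high` (ties broken by
#' `sigma_low <= sigma_high`).
#'
#' @param pool Numeric vector of samples (or the list returned by
#'   [sample_mixture_pool()]).
#' @param cfg A [run_config()]; EM settings are taken from its `em_*`
#'   fields.
#' @return A `mixture_fit`: `mu_low`, `sigma_low`, `mu_high`, `sigma_high`,
#'   `w_high`, `log_likelihood`, `loglik_trace`, `n_iter`, `converged`,
#'   `n_samples`, `seed`.
#' @examples
#' pool <- sample_mixture_pool(mixture_truth(), 2000, seed = 7)
#' fit <- fit_gmm_em(pool)
#' fit$mu_high
#' @export
fit_gmm_em <- function(pool, cfg = run_config()) {
  if (is.list(pool) && !is.null(pool$samples)) pool <- pool$samples
  x <- as.numeric(pool)
  validate_run_config(cfg)
  if (length(x) < cfg$em_min_samples)
    abort(sprintf("need at least %d samples to fit the mixture, got %d",
                  cfg$em_min_samples, length(x)),
          "accelmix_insufficient_data_error")
  if (!all(is.finite(x)))
    abort("pool contains non-finite values", "accelmix_input_error")

  runs <- with_seed(cfg$em_seed, {
    lapply(seq_len(cfg$em_n_init), function(init) {
      g <- if (init == 1L) {
        g0 <- as.numeric(x > median(x))
        if (all(g0 == g0[1])) runif(length(x)) else g0
      } else {
        runif(length(x))
      }
      em_run_cpp(x, g, cfg$em_tol, cfg$em_max_iter, cfg$var_floor)
    })
  })
  ok <- !vapply(runs, `[[`, logical(1), "degenerate")
  if (!any(ok))
    abort("all EM initializations collapsed to a degenerate solution",
          "accelmix_degenerate_fit_error")
  runs <- runs[ok]
  best <- runs[[which.max(vapply(runs, `[[`, numeric(1), "log_likelihood"))]]

  swap <- best$mu1 > best$mu2 ||
    (best$mu1 == best$mu2 && best$sigma1 > best$sigma2)
  fit <- if (swap) {
    list(mu_low = best$mu2, sigma_low = best$sigma2,
         mu_high = best$mu1, sigma_high = best$sigma1,
         w_high = 1 - best$w2)
  } else {
    list(mu_low = best$mu1, sigma_low = best$sigma1,
         mu_high = best$mu2, sigma_high = best$sigma2,
         w_high = best$w2)
  }
  fit$log_likelihood <- best$log_likelihood
  fit$loglik_trace <- best$loglik_trace
  fit$n_iter <- best$n_iter
  fit$converged <- best$converged
  fit$n_samples <- length(x)
  fit$seed <- cfg$em_seed
  structure(fit, class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("<mixture_fit> two-component Gaussian mixture (EM)\n")
  cat(sprintf("  low : mu = %.4f G, sigma = %.4f G (w = %.3f)\n",
              x$mu_low, x$sigma_low, 1 - x$w_high))
  cat(sprintf("  high: mu = %.4f G, sigma = %.4f G (w = %.3f)\n",
              x$mu_high, x$sigma_high, x$w_high))
  cat(sprintf("  logLik %.2f after %d iteration(s) on %d samples (%s)\n",
              x$log_likelihood, x$n_iter, x$n_samples,
              if (isTRUE(x$converged)) "converged" else "not converged"))
  invisible(x)
}

#' Serialize a mixture fit to JSON
#'
#' @param fit A `mixture_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mixture_fit <- function(fit, path) {
  stopifnot(inherits(fit, "mixture_fit"))
  jsonlite::write_json(unclass(fit), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Histogram of a sample pool with the fitted mixture overlaid
#'
#' Mirrors the standard presentation of the in-play intensity distribution:
#' grey histogram (default 0.02-G bins), green mixture density, blue low
#' component, red high component.
#'
#' @param x A `mixture_fit`.
#' @param pool The samples the fit was computed from.
#' @param bin_width_g Histogram bin width in G.
#' @param ... Passed to [graphics::hist()].
#' @return Invisibly, the histogram object.
#' @export
plot.mixture_fit <- function(x, pool, bin_width_g = 0.02, ...) {
  if (is.list(pool) && !is.null(pool$samples)) pool <- pool$samples
  breaks <- seq(0, max(pool) + bin_width_g, by = bin_width_g)
  h <- hist(pool, breaks = breaks, freq = FALSE, col = "grey85",
            border = "grey60", xlab = "acceleration index (G)",
            main = "In-play intensity distribution", ...)
  xs <- seq(min(breaks), max(breaks), length.out = 512)
  lines(xs, (1 - x$w_high) * normal_pdf(xs, x$mu_low, x$sigma_low),
        col = "blue", lwd = 2)
  lines(xs, x$w_high * normal_pdf(xs, x$mu_high, x$sigma_high),
        col = "red", lwd = 2)
  lines(xs, mixture_pdf(xs, x), col = "darkgreen", lwd = 2)
  legend("topright", c("mixture", "high", "low"),
         col = c("darkgreen", "red", "blue"), lwd = 2, bty = "n")
  invisible(h)
}
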