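mix_loglik <- function(x, w, mu, sd) {
  k <- length(w)
  lg <- vapply(seq_len(k), function(j)
    log(w[j]) + stats::dnorm(x, mu[j], sd[j], log = TRUE),
    numeric(length(x)))
  if (is.null(dim(lg))) lg <- matrix(lg, nrow = length(x))
  m <- apply(lg, 1, max)
  sum(m + log(rowSums(exp(lg - m))))
}

#' Fit a one- or two-component Gaussian mixture to window SNP rates
#'
#' `k = 1` is the closed-form normal MLE. `k = 2` runs EM with a
#' deterministic quantile initialization (component `j` starts at the
#' `(2j - 1) / 2k` quantile) to relative log-likelihood tolerance `1e-8`
#' or 500 iterations; a second start with both components collapsed onto
#' the `k = 1` solution guarantees that the returned `k = 2` likelihood is
#' never below the `k = 1` likelihood. No randomness is involved, so fits
#' are reproducible. BIC is `-2 loglik + params log n` with 2 (`k = 1`) or
#' 5 (`k = 2`) parameters.
#'
#' @param rates Numeric vector of window SNP rates (SNP-free windows
#'   already excluded); at least 50 values.
#' @param k 1 or 2.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations.
#' @return A `mixture_fit`: list with `k`, `weights`, `means`, `sds`,
#'   `loglik`, `bic`, `n_iter`, `converged`, `n`, `rates`.
#' @export
fit_mixture <- function(rates, k, tol = 1e-8, max_iter = 500L) {
  x <- as.numeric(rates)
  n <- length(x)
  stopifnot(n >= 50, k %in% c(1L, 2L))
  if (k == 2 && stats::sd(x) == 0) {
    stop("degenerate input: all rates identical (k = 2 unidentifiable)")
  }
  if (k == 1) {
    mu <- mean(x)
    sd1 <- sqrt(mean((x - mu)^2))
    ll <- mix_loglik(x, 1, mu, sd1)
    return(new_mixture_fit(1L, 1, mu, sd1, ll, n_iter = 0L,
                           converged = TRUE, n = n, rates = x))
  }
  run_em <- function(w, mu, sd) {
    ll_old <- mix_loglik(x, w, mu, sd)
    ll_trace <- ll_old
    converged <- FALSE
    it <- 0L
    while (it < max_iter) {
      it <- it + 1L
      lg <- vapply(1:2, function(j)
        log(w[j]) + stats::dnorm(x, mu[j], sd[j], log = TRUE),
        numeric(n))
      m <- pmax(lg[, 1], lg[, 2])
      den <- m + log(exp(lg[, 1] - m) + exp(lg[, 2] - m))
      r <- exp(lg - den)          # responsibilities
      nk <- colSums(r)
      w <- nk / n
      mu <- colSums(r * x) / nk
      sd <- sqrt(pmax(colSums(r * (x - rep(mu, each = n))^2) / nk,
                      1e-20))
      ll <- mix_loglik(x, w, mu, sd)
      if (ll < ll_old - 1e-6) {
        stop("EM log-likelihood decreased: numerical failure")
      }
      ll_trace <- c(ll_trace, ll)
      if (abs(ll - ll_old) <= tol * (abs(ll_old) + 1)) {
        converged <- TRUE
        ll_old <- ll
        break
      }
      ll_old <- ll
    }
    list(w = w, mu = mu, sd = sd, loglik = ll_old, n_iter = it,
         converged = converged, trace = ll_trace)
  }
  q <- stats::quantile(x, c(1, 3) / 4, names = FALSE)
  s0 <- max(stats::sd(x), 1e-10)
  fit_q <- run_em(c(0.5, 0.5), q, c(s0, s0))
  # collapsed start: both components at the k = 1 MLE (same likelihood)
  mu1 <- mean(x); sd1 <- sqrt(mean((x - mu1)^2))
  fit_c <- list(w = c(0.5, 0.5), mu = c(mu1, mu1), sd = c(sd1, sd1),
                loglik = mix_loglik(x, c(0.5, 0.5), c(mu1, mu1),
                                    c(sd1, sd1)),
                n_iter = 0L, converged = TRUE,
                trace = numeric())
  best <- if (fit_q$loglik >= fit_c$loglik) fit_q else fit_c
  ord <- order(best$mu)
  new_mixture_fit(2L, best$w[ord], best$mu[ord], best$sd[ord],
                  best$loglik, n_iter = best$n_iter,
                  converged = best$converged, n = n, rates = x,
                  trace = best$trace)
}

new_mixture_fit <- function(k, w, mu, sd, loglik, n_iter, converged, n,
                            rates, trace = numeric()) {
  params <- if (k == 1) 2L else 5L
  structure(list(k = k, weights = w, means = mu, sds = sd,
                 loglik = loglik, bic = -2 * loglik + params * log(n),
                 n_iter = n_iter, converged = converged, n = n,
                 rates = rates, loglik_trace = trace),
            class = "mixture_fit")
}

#' Choose between one- and two-component fits by BIC
#'
#' @param fit1,fit2 `mixture_fit` objects for the same data.
#' @return The fit with the lower BIC.
#' @export
select_model <- function(fit1, fit2) {
  stopifnot(inherits(fit1, "mixture_fit"), inherits(fit2, "mixture_fit"))
  if (fit1$bic <= fit2$bic) fit1 else fit2
}

#' Fit and select the SNP-rate mixture in one call
#'
#' @inheritParams fit_mixture
#' @return The BIC-selected `mixture_fit` with both candidates attached
#'   as attributes `fit1` and `fit2`.
#' @export
fit_snp_mixture <- function(rates, tol = 1e-8, max_iter = 500L) {
  f1 <- fit_mixture(rates, 1L, tol, max_iter)
  f2 <- tryCatch(fit_mixture(rates, 2L, tol, max_iter),
                 error = function(e) NULL)
  best <- if (is.null(f2)) f1 else select_model(f1, f2)
  attr(best, "fit1") <- f1
  attr(best, "fit2") <- f2
  best
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("Gaussian mixture fit: k = %d, n = %d, loglik = %.3f, BIC = %.3f\n",
              x$k, x$n, x$loglik, x$bic))
  for (j in seq_len(x$k)) {
    cat(sprintf("  component %d: weight %.3f, mean %.5f, sd %.5f\n",
                j, x$weights[j], x$means[j], x$sds[j]))
  }
  invisible(x)
}

#' Tidy a mixture fit
#'
#' @param x A `mixture_fit`.
#' @param ... Ignored.
#' @return Tibble with one row per component: `component`, `weight`,
#'   `mean`, `sd`.
#' @export
tidy.mixture_fit <- function(x, ...) {
  tibble(component = seq_len(x$k), weight = x$weights, mean = x$means,
         sd = x$sds)
}

#' One-row summary of a mixture fit
#'
#' @param x A `mixture_fit`.
#' @param ... Ignored.
#' @return Tibble: `k`, `loglik`, `bic`, `n_iter`, `converged`, `n`.
#' @export
glance.mixture_fit <- function(x, ...) {
  tibble(k = x$k, loglik = x$loglik, bic = x$bic, n_iter = x$n_iter,
         converged = x$converged, n = x$n)
}

#' Plot a mixture fit over the rate histogram
#'
#' @param object A `mixture_fit`.
#' @param bins Histogram bins.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.mixture_fit <- function(object, bins = 60, ...) {
  df <- tibble(rate = object$rates)
  grid <- seq(min(df$rate), max(df$rate), length.out = 400)
  dens <- rowSums(vapply(seq_len(object$k), function(j)
    object$weights[j] * stats::dnorm(grid, object$means[j],
                                     object$sds[j]),
    numeric(length(grid))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rate)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey80",
                            colour = "grey50") +
    ggplot2::geom_line(data = tibble(rate = grid, density = dens),
                       ggplot2::aes(y = .data$density),
                       colour = "firebrick", linewidth = 0.8) +
    ggplot2::labs(x = "window SNP rate", y = "density") +
    ggplot2::theme_minimal()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
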