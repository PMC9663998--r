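#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
print.exp_fit <- function(x, ...) {
  cat("Exponential elongation fit: eps(t) = A (1 - exp(-t/tau))\n")
  cat(sprintf("  A   = %.4g (se %.2g)\n", x$A, x$se[["A"]]))
  cat(sprintf("  tau = %.4g (se %.2g)\n", x$tau, x$se[["tau"]]))
  cat(sprintf("  rss = %.3g over %d points\n", x$rss, x$n))
  invisible(x)
}

#' Tidy an elongation fit
#'
#' @param x An `exp_fit`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`.
#' @export
tidy.exp_fit <- function(x, ...) {
  terms <- names(x$se)
  est <- c(A = x$A, tau = x$tau, t0 = x$t0)[terms]
  tibble::tibble(term = terms, estimate = unname(est),
                 std.error = unname(x$se))
}

#' @rdname tidy.exp_fit
#' @export
glance.exp_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, sigma = sqrt(x$rss / max(x$n - 2, 1)),
                 nobs = x$n)
}

#' @export
print.two_mode_fit <- function(x, ...) {
  cat("Two-mode contraction fit: eps(t) = B1 exp(-t/tau1) + B2 exp(-t/tau2)\n")
  cat(sprintf("  tau1 = %.4g ms, tau2 = %.4g ms (B1 %.3g, B2 %.3g)\n",
              x$tau1, x$tau2, x$B1, x$B2))
  cat(sprintf("  rss = %.3g (single-mode rss = %.3g)\n", x$rss,
              x$single$rss))
  invisible(x)
}

#' Tidy a contraction fit
#'
#' @param x A `two_mode_fit`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`.
#' @export
tidy.two_mode_fit <- function(x, ...) {
  tibble::tibble(term = c("B1", "tau1", "B2", "tau2"),
                 estimate = c(x$B1, x$tau1, x$B2, x$tau2),
                 std.error = unname(x$se[c("B1", "tau1", "B2", "tau2")]))
}

#' @rdname tidy.two_mode_fit
#' @export
glance.two_mode_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, rss_single = x$single$rss, nobs = x$n,
                 tau_ratio = x$tau2 / x$tau1)
}

#' @export
print.power_law_fits <- function(x, ...) {
  cat("Piecewise speed-length power laws (log-log OLS)\n")
  for (f in x)
    cat(sprintf("  range %.3g-%.3g: exponent %.3g (n = %d)\n",
                f$range[1], f$range[2], f$exponent, f$n))
  invisible(x)
}

#' Tidy piecewise power-law fits
#'
#' @param x A `power_law_fits`.
#' @param ... Unused.
#' @return Tibble with one row per range.
#' @export
tidy.power_law_fits <- function(x, ...) {
  tibble::tibble(
    range_lo = vapply(x, function(f) f$range[1], numeric(1)),
    range_hi = vapply(x, function(f) f$range[2], numeric(1)),
    exponent = vapply(x, function(f) f$exponent, numeric(1)),
    intercept = vapply(x, function(f) f$intercept, numeric(1)),
    n = vapply(x, function(f) f$n, numeric(1))
  )
}
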