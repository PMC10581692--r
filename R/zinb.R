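# Zero-inflated negative binomial (ZINB) model: pmf, sampler, mean, MLE fit.
#
# Parameterisation throughout: theta = zero-inflation proportion ("real"
# zeros), r = NB size, p = NB success probability, so the NB mean is
# p * r / (1 - p) and the ZINB mean is (1 - theta) * p * r / (1 - p).

.check_zinb_params <- function(theta, r, p) {
  if (!is.numeric(theta) || anyNA(theta) || any(theta < 0 | theta > 1))
    stop("`theta` must be a proportion in [0, 1]", call. = FALSE)
  if (!is.numeric(r) || anyNA(r) || any(r <= 0))
    stop("`r` (size) must be a positive real", call. = FALSE)
  if (!is.numeric(p) || anyNA(p) || any(p <= 0 | p >= 1))
    stop("`p` must be a probability in (0, 1)", call. = FALSE)
  invisible(TRUE)
}

# Log density with the continuous gamma-function extension of the binomial
# coefficient, valid for any x >= 0 (median-normalized counts are not
# integral). Vectorised over x.
.dzinb_log <- function(x, theta, r, p) {
  nb_log <- lgamma(x + r) - lgamma(r) - lgamma(x + 1) +
    x * log(p) + r * log1p(-p)
  out <- log1p(-theta) + nb_log
  if (theta > 0) {
    is0 <- x == 0
    if (any(is0)) {
      # P(0) = theta + (1 - theta) * (1 - p)^r, computed stably
      out[is0] <- log(theta + exp(log1p(-theta) + r * log1p(-p)))
    }
  }
  out
}

#' ZINB probability mass function
#'
#' Probability of observing count `n` under a zero-inflated negative
#' binomial: `theta * I(n == 0) + (1 - theta) * choose(n + r - 1, n) *
#' p^n * (1 - p)^r`. Evaluated in log space internally.
#'
#' @param n Non-negative integer count (vectorised).
#' @param theta Zero-inflation proportion in `[0, 1]`.
#' @param r NB size parameter, `> 0`.
#' @param p NB success probability in `(0, 1)`.
#' @param log Return the log probability?
#' @return Numeric vector of probabilities (or log probabilities).
#' @examples
#' dzinb(0, theta = 1, r = 2, p = 0.5)   # 1: pure zero inflation
#' dzinb(0, theta = 0, r = 2, p = 0.5)   # (1 - p)^r = 0.25
#' @export
dzinb <- function(n, theta, r, p, log = FALSE) {
  .check_zinb_params(theta, r, p)
  if (!is.numeric(n) || anyNA(n) || any(n < 0))
    stop("`n` must be a non-negative integer count", call. = FALSE)
  if (any(n != floor(n)))
    stop("`n` must be integral; the pmf is defined on counts", call. = FALSE)
  lp <- .dzinb_log(n, theta, r, p)
  if (log) lp else exp(lp)
}

#' Sample ZINB-distributed counts
#'
#' Draws are structural zeros with probability `theta`, otherwise negative
#' binomial with size `r` and success probability `p` (mean
#' `p * r / (1 - p)`).
#'
#' @inheritParams dzinb
#' @param n Number of draws.
#' @param seed Optional integer; if given the draws are reproducible and the
#'   caller's RNG state is left untouched.
#' @return Integer vector of length `n`.
#' @export
rzinb <- function(n, theta, r, p, seed = NULL) {
  .check_zinb_params(theta, r, p)
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != floor(n))
    stop("`n` must be a positive integer", call. = FALSE)
  draw <- function() {
    x <- stats::rnbinom(n, size = r, prob = 1 - p)
    if (theta > 0)
      x[stats::runif(n) < theta] <- 0L
    as.integer(x)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' ZINB expected count
#'
#' `mu = (1 - theta) * p * r / (1 - p)`.
#'
#' @param fit A `zinb_fit` object, or the `theta` parameter if `r`, `p` are
#'   supplied directly.
#' @param r,p NB parameters when `fit` is given as a plain `theta` value.
#' @return Non-negative expected count.
#' @export
zinb_mean <- function(fit, r = NULL, p = NULL) {
  if (inherits(fit, "zinb_fit") || (is.list(fit) && all(c("theta", "r", "p") %in% names(fit)))) {
    theta <- fit$theta; r <- fit$r; p <- fit$p
  } else {
    theta <- fit
  }
  if (theta == 1) return(0)  # degenerate all-zero convention: r, p unused
  .check_zinb_params(theta, r, p)
  (1 - theta) * p * r / (1 - p)
}

.zinb_nll <- function(par, x) {
  theta <- stats::plogis(par[1L])
  r <- exp(par[2L])
  p <- stats::plogis(par[3L])
  if (!is.finite(r) || r <= 0) return(Inf)
  nll <- -sum(.dzinb_log(x, theta, r, p))
  if (!is.finite(nll)) Inf else nll
}

.nb_nll <- function(par, x) .zinb_nll(c(-Inf, par), x)

#' Fit a ZINB model by maximum likelihood
#'
#' Direct MLE on the unconstrained scale (logit `theta`, log `r`, logit
#' `p`) by quasi-Newton optimisation, initialised from the observed zero
#' fraction and negative-binomial method-of-moments. Observations may be
#' non-integral (e.g. median-normalized counts); the likelihood uses the
#' continuous gamma-function extension of the NB coefficient.
#'
#' Degenerate inputs: an all-zero vector returns the `theta = 1`
#' convention (expected count 0, converged); a vector without zeros is
#' fitted with `theta` fixed at the 0 boundary, i.e. a plain NB MLE.
#'
#' @param x Non-negative numeric observations, at least 5 of them.
#' @return An object of class `zinb_fit`: list with `theta`, `r`, `p`,
#'   `mu` (expected count), `loglik`, `n_obs`, `converged`, `boundary`.
#' @export
fit_zinb <- function(x) {
  if (!is.numeric(x) || anyNA(x))
    stop("`x` must be numeric with no missing values", call. = FALSE)
  if (length(x) < 5L)
    stop("ZINB fitting requires at least 5 observations, got ", length(x),
         call. = FALSE)
  if (any(x < 0))
    stop("counts must be non-negative", call. = FALSE)

  n <- length(x)
  if (all(x == 0)) {
    fit <- list(theta = 1, r = 1, p = 0.5, mu = 0, loglik = 0,
                n_obs = n, converged = TRUE, boundary = "all_zero")
    class(fit) <- "zinb_fit"
    return(fit)
  }

  # Moment-based NB start: r from mean/variance, p from the mean
  mom_nb <- function(m, v) {
    r0 <- if (v > m) m^2 / (v - m) else 100
    r0 <- min(max(r0, 1e-3), 1e4)
    p0 <- min(max(m / (m + r0), 1e-4), 1 - 1e-4)
    c(log(r0), stats::qlogis(p0))
  }

  zfrac <- mean(x == 0)

  # Box constraints on the working scale keep the optimiser away from the
  # r -> Inf ridge where lgamma(x + r) - lgamma(r) loses all precision.
  lo_nb <- c(log(1e-3), stats::qlogis(1e-6))
  hi_nb <- c(log(1e4), stats::qlogis(1 - 1e-6))

  if (zfrac == 0) {
    start <- mom_nb(mean(x), stats::var(x))
    opt <- stats::optim(start, .nb_nll, x = x, method = "L-BFGS-B",
                        lower = lo_nb, upper = hi_nb,
                        control = list(maxit = 500))
    if (opt$value > .nb_nll(start, x)) opt <- list(par = start, value = .nb_nll(start, x), convergence = 1L)
    fit <- list(theta = 0, r = exp(opt$par[1L]),
                p = stats::plogis(opt$par[2L]),
                loglik = -opt$value, n_obs = n,
                converged = opt$convergence == 0L, boundary = "theta_zero")
  } else {
    # Two starts: moderate zero inflation, and near-zero inflation with
    # moments taken over all observations.
    m_all <- mean(x); v_all <- stats::var(x)
    th_starts <- unique(pmin(pmax(c(0.5 * zfrac, 0.9 * zfrac, 0.01), 0.01),
                             0.95))
    starts <- lapply(th_starts, function(th)
      c(stats::qlogis(th), mom_nb(m_all / (1 - th), v_all)))
    lo <- c(stats::qlogis(1e-8), lo_nb)
    hi <- c(stats::qlogis(1 - 1e-8), hi_nb)
    best <- NULL
    for (s in starts) {
      o <- tryCatch(
        stats::optim(pmin(pmax(s, lo), hi), .zinb_nll, x = x,
                     method = "L-BFGS-B", lower = lo, upper = hi,
                     control = list(maxit = 500)),
        error = function(e) list(par = s, value = .zinb_nll(s, x), convergence = 52L))
      if (is.null(best) || o$value < best$value) best <- o
    }
    # never report a point worse than the moment-based start
    v0 <- .zinb_nll(starts[[1L]], x)
    if (best$value > v0) best <- list(par = starts[[1L]], value = v0, convergence = 1L)
    fit <- list(theta = stats::plogis(best$par[1L]),
                r = exp(best$par[2L]),
                p = stats::plogis(best$par[3L]),
                loglik = -best$value, n_obs = n,
                converged = best$convergence == 0L, boundary = "interior")
  }
  fit$mu <- zinb_mean(fit$theta, fit$r, fit$p)
  class(fit) <- "zinb_fit"
  fit
}

#' @export
print.zinb_fit <- function(x, ...) {
  cat(sprintf(
    "ZINB fit (n = %d): theta = %.4f, r = %.4f, p = %.4f, mu = %.4f\n",
    x$n_obs, x$theta, x$r, x$p, x$mu))
  cat(sprintf("  loglik = %.3f, converged = %s\n", x$loglik, x$converged))
  invisible(x)
}
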