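#' Psychometric function for 2AFC viscosity discrimination
#'
#' Probability that a test stimulus of viscosity `eta` is judged thicker
#' than a reference of perceived viscosity `p`, for a Weber fraction `w`:
#'
#' \deqn{f(\eta) = \tfrac12 + \tfrac12\,
#'   \mathrm{erf}\!\left(\frac{\log(\eta/p)}{\sqrt2\,\log(w+1)}\right)}
#'
#' i.e. a cumulative Gaussian in log viscosity whose slope is set directly
#' by the Weber fraction: at `eta = p*(1+w)` the curve passes through
#' 0.8413 (the 84% discriminability threshold) and at `eta = p/(1+w)`
#' through 0.1587. The log base cancels between numerator and denominator,
#' so the natural log used here is a pure convention.
#'
#' @param eta Test viscosity (cP), positive; vectorized.
#' @param w Weber fraction, positive.
#' @param p Reference / PSE viscosity (cP), positive.
#' @return Probability of a "test thicker" response, in (0, 1).
#' @examples
#' psychometric_prob(1500, w = 0.5, p = 1000)  # 0.8413
#' @export
psychometric_prob <- function(eta, w, p) {
  if (any(eta <= 0) || any(!is.finite(eta))) stop("eta must be positive")
  if (length(w) != 1L || !is.finite(w) || w <= 0) stop("w must be positive")
  if (length(p) != 1L || !is.finite(p) || p <= 0) stop("p must be positive")
  stats::pnorm(log(eta / p) / log1p(w))
}

# epsilon clip keeps log-likelihood finite for k=0 / k=n rows at extreme
# parameter values
.prob_eps <- 1e-9

#' Binomial negative log-likelihood of a response table
#'
#' Independent-binomial likelihood of the pooled k-of-n counts at each test
#' viscosity under the psychometric model. Probabilities are clipped to
#' `[1e-9, 1 - 1e-9]`.
#'
#' @param table A `response_table` (or data.frame with `eta_cp`,
#'   `k_thicker`, `n_total`).
#' @inheritParams psychometric_prob
#' @return Non-negative scalar, the negative log-likelihood.
#' @export
psychometric_nll <- function(table, w, p) {
  if (nrow(table) == 0L) stop("empty response table")
  f <- psychometric_prob(table$eta_cp, w, p)
  f <- pmin(pmax(f, .prob_eps), 1 - .prob_eps)
  -sum(table$k_thicker * log(f) +
         (table$n_total - table$k_thicker) * log1p(-f))
}

#' Fitting constraints and starting values
#'
#' Box constraints and initial values for the maximum-likelihood fit. The
#' defaults are the analysis-wide conventions: `w` confined to
#' `[0.1, 100]`, `p` to `[10, 20500]` cP, starting from
#' `(w, p) = (0.5, p_true)`.
#'
#' @param w_bounds,p_bounds Length-2 numeric intervals.
#' @param w_init Starting Weber fraction.
#' @param p_init Starting PSE; `NA` means "use the true reference".
#' @return List of class `fit_constraints`.
#' @export
fit_constraints <- function(w_bounds = c(0.1, 100),
                            p_bounds = c(10, 20500),
                            w_init = 0.5, p_init = NA_real_) {
  stopifnot(length(w_bounds) == 2L, w_bounds[1] > 0,
            w_bounds[1] < w_bounds[2],
            length(p_bounds) == 2L, p_bounds[1] > 0,
            p_bounds[1] < p_bounds[2])
  if (w_init < w_bounds[1] || w_init > w_bounds[2]) {
    stop("w_init outside w_bounds")
  }
  if (!is.na(p_init) && (p_init < p_bounds[1] || p_init > p_bounds[2])) {
    stop("p_init outside p_bounds")
  }
  structure(list(w_bounds = w_bounds, p_bounds = p_bounds,
                 w_init = w_init, p_init = p_init),
            class = "fit_constraints")
}

# relative closeness to a box edge that we treat as "pinned at the bound"
.bound_tol <- 1e-4

#' Maximum-likelihood psychometric fit
#'
#' Minimizes the binomial negative log-likelihood over `(w, p)` in log
#' coordinates within box constraints. Two modes:
#' \describe{
#'   \item{`fixed_p`}{`p` pinned to the true reference viscosity; only the
#'     Weber fraction is estimated (symmetric discrimination tasks).}
#'   \item{`free_p`}{both `p` (the PSE) and `w` are estimated
#'     (bias / PSE tasks).}
#' }
#' Optimization uses L-BFGS-B (Brent in one dimension) on `(log w, log p)`
#' with a Nelder-Mead restart on failure. An optimum within `1e-4`
#' relative distance of a box edge, a degenerate table (all `k = 0` or all
#' `k = n`), or an optimizer failure yields `converged = FALSE` — never an
#' error.
#'
#' @param table A `response_table` with at least 2 rows.
#' @param mode `"fixed_p"` or `"free_p"`.
#' @param p_true True reference viscosity (cP). Defaults to the
#'   `reference_viscosity_cp` attribute of `table`.
#' @param constraints A [fit_constraints()] object.
#' @return Object of class `psychfit`: list with `w`, `p`, `mode`,
#'   `log_likelihood`, `converged`, `n_points`, `p_true`.
#' @examples
#' tab <- data.frame(eta_cp = c(500, 800, 1000, 1300, 2000),
#'                   n_total = 60)
#' tab$k_thicker <- round(60 * psychometric_prob(tab$eta_cp, 0.6, 1000))
#' fit_psychometric(tab, mode = "fixed_p", p_true = 1000)
#' @export
fit_psychometric <- function(table, mode = c("fixed_p", "free_p"),
                             p_true = attr(table, "reference_viscosity_cp"),
                             constraints = fit_constraints()) {
  mode <- match.arg(mode)
  if (nrow(table) < 2L) stop("need at least 2 response rows")
  if (is.null(p_true) || !is.finite(p_true) || p_true <= 0) {
    stop("p_true must be a positive reference viscosity")
  }
  cs <- constraints
  p_init <- if (is.na(cs$p_init)) p_true else cs$p_init
  p_init <- min(max(p_init, cs$p_bounds[1]), cs$p_bounds[2])

  degenerate <- all(table$k_thicker == 0L) ||
    all(table$k_thicker == table$n_total)

  nll_w <- function(lw) psychometric_nll(table, exp(lw), p_true)
  nll_wp <- function(par) psychometric_nll(table, exp(par[1]), exp(par[2]))

  converged <- TRUE
  if (mode == "fixed_p") {
    opt <- stats::optim(log(cs$w_init), nll_w, method = "Brent",
                        lower = log(cs$w_bounds[1]),
                        upper = log(cs$w_bounds[2]),
                        control = list(reltol = 1e-12))
    w_hat <- exp(opt$par)
    p_hat <- p_true
    nll <- opt$value
    converged <- opt$convergence == 0L
  } else {
    lower <- log(c(cs$w_bounds[1], cs$p_bounds[1]))
    upper <- log(c(cs$w_bounds[2], cs$p_bounds[2]))
    start <- log(c(cs$w_init, p_init))
    opt <- tryCatch(
      stats::optim(start, nll_wp, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(factr = 1e7)),  # ~1e-8 absolute on NLL
      error = function(e) NULL)
    if (is.null(opt) || opt$convergence != 0L) {
      # derivative-free restart: simplex on a softly penalized objective
      pen <- function(par) {
        out <- sum(pmax(0, par - upper)^2) + sum(pmax(0, lower - par)^2)
        par <- pmin(pmax(par, lower), upper)
        nll_wp(par) + 1e4 * out
      }
      opt2 <- stats::optim(start, pen, method = "Nelder-Mead",
                           control = list(reltol = 1e-10, maxit = 2000))
      opt2$par <- pmin(pmax(opt2$par, lower), upper)
      if (is.null(opt) || opt2$value <= opt$value) {
        opt <- opt2
        converged <- opt2$convergence == 0L
      }
    }
    w_hat <- exp(opt$par[1])
    p_hat <- exp(opt$par[2])
    nll <- nll_wp(opt$par)
  }

  at_bound <- function(x, bounds) {
    log_span <- log(bounds[2]) - log(bounds[1])
    min(log(x) - log(bounds[1]), log(bounds[2]) - log(x)) < .bound_tol * log_span
  }
  pinned <- at_bound(w_hat, cs$w_bounds) ||
    (mode == "free_p" && at_bound(p_hat, cs$p_bounds))
  if (degenerate || pinned) converged <- FALSE

  structure(list(w = w_hat, p = p_hat, mode = mode,
                 log_likelihood = -nll, converged = converged,
                 n_points = nrow(table), p_true = p_true),
            class = "psychfit")
}

#' @export
print.psychfit <- function(x, ...) {
  cat("Psychometric fit (", x$mode, ")\n", sep = "")
  cat("  Weber fraction w = ", signif(x$w, 4), "\n", sep = "")
  cat("  PSE p = ", signif(x$p, 6), " cP",
      if (x$mode == "fixed_p") " [pinned to reference]", "\n", sep = "")
  cat("  logLik = ", signif(x$log_likelihood, 6),
      ", points = ", x$n_points,
      ", converged = ", x$converged, "\n", sep = "")
  invisible(x)
}

#' @export
logLik.psychfit <- function(object, ...) {
  structure(object$log_likelihood,
            df = if (object$mode == "free_p") 2L else 1L,
            class = "logLik")
}

#' @export
predict.psychfit <- function(object, eta, ...) {
  psychometric_prob(eta, object$w, object$p)
}

#' @export
coef.psychfit <- function(object, ...) c(w = object$w, p = object$p)

#' Just-noticeable-difference bounds
#'
#' The JND around a reference `p` for Weber fraction `w` is the pair of
#' viscosities discriminated from the reference at the 84%/16% response
#' levels: `upper = p*(1+w)` and `lower = p/(1+w)`.
#'
#' @param w Weber fraction (or a `psychfit` object as first argument).
#' @param p Reference viscosity (cP); ignored when `w` is a `psychfit`.
#' @return Named numeric vector `c(lower, upper)` in cP.
#' @examples
#' weber_jnd(w = 1.0, p = 547)  # 273.5, 1094
#' @export
weber_jnd <- function(w, p) {
  if (inherits(w, "psychfit")) {
    p <- w$p
    w <- w$w
  }
  stopifnot(w > 0, p > 0)
  c(lower = p / (1 + w), upper = p * (1 + w))
}

#' Serialize a fit to a JSON record
#'
#' @param fit A `psychfit` object.
#' @param path Optional output path; if `NULL`, the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
fit_to_json <- function(fit, path = NULL) {
  rec <- list(mode = fit$mode, w = fit$w, p = fit$p,
              loglik = fit$log_likelihood, converged = fit$converged,
              n_points = fit$n_points, p_true = fit$p_true)
  js <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
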