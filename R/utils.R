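# Shared numerical helpers and constants.

# Gas constant, J/(mol K)
GAS_CONSTANT <- 8.314

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so generators are reproducible without clobbering the global
#' random stream.
#'
#' @param seed Integer seed, or `NULL` to use the current stream.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Parameter table (estimate, se, 95% CI) from an nls.lm fit.
# df = residual degrees of freedom; singular information matrices yield NA
# standard errors rather than an error, so callers can flag the fit.
nlslm_param_table <- function(fit, df) {
  est <- fit$par
  hess <- fit$hessian
  se <- rep(NA_real_, length(est))
  s2 <- fit$deviance / max(df, 1)
  cov <- try(solve(hess) * 2 * s2, silent = TRUE)
  if (!inherits(cov, "try-error")) {
    d <- diag(cov)
    se[d >= 0] <- sqrt(d[d >= 0])
  }
  tq <- stats::qt(0.975, max(df, 1))
  data.frame(
    parameter = names(est), estimate = unname(unlist(est)), se = se,
    ci_lo = unname(unlist(est)) - tq * se,
    ci_hi = unname(unlist(est)) + tq * se,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

# Levenberg-Marquardt least squares with multiple starts; returns the
# converged fit with the lowest deviance.  `starts` is a list of named
# parameter vectors (as lists); `lower`/`upper` are box bounds.
multistart_nlslm <- function(resid_fn, starts, lower, upper,
                             control = minpack.lm::nls.lm.control(maxiter = 200)) {
  best <- NULL
  for (st in starts) {
    fit <- try(minpack.lm::nls.lm(par = st, fn = resid_fn,
                                  lower = lower, upper = upper,
                                  control = control), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("nonlinear least-squares failed from every start")
  best
}

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a positive finite scalar", name))
  invisible(x)
}
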