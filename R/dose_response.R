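# IC50 dose-response: four-parameter logistic fitting of kinase-inhibition
# data (luminescent ADP readout) and fold-enhancement comparison between
# inhibitors.

# 4PL in log10-concentration: response falls from `top` to `bottom` around
# log10(IC50) with slope `hill`.
.fourpl <- function(conc, ic50, hill, top, bottom) {
  bottom + (top - bottom) / (1 + (conc / ic50)^hill)
}

#' Fit a sigmoidal dose-response curve (4PL)
#'
#' Global four-parameter logistic fit across replicate dose-response
#' series: `y = bottom + (top - bottom) / (1 + (c/IC50)^hill)`, fitted in
#' log10-concentration with IC50 on the log scale and the Hill slope
#' bounded to \[0.3, 4\]. All four parameters are shared across replicates
#' (plateaus can instead be fixed via `top`/`bottom`). A response range
#' smaller than three times the replicate noise makes the IC50
#' unidentifiable and raises an error.
#'
#' @param data Data frame with columns `conc_M`, `response`, optionally
#'   `replicate`.
#' @param top,bottom Optional fixed plateaus (default both free).
#' @param hill_bounds Bounds for the Hill slope.
#' @return Object of class `"ic50_fit"`: `IC50`, `sigma_IC50`, `ci_IC50`
#'   (95%), `hill`, `top`, `bottom`, parameter table, `converged`.
#' @examples
#' d <- generate_scenario("ic50_bisubstrate", seed = 1)
#' fit_ic50(d$data)$IC50
#' @export
fit_ic50 <- function(data, top = NULL, bottom = NULL,
                     hill_bounds = c(0.3, 4)) {
  stopifnot(all(c("conc_M", "response") %in% names(data)))
  if (any(data$conc_M <= 0)) stop("concentrations must be > 0")
  concs <- sort(unique(data$conc_M))
  if (length(concs) < 5) stop("need at least 5 distinct concentrations")

  # identifiability: response swing must exceed 3x the replicate noise
  mu <- as.numeric(tapply(data$response, factor(data$conc_M, levels = concs),
                          mean))  # aligned with `concs`
  noise <- stats::sd(data$response -
                       stats::ave(data$response, data$conc_M, FUN = mean))
  if (!is.finite(noise)) noise <- 0
  swing <- diff(range(mu))
  if (swing < 3 * noise || swing == 0)
    stop(structure(class = c("peptherm_unidentifiable", "error", "condition"),
                   list(message = "response range below 3x noise: IC50 unidentifiable",
                        call = sys.call())))

  fix_top <- !is.null(top); fix_bottom <- !is.null(bottom)
  resid_fn <- function(p) {
    tp <- if (fix_top) top else p[["top"]]
    bt <- if (fix_bottom) bottom else p[["bottom"]]
    data$response - .fourpl(data$conc_M, 10^p[["l10ic50"]], p[["hill"]], tp, bt)
  }
  top0 <- max(mu); bot0 <- min(mu)
  mid <- (top0 + bot0) / 2
  ic50_0 <- concs[which.min(abs(mu - mid))]
  starts <- lapply(log10(c(ic50_0, ic50_0 / 30, ic50_0 * 30,
                           min(concs) * 10, max(concs) / 10)), function(l) {
    st <- list(l10ic50 = l, hill = 1)
    if (!fix_top) st$top <- top0
    if (!fix_bottom) st$bottom <- bot0
    st
  })
  nfree <- 2 + (!fix_top) + (!fix_bottom)
  lower <- c(log10(min(concs)) - 4, hill_bounds[1],
             rep(-Inf, nfree - 2))
  upper <- c(log10(max(concs)) + 4, hill_bounds[2], rep(Inf, nfree - 2))
  fit <- multistart_nlslm(resid_fn, starts, lower, upper,
                          control = minpack.lm::nls.lm.control(
                            maxiter = 500, ftol = 1e-14, ptol = 1e-14))
  df <- nrow(data) - length(fit$par)
  ptab <- nlslm_param_table(fit, df)
  i <- match("l10ic50", ptab$parameter)
  ic50 <- 10^ptab$estimate[i]
  ln10 <- log(10)
  structure(list(
    IC50 = ic50, sigma_IC50 = ic50 * ln10 * ptab$se[i],
    ci_IC50 = 10^c(ptab$ci_lo[i], ptab$ci_hi[i]),
    hill = ptab$estimate[match("hill", ptab$parameter)],
    top = if (fix_top) top else ptab$estimate[match("top", ptab$parameter)],
    bottom = if (fix_bottom) bottom
             else ptab$estimate[match("bottom", ptab$parameter)],
    parameters = ptab, converged = fit$info %in% 1:4,
    deviance = fit$deviance, n_obs = nrow(data)
  ), class = "ic50_fit")
}

#' @export
print.ic50_fit <- function(x, ...) {
  cat(sprintf("4PL dose-response fit (%d points)\n", x$n_obs))
  cat(sprintf("  IC50 = %.3g +/- %.2g M  [95%% CI %.3g, %.3g];  hill = %.2f\n",
              x$IC50, x$sigma_IC50, x$ci_IC50[1], x$ci_IC50[2], x$hill))
  invisible(x)
}

#' Fold enhancement between two inhibitors
#'
#' Potency gain of a derived compound over its parent as the IC50 ratio
#' parent/derived, with the standard quotient error propagation
#' `sigma_ratio = ratio * sqrt((s_p/p)^2 + (s_d/d)^2)`.
#'
#' @param ic50_parent,ic50_derived IC50 values, same units (> 0).
#' @param sigma_parent,sigma_derived Optional standard errors.
#' @return List `ratio`, `sigma` (NA when no errors given).
#' @examples
#' fold_enhancement(8.0e-6, 0.67e-6)$ratio  # ~11.9
#' @export
fold_enhancement <- function(ic50_parent, ic50_derived,
                             sigma_parent = NULL, sigma_derived = NULL) {
  stopifnot_scalar_pos(ic50_parent, "ic50_parent")
  stopifnot_scalar_pos(ic50_derived, "ic50_derived")
  ratio <- ic50_parent / ic50_derived
  sigma <- if (is.null(sigma_parent) && is.null(sigma_derived)) NA_real_
  else ratio * sqrt(((sigma_parent %||% 0) / ic50_parent)^2 +
                      ((sigma_derived %||% 0) / ic50_derived)^2)
  list(ratio = ratio, sigma = sigma)
}
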