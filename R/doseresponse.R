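# Hill-equation concentration-response fitting. The model is
#   response = baseline + Emax * c^nH / (c^nH + EC50^nH)
# with the baseline optionally fixed to 0 (the convention for normalized
# GABA currents and for percent-potentiation curves). EC50 is fitted on the
# log10 scale to keep it positive.

#' Hill equation response
#'
#' @param conc concentration(s), same units as \code{ec50}.
#' @param ec50 half-maximal concentration (> 0).
#' @param hill Hill coefficient (> 0).
#' @param emax maximal response above baseline.
#' @param baseline response at zero concentration.
#' @return Response value(s).
#' @examples
#' hillResponse(1, ec50 = 1, hill = 1, emax = 1)  # 0.5
#' @export
hillResponse <- function(conc, ec50, hill, emax, baseline = 0) {
  stopifnot(ec50 > 0, hill > 0)
  baseline + emax * conc^hill / (conc^hill + ec50^hill)
}

checkDoseTable <- function(table) {
  if (!all(c("concentration_uM", "response") %in% names(table)))
    stop("table must have columns concentration_uM and response")
  conc <- table$concentration_uM; resp <- table$response
  if (any(!is.finite(conc)) || any(conc <= 0))
    stop("concentrations must be positive and finite")
  if (any(!is.finite(resp))) stop("responses must be finite")
  if (length(unique(conc)) < 3)
    stop("at least 3 distinct concentrations are required")
  if (diff(range(resp)) == 0)
    stop("all responses are equal; the fit is degenerate")
  invisible(table)
}

#' Fit the Hill equation to a concentration-response table
#'
#' Nonlinear least squares (Levenberg-Marquardt via
#' \code{\link[minpack.lm]{nlsLM}}) of
#' \eqn{R = b + E_{max} c^{n_H} / (c^{n_H} + EC_{50}^{n_H})}, with EC50
#' parameterized as \eqn{10^{\ell}} to enforce positivity. Replicates are
#' pooled (no per-cell weighting). The default initializer takes EC50 at the
#' concentration nearest the half-maximal observed response, a Hill
#' coefficient of 1 and Emax at the maximum observed response; it can be
#' overridden through \code{start}. Non-convergence yields a flagged
#' \linkS4class{HillFit} with diagnostics, not an error.
#'
#' @param table data.frame with columns \code{concentration_uM} and
#'   \code{response} (replicate rows allowed).
#' @param fixBaseline logical; fix the baseline to 0 (default TRUE).
#' @param start optional named list overriding initial values: \code{ec50},
#'   \code{hill}, \code{emax}, \code{baseline}.
#' @return A \linkS4class{HillFit}.
#' @examples
#' tab <- simulateDoseResponse(ec50 = 1, hill = 1.5, emax = 100,
#'                             concentrations = 10^seq(-2, 2, length.out = 8))
#' fitHill(tab)
#' @importFrom minpack.lm nls.lm nls.lm.control
#' @export
fitHill <- function(table, fixBaseline = TRUE, start = NULL) {
  checkDoseTable(table)
  conc <- table$concentration_uM
  resp <- table$response

  emax0 <- start$emax %||% max(resp)
  half <- emax0 / 2
  ec500 <- start$ec50 %||% conc[which.min(abs(resp - half))]
  hill0 <- start$hill %||% 1
  base0 <- start$baseline %||% min(resp)

  # parameters: (log10 EC50, nH, Emax[, baseline])
  model <- function(p) {
    ch <- conc^p[2]
    mu <- p[3] * ch / (ch + (10^p[1])^p[2])
    if (!fixBaseline) mu <- mu + p[4]
    mu
  }
  rfun <- function(p) resp - model(p)
  par0 <- c(log10(ec500), hill0, emax0)
  if (!fixBaseline) par0 <- c(par0, base0)
  # convergence on relative SSE change (ftol); Levenberg-Marquardt
  ctrl <- nls.lm.control(maxiter = 500, ftol = 1e-10)
  out <- tryCatch(minpack.lm::nls.lm(par = par0, fn = rfun, control = ctrl),
                  error = function(e) e)

  naFit <- function(msg) new("HillFit",
    estimates = c(ec50 = NA_real_, hill = NA_real_, emax = NA_real_,
                  baseline = if (fixBaseline) 0 else NA_real_),
    se = c(ec50 = NA_real_, hill = NA_real_, emax = NA_real_,
           baseline = NA_real_),
    fixedBaseline = fixBaseline, converged = FALSE,
    rss = NA_real_, nObs = length(resp), message = msg)
  if (inherits(out, "error")) return(naFit(conditionMessage(out)))

  p <- out$par
  isConv <- out$info %in% 1:4 && all(is.finite(p)) && p[2] > 0
  rss <- sum(out$fvec^2)
  # SEs from the Gauss-Newton approximation J'J at the solution
  np <- length(p)
  seP <- rep(NA_real_, np)
  if (isConv && length(resp) > np) {
    covm <- tryCatch(solve(out$hessian) * rss / (length(resp) - np),
                     error = function(e) NULL)
    if (!is.null(covm)) seP <- sqrt(pmax(diag(covm), 0))
  }
  ec50 <- 10^p[1]
  # delta method: SE(EC50) = ln(10) * EC50 * SE(log10 EC50)
  est <- c(ec50 = ec50, hill = p[2], emax = p[3],
           baseline = if (fixBaseline) 0 else p[4])
  seOut <- c(ec50 = log(10) * ec50 * seP[1], hill = seP[2], emax = seP[3],
             baseline = if (fixBaseline) 0 else seP[4])
  new("HillFit", estimates = est, se = seOut,
      fixedBaseline = fixBaseline, converged = isConv,
      rss = rss, nObs = length(resp),
      message = if (isConv) "" else out$message)
}

#' Concentration producing a given fraction of the maximal response
#'
#' Closed form from the Hill equation:
#' \eqn{EC_f = EC_{50} (f / (1 - f))^{1/n_H}}. The EC5 (f = 0.05) is the
#' conventional low, virtually nondesensitizing agonist concentration used
#' when measuring modulator potentiation.
#'
#' @param fit a converged \linkS4class{HillFit}.
#' @param fraction target response fraction in (0, 1).
#' @return Concentration in the fit's units.
#' @export
ecFraction <- function(fit, fraction = 0.05) {
  if (!is.finite(fraction) || fraction <= 0 || fraction >= 1)
    stop("fraction must lie strictly between 0 and 1")
  if (!converged(fit)) stop("ecFraction requires a converged fit")
  e <- fit@estimates
  unname(e[["ec50"]] * (fraction / (1 - fraction))^(1 / e[["hill"]]))
}

#' Fit a modulator potentiation concentration-response curve
#'
#' Convenience wrapper for percent-potentiation data: the Hill equation is
#' fitted with the baseline fixed to 0, estimating the modulator EC50 and
#' the potentiation plateau Emax (percent).
#'
#' @param table data.frame with columns \code{concentration_uM} and
#'   \code{response} (percent potentiation).
#' @param start optional initializer overrides (see \code{\link{fitHill}}).
#' @return A \linkS4class{HillFit}.
#' @export
fitPotentiation <- function(table, start = NULL) {
  fitHill(table, fixBaseline = TRUE, start = start)
}

#' Percent potentiation of an agonist current by a modulator
#'
#' \eqn{100 (I_{mod} - I_{ctrl}) / I_{ctrl}}: the increase of the
#' GABA-evoked current during modulator coapplication, relative to the
#' current evoked by the same (low, typically EC5) GABA concentration alone.
#'
#' @param iControl current with agonist alone.
#' @param iModulated current with agonist plus modulator.
#' @return Percent potentiation.
#' @export
percentPotentiation <- function(iControl, iModulated) {
  stopifnot(all(iControl > 0))
  100 * (iModulated - iControl) / iControl
}
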