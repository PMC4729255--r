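#' @export
print.hlmm <- function(x, ...) {
  cat("Heteroscedastic random-intercept linear mixed model (",
      if (x$reml) "REML" else "ML", ")\n", sep = "")
  cat("  ", deparse(x$formula), "\n", sep = "")
  if (!is.null(x$random)) {
    cat("  random intercept: ", x$random,
        " (sd = ", signif(sqrt(x$sigma2_plot), 4), ")\n", sep = "")
  }
  cat("  residual sd",
      if (length(x$sigma2_resid) > 1L) paste0(" by ", x$var_group) else "",
      ": ", paste(names(x$sigma2_resid),
                  signif(sqrt(x$sigma2_resid), 4),
                  sep = " = ", collapse = ", "), "\n", sep = "")
  cat("Coefficients:\n")
  print(signif(x$coefficients, 5))
  if (!identical(x$flag, "ok")) cat("Flag:", x$flag, "\n")
  invisible(x)
}

#' Summarize an hlmm fit
#'
#' @param object an `hlmm` fit.
#' @param ... unused.
#' @return object of class `summary.hlmm`: coefficient table with
#'   estimates, standard errors, z-values (estimate/SE) and two-sided
#'   normal p-values, plus variance components and an adjusted-R2-style
#'   fit summary (squared correlation between marginal fitted values and
#'   the response, adjusted for the number of fixed-effect parameters).
#' @export
summary.hlmm <- function(object, ...) {
  ct <- cbind(Estimate = object$coefficients,
              `Std. Error` = object$se,
              `z value` = object$z,
              `Pr(>|z|)` = 2 * pnorm(-abs(object$z)))
  out <- list(call = object$call, formula = object$formula,
              coefficients = ct,
              sigma_plot = sqrt(object$sigma2_plot),
              sigma_resid = sqrt(object$sigma2_resid),
              random = object$random, var_group = object$var_group,
              logLik = object$logLik, reml = object$reml,
              adj_r2 = object$adj_r2, n = object$n, flag = object$flag)
  class(out) <- "summary.hlmm"
  out
}

#' @export
print.summary.hlmm <- function(x, ...) {
  cat("Heteroscedastic random-intercept LMM (",
      if (x$reml) "REML" else "ML", "), n = ", x$n, "\n", sep = "")
  cat("  ", deparse(x$formula), "\n\n", sep = "")
  stats::printCoefmat(x$coefficients, digits = 4, signif.stars = TRUE,
                      na.print = "NA")
  cat("\nVariance components:\n")
  if (!is.null(x$random)) {
    cat("  ", x$random, " intercept sd: ", signif(x$sigma_plot, 4), "\n",
        sep = "")
  }
  cat("  residual sd: ",
      paste(names(x$sigma_resid), signif(x$sigma_resid, 4),
            sep = " = ", collapse = ", "), "\n", sep = "")
  cat("log-likelihood (", if (x$reml) "REML" else "ML", "): ",
      signif(x$logLik, 6), ";  adj. R2: ", signif(x$adj_r2, 3), "\n",
      sep = "")
  if (!identical(x$flag, "ok")) cat("Flag:", x$flag, "\n")
  invisible(x)
}

#' @export
coef.hlmm <- function(object, ...) object$coefficients

#' @export
vcov.hlmm <- function(object, ...) object$vcov

#' @export
nobs.hlmm <- function(object, ...) object$n

#' @export
logLik.hlmm <- function(object, ...) {
  structure(object$logLik,
            df = object$p + length(object$sigma2_resid) +
              as.integer(!is.null(object$random)),
            nobs = object$n, class = "logLik")
}

#' @export
fitted.hlmm <- function(object, type = c("conditional", "marginal"), ...) {
  type <- match.arg(type)
  f <- object$fitted_marginal
  if (type == "conditional" && !is.null(object$blup)) {
    f <- f + object$blup[as.character(object$plot)]
  }
  unname(f)
}

#' Residuals of an hlmm fit
#'
#' `"response"` residuals are observed minus conditional fitted values
#' (fixed effects plus plot BLUPs); `"pearson"` residuals additionally
#' divide by the estimated residual standard deviation of the row's
#' variance stratum, so they are comparable across strata.
#'
#' @param object an `hlmm` fit.
#' @param type `"response"` or `"pearson"`.
#' @param ... unused.
#' @export
residuals.hlmm <- function(object, type = c("response", "pearson"), ...) {
  type <- match.arg(type)
  r <- object$y - fitted(object, type = "conditional")
  if (type == "pearson") {
    r <- r / sqrt(object$sigma2_resid[as.character(object$vgroup)])
  }
  unname(r)
}

#' Predict from an hlmm fit
#'
#' @param object an `hlmm` fit.
#' @param newdata optional data frame; if omitted, fitted values are
#'   returned.
#' @param level `0` for population-level (fixed effects only) predictions,
#'   `1` to add the estimated plot intercept (unknown plots get 0).
#' @param ... unused.
#' @export
predict.hlmm <- function(object, newdata = NULL, level = 0, ...) {
  if (is.null(newdata)) {
    return(fitted(object, type = if (level > 0) "conditional" else "marginal"))
  }
  trm <- stats::delete.response(object$terms)
  mf <- model.frame(trm, newdata, xlev = object$xlevels)
  Xn <- model.matrix(trm, mf, contrasts.arg = object$contrasts)
  pred <- drop(Xn %*% object$coefficients)
  if (level > 0 && !is.null(object$blup) && !is.null(object$random) &&
      object$random %in% names(newdata)) {
    b <- object$blup[as.character(newdata[[object$random]])]
    b[is.na(b)] <- 0
    pred <- pred + b
  }
  unname(pred)
}

#' Simulate responses from an hlmm fit
#'
#' Draws new plot intercepts and residuals from the estimated variance
#' components around the fixed-effect predictions.
#'
#' @param object an `hlmm` fit.
#' @param nsim number of simulated response vectors.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return data frame with `nsim` columns.
#' @export
simulate.hlmm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- object$n
  sdr <- sqrt(object$sigma2_resid[as.integer(object$vgroup)])
  out <- replicate(nsim, {
    y <- object$fitted_marginal + rnorm(n, sd = sdr)
    if (!is.null(object$plot)) {
      b <- rnorm(nlevels(object$plot), sd = sqrt(object$sigma2_plot))
      y <- y + b[as.integer(object$plot)]
    }
    y
  })
  as.data.frame(out, col.names = paste0("sim_", seq_len(nsim)))
}

#' Diagnostic plot for an hlmm fit
#'
#' Pearson residuals against conditional fitted values, coloured by
#' variance stratum.
#'
#' @param x an `hlmm` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.hlmm <- function(x, ...) {
  f <- fitted(x, type = "conditional")
  r <- residuals(x, type = "pearson")
  graphics::plot(f, r, col = as.integer(x$vgroup),
                 xlab = "Conditional fitted values",
                 ylab = "Pearson residuals", ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}
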