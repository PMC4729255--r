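#' Join assemblage metrics with gradient scores for regression
#'
#' Builds the modelling data frame: one row per plot/guild/year with the
#' raw assemblage means, the SES metrics in wide form, and the PCA scores.
#' Reference levels follow the reporting convention: guild `ST`, first
#' year.
#'
#' @param means assemblage means (rows from [assemblage_means()], all
#'   guild/year combinations stacked).
#' @param ses_df SES results from [ses_table()] (any mix of null models),
#'   or `NULL`.
#' @param scores a `gradient_scores` object from [pca_gradient()] or its
#'   `scores` data frame.
#' @return data frame with columns `plot_id`, `guild` (factor, ref `ST`),
#'   `year` (factor, ref first year), `richness`, `resource`, `age_axis`,
#'   `mean_log_size`, `mean_log_n`, and (when available)
#'   `ses_size_regional`, `ses_size_swap`, `ses_n_swap`.
#' @export
gradient_data <- function(means, ses_df = NULL, scores) {
  if (inherits(scores, "gradient_scores")) scores <- scores$scores
  out <- means
  key <- function(d) paste(d$plot_id, d$guild, d$year, sep = "\r")
  if (!is.null(ses_df)) {
    pick <- function(nm, metric) {
      sub <- ses_df[ses_df$null_model == nm & ses_df$metric == metric, ,
                    drop = FALSE]
      if (nrow(sub) == 0L) return(NULL)
      sub$ses[match(key(out), key(sub))]
    }
    v <- pick("regional_pool", "mean_log_size")
    if (!is.null(v)) out$ses_size_regional <- v
    v <- pick("local_swap", "mean_log_size")
    if (!is.null(v)) out$ses_size_swap <- v
    v <- pick("local_swap", "mean_log_n")
    if (!is.null(v)) out$ses_n_swap <- v
  }
  m <- match(out$plot_id, scores$plot_id)
  if (anyNA(m)) {
    stop("gradient_data: plots without environment scores: ",
         paste(unique(out$plot_id[is.na(m)]), collapse = ", "),
         call. = FALSE)
  }
  out$resource <- scores$resource[m]
  out$age_axis <- scores$age_axis[m]
  out$guild <- factor(out$guild, levels = c("ST", "ECM"))
  out$year <- factor(out$year, levels = sort(unique(out$year)))
  rownames(out) <- NULL
  out
}

#' Gradient regressions for assemblage metrics
#'
#' Fits, for each response metric, the linear mixed-effects model with
#' fixed effects guild, year (factor), resource availability, stand age,
#' guild x resource and guild x year; a random plot intercept; and
#' guild-specific residual variances (see [hlmm()]). Reference levels are
#' guild `ST` and the first year. The three-way
#' guild x resource x year interaction is excluded by default and can be
#' added with `with_three_way = TRUE`.
#'
#' @param data data frame from [gradient_data()].
#' @param responses response columns to model (defaults to all metric
#'   columns present in `data`).
#' @param with_three_way include the guild x resource x year interaction.
#' @return object of class `gradient_report`: list with `fits` (named
#'   `hlmm` objects), `coefficients` (long data frame: response, term,
#'   estimate, se, z, stars), `variance_components` and `fit_stats` data
#'   frames. The adjusted R2 reported is the squared correlation between
#'   marginal fitted values and the response, adjusted for the number of
#'   fixed-effect parameters.
#' @export
gradient_models <- function(data,
                            responses = c("mean_log_size", "mean_log_n",
                                          "ses_size_regional",
                                          "ses_size_swap", "ses_n_swap"),
                            with_three_way = FALSE) {
  responses <- intersect(responses, names(data))
  if (length(responses) == 0L) {
    stop("gradient_models: none of the requested responses are in data",
         call. = FALSE)
  }
  multi_year <- nlevels(droplevels(factor(data$year))) > 1L
  both_guilds <- nlevels(droplevels(data$guild)) > 1L
  rhs <- c(if (both_guilds) "guild",
           if (multi_year) "year",
           "resource", "age_axis",
           if (both_guilds) "guild:resource",
           if (both_guilds && multi_year) "guild:year",
           if (with_three_way && both_guilds && multi_year)
             c("resource:year", "guild:resource:year"))
  fits <- list()
  coefs <- list()
  vcomp <- list()
  stats_ <- list()
  for (resp in responses) {
    fml <- as.formula(paste(resp, "~", paste(rhs, collapse = " + ")))
    fit <- hlmm(fml, data, random = "plot_id",
                var_group = if (both_guilds) "guild" else NULL)
    fits[[resp]] <- fit
    z <- fit$z
    pval <- 2 * pnorm(-abs(z))
    stars <- ifelse(is.na(pval), "",
                    ifelse(pval < 0.001, "***",
                           ifelse(pval < 0.01, "**",
                                  ifelse(pval < 0.05, "*", ""))))
    coefs[[resp]] <- data.frame(
      response = resp, term = names(coef(fit)),
      estimate = unname(coef(fit)), se = unname(fit$se), z = unname(z),
      stars = stars, row.names = NULL, stringsAsFactors = FALSE)
    vc <- data.frame(response = resp, component = "plot_intercept_sd",
                     value = sqrt(fit$sigma2_plot),
                     stringsAsFactors = FALSE)
    vc <- rbind(vc, data.frame(
      response = resp,
      component = paste0("residual_sd_", names(fit$sigma2_resid)),
      value = sqrt(unname(fit$sigma2_resid)), stringsAsFactors = FALSE))
    vcomp[[resp]] <- vc
    stats_[[resp]] <- data.frame(response = resp, n = fit$n,
                                 adj_r2 = fit$adj_r2, logLik = fit$logLik,
                                 stringsAsFactors = FALSE)
  }
  out <- list(fits = fits,
              coefficients = do.call(rbind, c(coefs, make.row.names = FALSE)),
              variance_components = do.call(rbind, c(vcomp,
                                                     make.row.names = FALSE)),
              fit_stats = do.call(rbind, c(stats_, make.row.names = FALSE)),
              formula_rhs = paste(rhs, collapse = " + "))
  class(out) <- "gradient_report"
  out
}

#' @export
print.gradient_report <- function(x, ...) {
  cat("Gradient regressions (", length(x$fits), " response metric(s))\n",
      sep = "")
  cat("  fixed effects: ~ ", x$formula_rhs, "\n", sep = "")
  cat("  random: plot intercept; residual variance per guild\n\n")
  df <- x$coefficients
  df$estimate <- signif(df$estimate, 4)
  df$se <- signif(df$se, 4)
  df$z <- signif(df$z, 4)
  print(df, row.names = FALSE)
  cat("\nFit summaries:\n")
  fs <- x$fit_stats
  fs$adj_r2 <- signif(fs$adj_r2, 3)
  print(fs, row.names = FALSE)
  invisible(x)
}
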