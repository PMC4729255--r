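# shared simulated design: 48 plots x 3 years x 2 guilds
make_lmm_data <- function(seed, beta_resource = 2, sd_plot = 0.3,
                          sd_st = 0.5, sd_ecm = 0.25) {
  set.seed(seed)
  plots <- sprintf("p%02d", 1:48)
  d <- expand.grid(plot_id = plots, year = factor(2009:2011),
                   guild = factor(c("ST", "ECM"), levels = c("ST", "ECM")),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res <- rnorm(48); names(res) <- plots
  age <- rnorm(48); names(age) <- plots
  d$resource <- res[d$plot_id]
  d$age_axis <- age[d$plot_id]
  b <- rnorm(48, sd = sd_plot); names(b) <- plots
  sdr <- ifelse(d$guild == "ST", sd_st, sd_ecm)
  d$y <- 1 + beta_resource * d$resource + b[d$plot_id] +
    rnorm(nrow(d), sd = sdr)
  d
}

test_that("with no random effect and one variance group the fit is OLS", {
  d <- make_lmm_data(1)
  fit <- hlmm(y ~ guild + year + resource, d, random = NULL,
              var_group = NULL)
  ref <- lm(y ~ guild + year + resource, d)
  expect_equal(coef(fit), coef(ref), tolerance = 1e-6)
  # REML single-variance GLS standard errors coincide with OLS ones
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(ref)))),
               tolerance = 1e-6)
})

test_that("z-values are invariant under affine rescaling of the covariate", {
  d <- make_lmm_data(2)
  f1 <- hlmm(y ~ guild + resource, d, random = "plot_id",
             var_group = "guild")
  d2 <- d
  d2$resource <- 100 * d$resource + 7
  f2 <- hlmm(y ~ guild + resource, d2, random = "plot_id",
             var_group = "guild")
  expect_equal(f2$z[["resource"]], f1$z[["resource"]], tolerance = 1e-5)
  expect_equal(f2$coefficients[["resource"]],
               f1$coefficients[["resource"]] / 100, tolerance = 1e-5)
})

test_that("estimates agree with nlme::lme under varIdent weighting", {
  skip_if_not_installed("nlme")
  d <- make_lmm_data(3)
  fit <- hlmm(y ~ guild + year + resource + age_axis, d,
              random = "plot_id", var_group = "guild")
  ref <- nlme::lme(y ~ guild + year + resource + age_axis,
                   random = ~ 1 | plot_id,
                   weights = nlme::varIdent(form = ~ 1 | guild),
                   data = d, method = "REML")
  expect_equal(unname(coef(fit)), unname(nlme::fixef(ref)),
               tolerance = 1e-5)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(ref)))),
               tolerance = 1e-4)
  expect_equal(sqrt(fit$sigma2_plot),
               as.numeric(nlme::VarCorr(ref)["(Intercept)", "StdDev"]),
               tolerance = 1e-3)
  expect_equal(unname(fit$logLik), as.numeric(ref$logLik), tolerance = 1e-6)
})

test_that("known slope and variance structure are recovered", {
  d <- make_lmm_data(4, beta_resource = 2, sd_plot = 0.3,
                     sd_st = 0.5, sd_ecm = 0.25)
  fit <- hlmm(y ~ guild + year + resource, d, random = "plot_id",
              var_group = "guild")
  est <- fit$coefficients[["resource"]]
  se <- fit$se[["resource"]]
  expect_lt(abs(est - 2), 3 * se)
  ratio <- sqrt(fit$sigma2_resid[["ST"]] / fit$sigma2_resid[["ECM"]])
  expect_gte(ratio, 1.5)
  expect_lte(ratio, 2.5)
})

test_that("zero plot variance is detected on homoscedastic data", {
  d <- make_lmm_data(5, sd_plot = 0, sd_st = 0.5, sd_ecm = 0.5)
  fit <- hlmm(y ~ guild + resource, d, random = "plot_id",
              var_group = NULL)
  expect_lt(abs(fit$coefficients[["resource"]] - 2),
            3 * fit$se[["resource"]])
  expect_lte(fit$sigma2_plot, fit$sigma2_resid[[1L]] / 10)
})

test_that("degenerate designs raise informative errors", {
  d <- make_lmm_data(6)
  d$dup <- d$resource
  expect_error(hlmm(y ~ resource + dup, d, random = "plot_id"),
               "aliased.*dup")
  expect_error(hlmm(y ~ nonexistent, d), "nonexistent")

  d$y <- 5
  fit <- hlmm(y ~ guild + resource, d, random = "plot_id",
              var_group = "guild")
  expect_equal(fit$flag, "constant-response")
  expect_equal(unname(fit$coefficients), c(5, 0, 0))
  expect_true(all(is.na(fit$z)))
})

test_that("accessor methods are coherent", {
  d <- make_lmm_data(7)
  fit <- hlmm(y ~ guild + resource, d, random = "plot_id",
              var_group = "guild")
  expect_equal(predict(fit, newdata = d, level = 0),
               fitted(fit, type = "marginal"))
  expect_equal(predict(fit, newdata = d, level = 1),
               fitted(fit, type = "conditional"))
  expect_equal(residuals(fit),
               d$y - fitted(fit, type = "conditional"))
  pr <- residuals(fit, type = "pearson")
  expect_equal(length(pr), nrow(d))
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(nrow(d), 3L))
  expect_identical(simulate(fit, nsim = 2, seed = 9),
                   simulate(fit, nsim = 2, seed = 9))
  ll <- logLik(fit)
  expect_s3_class(ll, "logLik")
  expect_true(is.finite(as.numeric(ll)))
  s <- summary(fit)
  expect_equal(unname(s$coefficients[, "z value"]),
               unname(coef(fit) / fit$se))
  expect_output(print(s), "Variance components")
})
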