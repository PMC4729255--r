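#' Heteroscedastic random-intercept linear mixed model
#'
#' Fits, by restricted maximum likelihood, the linear mixed model
#' \deqn{y = X\beta + b_{plot} + \epsilon,\qquad
#'       b \sim N(0, \sigma^2_{plot}),\quad
#'       \epsilon_i \sim N(0, \sigma^2_{g(i)})}
#' with a random intercept per grouping unit (typically the plot, to
#' account for repeated measurements across years) and a separate residual
#' variance per stratum of `var_group` (typically the trophic guild, to
#' account for within-group heteroscedasticity). The variance parameters
#' are log-parameterized and optimized numerically; fixed effects are
#' profiled out by generalized least squares at each evaluation, using a
#' Woodbury decomposition of the per-group covariance blocks. Per-term
#' z-values are estimates divided by their standard errors.
#'
#' With `random = NULL` and `var_group = NULL` the fit reduces exactly to
#' ordinary least squares.
#'
#' @param formula model formula for the fixed effects.
#' @param data data frame; rows with missing values in any model variable
#'   are dropped.
#' @param random name of the grouping column for the random intercept, or
#'   `NULL` for none.
#' @param var_group name of the factor column defining residual-variance
#'   strata, or `NULL` for a single residual variance.
#' @param reml logical; use REML (default) or ML.
#' @param control list passed to [stats::optim()] `control` (Nelder-Mead).
#' @return an object of class `hlmm` with the usual accessor methods
#'   (`print`, `summary`, `coef`, `vcov`, `fitted`, `residuals`,
#'   `predict`, `simulate`, `logLik`, `plot`).
#' @examples
#' set.seed(1)
#' d <- data.frame(plot = rep(sprintf("p%02d", 1:20), each = 3),
#'                 g = rep(c("ST", "ECM"), 30), x = rnorm(60))
#' d$y <- 1 + 2 * d$x + rnorm(20, sd = 0.5)[match(d$plot, unique(d$plot))] +
#'   rnorm(60, sd = ifelse(d$g == "ST", 1, 0.5))
#' fit <- hlmm(y ~ g + x, d, random = "plot", var_group = "g")
#' summary(fit)
#' @export
hlmm <- function(formula, data, random = NULL, var_group = NULL,
                 reml = TRUE, control = list()) {
  cl <- match.call()
  vars <- unique(c(all.vars(formula), random, var_group))
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols) > 0L) {
    stop("hlmm: variable(s) not in data: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  dat <- data[complete.cases(data[vars]), , drop = FALSE]
  mf <- model.frame(formula, dat)
  trm <- attr(mf, "terms")
  y <- as.numeric(model.response(mf))
  X <- model.matrix(trm, mf)
  n <- length(y)
  p <- ncol(X)
  if (n <= p) stop("hlmm: fewer rows than fixed-effect parameters",
                   call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < p) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):p]]
    stop("hlmm: design matrix rank deficient; aliased term(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  pl <- if (is.null(random)) NULL else factor(dat[[random]])
  vg <- if (is.null(var_group)) factor(rep("all", n)) else factor(dat[[var_group]])
  vg_i <- as.integer(vg)
  K <- nlevels(vg)
  has_random <- !is.null(pl)

  base <- list(call = cl, formula = formula, terms = trm,
               xlevels = stats::.getXlevels(trm, mf),
               contrasts = attr(X, "contrasts"),
               random = random, var_group = var_group, reml = reml,
               y = y, X = X, n = n, p = p,
               plot = pl, vgroup = vg)

  if (sd(y) == 0) {
    # degenerate: constant response; slopes 0 by construction, z undefined
    beta <- c(y[1L], rep(0, p - 1L))
    names(beta) <- colnames(X)
    out <- c(base, list(
      coefficients = beta, se = setNames(rep(NA_real_, p), colnames(X)),
      z = setNames(rep(NA_real_, p), colnames(X)),
      vcov = matrix(NA_real_, p, p, dimnames = list(colnames(X), colnames(X))),
      sigma2_plot = 0,
      sigma2_resid = setNames(rep(0, K), levels(vg)),
      logLik = NA_real_, fitted_marginal = rep(y[1L], n),
      blup = NULL, adj_r2 = NA_real_, optim = NULL,
      flag = "constant-response"))
    class(out) <- "hlmm"
    return(out)
  }

  blocks <- if (has_random) split(seq_len(n), pl) else list(seq_len(n))

  # REML/ML criterion via per-block Woodbury inverse of
  # V_b = diag(s2[vg]) + sb2 * 11'
  profile <- function(sb2, s2) {
    A <- matrix(0, p, p)
    bvec <- numeric(p)
    q <- 0
    logdet <- 0
    for (idx in blocks) {
      d <- s2[vg_i[idx]]
      dinv <- 1 / d
      Xb <- X[idx, , drop = FALSE]
      yb <- y[idx]
      s <- sum(dinv)
      f <- if (has_random) sb2 / (1 + sb2 * s) else 0
      aX <- drop(crossprod(Xb, dinv))        # X' D^-1 1
      ay <- sum(dinv * yb)                   # y' D^-1 1
      A <- A + crossprod(Xb, dinv * Xb) - f * tcrossprod(aX)
      bvec <- bvec + drop(crossprod(Xb, dinv * yb)) - f * aX * ay
      q <- q + sum(dinv * yb^2) - f * ay^2
      logdet <- logdet + sum(log(d)) + if (has_random) log1p(sb2 * s) else 0
    }
    chA <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(chA)) return(NULL)
    beta <- backsolve(chA, forwardsolve(t(chA), bvec))
    quad <- q - sum(bvec * beta)
    list(A = A, chA = chA, beta = beta, quad = quad, logdet = logdet)
  }

  nll <- function(theta) {
    sb2 <- if (has_random) exp(theta[1L]) else 0
    s2 <- exp(theta[(has_random + 1L):length(theta)])
    pr <- profile(sb2, s2)
    if (is.null(pr) || !is.finite(pr$quad) || pr$quad < 0) return(1e10)
    val <- 0.5 * (pr$logdet + pr$quad)
    if (reml) val <- val + sum(log(diag(pr$chA)))
    if (!is.finite(val)) return(1e10)
    val
  }

  v0 <- sum(lm.fit(X, y)$residuals^2) / (n - p)
  theta0 <- c(if (has_random) log(v0 / 2), rep(log(v0), K))
  if (length(theta0) == 1L) {
    opt <- stats::optimize(nll, interval = log(v0) + c(-25, 25), tol = 1e-12)
    opt <- list(par = opt$minimum, value = opt$objective, convergence = 0L,
                counts = NA, message = "optimize() on one variance parameter")
  } else {
    ctrl <- utils::modifyList(list(maxit = 5000L, reltol = 1e-12), control)
    opt <- optim(theta0, nll, method = "Nelder-Mead", control = ctrl)
    if (opt$convergence != 0L) {
      stop("hlmm: variance optimization did not converge (optim code ",
           opt$convergence, ", ", opt$counts[1L], " evaluations",
           if (!is.null(opt$message)) paste0(", ", opt$message) else "",
           ")", call. = FALSE)
    }
  }

  theta <- opt$par
  sb2 <- if (has_random) exp(theta[1L]) else 0
  s2 <- exp(theta[(has_random + 1L):length(theta)])
  names(s2) <- levels(vg)
  pr <- profile(sb2, s2)
  beta <- setNames(pr$beta, colnames(X))
  Vb <- chol2inv(pr$chA)
  dimnames(Vb) <- list(colnames(X), colnames(X))
  se <- sqrt(diag(Vb))
  fitted_marginal <- drop(X %*% beta)

  # BLUPs: b_hat = sb2 * 1' V_b^-1 (y - X beta) per block
  blup <- NULL
  if (has_random) {
    r <- y - fitted_marginal
    blup <- vapply(blocks, function(idx) {
      dinv <- 1 / s2[vg_i[idx]]
      s <- sum(dinv)
      f <- sb2 / (1 + sb2 * s)
      sb2 * (1 - f * s) * sum(dinv * r[idx])
    }, numeric(1L))
    names(blup) <- levels(pl)
  }

  ll <- -0.5 * (pr$logdet + pr$quad) - 0.5 * (n - reml * p) * log(2 * pi)
  if (reml) ll <- ll - sum(log(diag(pr$chA)))
  r2 <- if (sd(fitted_marginal) > 0) cor(fitted_marginal, y)^2 else 0
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - p)

  out <- c(base, list(
    coefficients = beta, se = se, z = beta / se, vcov = Vb,
    sigma2_plot = unname(sb2), sigma2_resid = s2,
    logLik = ll, fitted_marginal = fitted_marginal, blup = blup,
    adj_r2 = adj_r2, optim = opt, flag = "ok"))
  class(out) <- "hlmm"
  out
}
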