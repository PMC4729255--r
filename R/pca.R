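#' Resource-availability gradient from stand variables
#'
#' Principal component analysis of the plot-level stand variables, based on
#' the correlation matrix (variables are z-standardized). The first
#' component is interpreted as resource availability and is oriented so
#' that growing-stock `volume` loads positively (large scores = productive
#' stands); the second component represents stand succession and is
#' oriented so that `stand_age` loads positively (large scores = old
#' stands). Missing values are mean-imputed with a warning; constant
#' variables are dropped with a warning (their correlations are undefined).
#'
#' @param env environment table (see [read_environment_table()]); `plot_id`
#'   plus numeric stand variables.
#' @return an object of class `gradient_scores`: a list with `scores` (data
#'   frame `plot_id`, `resource`, `age_axis`), `all_scores` (full score
#'   matrix), `loadings` (variable loadings), `var_fraction`
#'   (variance-explained fractions), `dropped` (names of dropped
#'   variables).
#' @export
pca_gradient <- function(env) {
  stopifnot(is.data.frame(env), "plot_id" %in% names(env))
  if (nrow(env) < 3L) {
    stop("pca_gradient: need at least 3 plots", call. = FALSE)
  }
  vars <- setdiff(names(env), "plot_id")
  x <- as.matrix(env[vars])
  storage.mode(x) <- "double"
  if (anyNA(x)) {
    warning("pca_gradient: mean-imputing missing environment values",
            call. = FALSE)
    for (j in seq_len(ncol(x))) {
      miss <- is.na(x[, j])
      if (any(miss)) x[miss, j] <- mean(x[, j], na.rm = TRUE)
    }
  }
  sds <- apply(x, 2L, sd)
  dropped <- colnames(x)[sds == 0]
  if (length(dropped) > 0L) {
    warning("pca_gradient: dropping constant variable(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
    x <- x[, sds > 0, drop = FALSE]
  }
  pr <- prcomp(x, center = TRUE, scale. = TRUE)
  scores <- pr$x
  rotation <- pr$rotation
  # orientation convention: volume up on PC1, stand age up on PC2
  flip <- function(comp, varname) {
    if (comp <= ncol(rotation) && varname %in% rownames(rotation) &&
        rotation[varname, comp] < 0) {
      scores[, comp] <<- -scores[, comp]
      rotation[, comp] <<- -rotation[, comp]
    }
  }
  flip(1L, "volume")
  flip(2L, "stand_age")
  var_fraction <- pr$sdev^2 / sum(pr$sdev^2)
  names(var_fraction) <- colnames(rotation)
  out <- list(
    scores = data.frame(plot_id = env$plot_id,
                        resource = scores[, 1L],
                        age_axis = if (ncol(scores) >= 2L) scores[, 2L] else 0,
                        row.names = NULL, stringsAsFactors = FALSE),
    all_scores = scores,
    loadings = rotation,
    var_fraction = var_fraction,
    dropped = dropped)
  class(out) <- "gradient_scores"
  out
}

#' @export
print.gradient_scores <- function(x, ...) {
  cat("Stand-structure PCA (correlation matrix), ",
      nrow(x$scores), " plots\n", sep = "")
  pc12 <- round(100 * x$var_fraction[seq_len(min(2L, length(x$var_fraction)))], 1)
  cat("Variance explained: ",
      paste(names(pc12), paste0(pc12, "%"), sep = " = ", collapse = ", "),
      "\n", sep = "")
  cat("PC1 = resource availability (volume loads +), ",
      "PC2 = stand succession (age loads +)\n", sep = "")
  if (length(x$dropped) > 0L) {
    cat("Dropped constant variable(s): ",
        paste(x$dropped, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
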