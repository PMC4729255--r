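#' Regional-pool null distribution of mean fruit-body size
#'
#' For an assemblage of given richness, each null replicate draws the same
#' number of species without replacement from the regional pool's guild
#' stratum and records the mean of log10 fruit-body size across the draw.
#' This tests whether locally co-occurring species differ in size from a
#' random selection of the regional species pool; only fruit-body size is
#' supported (regional fruit-body counts are not observable).
#'
#' @param pool regional pool (see [read_regional_pool()]).
#' @param guild `"ECM"` or `"ST"`.
#' @param richness number of species to draw per replicate.
#' @param n_rand number of replicates (default 100).
#' @param seed optional integer seed.
#' @return object of class `null_distribution`: list with `metric`
#'   (`"mean_log_size"`), `values` (length `n_rand`), `null_model`
#'   (`"regional_pool"`), `guild`, `richness`.
#' @export
regional_pool_null <- function(pool, guild, richness, n_rand = 100L,
                               seed = NULL) {
  stopifnot(guild %in% c("ECM", "ST"), richness >= 1, n_rand >= 1)
  if (!is.null(seed)) set.seed(seed)
  logsize <- log10(pool$fruit_body_size[pool$guild == guild])
  if (length(logsize) == 0L) {
    stop("regional pool stratum for guild ", guild, " is empty",
         call. = FALSE)
  }
  if (richness > length(logsize)) {
    stop("richness (", richness, ") exceeds pool stratum size (",
         length(logsize), "); cannot draw without replacement",
         call. = FALSE)
  }
  values <- vapply(seq_len(n_rand), function(i) {
    mean(logsize[sample.int(length(logsize), richness)])
  }, numeric(1L))
  structure(list(metric = "mean_log_size", values = values,
                 null_model = "regional_pool", guild = guild,
                 richness = as.integer(richness)),
            class = "null_distribution")
}

#' Independent-swap randomization of a binary matrix
#'
#' Performs `n_swaps` successful checkerboard swaps on a binary
#' species-by-plot matrix: repeatedly pick a random pair of rows and pair
#' of columns; whenever the 2x2 submatrix is a checkerboard
#' (`10/01` or `01/10`), exchange it for the opposite pattern. Row sums
#' (species occupancies) and column sums (plot richness) are preserved
#' exactly — the fixed-fixed null. Attempts that hit a non-checkerboard are
#' rejected and do not count; a global attempt budget of `1e6` per
#' requested swap guards matrices with no (or few) checkerboards, in which
#' case the matrix is returned as-is with a warning.
#'
#' @param mat binary matrix (0/1 entries).
#' @param n_swaps number of successful swaps to perform.
#' @param seed optional integer seed; with `seed = NULL` the current RNG
#'   stream is used, so successive calls continue one Markov chain.
#' @param max_attempts attempt budget (default `1e6 * max(1, n_swaps)`).
#' @return the randomized matrix (attributes preserved).
#' @export
independent_swap <- function(mat, n_swaps, seed = NULL, max_attempts = NULL) {
  stopifnot(is.matrix(mat), n_swaps >= 0)
  if (!all(mat %in% c(0L, 1L))) {
    stop("independent_swap: matrix must be binary", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  if (n_swaps == 0L) return(mat)
  nr <- nrow(mat); nc <- ncol(mat)
  if (nr < 2L || nc < 2L) {
    warning("independent_swap: matrix too small to swap; returned unchanged",
            call. = FALSE)
    return(mat)
  }
  if (is.null(max_attempts)) max_attempts <- 1e6 * max(1, n_swaps)
  storage.mode(mat) <- "integer"
  m <- .swap_engine(mat, n_swaps, max_attempts)
  done <- attr(m, "swaps_done")
  attr(m, "swaps_done") <- NULL
  attr(m, "attempts") <- NULL
  for (a in c("guild", "year")) attr(m, a) <- attr(mat, a)
  if (done < n_swaps) {
    warning("independent_swap: only ", done, " of ", n_swaps,
            " swaps possible within the attempt budget; ",
            "matrix may have no checkerboard submatrix", call. = FALSE)
  }
  m
}

#' Swap-null distributions of assemblage mean traits
#'
#' Runs one independent-swap Markov chain on a guild/year binary matrix and
#' records, at thinned intervals, the per-plot assemblage means of the
#' requested log10 traits over the randomized matrices. Because the swap
#' preserves plot richness, each plot's null distribution is
#' richness-matched by construction. Defaults follow standard practice for
#' sequential swap nulls: burn-in of `10 x fill` successful swaps and
#' `2 x fill` between samples, where fill is the number of presences.
#'
#' @param mat binary matrix from [to_binary_matrix()].
#' @param trait_table trait table covering all species in `mat`.
#' @param metrics any of `"mean_log_size"`, `"mean_log_n"`.
#' @param n_rand number of null samples (default 100).
#' @param burn_in successful swaps before the first sample; default
#'   `10 * sum(mat)`.
#' @param thin successful swaps between samples; default `2 * sum(mat)`.
#' @param seed optional integer seed.
#' @param restart if `TRUE`, each sample restarts the chain from the
#'   observed matrix and applies `burn_in` swaps (independent
#'   randomizations instead of one thinned chain).
#' @return object of class `swap_null`: list with `plot_id`, `richness`,
#'   and per metric a `plots x n_rand` matrix of null means; degenerate
#'   matrices (fewer than 2 species or 2 occupied plots) yield `NULL`
#'   values with `flag = "degenerate"`.
#' @export
swap_null <- function(mat, trait_table,
                      metrics = c("mean_log_size", "mean_log_n"),
                      n_rand = 100L, burn_in = NULL, thin = NULL,
                      seed = NULL, restart = FALSE) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  if (!is.null(seed)) set.seed(seed)
  occupied <- colSums(mat) > 0L
  if (nrow(mat) < 2L || sum(occupied) < 2L) {
    return(structure(list(plot_id = colnames(mat), richness = colSums(mat),
                          values = NULL, metrics = metrics,
                          flag = "degenerate", n_randomizations = 0L,
                          guild = attr(mat, "guild"), year = attr(mat, "year")),
                     class = "swap_null"))
  }
  idx <- match(rownames(mat), trait_table$species_id)
  if (anyNA(idx)) {
    stop("swap_null: no traits for species ",
         paste(rownames(mat)[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  tvals <- list(
    mean_log_size = log10(trait_table$fruit_body_size[idx]),
    mean_log_n = log10(trait_table$mean_fruit_bodies[idx]))
  fill <- sum(mat)
  if (is.null(burn_in)) burn_in <- 10L * fill
  if (is.null(thin)) thin <- 2L * fill
  richness <- colSums(mat)
  values <- lapply(metrics, function(m) {
    matrix(NA_real_, nrow = ncol(mat), ncol = n_rand,
           dimnames = list(colnames(mat), NULL))
  })
  names(values) <- metrics
  m <- mat
  if (!restart) m <- independent_swap(m, burn_in)
  for (k in seq_len(n_rand)) {
    if (restart) {
      m <- independent_swap(mat, burn_in)
    } else {
      m <- independent_swap(m, thin)
    }
    for (met in metrics) {
      values[[met]][, k] <- as.numeric(crossprod(m, tvals[[met]])) / richness
    }
  }
  structure(list(plot_id = colnames(mat), richness = richness,
                 values = values, metrics = metrics, flag = "ok",
                 n_randomizations = as.integer(n_rand),
                 guild = attr(mat, "guild"), year = attr(mat, "year")),
            class = "swap_null")
}

#' Standardized effect size
#'
#' `ses = (observed - mean(null)) / sd(null)`, with the sample (n-1)
#' standard deviation across null replicates. A null with zero spread
#' yields an undefined SES, flagged rather than infinite. By convention
#' |SES| > 2 indicates a significant deviation from the null expectation.
#'
#' @param observed observed value of the metric.
#' @param null a `null_distribution` (or bare numeric vector of null
#'   values).
#' @return one-row data frame with `observed`, `null_mean`, `null_sd`,
#'   `ses`, `flag` (`"ok"` or `"degenerate"`).
#' @export
ses <- function(observed, null) {
  values <- if (inherits(null, "null_distribution")) null$values else null
  if (length(values) == 0L) stop("ses: empty null distribution", call. = FALSE)
  m <- mean(values)
  s <- sd(values)
  degenerate <- !is.finite(s) || s == 0
  data.frame(observed = observed, null_mean = m, null_sd = s,
             ses = if (degenerate) NA_real_ else (observed - m) / s,
             flag = if (degenerate) "degenerate" else "ok",
             stringsAsFactors = FALSE)
}

#' Classify standardized effect sizes
#'
#' `"low"` if SES < -2 (observed below the null expectation), `"high"` if
#' SES > 2, `"ns"` otherwise. Undefined SES propagates as `NA`.
#'
#' @param ses_values numeric vector of SES values.
#' @return character vector of classes.
#' @export
significance_class <- function(ses_values) {
  out <- rep(NA_character_, length(ses_values))
  ok <- !is.na(ses_values)
  out[ok & ses_values < -2] <- "low"
  out[ok & ses_values > 2] <- "high"
  out[ok & ses_values >= -2 & ses_values <= 2] <- "ns"
  out
}

#' SES table for all plot/guild/year assemblages
#'
#' High-level driver: splits the community by guild and year, computes
#' observed assemblage means, generates the requested null model per
#' assemblage, and returns the SES results in long format. Metric and null
#' model must be compatible: the regional pool provides fruit-body sizes
#' only, so `mean_log_n` is available only under the local swap null.
#'
#' @param community community table (after [occupancy_filter()]).
#' @param trait_table trait table from [build_trait_table()].
#' @param null_model `"regional_pool"` or `"local_swap"`.
#' @param pool regional pool (required for `"regional_pool"`).
#' @param metrics metrics to score.
#' @param n_rand number of randomizations per assemblage (default 100).
#' @param burn_in,thin,restart swap-chain controls, see [swap_null()].
#' @param seed optional integer seed.
#' @return data frame with columns `plot_id`, `guild`, `year`, `metric`,
#'   `null_model`, `observed`, `null_mean`, `null_sd`, `ses`, `flag`,
#'   `n_randomizations`.
#' @export
ses_table <- function(community, trait_table,
                      null_model = c("regional_pool", "local_swap"),
                      pool = NULL,
                      metrics = c("mean_log_size", "mean_log_n"),
                      n_rand = 100L, burn_in = NULL, thin = NULL,
                      seed = NULL, restart = FALSE) {
  null_model <- match.arg(null_model)
  metrics <- match.arg(metrics, several.ok = TRUE)
  if (null_model == "regional_pool") {
    if ("mean_log_n" %in% metrics && length(metrics) > 1L) {
      metrics <- "mean_log_size"
    }
    if (identical(metrics, "mean_log_n")) {
      stop("mean_log_n is not available under the regional-pool null ",
           "(regional fruit-body counts are unobservable); ",
           "use null_model = 'local_swap'", call. = FALSE)
    }
    if (is.null(pool)) {
      stop("regional_pool null requires a pool", call. = FALSE)
    }
  }
  if (!is.null(seed)) set.seed(seed)
  years <- sort(unique(community$year))
  rows <- list()
  for (guild in c("ECM", "ST")) {
    for (year in years) {
      mat <- to_binary_matrix(community, trait_table, guild, year)
      if (nrow(mat) == 0L) next
      obs <- assemblage_means(mat, trait_table)
      if (null_model == "regional_pool") {
        for (i in seq_len(nrow(obs))) {
          nd <- regional_pool_null(pool, guild, obs$richness[i], n_rand)
          frag <- ses(obs$mean_log_size[i], nd)
          rows[[length(rows) + 1L]] <- data.frame(
            plot_id = obs$plot_id[i], guild = guild, year = year,
            metric = "mean_log_size", null_model = "regional_pool",
            frag, n_randomizations = n_rand, stringsAsFactors = FALSE)
        }
      } else {
        sn <- swap_null(mat, trait_table, metrics = metrics, n_rand = n_rand,
                        burn_in = burn_in, thin = thin, restart = restart)
        for (met in metrics) {
          obs_met <- obs[[met]]
          for (i in seq_len(nrow(obs))) {
            if (identical(sn$flag, "degenerate")) {
              frag <- data.frame(observed = obs_met[i], null_mean = NA_real_,
                                 null_sd = NA_real_, ses = NA_real_,
                                 flag = "degenerate", stringsAsFactors = FALSE)
            } else {
              frag <- ses(obs_met[i], sn$values[[met]][obs$plot_id[i], ])
            }
            rows[[length(rows) + 1L]] <- data.frame(
              plot_id = obs$plot_id[i], guild = guild, year = year,
              metric = met, null_model = "local_swap",
              frag, n_randomizations = n_rand, stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (length(rows) == 0L) {
    stop("ses_table: no non-empty guild/year assemblages", call. = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
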