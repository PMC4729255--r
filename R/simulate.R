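#' Simulation configuration
#'
#' Parameters for the synthetic fruit-body inventory generator. Defaults
#' emulate a three-year survey of 48 plots drawing on a regional pool of
#' 300 ECM and 300 ST species, with lognormal fruit-body sizes (ECM larger
#' than ST on the log10 mm^2 scale), a size-number trade-off
#' (`log10 count = a - b log10 size + noise`), right-skewed occupancy
#' weights, and size filtering whose strength declines along a latent
#' resource gradient: `lambda(r) = max(0, lambda0 - lambda1 * r)`, with
#' species inclusion weight proportional to
#' `exp(-lambda(r) * (log10 size - guild pool mean))`. Defaults make the
#' filter strong for ST and weak for ECM.
#'
#' @param n_plots number of plots (48).
#' @param years year labels (2009:2011).
#' @param n_pool pool size per guild, named `c(ECM=, ST=)`.
#' @param size_mean,size_sd per-guild mean and sd of log10 fruit-body size
#'   (mm^2 scale; defaults ECM 3.2, ST 2.6, sd 0.5).
#' @param tradeoff_intercept,tradeoff_slope,tradeoff_sd parameters a, b
#'   and noise sd of the log10 size-number trade-off.
#' @param occupancy_sdlog sd (log scale) of the lognormal base occupancy
#'   weights; larger values concentrate occurrences on fewer species.
#' @param richness_target expected per-plot, per-year richness per guild.
#' @param lambda0,lambda1 per-guild filter baseline and gradient coupling.
#' @param env_noise sd of environment-variable noise in units of the
#'   latent-signal sd.
#' @param age_coupling coupling of stand age to the resource gradient
#'   (0 = independent).
#' @param count_dispersion negative-binomial size parameter of realized
#'   fruit-body counts around the species' characteristic count (emulates
#'   the heavy right tail of field counts).
#' @param seed integer master seed (must be below 2^31 - 1000).
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_plots = 48L,
                       years = c(2009L, 2010L, 2011L),
                       n_pool = c(ECM = 300L, ST = 300L),
                       size_mean = c(ECM = 3.2, ST = 2.6),
                       size_sd = c(ECM = 0.5, ST = 0.5),
                       tradeoff_intercept = 4,
                       tradeoff_slope = 1,
                       tradeoff_sd = 0.3,
                       occupancy_sdlog = 1.2,
                       richness_target = c(ECM = 12, ST = 10),
                       lambda0 = c(ECM = 0.5, ST = 2.5),
                       lambda1 = c(ECM = 0.5, ST = 0.5),
                       env_noise = 0.4,
                       age_coupling = 0.1,
                       count_dispersion = 1,
                       seed = 1L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, seed >= 0,
            seed < 2^31 - 1000)
  cfg <- list(n_plots = as.integer(n_plots), years = as.integer(years),
              n_pool = n_pool, size_mean = size_mean, size_sd = size_sd,
              tradeoff_intercept = tradeoff_intercept,
              tradeoff_slope = tradeoff_slope, tradeoff_sd = tradeoff_sd,
              occupancy_sdlog = occupancy_sdlog,
              richness_target = richness_target,
              lambda0 = lambda0, lambda1 = lambda1,
              env_noise = env_noise, age_coupling = age_coupling,
              count_dispersion = count_dispersion, seed = as.integer(seed))
  stopifnot(cfg$n_plots >= 1L, length(cfg$years) >= 1L,
            all(cfg$n_pool >= 1L), all(cfg$size_sd >= 0),
            cfg$tradeoff_sd >= 0, cfg$occupancy_sdlog > 0,
            all(cfg$richness_target > 0), all(cfg$lambda1 >= 0),
            cfg$env_noise >= 0, cfg$count_dispersion > 0,
            cfg$seed >= 0L, cfg$seed < 2^31 - 1000)
  for (nm in c("n_pool", "size_mean", "size_sd", "richness_target",
               "lambda0", "lambda1")) {
    if (!all(c("ECM", "ST") %in% names(cfg[[nm]]))) {
      stop("sim_config: '", nm, "' must be named with ECM and ST",
           call. = FALSE)
    }
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate the regional species pool
#'
#' Draws per-guild species with lognormal fruit-body sizes, characteristic
#' fruit-body counts on the size-number trade-off line, and lognormal base
#' occupancy weights.
#'
#' @param config a [sim_config()].
#' @param seed optional integer seed (defaults to a substream of
#'   `config$seed`).
#' @return list with `pool` (data frame `species_id`, `guild`,
#'   `cap_diameter_mm`, `fruit_body_size`) and `truth` (additionally
#'   `log10_size`, `log10_count`, `char_count`, `weight`).
#' @export
simulate_pool <- function(config, seed = config$seed + 101L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  rows <- lapply(c("ECM", "ST"), function(g) {
    n <- config$n_pool[[g]]
    log10_size <- rnorm(n, config$size_mean[[g]], config$size_sd[[g]])
    log10_count <- config$tradeoff_intercept -
      config$tradeoff_slope * log10_size + rnorm(n, 0, config$tradeoff_sd)
    data.frame(
      species_id = sprintf("%s%03d", g, seq_len(n)),
      guild = g,
      log10_size = log10_size,
      log10_count = log10_count,
      char_count = 10^log10_count,
      weight = rlnorm(n, 0, config$occupancy_sdlog),
      stringsAsFactors = FALSE)
  })
  truth <- do.call(rbind, rows)
  rownames(truth) <- NULL
  pool <- data.frame(species_id = truth$species_id, guild = truth$guild,
                     cap_diameter_mm = sqrt(10^truth$log10_size),
                     fruit_body_size = 10^truth$log10_size,
                     stringsAsFactors = FALSE)
  list(pool = pool, truth = truth)
}

#' Simulate the plot environment
#'
#' A latent standard-normal resource level `r` per plot drives the
#' growing-stock variables (volume, basal area, mean DBH, tree count,
#' upper cover load positively on `r`); a second latent `u` drives stand
#' age and lower tree cover, mostly independent of `r` (mirroring the
#' succession axis); the shrub layer is mostly noise.
#'
#' @param config a [sim_config()].
#' @param seed optional integer seed.
#' @return list with `environment` (data frame: `plot_id` plus the eight
#'   stand variables) and `latent` (data frame `plot_id`, `resource`,
#'   `succession`).
#' @export
simulate_environment <- function(config, seed = config$seed + 202L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  n <- config$n_plots
  plot_id <- sprintf("plot%02d", seq_len(n))
  r <- rnorm(n)
  u <- rnorm(n)
  nz <- function() config$env_noise * rnorm(n)
  env <- data.frame(
    plot_id = plot_id,
    tree_count = 420 + 90 * (r + nz()),
    volume = 350 + 130 * (r + nz()),
    basal_area = 32 + 9 * (r + nz()),
    mean_dbh = 0.35 + 0.09 * (r + nz()),
    cover_shrub = pmin(100, pmax(0, 15 + 6 * rnorm(n))),
    cover_lower = pmin(100, pmax(0, 30 + 12 * (u + nz()))),
    cover_upper = pmin(100, pmax(0, 55 + 14 * (r + nz()))),
    stand_age = pmax(10, 95 + 28 * (u + config$age_coupling * r + nz())),
    stringsAsFactors = FALSE)
  list(environment = env,
       latent = data.frame(plot_id = plot_id, resource = r, succession = u,
                           stringsAsFactors = FALSE))
}

#' Simulate multi-year community observations
#'
#' For each plot, year and guild, species are included independently with
#' probability proportional to their base occupancy weight times the size
#' filter `exp(-lambda(r) * (log10 size - guild pool mean))`, scaled so
#' the expected richness matches `richness_target` (probabilities capped
#' at 0.95); `lambda(r) = max(0, lambda0 - lambda1 * r)`. Realized counts
#' are negative-binomial around the species' characteristic count, with
#' zeros promoted to 1 (presence implies at least one fruit body).
#'
#' @param pool_truth the `truth` component of [simulate_pool()].
#' @param latent the `latent` component of [simulate_environment()].
#' @param config a [sim_config()].
#' @param seed optional integer seed.
#' @return list with `community` (community table) and `latent_filter`
#'   (data frame `plot_id`, `guild`, `lambda`).
#' @export
simulate_communities <- function(pool_truth, latent, config,
                                 seed = config$seed + 303L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  recs <- vector("list", 2L * config$n_plots * length(config$years))
  lam_rows <- list()
  k <- 0L
  for (g in c("ECM", "ST")) {
    sp <- pool_truth[pool_truth$guild == g, , drop = FALSE]
    centred <- sp$log10_size - config$size_mean[[g]]
    for (i in seq_len(config$n_plots)) {
      r_i <- latent$resource[i]
      lam <- max(0, config$lambda0[[g]] - config$lambda1[[g]] * r_i)
      lam_rows[[length(lam_rows) + 1L]] <- data.frame(
        plot_id = latent$plot_id[i], guild = g, lambda = lam,
        stringsAsFactors = FALSE)
      w <- sp$weight * exp(-lam * centred)
      p <- pmin(0.95, config$richness_target[[g]] * w / sum(w))
      for (yr in config$years) {
        inc <- runif(nrow(sp)) < p
        if (!any(inc)) next
        cnt <- rnbinom(sum(inc), mu = sp$char_count[inc],
                       size = config$count_dispersion)
        cnt[cnt == 0L] <- 1L
        k <- k + 1L
        recs[[k]] <- data.frame(
          plot_id = latent$plot_id[i],
          species_id = sp$species_id[inc],
          year = yr, count = as.integer(cnt),
          stringsAsFactors = FALSE)
      }
    }
  }
  community <- do.call(rbind, recs[seq_len(k)])
  community <- community[order(community$plot_id, community$species_id,
                               community$year), , drop = FALSE]
  rownames(community) <- NULL
  list(community = community,
       latent_filter = do.call(rbind, lam_rows))
}

#' Simulate a complete synthetic dataset
#'
#' Runs [simulate_pool()], [simulate_environment()] and
#' [simulate_communities()] with per-stage seed substreams derived from
#' `config$seed`, so the whole dataset is reproducible from `(config,
#' seed)` and adding randomizations to one stage does not perturb another.
#'
#' @param config a [sim_config()].
#' @return list with `community`, `traits` (species_id, guild,
#'   cap_diameter_mm for all pool species), `pool`, `environment`, and
#'   `latent` (list: `plots`, `filter`, `pool`), plus the `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  pl <- simulate_pool(config)
  env <- simulate_environment(config)
  com <- simulate_communities(pl$truth, env$latent, config)
  list(community = com$community,
       traits = pl$pool[c("species_id", "guild", "cap_diameter_mm")],
       pool = pl$pool,
       environment = env$environment,
       latent = list(plots = env$latent, filter = com$latent_filter,
                     pool = pl$truth),
       config = config)
}

#' Write a synthetic dataset to disk
#'
#' Emits `communities.csv`, `traits.csv`, `pool.csv`, `environment.csv`,
#' the latent truth (`latent_truth.csv`, for recovery tests) and a
#' `config.yaml` snapshot, so the dataset is regenerable and traceable.
#'
#' @param dataset result of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_community_table(dataset$community, file.path(dir, "communities.csv"))
  write.csv(dataset$traits, file.path(dir, "traits.csv"), row.names = FALSE)
  write.csv(dataset$pool[c("species_id", "guild", "cap_diameter_mm")],
            file.path(dir, "pool.csv"), row.names = FALSE)
  write.csv(dataset$environment, file.path(dir, "environment.csv"),
            row.names = FALSE)
  truth <- merge(dataset$latent$plots, dataset$latent$filter, by = "plot_id")
  truth <- truth[order(truth$plot_id, truth$guild), , drop = FALSE]
  write.csv(truth, file.path(dir, "latent_truth.csv"), row.names = FALSE)
  cfg <- unclass(dataset$config)
  writeLines(yaml::as.yaml(cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}
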