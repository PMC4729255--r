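test_that("independent swap performs checkerboard exchanges only", {
  m <- diag(2L)
  dimnames(m) <- list(c("s1", "s2"), c("p1", "p2"))
  swapped <- independent_swap(m, 1, seed = 1)
  expect_equal(unname(swapped), matrix(c(0L, 1L, 1L, 0L), 2, 2))

  # zero swaps is the identity
  expect_equal(independent_swap(m, 0, seed = 1), m)

  # a matrix without checkerboards is returned unchanged with a warning
  ones <- matrix(1L, 3, 3)
  expect_warning(out <- independent_swap(ones, 5, seed = 1,
                                         max_attempts = 1e4),
                 "attempt budget")
  expect_equal(out, ones)
})

test_that("swap randomization preserves both marginals exactly", {
  set.seed(99)
  for (rep in 1:5) {
    m <- random_binary_matrix(12, 8)
    out <- independent_swap(m, 500)
    expect_identical(rowSums(out), rowSums(m))
    expect_identical(colSums(out), colSums(m))
  }
})

test_that("swap chains are reproducible given a seed", {
  set.seed(4)
  m <- random_binary_matrix(15, 10)
  expect_identical(independent_swap(m, 200, seed = 42),
                   independent_swap(m, 200, seed = 42))
  nd1 <- regional_pool_null(sim_pool_fixture(), "ST", 5, 50, seed = 7)
  nd2 <- regional_pool_null(sim_pool_fixture(), "ST", 5, 50, seed = 7)
  expect_identical(nd1$values, nd2$values)
})

test_that("regional-pool null matches closed forms on tiny pools", {
  pool <- data.frame(species_id = c("a", "b", "c"), guild = "ST",
                     cap_diameter_mm = sqrt(sqrt(c(1e1, 1e2, 1e3))),
                     fruit_body_size = sqrt(c(1e1, 1e2, 1e3)))
  pool$fruit_body_size <- 10^c(1, 2, 3)  # log10 sizes exactly {1, 2, 3}

  # drawing the whole stratum: every replicate identical, sd 0, flagged
  nd <- regional_pool_null(pool, "ST", 3, 20, seed = 1)
  expect_true(all(nd$values == 2))
  expect_equal(ses(2, nd)$flag, "degenerate")
  expect_true(is.na(ses(2, nd)$ses))

  # richness 1: null converges to pool mean and population sd
  nd1 <- regional_pool_null(pool, "ST", 1, 6000, seed = 2)
  expect_lt(abs(mean(nd1$values) - 2), 3 * sqrt(2 / 3) / sqrt(6000))
  expect_lt(abs(sd(nd1$values) - sqrt(2 / 3)), 0.05)

  # richness beyond the stratum cannot be drawn without replacement
  expect_error(regional_pool_null(pool, "ST", 4, 10), "exceeds")
  expect_error(regional_pool_null(pool, "ECM", 1, 10), "empty")
})

test_that("SES is the null-centred observation in null-sd units", {
  expect_equal(ses(5, c(3, 4, 5, 6, 7))$ses, 0)
  frag <- ses(7, c(4, 5, 6))
  expect_equal(frag$null_mean, 5)
  expect_equal(frag$null_sd, 1)  # sample (n-1) standard deviation
  expect_equal(frag$ses, 2)
  expect_equal(ses(1.5, c(1, 2))$ses, 0)
  const <- ses(3, rep(1.7, 10))
  expect_equal(const$flag, "degenerate")
  expect_true(is.na(const$ses))
})

test_that("SES classes follow the |2| convention", {
  expect_equal(significance_class(c(-2.5, 0, 2.01, -2, 2, NA)),
               c("low", "ns", "high", "ns", "ns", NA))
})

test_that("swap null on a 2x2 checkerboard alternates the two states", {
  m <- diag(2L)
  dimnames(m) <- list(c("s1", "s2"), c("p1", "p2"))
  attr(m, "guild") <- "ST"; attr(m, "year") <- 2009L
  tt <- data.frame(species_id = c("s1", "s2"), guild = "ST",
                   cap_diameter_mm = c(10, 100),
                   fruit_body_size = c(100, 10000),
                   mean_fruit_bodies = c(10, 100))
  sn <- swap_null(m, tt, metrics = "mean_log_size", n_rand = 400,
                  burn_in = 1, thin = 1, seed = 3)
  vals <- sn$values$mean_log_size["p1", ]
  expect_true(all(vals %in% c(2, 4)))
  # the two states are visited equally often (binomial 3-sigma band)
  expect_lt(abs(mean(vals == 2) - 0.5), 3 * sqrt(0.25 / 400))
})

test_that("swap null flags degenerate and constant-trait matrices", {
  m1 <- matrix(1L, 1, 3, dimnames = list("s1", c("p1", "p2", "p3")))
  expect_equal(swap_null(m1, data.frame())$flag, "degenerate")

  set.seed(5)
  m <- random_binary_matrix(6, 5)
  attr(m, "guild") <- "ST"; attr(m, "year") <- 2009L
  tt <- data.frame(species_id = rownames(m), guild = "ST",
                   cap_diameter_mm = 10, fruit_body_size = 100,
                   mean_fruit_bodies = 5)
  sn <- swap_null(m, tt, metrics = "mean_log_size", n_rand = 30, seed = 6)
  first_plot <- sn$values$mean_log_size[1L, ]
  expect_true(all(first_plot == 2))
  expect_equal(ses(2, first_plot)$flag, "degenerate")
})

test_that("richness-1 plots sample species by occupancy symmetry", {
  # 3 species x 3 plots, all marginals 1: the class is the 6 permutation
  # matrices and the chain is symmetric, so each plot's null trait is
  # uniform over the three species traits
  m <- diag(3L)
  dimnames(m) <- list(c("s1", "s2", "s3"), c("p1", "p2", "p3"))
  attr(m, "guild") <- "ST"; attr(m, "year") <- 2009L
  tt <- data.frame(species_id = c("s1", "s2", "s3"), guild = "ST",
                   cap_diameter_mm = c(10, 100, 1000),
                   fruit_body_size = c(1e2, 1e4, 1e6),
                   mean_fruit_bodies = c(1, 1, 1))
  sn <- swap_null(m, tt, metrics = "mean_log_size", n_rand = 600,
                  burn_in = 5, thin = 3, seed = 9)
  vals <- sn$values$mean_log_size["p2", ]
  expect_true(all(vals %in% c(2, 4, 6)))
  for (trait in c(2, 4, 6)) {
    expect_lt(abs(mean(vals == trait) - 1 / 3), 4 * sqrt(2 / 9 / 600))
  }
})

test_that("metric and null model compatibility is enforced", {
  ds <- simulate_dataset(sim_config(n_plots = 8, years = 2009L, seed = 12))
  filt <- suppressMessages(occupancy_filter(ds$community, 2))
  tt <- suppressWarnings(build_trait_table(filt, ds$traits))
  expect_error(ses_table(filt, tt, "regional_pool", pool = ds$pool,
                         metrics = "mean_log_n"),
               "local_swap")
  expect_error(ses_table(filt, tt, "regional_pool", pool = NULL),
               "pool")
})

test_that("ses_table produces one row per plot, guild, year and metric", {
  ds <- simulate_dataset(sim_config(n_plots = 10, years = c(2009L, 2010L),
                                    seed = 13))
  filt <- suppressMessages(occupancy_filter(ds$community, 2))
  tt <- suppressWarnings(build_trait_table(filt, ds$traits))
  st <- ses_table(filt, tt, "local_swap", n_rand = 20, seed = 14)
  key <- paste(st$plot_id, st$guild, st$year, st$metric)
  expect_false(anyDuplicated(key) > 0)
  expect_setequal(unique(st$metric), c("mean_log_size", "mean_log_n"))
  ok <- st[st$flag == "ok", ]
  expect_equal(ok$ses, (ok$observed - ok$null_mean) / ok$null_sd)

  sr <- ses_table(filt, tt, "regional_pool", pool = ds$pool, n_rand = 20,
                  seed = 15)
  expect_true(all(sr$metric == "mean_log_size"))
  expect_true(all(sr$n_randomizations == 20L))
})
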