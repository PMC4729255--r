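test_that("fruit-body size is the squared cap diameter", {
  expect_equal(fruit_body_size(10), 100)
  expect_equal(fruit_body_size(1), 1)
  expect_equal(fruit_body_size(2.5), 6.25)
  expect_equal(fruit_body_size(c(2, 3)), c(4, 9))
  expect_error(fruit_body_size(0), "> 0")
  expect_error(fruit_body_size(-3), "> 0")
})

test_that("mean fruit bodies divides yearly sums by occupied plots", {
  one_year <- data.frame(plot_id = c("p1", "p2"), species_id = "sX",
                         year = 2009L, count = c(10L, 20L))
  expect_equal(mean_fruit_bodies(one_year, "sX", mode = "pooled"), 15)

  # yearly sums {10, 20, 30}; 4 distinct plots overall; per-year
  # occupancies {2, 2, 3}
  multi <- data.frame(
    plot_id = c("p1", "p2", "p1", "p3", "p1", "p2", "p4"),
    species_id = "sX",
    year = c(2009L, 2009L, 2010L, 2010L, 2011L, 2011L, 2011L),
    count = c(4L, 6L, 8L, 12L, 10L, 10L, 10L))
  expect_equal(mean_fruit_bodies(multi, "sX", mode = "pooled"), 60 / 4)
  expect_equal(mean_fruit_bodies(multi, "sX", mode = "per_year"),
               c("2009" = 5, "2010" = 10, "2011" = 10))

  expect_error(mean_fruit_bodies(multi, "missing"), "not found")
})

test_that("occupancy filter keeps species on >= min_plots distinct plots", {
  com <- community_with_occupancies(c(1L, 3L, 4L, 5L, 6L))
  filt <- suppressMessages(occupancy_filter(com, min_plots = 4))
  expect_equal(length(unique(filt$species_id)), 3L)

  # min_plots = 1 is the identity
  expect_equal(occupancy_filter(com, min_plots = 1), com)

  # distinct plots are counted across years
  cross <- data.frame(
    plot_id = c("p1", "p2", "p3", "p4"), species_id = "sY",
    year = c(2009L, 2009L, 2010L, 2010L), count = 1L)
  expect_equal(nrow(occupancy_filter(cross, min_plots = 4)), 4L)

  # idempotent, and monotone in min_plots
  expect_equal(suppressMessages(occupancy_filter(filt, min_plots = 4)), filt)
  for (mp in 1:6) {
    a <- unique(suppressMessages(occupancy_filter(com, mp))$species_id)
    b <- unique(suppressMessages(suppressWarnings(
      occupancy_filter(com, mp + 1)))$species_id)
    expect_true(all(b %in% a))
  }
})

test_that("binary matrices are guild/year views with preserved richness", {
  ct <- toy_community()
  tr <- toy_traits()
  m <- to_binary_matrix(ct, tr, "ST", 2009)
  expect_equal(m, matrix(c(1L, 1L, 1L, 0L), 2, 2), ignore_attr = TRUE)
  expect_equal(rownames(m), c("sA", "sB"))
  expect_equal(colnames(m), c("p1", "p2"))

  expect_message(empty <- to_binary_matrix(ct, tr, "ECM", 2009), "no ECM")
  expect_equal(nrow(empty), 0L)

  # mixed-guild table: row count equals the guild's species only
  mixed <- rbind(ct, data.frame(plot_id = "p1", species_id = "sC",
                                year = 2009L, count = 7L))
  expect_equal(nrow(to_binary_matrix(mixed, tr, "ST", 2009)), 2L)
  expect_equal(nrow(to_binary_matrix(mixed, tr, "ECM", 2009)), 1L)

  # column sums equal per-plot richness computed directly from the table
  cfg <- sim_config(n_plots = 10, seed = 3)
  ds <- simulate_dataset(cfg)
  for (g in c("ECM", "ST")) {
    mat <- to_binary_matrix(ds$community, ds$traits, g, 2010)
    sub <- ds$community[ds$community$year == 2010, ]
    sub <- sub[sub$species_id %in% ds$traits$species_id[ds$traits$guild == g], ]
    rich <- table(factor(sub$plot_id, levels = colnames(mat)))
    expect_equal(unname(colSums(mat)), as.vector(rich))
  }
})

test_that("assemblage means average log10 traits unweighted", {
  tt <- data.frame(species_id = c("sA", "sB"), guild = "ST",
                   cap_diameter_mm = c(10, 100),
                   fruit_body_size = c(100, 10000),
                   mean_fruit_bodies = c(10, 1000))
  m <- matrix(c(1L, 1L, 1L, 0L, 0L, 0L), 2, 3,
              dimnames = list(c("sA", "sB"), c("p1", "p2", "p3")))
  attr(m, "guild") <- "ST"; attr(m, "year") <- 2009L
  am <- assemblage_means(m, tt)
  # plot with sizes {100, 10000} -> mean log10 size (2 + 4) / 2 = 3
  expect_equal(am$mean_log_size[am$plot_id == "p1"], 3)
  expect_equal(am$mean_log_n[am$plot_id == "p1"], 2)
  # single-species plot: means equal that species' log traits
  expect_equal(am$mean_log_size[am$plot_id == "p2"], 2)
  # empty plot: no row emitted
  expect_false("p3" %in% am$plot_id)
  expect_equal(am$richness, c(2L, 1L))

  # permutation invariance in species order
  am2 <- assemblage_means(m[c("sB", "sA"), ], tt)
  expect_equal(am2$mean_log_size, am$mean_log_size)

  # adding a species whose trait equals the current mean leaves it unchanged
  tt3 <- rbind(tt, data.frame(species_id = "sM", guild = "ST",
                              cap_diameter_mm = sqrt(1000),
                              fruit_body_size = 1000,
                              mean_fruit_bodies = 100))
  m3 <- rbind(m, sM = c(1L, 0L, 0L))
  attr(m3, "guild") <- "ST"; attr(m3, "year") <- 2009L
  expect_equal(assemblage_means(m3, tt3)$mean_log_size[1L], 3)

  # species lacking traits is a hard error naming the species
  m4 <- rbind(m, sZ = c(1L, 0L, 0L))
  attr(m4, "guild") <- "ST"; attr(m4, "year") <- 2009L
  expect_error(assemblage_means(m4, tt), "sZ")
})

test_that("trait table building excludes unknown guilds with a warning", {
  ct <- rbind(toy_community(),
              data.frame(plot_id = "p2", species_id = "sU", year = 2009L,
                         count = 2L))
  tr <- rbind(toy_traits(),
              data.frame(species_id = "sU", guild = "unknown",
                         cap_diameter_mm = 5))
  expect_warning(tt <- build_trait_table(ct, tr), "sU")
  expect_false("sU" %in% tt$species_id)
  expect_equal(tt$fruit_body_size, tt$cap_diameter_mm^2)
  expect_equal(tt$mean_fruit_bodies[tt$species_id == "sA"], 3)
  expect_equal(tt$occupancy[tt$species_id == "sA"], 2L)
})
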