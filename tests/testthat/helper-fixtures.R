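# Small in-code fixtures shared across test files.

toy_community <- function() {
  data.frame(
    plot_id = c("p1", "p1", "p2"),
    species_id = c("sA", "sB", "sA"),
    year = c(2009L, 2009L, 2009L),
    count = c(5L, 2L, 1L),
    stringsAsFactors = FALSE)
}

toy_traits <- function() {
  data.frame(
    species_id = c("sA", "sB", "sC"),
    guild = c("ST", "ST", "ECM"),
    cap_diameter_mm = c(10, 100, 20),
    stringsAsFactors = FALSE)
}

write_csv_fixture <- function(df, sep = ",") {
  path <- tempfile(fileext = ".csv")
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  path
}

# community where species occupancies (distinct plots across years) are known
community_with_occupancies <- function(occ) {
  rows <- list()
  for (i in seq_along(occ)) {
    sp <- sprintf("sp%02d", i)
    for (j in seq_len(occ[i])) {
      rows[[length(rows) + 1L]] <- data.frame(
        plot_id = sprintf("p%02d", j), species_id = sp,
        year = 2009L, count = 1L, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# random binary matrix with no empty rows/columns, for swap properties
random_binary_matrix <- function(nr, nc, fill_prob = 0.3) {
  repeat {
    m <- matrix(as.integer(runif(nr * nc) < fill_prob), nr, nc,
                dimnames = list(sprintf("s%02d", seq_len(nr)),
                                sprintf("p%02d", seq_len(nc))))
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) return(m)
  }
}

# all 0/1 matrices of dimension dim(template) with the same marginals,
# found by exhaustive enumeration; returned as a character set of keys
enumerate_marginal_class <- function(rs, cs) {
  nr <- length(rs); nc <- length(cs)
  n <- nr * nc
  keys <- character(0)
  for (v in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(v))[seq_len(n)]
    m <- matrix(bits, nr, nc)
    if (all(rowSums(m) == rs) && all(colSums(m) == cs)) {
      keys <- c(keys, paste(bits, collapse = ""))
    }
  }
  keys
}

matrix_key <- function(m) paste(as.integer(m), collapse = "")

sim_pool_fixture <- function() {
  simulate_pool(sim_config(n_pool = c(ECM = 30L, ST = 30L), seed = 20))$pool
}
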