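#' Read a long-format community table
#'
#' Reads fruit-body observations from a delimited text file with header
#' `plot_id,species_id,year,count` (comma or tab delimited; the delimiter is
#' sniffed from the header line). Each row is the number of fruit bodies of
#' one species on one plot in one year. Records with `count == 0` are dropped
#' on load (presence means at least one fruit body was recorded); duplicate
#' `(plot_id, species_id, year)` keys and negative counts are errors.
#'
#' @param path path to a delimited text file.
#' @return a `data.frame` with columns `plot_id`, `species_id` (character),
#'   `year` (integer) and `count` (integer, all >= 1).
#' @seealso [write_community_table()]
#' @export
read_community_table <- function(path) {
  df <- read_delim_sniffed(path)
  required <- c("plot_id", "species_id", "year", "count")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("community table schema error: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- df[required]
  df$plot_id <- as.character(df$plot_id)
  df$species_id <- as.character(df$species_id)
  if (!is.numeric(df$year)) {
    stop("community table: 'year' must be an integer label", call. = FALSE)
  }
  df$year <- as.integer(df$year)
  if (!is.numeric(df$count) || any(df$count != floor(df$count))) {
    stop("community table: 'count' must be integer-valued", call. = FALSE)
  }
  bad <- which(df$count < 0)
  if (length(bad) > 0L) {
    stop("community table validation error: negative count in data row ",
         bad[1L], call. = FALSE)
  }
  df$count <- as.integer(df$count)
  key <- paste(df$plot_id, df$species_id, df$year, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    stop("community table schema error: duplicate (plot_id, species_id, year) key: ",
         gsub("\r", ", ", dup, fixed = TRUE), call. = FALSE)
  }
  n_zero <- sum(df$count == 0L)
  if (n_zero > 0L) {
    message("read_community_table: dropped ", n_zero, " zero-count record(s)")
    df <- df[df$count > 0L, , drop = FALSE]
  }
  validate_community(df)
}

#' Write a community table to CSV
#'
#' Rows are written in lexicographic `(plot_id, species_id, year)` order, so
#' output is canonical: reading the file back gives a record-identical table.
#'
#' @param x community table (see [read_community_table()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_community_table <- function(x, path) {
  x <- validate_community(x)
  x <- x[order(x$plot_id, x$species_id, x$year), , drop = FALSE]
  write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_community <- function(df) {
  stopifnot(is.data.frame(df))
  required <- c("plot_id", "species_id", "year", "count")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("community table: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- df[required]
  if (any(df$count < 1L)) {
    stop("community table: counts must be >= 1 after load", call. = FALSE)
  }
  rownames(df) <- NULL
  df
}

#' Read a species trait table
#'
#' Expects columns `species_id, guild, cap_diameter_mm`: the trophic guild
#' (`ECM` or `ST`) and the mean cap diameter d of mature fruit bodies in mm.
#' Cap diameters must be strictly positive. Guild labels other than
#' ECM/ST are kept at this stage; [build_trait_table()] excludes such
#' species with a warning.
#'
#' @param path path to a delimited text file.
#' @return a `data.frame` with columns `species_id`, `guild`,
#'   `cap_diameter_mm`.
#' @export
read_trait_table <- function(path) {
  df <- read_delim_sniffed(path)
  required <- c("species_id", "guild", "cap_diameter_mm")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("trait table schema error: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- df[required]
  df$species_id <- as.character(df$species_id)
  df$guild <- as.character(df$guild)
  if (anyDuplicated(df$species_id)) {
    stop("trait table schema error: duplicate species_id", call. = FALSE)
  }
  if (!is.numeric(df$cap_diameter_mm) || any(df$cap_diameter_mm <= 0)) {
    stop("trait table validation error: cap_diameter_mm must be positive",
         call. = FALSE)
  }
  rownames(df) <- NULL
  df
}

#' Read a regional species-pool table
#'
#' Same schema as [read_trait_table()] (`species_id, guild, cap_diameter_mm`);
#' the derived column `fruit_body_size` (= d^2, mm^2) is added. Both guild
#' strata must be non-empty.
#'
#' @param path path to a delimited text file.
#' @return a `data.frame` with columns `species_id`, `guild`,
#'   `cap_diameter_mm`, `fruit_body_size`.
#' @export
read_regional_pool <- function(path) {
  df <- read_trait_table(path)
  df$fruit_body_size <- fruit_body_size(df$cap_diameter_mm)
  for (g in c("ECM", "ST")) {
    if (!any(df$guild == g)) {
      stop("regional pool: guild stratum '", g, "' is empty", call. = FALSE)
    }
  }
  df
}

#' Read a plot environment table
#'
#' Expects `plot_id` plus the eight stand variables: `tree_count` (ha^-1),
#' `volume` (m^3 ha^-1), `basal_area` (m^2 ha^-1), `mean_dbh` (m),
#' `cover_shrub`, `cover_lower`, `cover_upper` (percent) and `stand_age`
#' (years).
#'
#' @param path path to a delimited text file.
#' @return a `data.frame` with `plot_id` and eight numeric columns.
#' @export
read_environment_table <- function(path) {
  df <- read_delim_sniffed(path)
  required <- c("plot_id", env_variables())
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("environment table schema error: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- df[required]
  df$plot_id <- as.character(df$plot_id)
  if (anyDuplicated(df$plot_id)) {
    stop("environment table schema error: duplicate plot_id", call. = FALSE)
  }
  rownames(df) <- NULL
  df
}

env_variables <- function() {
  c("tree_count", "volume", "basal_area", "mean_dbh",
    "cover_shrub", "cover_lower", "cover_upper", "stand_age")
}

# Delimiter sniffing: tab wins if the header contains one, else comma.
read_delim_sniffed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
             comment.char = "", quote = "\"", fileEncoding = "UTF-8")
}
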