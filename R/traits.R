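#' Fruit-body size from cap diameter
#'
#' The size of a species' fruit body is indexed by the squared mean cap
#' diameter, d^2 (mm^2), a standard proxy for fruit-body biomass in
#' macrofungi.
#'
#' @param d mean cap diameter(s) in mm; must be strictly positive.
#' @return d^2 in mm^2.
#' @examples
#' fruit_body_size(10) # 100
#' @export
fruit_body_size <- function(d) {
  if (!is.numeric(d) || any(!is.finite(d)) || any(d <= 0)) {
    stop("cap diameter d must be finite and > 0", call. = FALSE)
  }
  d * d
}

#' Species occupancy
#'
#' Number of distinct plots on which each species was recorded, pooled
#' across all years.
#'
#' @param community community table (see [read_community_table()]).
#' @return named integer vector, one entry per species.
#' @export
occupancy <- function(community) {
  community <- validate_community(community)
  sp <- unique(community[c("plot_id", "species_id")])
  tab <- table(sp$species_id)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Mean number of fruit bodies per occupied plot
#'
#' The species-level fruit-body number trait: the total number of fruit
#' bodies of a species divided by the number of plots on which the species
#' was recorded. In `"pooled"` mode (the default, used for the species trait
#' throughout the analyses) counts are summed over all years and divided by
#' the number of distinct plots ever occupied. In `"per_year"` mode each
#' year's sum is divided by the number of plots occupied in that year.
#'
#' @param community community table.
#' @param species optional single species id; if omitted, values for all
#'   species are returned as a data frame.
#' @param mode `"pooled"` or `"per_year"`.
#' @return for a single species: a numeric scalar (pooled) or a named
#'   numeric vector over years (per-year). Otherwise a data frame with
#'   columns `species_id` (`, year`) `, mean_fruit_bodies`.
#' @export
mean_fruit_bodies <- function(community, species = NULL,
                              mode = c("pooled", "per_year")) {
  mode <- match.arg(mode)
  community <- validate_community(community)
  if (!is.null(species)) {
    if (!species %in% community$species_id) {
      stop("species not found in community table: ", species, call. = FALSE)
    }
    community <- community[community$species_id == species, , drop = FALSE]
  }
  if (mode == "pooled") {
    tot <- tapply(community$count, community$species_id, sum)
    occ <- occupancy(community)
    val <- as.numeric(tot) / as.numeric(occ[names(tot)])
    if (!is.null(species)) return(unname(val))
    data.frame(species_id = names(tot), mean_fruit_bodies = val,
               row.names = NULL, stringsAsFactors = FALSE)
  } else {
    key <- interaction(community$species_id, community$year, drop = TRUE)
    tot <- tapply(community$count, key, sum)
    nplots <- tapply(community$plot_id, key, function(p) length(unique(p)))
    parts <- strsplit(names(tot), ".", fixed = TRUE)
    out <- data.frame(
      species_id = vapply(parts, `[`, "", 1L),
      year = as.integer(vapply(parts, `[`, "", 2L)),
      mean_fruit_bodies = as.numeric(tot) / as.numeric(nplots),
      row.names = NULL, stringsAsFactors = FALSE)
    out <- out[order(out$species_id, out$year), , drop = FALSE]
    rownames(out) <- NULL
    if (!is.null(species)) {
      return(setNames(out$mean_fruit_bodies, out$year))
    }
    out
  }
}

#' Filter species by plot occupancy
#'
#' Retains species recorded on at least `min_plots` distinct plots, counting
#' plots across all years. This stabilises the per-species mean fruit-body
#' number before assemblage means are formed. Idempotent and monotone in
#' `min_plots`.
#'
#' @param community community table.
#' @param min_plots minimum number of distinct occupied plots (default 4).
#' @return the filtered community table.
#' @export
occupancy_filter <- function(community, min_plots = 4L) {
  stopifnot(is.numeric(min_plots), min_plots >= 1)
  community <- validate_community(community)
  occ <- occupancy(community)
  keep <- names(occ)[occ >= min_plots]
  removed <- length(occ) - length(keep)
  if (removed > 0L) {
    message("occupancy_filter: removed ", removed, " of ", length(occ),
            " species occupying < ", min_plots, " plots")
  }
  out <- community[community$species_id %in% keep, , drop = FALSE]
  if (nrow(out) == 0L) {
    warning("occupancy_filter: no species passed the filter", call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Build the analysis trait table
#'
#' Joins the measured trait table (guild, cap diameter) with the
#' community-derived traits: fruit-body size (d^2), mean fruit-body number
#' per occupied plot, and occupancy. Species observed in the community but
#' lacking a guild in `ECM`/`ST` (or absent from `traits`) are excluded with
#' a warning.
#'
#' @param community community table (typically after [occupancy_filter()]).
#' @param traits data frame from [read_trait_table()].
#' @param count_mode `"pooled"` (default: one fruit-body-number trait per
#'   species, used in all years) or `"per_year"` (trait computed from one
#'   year's data only; `year` must then be given).
#' @param year year label, only for `count_mode = "per_year"`.
#' @return a data frame with columns `species_id`, `guild`,
#'   `cap_diameter_mm`, `fruit_body_size`, `mean_fruit_bodies`, `occupancy`.
#' @export
build_trait_table <- function(community, traits,
                              count_mode = c("pooled", "per_year"),
                              year = NULL) {
  count_mode <- match.arg(count_mode)
  community <- validate_community(community)
  observed <- sort(unique(community$species_id))
  tr <- traits[match(observed, traits$species_id), , drop = FALSE]
  known <- !is.na(tr$species_id) & tr$guild %in% c("ECM", "ST")
  if (any(!known)) {
    warning("build_trait_table: excluded ", sum(!known),
            " species with unknown guild or missing traits: ",
            paste(head(observed[!known], 5L), collapse = ", "),
            if (sum(!known) > 5L) ", ..." else "", call. = FALSE)
  }
  tr <- tr[known, , drop = FALSE]
  if (count_mode == "pooled") {
    mfb <- mean_fruit_bodies(community, mode = "pooled")
  } else {
    if (is.null(year)) {
      stop("count_mode = 'per_year' requires a year", call. = FALSE)
    }
    mfb <- mean_fruit_bodies(community[community$year == year, , drop = FALSE],
                             mode = "pooled")
  }
  occ <- occupancy(community)
  out <- data.frame(
    species_id = tr$species_id,
    guild = tr$guild,
    cap_diameter_mm = tr$cap_diameter_mm,
    fruit_body_size = fruit_body_size(tr$cap_diameter_mm),
    mean_fruit_bodies = mfb$mean_fruit_bodies[match(tr$species_id,
                                                    mfb$species_id)],
    occupancy = as.integer(occ[tr$species_id]),
    row.names = NULL, stringsAsFactors = FALSE)
  out
}

#' Binary species-by-plot matrix for one guild and year
#'
#' Derives the presence/absence community matrix the null models operate on:
#' rows are the guild's species observed in `year` (count >= 1), columns are
#' all plots of the community table; both in lexicographic order so the
#' layout is reproducible. Row sums are species occupancies, column sums are
#' plot richness for that guild/year.
#'
#' @param community community table.
#' @param traits trait table carrying the guild assignment
#'   (see [build_trait_table()] or [read_trait_table()]).
#' @param guild `"ECM"` or `"ST"`.
#' @param year year label present in the community table.
#' @return a 0/1 integer matrix with `dimnames` (species, plots) and
#'   attributes `guild` and `year`; a matrix with zero rows (empty sentinel)
#'   if the guild has no species that year.
#' @export
to_binary_matrix <- function(community, traits, guild, year) {
  stopifnot(guild %in% c("ECM", "ST"))
  community <- validate_community(community)
  if (!year %in% community$year) {
    stop("year ", year, " not present in community table", call. = FALSE)
  }
  plots <- sort(unique(community$plot_id))
  guild_sp <- traits$species_id[traits$guild == guild]
  sub <- community[community$year == year &
                     community$species_id %in% guild_sp, , drop = FALSE]
  species <- sort(unique(sub$species_id))
  m <- matrix(0L, nrow = length(species), ncol = length(plots),
              dimnames = list(species, plots))
  if (length(species) == 0L) {
    message("to_binary_matrix: no ", guild, " species in year ", year,
            " (empty matrix)")
  } else {
    m[cbind(match(sub$species_id, species), match(sub$plot_id, plots))] <- 1L
  }
  attr(m, "guild") <- guild
  attr(m, "year") <- as.integer(year)
  m
}

#' Unweighted assemblage mean traits
#'
#' For each plot with at least one species in the matrix, the mean across
#' species present of log10 fruit-body size and log10 mean fruit-body
#' number. Species-level traits are log10-transformed before averaging, and
#' every species counts equally (no abundance weighting).
#'
#' @param mat binary matrix from [to_binary_matrix()].
#' @param trait_table trait table from [build_trait_table()] covering every
#'   species in `mat`.
#' @return a data frame with columns `plot_id`, `guild`, `year`, `richness`,
#'   `mean_log_size`, `mean_log_n`; one row per occupied plot.
#' @export
assemblage_means <- function(mat, trait_table) {
  species <- rownames(mat)
  idx <- match(species, trait_table$species_id)
  if (anyNA(idx)) {
    stop("assemblage_means: no traits for species ",
         paste(species[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  lsize <- log10(trait_table$fruit_body_size[idx])
  ln <- log10(trait_table$mean_fruit_bodies[idx])
  if (anyNA(ln)) {
    stop("assemblage_means: missing mean_fruit_bodies for species ",
         paste(species[is.na(ln)], collapse = ", "), call. = FALSE)
  }
  richness <- colSums(mat)
  keep <- richness >= 1L
  guild <- attr(mat, "guild")
  year <- attr(mat, "year")
  out <- data.frame(
    plot_id = colnames(mat)[keep],
    guild = if (is.null(guild)) NA_character_ else guild,
    year = if (is.null(year)) NA_integer_ else year,
    richness = as.integer(richness[keep]),
    mean_log_size = as.numeric(crossprod(mat[, keep, drop = FALSE], lsize)) /
      richness[keep],
    mean_log_n = as.numeric(crossprod(mat[, keep, drop = FALSE], ln)) /
      richness[keep],
    row.names = NULL, stringsAsFactors = FALSE)
  out
}
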