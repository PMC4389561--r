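# Synthetic occurrence tables with controlled contamination. Points are
# drawn uniformly inside each species' home region; a configurable fraction
# of rows is then corrupted with exactly the pathologies the cleaning step
# targets (duplicates, zero coordinates, lat == lon, missing names,
# non-numeric coordinates, source-flagged rows) plus "stray" points placed
# in a wrong region. Ground truth is kept alongside for round-trip tests.

#' Contamination configuration for the occurrence generator
#'
#' All rates are per-row probabilities in `[0, 1]`. `duplicate` appends an
#' exact copy of a row; the remaining destructive pathologies are mutually
#' exclusive per row (at most one applied, chosen in the listed order).
#'
#' @param duplicate rate of exact-duplicate rows.
#' @param flagged rate of rows carrying a truthy source flag.
#' @param missing_name rate of blank species names.
#' @param nonnumeric rate of unparseable coordinate strings.
#' @param zero_coord rate of a zero longitude or latitude.
#' @param lat_eq_lon rate of latitude set equal to longitude.
#' @param stray rate of points relocated into a wrong region.
#' @return a named list of rates (class `contamination_config`).
#' @export
contamination_config <- function(duplicate = 0, flagged = 0, missing_name = 0,
                                 nonnumeric = 0, zero_coord = 0,
                                 lat_eq_lon = 0, stray = 0) {
  rates <- list(duplicate = duplicate, flagged = flagged,
                missing_name = missing_name, nonnumeric = nonnumeric,
                zero_coord = zero_coord, lat_eq_lon = lat_eq_lon,
                stray = stray)
  if (any(unlist(rates) < 0) || any(unlist(rates) > 1)) {
    stop("contamination rates must be in [0, 1]")
  }
  structure(rates, class = "contamination_config")
}

#' Generate a raw occurrence table with known ground truth
#'
#' @param species_ranges data frame with columns `species`, `region`,
#'   `n_points`: each species' home region and clean point count.
#' @param regions a [region_set()].
#' @param error_rates a [contamination_config()].
#' @param seed integer seed.
#' @return data frame with columns `species`, `decimalLongitude`,
#'   `decimalLatitude`, `flag` (coordinates are character columns whenever
#'   non-numeric contamination is requested). Attribute `"truth"` holds one
#'   row per output row: `pathology` (`"clean"`, `"duplicate"`, `"flagged"`,
#'   `"missing_name"`, `"nonnumeric"`, `"zero_coord"`, `"lat_eq_lon"`,
#'   `"stray"`) and `true_region`.
#' @export
generate_occurrences <- function(species_ranges, regions,
                                 error_rates = contamination_config(),
                                 seed = NULL) {
  stopifnot(inherits(regions, "region_set"))
  if (!all(c("species", "region", "n_points") %in% names(species_ranges))) {
    stop("`species_ranges` needs columns species, region, n_points")
  }
  unknown <- setdiff(species_ranges$region, names(regions$regions))
  if (length(unknown) > 0) stop("unknown region name: ", unknown[1])
  if (any(species_ranges$n_points < 0)) stop("`n_points` must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  er <- error_rates

  sp_col <- character(0); lon <- numeric(0); lat <- numeric(0)
  true_region <- character(0)
  for (i in seq_len(nrow(species_ranges))) {
    n <- species_ranges$n_points[i]
    if (n == 0) next
    pts <- sample_points_in_ring(n, regions$regions[[species_ranges$region[i]]])
    sp_col <- c(sp_col, rep(species_ranges$species[i], n))
    lon <- c(lon, round(pts[, 1], 6)); lat <- c(lat, round(pts[, 2], 6))
    true_region <- c(true_region, rep(species_ranges$region[i], n))
  }
  n <- length(sp_col)
  pathology <- rep("clean", n)
  flag <- rep("", n)

  # stray points first: relocated into a wrong (random other) region
  if (er$stray > 0 && length(regions$regions) > 1) {
    hit <- runif(n) < er$stray
    for (j in which(hit)) {
      other <- setdiff(names(regions$regions), true_region[j])
      tgt <- other[sample.int(length(other), 1)]
      p <- sample_points_in_ring(1, regions$regions[[tgt]])
      lon[j] <- round(p[1], 6); lat[j] <- round(p[2], 6)
      pathology[j] <- "stray"
    }
  }

  # destructive pathologies, at most one per row, applied to clean rows
  lon_chr <- as.character(lon); lat_chr <- as.character(lat)
  want_chr <- er$nonnumeric > 0
  destructive <- c("flagged", "missing_name", "nonnumeric", "zero_coord",
                   "lat_eq_lon")
  u <- runif(n)
  for (j in seq_len(n)) {
    if (pathology[j] != "clean") next
    cum <- 0
    for (p in destructive) {
      cum <- cum + er[[p]]
      if (u[j] < cum) {
        pathology[j] <- p
        if (p == "flagged") flag[j] <- "coordinate_issue"
        if (p == "missing_name") sp_col[j] <- ""
        if (p == "nonnumeric") lon_chr[j] <- paste0(lon_chr[j], "_x")
        if (p == "zero_coord") {
          if (j %% 2 == 0) lon_chr[j] <- "0" else lat_chr[j] <- "0"
        }
        if (p == "lat_eq_lon") lat_chr[j] <- lon_chr[j]
        break
      }
    }
  }

  tab <- data.frame(
    species = sp_col,
    decimalLongitude = if (want_chr) lon_chr else as.numeric(lon_chr),
    decimalLatitude = if (want_chr) lat_chr else as.numeric(lat_chr),
    flag = flag,
    stringsAsFactors = FALSE
  )
  truth <- data.frame(pathology = pathology, true_region = true_region,
                      stringsAsFactors = FALSE)

  # exact duplicates appended last
  if (er$duplicate > 0 && n > 0) {
    dup <- which(runif(n) < er$duplicate & pathology == "clean")
    if (length(dup) > 0) {
      tab <- rbind(tab, tab[dup, , drop = FALSE])
      truth <- rbind(truth, data.frame(pathology = "duplicate",
                                       true_region = true_region[dup]))
    }
  }
  rownames(tab) <- NULL; rownames(truth) <- NULL
  attr(tab, "truth") <- truth
  tab
}
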