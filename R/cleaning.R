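# Occurrence-record cleaning. Rules are applied in a fixed order and each
# row is removed by the first rule it matches, so the removal counts in the
# report are reproducible and conserve the row total.

CLEANING_RULES <- c("flagged_issue", "missing_name", "nonnumeric_coords",
                    "out_of_range", "lat_equals_lon", "zero_coordinate",
                    "duplicate_location")

#' Clean a raw occurrence table
#'
#' Applies, in order: removal of rows whose source flag marks a known
#' coordinate issue; missing/blank species names; non-numeric or missing
#' coordinates; out-of-range coordinates (|lat| > 90, |lon| > 180);
#' latitude equal to longitude; zero latitude or longitude (taken as
#' blank data entry); and deduplication to one record per species per
#' location (coordinates compared after rounding to 4 decimals, ~11 m).
#'
#' @param raw data frame with columns `species`, `decimalLongitude`,
#'   `decimalLatitude` and optionally `flag`.
#' @return list with `clean` (the cleaned table, numeric coordinates) and
#'   `report` (class `cleaning_report`: per-rule removal counts and totals).
#' @export
clean_occurrences <- function(raw) {
  mandatory <- c("species", "decimalLongitude", "decimalLatitude")
  for (col in mandatory) {
    if (!col %in% names(raw)) stop("missing mandatory column: ", col)
  }
  n_input <- nrow(raw)
  removed <- setNames(integer(length(CLEANING_RULES)), CLEANING_RULES)

  sp <- as.character(raw$species)
  lon <- suppressWarnings(as.numeric(as.character(raw$decimalLongitude)))
  lat <- suppressWarnings(as.numeric(as.character(raw$decimalLatitude)))
  flag <- if ("flag" %in% names(raw)) as.character(raw$flag) else rep("", n_input)
  flag[is.na(flag)] <- ""

  keep <- rep(TRUE, n_input)
  drop_rule <- function(bad, rule) {
    bad <- bad & keep
    removed[rule] <<- sum(bad)
    keep[bad] <<- FALSE
  }
  truthy <- !(flag == "" | flag == "0" | tolower(flag) %in% c("false", "na"))
  drop_rule(truthy, "flagged_issue")
  drop_rule(is.na(sp) | trimws(sp) == "", "missing_name")
  drop_rule(is.na(lon) | is.na(lat), "nonnumeric_coords")
  drop_rule(abs(lat) > 90 | abs(lon) > 180, "out_of_range")
  drop_rule(lat == lon, "lat_equals_lon")
  drop_rule(lat == 0 | lon == 0, "zero_coordinate")
  loc_key <- paste(sp, round(lon, 4), round(lat, 4), sep = "\r")
  # only duplicates among retained rows count; dropped rows get unique keys
  loc_key[!keep] <- paste0("dropped", which(!keep))
  dup <- keep & duplicated(loc_key)
  drop_rule(dup, "duplicate_location")

  clean <- data.frame(
    species = sp[keep],
    decimalLongitude = lon[keep],
    decimalLatitude = lat[keep],
    flag = flag[keep],
    stringsAsFactors = FALSE
  )
  rownames(clean) <- NULL
  report <- structure(
    list(removed = removed, n_input = n_input, n_output = nrow(clean)),
    class = "cleaning_report"
  )
  stopifnot(report$n_input == report$n_output + sum(report$removed))
  attr(clean, "kept_rows") <- which(keep)
  list(clean = clean, report = report)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("cleaning report:", x$n_input, "rows in,", x$n_output, "rows out\n")
  for (r in names(x$removed)) {
    cat(sprintf("  %-20s %d\n", r, x$removed[[r]]))
  }
  invisible(x)
}

#' Serialize a cleaning report to JSON
#' @param report a `cleaning_report`.
#' @param path output file.
#' @export
write_cleaning_report <- function(report, path) {
  jsonlite::write_json(
    list(removed = as.list(report$removed), n_input = report$n_input,
         n_output = report$n_output),
    path, auto_unbox = TRUE, pretty = TRUE
  )
}
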