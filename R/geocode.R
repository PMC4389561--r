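# Region coding: point-in-polygon assignment of cleaned occurrence records,
# per-species per-region record counts, the tiered presence filters
# (minimum record count, minimum record percentage, single-region rule),
# name matching against a tree's tip set, and sampling fractions.

#' Assign occurrence points to regions
#'
#' Each point is labelled with the unique region whose closed polygon covers
#' it (boundary points count as inside; contacts on a shared boundary are
#' resolved by the region precedence order), or `"unassigned"`.
#'
#' @param table a cleaned occurrence table (numeric coordinates).
#' @param regions a [region_set()]; validated for pairwise interior
#'   disjointness before any assignment.
#' @return the table with an added `region` column; attributes
#'   `"region_names"` and `"precedence"` carry the region set's names.
#' @export
assign_points_to_regions <- function(table, regions) {
  stopifnot(inherits(regions, "region_set"))
  validate_region_set(regions)
  lon <- table$decimalLongitude
  lat <- table$decimalLatitude
  if (!is.numeric(lon) || !is.numeric(lat)) {
    stop("coordinates must be numeric; run clean_occurrences() first")
  }
  label <- rep("unassigned", nrow(table))
  for (nm in rev(regions$precedence)) {
    ring <- regions$regions[[nm]]
    inside <- sp::point.in.polygon(lon, lat, ring[, 1], ring[, 2]) > 0
    label[inside] <- nm
  }
  out <- table
  out$region <- label
  attr(out, "region_names") <- names(regions$regions)
  attr(out, "precedence") <- regions$precedence
  out
}

#' Tabulate per-species per-region record counts
#'
#' @param labelled output of [assign_points_to_regions()]; unassigned points
#'   are excluded from counts.
#' @return object of class `presence_matrix` holding the count matrix
#'   (species x region) with regions in precedence order.
#' @export
tabulate_presence <- function(labelled) {
  regions <- attr(labelled, "precedence")
  if (is.null(regions)) {
    regions <- setdiff(sort(unique(labelled$region)), "unassigned")
  }
  assigned <- labelled[labelled$region != "unassigned", , drop = FALSE]
  species <- sort(unique(assigned$species))
  counts <- matrix(0L, length(species), length(regions),
                   dimnames = list(species, regions))
  if (nrow(assigned) > 0) {
    tab <- table(factor(assigned$species, levels = species),
                 factor(assigned$region, levels = regions))
    counts[] <- as.integer(tab)
  }
  structure(list(counts = counts, presence = NULL, filter_level = NULL),
            class = "presence_matrix")
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat("presence_matrix:", nrow(x$counts), "species x", ncol(x$counts),
      "regions")
  if (!is.null(x$filter_level)) cat("; presence at filter", x$filter_level)
  cat("\n")
  invisible(x)
}

#' Apply a tiered presence filter to a count matrix
#'
#' Filter levels: 0 — present with >= 1 record; 1 — >= 3 records in the
#' region; 2 — additionally the region must hold >= 10% of the species'
#' assigned records; 3 — additionally presence is kept only in the single
#' region with the highest record count (ties broken by precedence order).
#'
#' @param matrix a `presence_matrix` (from [tabulate_presence()]).
#' @param level filter level 0, 1, 2, or 3.
#' @param min_records minimum record count for levels >= 1 (default 3).
#' @param min_fraction minimum share of a species' assigned records for
#'   levels >= 2 (default 0.10).
#' @return the `presence_matrix` with a logical `presence` matrix and the
#'   filter level recorded.
#' @export
apply_filter <- function(matrix, level, min_records = 3, min_fraction = 0.10) {
  stopifnot(inherits(matrix, "presence_matrix"))
  if (!level %in% 0:3) stop("unknown filter level: ", level)
  counts <- matrix$counts
  pres <- counts >= 1L
  if (level >= 1) pres <- counts >= min_records
  if (level >= 2) {
    tot <- rowSums(counts)
    share_ok <- counts >= min_fraction * tot
    pres <- pres & share_ok
  }
  if (level == 3) {
    # keep only the top-count region among those passing level 2;
    # ties resolved by column (precedence) order
    for (i in seq_len(nrow(counts))) {
      if (!any(pres[i, ])) next
      top <- which.max(counts[i, ])
      keep <- logical(ncol(counts))
      keep[top] <- pres[i, top]
      pres[i, ] <- keep
    }
  }
  matrix$presence <- pres
  matrix$filter_level <- level
  matrix
}

canonical_name <- function(x) {
  x <- tolower(gsub("_", " ", as.character(x)))
  x <- gsub("\\s+", " ", trimws(x))
  vapply(strsplit(x, " "), function(t) paste(head(t, 2), collapse = " "),
         character(1))
}

#' Match occurrence species names to tree tip labels
#'
#' Names are canonicalized (underscores to spaces, whitespace collapsed,
#' case-folded, first two name tokens kept) and matched exactly. Distinct
#' labels that collide on the same canonical form are reported and excluded
#' rather than silently merged.
#'
#' @param occ_names character vector of occurrence species names.
#' @param tip_labels character vector of tree tip labels.
#' @return list with `matched` (data frame `occurrence`, `tip`),
#'   `unmatched_occurrences`, `unmatched_tips`, and `collisions`.
#' @export
match_names <- function(occ_names, tip_labels) {
  occ_names <- unique(as.character(occ_names))
  tip_labels <- unique(as.character(tip_labels))
  occ_canon <- canonical_name(occ_names)
  tip_canon <- canonical_name(tip_labels)

  collide <- function(orig, canon) {
    tab <- split(orig, canon)
    names(tab)[vapply(tab, function(v) length(unique(v)) > 1, logical(1))]
  }
  collisions <- union(collide(occ_names, occ_canon),
                      collide(tip_labels, tip_canon))
  occ_ok <- !occ_canon %in% collisions
  tip_ok <- !tip_canon %in% collisions

  idx <- match(occ_canon, replace(tip_canon, !tip_ok, NA))
  idx[!occ_ok] <- NA
  matched <- data.frame(
    occurrence = occ_names[!is.na(idx)],
    tip = tip_labels[idx[!is.na(idx)]],
    stringsAsFactors = FALSE
  )
  list(
    matched = matched,
    unmatched_occurrences = occ_names[is.na(idx) & occ_ok],
    unmatched_tips = setdiff(tip_labels[tip_ok], matched$tip),
    collisions = collisions
  )
}

#' Per-region sampling fractions against a tree's tip set
#'
#' For every region (and optionally every clade-by-region cell): the number
#' of species coded present, the number of those matched to a tree tip, and
#' their ratio — the sampling fraction that feeds the state-dependent
#' diversification analysis.
#'
#' @param presence a `presence_matrix` with presence calls (see
#'   [apply_filter()]).
#' @param tip_labels tree tip labels.
#' @param clades optional data frame (`tip_id`, `clade`) restricting
#'   per-clade fractions.
#' @param groups optional named list of region groups; each adds a row whose
#'   species set is the union over the member regions.
#' @return data frame `region`, `n_region`, `n_in_tree`, `fraction`
#'   (rounded to 2 decimals), `fraction_raw`; with `clades`, an attribute
#'   `"by_clade"` holds the per-clade table.
#' @export
compute_sampling_fractions <- function(presence, tip_labels, clades = NULL,
                                       groups = NULL) {
  stopifnot(inherits(presence, "presence_matrix"))
  if (is.null(presence$presence)) stop("apply a filter level first")
  pres <- presence$presence
  mm <- match_names(rownames(pres), tip_labels)
  in_tree <- rownames(pres) %in% mm$matched$occurrence

  frac_row <- function(sel_species, region_name) {
    n_region <- length(sel_species)
    n_tree <- sum(sel_species %in% rownames(pres)[in_tree])
    data.frame(
      region = region_name, n_region = n_region, n_in_tree = n_tree,
      fraction = if (n_region > 0) sampling_fraction(n_region, n_tree) else NA_real_,
      fraction_raw = if (n_region > 0) n_tree / n_region else NA_real_,
      stringsAsFactors = FALSE
    )
  }
  rows <- lapply(colnames(pres), function(r) {
    frac_row(rownames(pres)[pres[, r]], r)
  })
  if (!is.null(groups)) {
    rows <- c(rows, lapply(names(groups), function(g) {
      members <- groups[[g]]
      sel <- rownames(pres)[rowSums(pres[, members, drop = FALSE]) > 0]
      frac_row(sel, g)
    }))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL

  if (!is.null(clades)) {
    tip2clade <- setNames(as.character(clades[[2]]), as.character(clades[[1]]))
    sp2tip <- setNames(mm$matched$tip, mm$matched$occurrence)
    by_clade <- do.call(rbind, lapply(unique(tip2clade), function(cl) {
      cl_tips <- names(tip2clade)[tip2clade == cl]
      cl_species <- names(sp2tip)[sp2tip %in% cl_tips]
      do.call(rbind, lapply(colnames(pres), function(r) {
        # denominator: species present in the region whose matched tip is in
        # the clade (clade membership is only knowable for matched species)
        sel <- intersect(rownames(pres)[pres[, r]], cl_species)
        cbind(clade = cl, frac_row(sel, r))
      }))
    }))
    rownames(by_clade) <- NULL
    attr(out, "by_clade") <- by_clade
  }
  out
}

#' Sampling-fraction arithmetic (rounded as reported)
#'
#' @param n_total species recorded in the region.
#' @param n_in_tree species of those also present in the phylogeny.
#' @param digits decimals for reporting (default 2).
#' @return the rounded ratio `n_in_tree / n_total`.
#' @export
sampling_fraction <- function(n_total, n_in_tree, digits = 2) {
  if (any(n_total <= 0)) stop("undefined sampling fraction: zero denominator")
  round(n_in_tree / n_total, digits)
}
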