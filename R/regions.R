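# Region polygons: a small container for named, interior-disjoint simple
# polygons in longitude/latitude degrees, WKT text IO, and point-in-polygon
# assignment (closed-polygon rule: boundary points count as inside).
# Containment tests are delegated to sp::point.in.polygon.

#' Construct a set of named region polygons
#'
#' @param regions named list of rings: each a 2-column matrix (lon, lat) in
#'   degrees; the ring may be open (first vertex not repeated).
#' @param precedence region names in tie-break order (default: list order).
#'   Used to resolve single-region (Filter 3) ties and boundary contacts.
#' @return object of class `region_set`.
#' @export
region_set <- function(regions, precedence = names(regions)) {
  if (is.null(names(regions)) || anyDuplicated(names(regions))) {
    stop("regions must have unique names")
  }
  regions <- lapply(regions, function(r) {
    r <- as.matrix(r)
    if (ncol(r) != 2 || nrow(r) < 3) stop("each region needs >= 3 (lon, lat) vertices")
    storage.mode(r) <- "double"
    # drop a repeated closing vertex; rings are stored open
    if (all(r[1, ] == r[nrow(r), ])) r <- r[-nrow(r), , drop = FALSE]
    colnames(r) <- c("lon", "lat")
    r
  })
  if (!setequal(precedence, names(regions)) ||
      length(precedence) != length(regions)) {
    stop("`precedence` must be a permutation of the region names")
  }
  structure(list(regions = regions, precedence = precedence),
            class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat("region_set with", length(x$regions), "regions:",
      paste(x$precedence, collapse = ", "), "\n")
  invisible(x)
}

point_in_ring <- function(lon, lat, ring) {
  sp::point.in.polygon(lon, lat, ring[, 1], ring[, 2]) > 0
}

# proper segment crossing test (shared endpoints/collinear touching excluded)
segments_cross <- function(p1, p2, q1, q2) {
  orient <- function(a, b, c) {
    (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  }
  d1 <- orient(q1, q2, p1); d2 <- orient(q1, q2, p2)
  d3 <- orient(p1, p2, q1); d4 <- orient(p1, p2, q2)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

ring_edges <- function(ring) {
  n <- nrow(ring)
  list(from = ring, to = ring[c(2:n, 1), , drop = FALSE])
}

rings_interior_overlap <- function(a, b) {
  # vertex of one strictly inside the other
  if (any(sp::point.in.polygon(a[, 1], a[, 2], b[, 1], b[, 2]) == 1)) return(TRUE)
  if (any(sp::point.in.polygon(b[, 1], b[, 2], a[, 1], a[, 2]) == 1)) return(TRUE)
  ea <- ring_edges(a); eb <- ring_edges(b)
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (segments_cross(ea$from[i, ], ea$to[i, ], eb$from[j, ], eb$to[j, ])) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Validate that regions are pairwise interior-disjoint
#' @param rs a [region_set()].
#' @return invisibly `TRUE`; errors naming an overlapping pair otherwise.
#' @export
validate_region_set <- function(rs) {
  stopifnot(inherits(rs, "region_set"))
  nm <- names(rs$regions)
  if (length(nm) >= 2) {
    for (i in seq_len(length(nm) - 1)) {
      for (j in seq(i + 1, length(nm))) {
        if (rings_interior_overlap(rs$regions[[i]], rs$regions[[j]])) {
          stop("regions overlap: ", nm[i], " / ", nm[j])
        }
      }
    }
  }
  invisible(TRUE)
}

#' Toy region fixtures: four disjoint rectangles
#'
#' Deterministic stand-ins for continental-scale operational units: three
#' tropical rectangles (America, Africa, Asia) in the latitude band
#' -23..23 and one northern non-tropical band.
#'
#' @return a [region_set()] with regions `AmericanTropics`,
#'   `AfricanTropics`, `AsianTropics`, `NonTropical`.
#' @export
make_region_fixtures <- function() {
  rect <- function(lon1, lon2, lat1, lat2) {
    cbind(lon = c(lon1, lon2, lon2, lon1), lat = c(lat1, lat1, lat2, lat2))
  }
  region_set(list(
    AmericanTropics = rect(-100, -40, -23, 23),
    AfricanTropics = rect(-20, 50, -23, 23),
    AsianTropics = rect(60, 160, -23, 23),
    NonTropical = rect(-180, 180, 30, 70)
  ))
}

#' Write a region set as WKT text (one `NAME<TAB>POLYGON(...)` per line)
#' @param rs a [region_set()].
#' @param path output file.
#' @export
write_regions_wkt <- function(rs, path) {
  stopifnot(inherits(rs, "region_set"))
  lines <- vapply(names(rs$regions), function(nm) {
    r <- rs$regions[[nm]]
    ring <- rbind(r, r[1, , drop = FALSE])
    coords <- paste(apply(ring, 1, function(p) paste(p[1], p[2])),
                    collapse = ", ")
    paste0(nm, "\tPOLYGON ((", coords, "))")
  }, character(1))
  writeLines(lines, path)
}

#' Read a region set from WKT text written by [write_regions_wkt()]
#' @param path input file.
#' @return a [region_set()].
#' @export
read_regions_wkt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t")
  nms <- vapply(parts, `[`, character(1), 1)
  regions <- lapply(parts, function(p) {
    wkt <- p[[2]]
    body <- sub("^\\s*POLYGON\\s*\\(\\(", "", wkt)
    body <- sub("\\)\\)\\s*$", "", body)
    pts <- strsplit(trimws(strsplit(body, ",")[[1]]), "\\s+")
    m <- t(vapply(pts, function(v) as.numeric(v[1:2]), numeric(2)))
    colnames(m) <- c("lon", "lat")
    m
  })
  names(regions) <- nms
  region_set(regions)
}

# uniform point sampling inside a ring by bounding-box rejection
sample_points_in_ring <- function(n, ring) {
  out <- matrix(NA_real_, 0, 2)
  lo <- apply(ring, 2, min); hi <- apply(ring, 2, max)
  while (nrow(out) < n) {
    m <- max(16L, 2L * (n - nrow(out)))
    cand <- cbind(runif(m, lo[1], hi[1]), runif(m, lo[2], hi[2]))
    ok <- sp::point.in.polygon(cand[, 1], cand[, 2], ring[, 1], ring[, 2]) == 1
    out <- rbind(out, cand[ok, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}
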