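# Occurrence cleaning, region assignment, presence filters, name matching
# and sampling fractions.

test_that("region fixtures are four named, interior-disjoint rectangles", {
  rs <- make_region_fixtures()
  expect_setequal(names(rs$regions),
                  c("AmericanTropics", "AfricanTropics", "AsianTropics",
                    "NonTropical"))
  expect_silent(validate_region_set(rs))
  # every pairwise overlap check is empty
  nm <- names(rs$regions)
  for (i in 1:3) for (j in (i + 1):4) {
    expect_false(geoshift:::rings_interior_overlap(rs$regions[[nm[i]]],
                                                   rs$regions[[nm[j]]]))
  }
})

test_that("overlapping regions are rejected before any assignment", {
  rect <- function(x1, x2, y1, y2) cbind(c(x1, x2, x2, x1), c(y1, y1, y2, y2))
  rs <- region_set(list(a = rect(0, 10, 0, 10), b = rect(5, 15, 5, 15)))
  tab <- data.frame(species = "s", decimalLongitude = 1, decimalLatitude = 1,
                    flag = "")
  expect_error(assign_points_to_regions(tab, rs), "overlap")
})

test_that("WKT round-trip preserves regions and downstream counts exactly", {
  rs <- make_region_fixtures()
  path <- withr::local_tempfile(fileext = ".wkt")
  write_regions_wkt(rs, path)
  rs2 <- read_regions_wkt(path)
  expect_equal(rs2$regions, rs$regions)

  occ <- generate_occurrences(
    data.frame(species = c("a", "b"), region = c("AsianTropics", "NonTropical"),
               n_points = c(30, 20)),
    rs, seed = 8
  )
  c1 <- tabulate_presence(assign_points_to_regions(occ, rs))$counts
  c2 <- tabulate_presence(assign_points_to_regions(occ, rs2))$counts
  expect_identical(c1, c2)
})

test_that("cleaning applies the documented rules in order and conserves totals", {
  raw <- data.frame(
    species = c("sp1", "sp1", "sp2", "", "sp3", "sp4", "sp5", "sp5", "sp5",
                "sp6"),
    decimalLongitude = c(0.0, 10.1, "12.3_x", 5, 20, 30.5, 10.1, 10.1, 10.1,
                         200),
    decimalLatitude = c(12.3, 20.2, 4, 5, 20, 8, 20.2, 20.2, 20.2, 10),
    flag = c("", "", "", "", "", "coordinate_issue", "", "", "", ""),
    stringsAsFactors = FALSE
  )
  res <- clean_occurrences(raw)
  rep <- res$report
  expect_equal(unname(rep$removed["zero_coordinate"]), 1) # (sp1, lon 0)
  expect_equal(unname(rep$removed["nonnumeric_coords"]), 1) # sp2
  expect_equal(unname(rep$removed["missing_name"]), 1)
  expect_equal(unname(rep$removed["lat_equals_lon"]), 1) # sp3 (20, 20)
  expect_equal(unname(rep$removed["flagged_issue"]), 1) # sp4
  expect_equal(unname(rep$removed["out_of_range"]), 1) # sp6 lon 200
  expect_equal(unname(rep$removed["duplicate_location"]), 2) # sp5 triplet
  expect_equal(rep$n_input, rep$n_output + sum(rep$removed))
  expect_equal(res$clean$species, c("sp1", "sp5"))
})

test_that("cleaning a clean table removes nothing and is idempotent", {
  rs <- make_region_fixtures()
  occ <- generate_occurrences(
    data.frame(species = "sp one", region = "AmericanTropics", n_points = 10),
    rs, seed = 1
  )
  res <- clean_occurrences(occ)
  expect_equal(res$report$n_output, 10)
  expect_true(all(res$report$removed == 0))
  res2 <- clean_occurrences(res$clean)
  expect_true(all(res2$report$removed == 0))
  expect_equal(res2$clean, res$clean, ignore_attr = TRUE)
})

test_that("the cleaner removes exactly the ground-truth contaminated rows", {
  rs <- make_region_fixtures()
  ranges <- data.frame(
    species = paste("Gen sp", 1:6), n_points = 80,
    region = c("AmericanTropics", "AfricanTropics", "AsianTropics",
               "NonTropical", "AmericanTropics", "AsianTropics")
  )
  occ <- generate_occurrences(
    ranges, rs,
    error_rates = contamination_config(duplicate = 0.1, flagged = 0.04,
                                       missing_name = 0.04, nonnumeric = 0.04,
                                       zero_coord = 0.04, lat_eq_lon = 0.04),
    seed = 77
  )
  truth <- attr(occ, "truth")
  res <- clean_occurrences(occ)
  kept <- attr(res$clean, "kept_rows")
  expect_setequal(kept, which(truth$pathology == "clean"))
})

test_that("missing mandatory columns give a schema error naming the column", {
  expect_error(clean_occurrences(data.frame(species = "a")),
               "decimalLongitude")
})

test_that("points are assigned by the closed-polygon rule", {
  rs <- make_region_fixtures()
  tab <- data.frame(
    species = c("a", "a", "a", "a"),
    decimalLongitude = c(-70, -100, 0, 55), # interior / boundary / inside Africa box? 0 is interior of Africa lon range
    decimalLatitude = c(10, 0, 25, 25), # third point: lat 25 outside all
    flag = ""
  )
  lab <- assign_points_to_regions(tab, rs)
  expect_equal(lab$region,
               c("AmericanTropics", "AmericanTropics", "unassigned",
                 "unassigned"))
  # boundary point of exactly one region counts as inside it
  expect_equal(assign_points_to_regions(
    data.frame(species = "b", decimalLongitude = -40, decimalLatitude = 23,
               flag = ""), rs)$region, "AmericanTropics")
})

test_that("ground-truth regions are recovered for all non-contaminated points", {
  rs <- make_region_fixtures()
  ranges <- data.frame(species = paste("sp", 1:4),
                       region = names(rs$regions), n_points = 50)
  occ <- generate_occurrences(ranges, rs,
                              error_rates = contamination_config(stray = 0.1),
                              seed = 12)
  truth <- attr(occ, "truth")
  lab <- assign_points_to_regions(clean_occurrences(occ)$clean, rs)
  clean_rows <- truth$pathology == "clean"
  expect_equal(lab$region[clean_rows], truth$true_region[clean_rows])
})

test_that("presence counts conserve assigned rows and filters follow the tier rules", {
  counts <- matrix(c(5, 1, 0, 0,
                     95, 5, 0, 0,
                     40, 60, 0, 0), nrow = 3, byrow = TRUE,
                   dimnames = list(c("s1", "s2", "s3"),
                                   c("A", "B", "C", "D")))
  pm <- structure(list(counts = counts, presence = NULL, filter_level = NULL),
                  class = "presence_matrix")
  f0 <- apply_filter(pm, 0)$presence
  f1 <- apply_filter(pm, 1)$presence
  f2 <- apply_filter(pm, 2)$presence
  f3 <- apply_filter(pm, 3)$presence
  # counts (5, 1): level 1 drops B (1 < 3)
  expect_equal(unname(f1["s1", ]), c(TRUE, FALSE, FALSE, FALSE))
  # counts (95, 5): level 1 keeps both (5 >= 3); level 2 drops B (5% < 10%)
  expect_equal(unname(f1["s2", ]), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(unname(f2["s2", ]), c(TRUE, FALSE, FALSE, FALSE))
  # counts (40, 60): level 3 keeps only the highest-count region
  expect_equal(unname(f2["s3", ]), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(unname(f3["s3", ]), c(FALSE, TRUE, FALSE, FALSE))
  # monotonicity 0 -> 1 -> 2, and level 3 keeps at most one region
  expect_true(all(f1 <= f0) && all(f2 <= f1) && all(f3 <= f2))
  expect_true(all(rowSums(f3) <= 1))
  expect_error(apply_filter(pm, 9), "unknown filter level")
})

test_that("tabulated counts sum to the number of assigned rows", {
  rs <- make_region_fixtures()
  occ <- generate_occurrences(
    data.frame(species = c("u", "v"), region = c("AfricanTropics",
                                                 "NonTropical"),
               n_points = c(12, 9)),
    rs, error_rates = contamination_config(stray = 0.2), seed = 3
  )
  lab <- assign_points_to_regions(occ, rs)
  pm <- tabulate_presence(lab)
  expect_equal(sum(pm$counts), sum(lab$region != "unassigned"))
  empty <- lab[0, , drop = FALSE]
  attr(empty, "precedence") <- attr(lab, "precedence")
  expect_equal(nrow(tabulate_presence(empty)$counts), 0)
})

test_that("name matching canonicalizes and reports collisions", {
  mm <- match_names(c("Abies alba", "Quercus robur var. x", "Pinus strobus"),
                    c("Abies_alba", "Quercus_robur", "Fagus_sylvatica"))
  expect_setequal(mm$matched$occurrence, c("Abies alba",
                                           "Quercus robur var. x"))
  expect_equal(mm$matched$tip[mm$matched$occurrence == "Abies alba"],
               "Abies_alba")
  expect_equal(mm$unmatched_occurrences, "Pinus strobus")
  expect_equal(mm$unmatched_tips, "Fagus_sylvatica")

  coll <- match_names(c("Abies alba", "Abies_alba subsp. y"), c("Abies alba"))
  # two distinct occurrence labels collapse to one canonical form
  expect_true("abies alba" %in% coll$collisions)
  expect_equal(nrow(coll$matched), 0)
})

test_that("sampling fractions report numerator, denominator and 2-dp ratio", {
  counts <- matrix(c(5, 0, 4, 0, 0, 6), nrow = 3, byrow = TRUE,
                   dimnames = list(c("Gen spa", "Gen spb", "Gen spc"),
                                   c("A", "B")))
  pm <- apply_filter(
    structure(list(counts = counts), class = "presence_matrix"), 1
  )
  fr <- compute_sampling_fractions(pm, c("Gen_spa", "Gen_spb"))
  a <- fr[fr$region == "A", ]
  expect_equal(a$n_region, 2)
  expect_equal(a$n_in_tree, 2)
  expect_equal(a$fraction, 1) # all species in the tree
  b <- fr[fr$region == "B", ]
  expect_equal(b$n_region, 1)
  expect_equal(b$n_in_tree, 0)
  expect_equal(b$fraction, 0)
  expect_error(sampling_fraction(0, 0), "zero denominator")
  # reported rounding matches the printed 2-decimal convention
  expect_equal(sampling_fraction(26194, 2460), 0.09)
  expect_equal(sampling_fraction(103682, 15666), 0.15)
})
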