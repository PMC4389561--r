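# End-to-end orchestration: a single validated config drives
# clean -> geocode -> filter -> match -> sampling fractions -> clustering
# tests -> shift rates -> per-clade MuSSE -> normalization/comparison, with
# per-stage seeds, machine-parseable logs, TSV outputs plus JSON metadata
# sidecars, and a manifest of file hashes that makes a run re-executable
# and byte-reproducible.

#' Pipeline configuration
#'
#' @param tree path to a Newick chronogram.
#' @param occurrences path to an occurrence CSV (`species`,
#'   `decimalLongitude`, `decimalLatitude`, optional `flag`).
#' @param regions path to a WKT region file (see [write_regions_wkt()]).
#' @param clades optional path to a clade TSV (`tip_id`, `clade`).
#' @param filter_shifts presence filter level used for range-shift states
#'   (default 2, reduced to single states by the highest-count rule).
#' @param filter_diversification presence filter level for diversification
#'   states (default 3).
#' @param n_maps stochastic maps for the shift-rate stage (default 100).
#' @param bin_width age bin width in Myr (default 5).
#' @param n_permutations tip permutations for the clustering tests
#'   (default 100).
#' @param seed master seed; stage seeds are derived with [substream_seed()].
#' @param root_mode MuSSE root treatment (see [musse_loglik()]).
#' @param denominator lineage-availability definition (see
#'   [lineages_in_bin()]).
#' @param widespread handling of species present in more than one region at
#'   the shift filter level: `"reduce"` (default) keeps the single
#'   highest-count region; `"drop"` excludes those species from the
#'   tree-based stages.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(tree, occurrences, regions, clades = NULL,
                            filter_shifts = 2, filter_diversification = 3,
                            n_maps = 100, bin_width = 5,
                            n_permutations = 100, seed = 1,
                            root_mode = "fitzjohn",
                            denominator = "branches",
                            widespread = c("reduce", "drop")) {
  widespread <- match.arg(widespread)
  for (lv in c(filter_shifts, filter_diversification)) {
    if (!lv %in% 0:3) stop("filter levels must be in 0..3")
  }
  if (filter_shifts > filter_diversification) {
    warning("filter levels are swapped relative to the usual defaults ",
            "(shifts = 2, diversification = 3)")
  }
  structure(
    list(tree = tree, occurrences = occurrences, regions = regions,
         clades = clades, filter_shifts = filter_shifts,
         filter_diversification = filter_diversification, n_maps = n_maps,
         bin_width = bin_width, n_permutations = n_permutations, seed = seed,
         root_mode = root_mode, denominator = denominator,
         widespread = widespread),
    class = "pipeline_config"
  )
}

#' Read a pipeline config from a YAML-style key: value text file
#' @param path config file.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- strsplit(lines, ":\\s*")
  vals <- setNames(lapply(kv, function(p) trimws(paste(p[-1], collapse = ":"))),
                   vapply(kv, `[`, character(1), 1))
  num <- function(x, d) if (is.null(x)) d else as.numeric(x)
  chr <- function(x, d = NULL) if (is.null(x) || x == "") d else x
  pipeline_config(
    tree = chr(vals$tree), occurrences = chr(vals$occurrences),
    regions = chr(vals$regions), clades = chr(vals$clades),
    filter_shifts = num(vals$filter_shifts, 2),
    filter_diversification = num(vals$filter_diversification, 3),
    n_maps = num(vals$n_maps, 100), bin_width = num(vals$bin_width, 5),
    n_permutations = num(vals$n_permutations, 100),
    seed = num(vals$seed, 1), root_mode = chr(vals$root_mode, "fitzjohn"),
    denominator = chr(vals$denominator, "branches"),
    widespread = chr(vals$widespread, "reduce")
  )
}

log_stage <- function(stage, level, msg) {
  message(sprintf("[%s]\t%s\t%s", stage, level, msg))
}

write_tsv <- function(d, path) {
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# single-state assignment from presence calls: the highest-count region
# among those coded present (ties by precedence = column order); with
# widespread = "drop", multi-region species are excluded instead
states_from_presence <- function(pm, widespread = "reduce") {
  pres <- pm$presence
  counts <- pm$counts
  out <- character(0)
  for (i in seq_len(nrow(pres))) {
    if (!any(pres[i, ])) next
    if (widespread == "drop" && sum(pres[i, ]) > 1) next
    cand <- which(pres[i, ])
    top <- cand[which.max(counts[i, cand])]
    out[rownames(pres)[i]] <- colnames(pres)[top]
  }
  out
}

#' Run the full pipeline
#'
#' Executes every stage on the configured inputs and writes versioned
#' outputs, per-stage seeds and a manifest into `out_dir`. Identical config
#' and seeds give byte-identical result tables.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  for (p in c(config$tree, config$occurrences, config$regions, config$clades)) {
    if (!is.null(p) && !file.exists(p)) stop("input path missing: ", p)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = unclass(config), stages = list(), outputs = list())
  fail <- function(stage, e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  stage_meta <- function(stage, seed, files, extra = list()) {
    manifest$stages[[stage]] <<- c(list(seed = seed, files = files), extra)
    for (f in files) manifest$outputs[[basename(f)]] <<- unname(tools::md5sum(f))
  }

  # --- load inputs
  tree <- ape::read.tree(config$tree)
  regions <- read_regions_wkt(config$regions)
  raw <- utils::read.csv(config$occurrences, stringsAsFactors = FALSE)
  clades <- if (!is.null(config$clades)) {
    read.table(config$clades, header = TRUE, sep = "\t",
               stringsAsFactors = FALSE)
  }

  # --- clean
  st <- tryCatch(clean_occurrences(raw), error = function(e) fail("clean", e))
  log_stage("clean", "info",
            paste0("rows_in=", st$report$n_input, " rows_out=",
                   st$report$n_output, " ",
                   paste(names(st$report$removed), st$report$removed,
                         sep = "=", collapse = " ")))
  f_clean <- write_tsv(st$clean, file.path(out_dir, "occurrences_clean.tsv"))
  f_report <- file.path(out_dir, "cleaning_report.json")
  write_cleaning_report(st$report, f_report)
  stage_meta("clean", NA, c(f_clean, f_report))

  # --- geocode + tabulate
  lab <- tryCatch(assign_points_to_regions(st$clean, regions),
                  error = function(e) fail("geocode", e))
  pm <- tabulate_presence(lab)
  f_counts <- write_tsv(
    data.frame(species = rownames(pm$counts), pm$counts,
               check.names = FALSE),
    file.path(out_dir, "region_counts.tsv")
  )
  stage_meta("geocode", NA, f_counts,
             list(unassigned = sum(lab$region == "unassigned")))

  # --- filters, name matching, sampling fractions
  pm_shift <- apply_filter(pm, config$filter_shifts)
  pm_div <- apply_filter(pm, config$filter_diversification)
  mm <- match_names(rownames(pm$counts), tree$tip.label)
  frac <- compute_sampling_fractions(pm_shift, tree$tip.label, clades)
  f_frac <- write_tsv(frac, file.path(out_dir, "sampling_fractions.tsv"))
  by_clade <- attr(frac, "by_clade")
  if (!is.null(by_clade)) {
    write_tsv(by_clade, file.path(out_dir, "sampling_fractions_by_clade.tsv"))
  }
  f_summary <- write_tsv(summarize_counts(lab, tree$tip.label),
                         file.path(out_dir, "counts_summary.tsv"))
  stage_meta("filters", NA, c(f_frac, f_summary),
             list(filter_shifts = config$filter_shifts,
                  filter_diversification = config$filter_diversification,
                  matched = nrow(mm$matched),
                  collisions = length(mm$collisions)))

  # --- tip states for the tree stages (occurrence species -> tips)
  occ2tip <- setNames(mm$matched$tip, mm$matched$occurrence)
  mk_states_all <- states_from_presence(pm_shift, config$widespread)
  log_stage("states", "info",
            paste0("widespread=", config$widespread, " coded=",
                   length(mk_states_all)))
  mk_states <- setNames(mk_states_all, occ2tip[names(mk_states_all)])
  mk_states <- mk_states[!is.na(names(mk_states))]
  div_states_all <- states_from_presence(pm_div)
  div_states <- setNames(div_states_all, occ2tip[names(div_states_all)])
  div_states <- div_states[!is.na(names(div_states))]
  tree_shift <- ape::keep.tip(tree, intersect(tree$tip.label, names(mk_states)))
  mk_states <- mk_states[tree_shift$tip.label]
  write_tip_states(mk_states, file.path(out_dir, "states_shifts.tsv"))

  # --- clustering tests (one-vs-rest per region)
  seed_sig <- substream_seed(config$seed, "signal")
  sig <- tryCatch(
    clustering_by_region(tree_shift, mk_states,
                         n_reps = config$n_permutations, seed = seed_sig),
    error = function(e) fail("signal", e)
  )
  f_sig <- file.path(out_dir, "clustering.json")
  jsonlite::write_json(
    lapply(sig, function(s) list(
      PS = s$PS[c("observed", "null_mean", "null_band", "p")],
      AI = s$AI[c("observed", "null_mean", "null_band", "p")],
      MC = lapply(s$MC, function(m) m[c("observed", "null_mean", "null_band", "p")]),
      definitions = as.list(s$definitions)
    )),
    f_sig, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  stage_meta("signal", seed_sig, f_sig)
  log_stage("signal", "info", paste0("regions=", length(sig)))

  # --- range-shift rates
  seed_shift <- substream_seed(config$seed, "shift-rates")
  mk_fit <- tryCatch(fit_mk(tree_shift, mk_states, "ARD"),
                     error = function(e) fail("shift-rates", e))
  shifts <- relative_shift_rates(
    tree_shift, mk_states, mk_fit, n_maps = config$n_maps,
    bin_width = config$bin_width, denominator = config$denominator,
    seed = seed_shift
  )
  f_shifts <- write_tsv(as.data.frame(shifts),
                        file.path(out_dir, "shift_rates.tsv"))
  jsonlite::write_json(attr(shifts, "metadata"),
                       file.path(out_dir, "shift_rates_meta.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  stage_meta("shift_rates", seed_shift,
             c(f_shifts, file.path(out_dir, "shift_rates_meta.json")))
  log_stage("shift-rates", "info",
            paste0("n_maps=", config$n_maps, " bins=", config$bin_width))

  # --- per-clade MuSSE on the diversification filter states
  tree_div <- ape::keep.tip(tree, intersect(tree$tip.label, names(div_states)))
  div_states <- div_states[tree_div$tip.label]
  clade_tab <- if (is.null(clades)) {
    data.frame(tip_id = tree_div$tip.label, clade = "all",
               stringsAsFactors = FALSE)
  } else clades
  subtrees <- clade_subtrees(tree_div, clade_tab, min_tips = 10)
  frac_div <- compute_sampling_fractions(pm_div, tree$tip.label, clade_tab)
  by_clade <- attr(frac_div, "by_clade")
  rate_rows <- list()
  for (cl in names(subtrees)) {
    sub <- subtrees[[cl]]
    sts <- div_states[sub$tip.label]
    if (length(unique(sts)) < 2) {
      log_stage("musse", "warn", paste0("clade=", cl, " single state; skipped"))
      next
    }
    # clade-specific sampling fraction per state: species of the clade in
    # the tree over species coded present in the region
    obs <- sort(unique(sts))
    rho <- setNames(rep(1, length(obs)), obs)
    if (!is.null(by_clade)) {
      bc <- by_clade[by_clade$clade == cl, , drop = FALSE]
      for (s in obs) {
        fr <- bc$fraction_raw[bc$region == s]
        if (length(fr) == 1 && is.finite(fr) && fr > 0) rho[s] <- min(fr, 1)
      }
    }
    fit <- tryCatch(
      fit_musse(sub, sts, rho = rho, q_constraint = "equal",
                root_mode = config$root_mode, states = obs),
      error = function(e) fail("musse", e)
    )
    rate_rows[[cl]] <- data.frame(
      clade = cl, region = fit$params$states,
      lambda = unname(fit$params$lambda), mu = unname(fit$params$mu),
      loglik = fit$loglik, n_tips = ape::Ntip(sub),
      stringsAsFactors = FALSE
    )
    log_stage("musse", "info", paste0("clade=", cl, " tips=", ape::Ntip(sub),
                                      " loglik=", round(fit$loglik, 3)))
  }
  rates <- do.call(rbind, rate_rows)
  rownames(rates) <- NULL
  f_rates <- write_tsv(rates, file.path(out_dir, "musse_rates.tsv"))
  stage_meta("musse", NA, f_rates, list(root_mode = config$root_mode))

  # --- normalization and cross-region comparison
  comparison_ok <- FALSE
  norm <- normalize_rates(rates[, c("clade", "region", "lambda", "mu")])
  f_norm <- write_tsv(norm, file.path(out_dir, "normalized_rates.tsv"))
  files <- f_norm
  if (length(unique(norm$region)) >= 2 &&
      all(table(norm$region) >= 2)) {
    cmp <- compare_regions(norm)
    f_cmp <- file.path(out_dir, "rate_comparison.json")
    jsonlite::write_json(
      lapply(cmp[c("lambda", "mu")], function(x) {
        list(F = x$F, p = x$p, means = as.list(x$means), tukey = x$tukey)
      }),
      f_cmp, auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    files <- c(files, f_cmp)
    comparison_ok <- TRUE
  } else {
    log_stage("compare", "warn", "too few clades per region for ANOVA")
  }
  stage_meta("compare", NA, files, list(anova_run = comparison_ok))

  f_manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, f_manifest, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  log_stage("pipeline", "info", paste0("done out_dir=", out_dir))
  invisible(manifest)
}

#' Species and record counts per region and filter level
#'
#' An analog of a per-region data-reduction summary: for every region, the
#' number of species and of occurrence records under the raw coding
#' (>= 1 record), the subset matched to the phylogeny, and filters 1-3.
#'
#' @param labelled output of [assign_points_to_regions()].
#' @param tip_labels tree tip labels (for the "matched" column).
#' @return data frame `region`, `dataset`, `n_species`, `n_records`.
#' @export
summarize_counts <- function(labelled, tip_labels) {
  pm <- tabulate_presence(labelled)
  mm <- match_names(rownames(pm$counts), tip_labels)
  in_tree <- rownames(pm$counts) %in% mm$matched$occurrence
  datasets <- c("raw", "matched", "filter1", "filter2", "filter3")
  rows <- list()
  for (ds in datasets) {
    pres <- switch(ds,
      raw = apply_filter(pm, 0)$presence,
      matched = apply_filter(pm, 0)$presence & in_tree,
      filter1 = apply_filter(pm, 1)$presence,
      filter2 = apply_filter(pm, 2)$presence,
      filter3 = apply_filter(pm, 3)$presence
    )
    for (r in colnames(pm$counts)) {
      rows[[paste(ds, r)]] <- data.frame(
        region = r, dataset = ds,
        n_species = sum(pres[, r]),
        n_records = sum(pm$counts[pres[, r], r]),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write synthetic demo inputs and run the pipeline end-to-end
#'
#' Simulates a four-region state-dependent birth-death tree, generates a
#' contaminated occurrence table whose species home regions are the true
#' tip states, writes all input files, and runs [run_pipeline()] on them.
#'
#' @param out_dir run directory.
#' @param seed master seed.
#' @param n_taxa tree size cap for the simulated tree (default 150).
#' @param n_points clean occurrence points per species (default 12).
#' @param n_maps,n_permutations stage replicate counts (defaults 100).
#' @return invisibly, the run manifest.
#' @export
run_demo <- function(out_dir, seed = 1, n_taxa = 150, n_points = 12,
                     n_maps = 100, n_permutations = 100) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  in_dir <- file.path(out_dir, "inputs")
  dir.create(in_dir, showWarnings = FALSE)
  regions <- make_region_fixtures()
  rn <- names(regions$regions)

  cfg <- sim_config(
    lambda = c(0.22, 0.14, 0.14, 0.14), mu = rep(0.03, 4),
    q = 0.015, max_taxa = n_taxa, states = rn,
    seed = substream_seed(seed, "simulate")
  )
  sim <- simulate_surviving(cfg, min_tips = round(0.8 * n_taxa))
  f_tree <- file.path(in_dir, "tree.nwk")
  ape::write.tree(sim$tree, f_tree)

  ranges <- data.frame(
    species = paste0("Genus", sub("^t", "", names(sim$tip_states)), " ",
                     "sp", sub("^t", "", names(sim$tip_states))),
    region = unname(sim$tip_states),
    n_points = n_points, stringsAsFactors = FALSE
  )
  # tip labels use underscores; occurrence names use spaces (the matcher
  # canonicalizes both)
  sim$tree$tip.label <- gsub(" ", "_", ranges$species[
    match(sim$tree$tip.label, names(sim$tip_states))])
  ape::write.tree(sim$tree, f_tree)
  occ <- generate_occurrences(
    ranges, regions,
    error_rates = contamination_config(
      duplicate = 0.05, flagged = 0.02, missing_name = 0.01,
      nonnumeric = 0.01, zero_coord = 0.01, lat_eq_lon = 0.01, stray = 0.03
    ),
    seed = substream_seed(seed, "occurrences")
  )
  f_occ <- file.path(in_dir, "occurrences.csv")
  utils::write.csv(occ, f_occ, row.names = FALSE)
  f_reg <- file.path(in_dir, "regions.wkt")
  write_regions_wkt(regions, f_reg)
  clades <- clades_from_tree(sim$tree, n = 4)
  f_clades <- file.path(in_dir, "clades.tsv")
  write_tsv(clades, f_clades)

  config <- pipeline_config(
    tree = f_tree, occurrences = f_occ, regions = f_reg, clades = f_clades,
    n_maps = n_maps, n_permutations = n_permutations, seed = seed
  )
  run_pipeline(config, out_dir)
}
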