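# Cross-region rate normalization and comparison. Rates estimated per clade
# (one clade = one observation) are normalized within each clade by the sum
# over regions — removing intrinsic between-clade rate differences — and
# regions are compared by one-way ANOVA with Tukey HSD pairwise tests.

#' Normalize per-clade rates across regions
#'
#' Each rate is divided by the sum of that clade's rates over all regions,
#' separately for speciation and extinction, so normalized values within a
#' clade sum to 1 per rate type.
#'
#' @param rates data frame with columns `clade`, `region`, `lambda`, `mu`.
#' @return the table with `lambda` and `mu` replaced by normalized values;
#'   clades with a zero rate sum for either type are flagged in attribute
#'   `"excluded"` and dropped.
#' @export
normalize_rates <- function(rates) {
  need <- c("clade", "region", "lambda", "mu")
  if (!all(need %in% names(rates))) {
    stop("`rates` needs columns ", paste(need, collapse = ", "))
  }
  if (any(rates$lambda < 0) || any(rates$mu < 0)) stop("rates must be >= 0")
  excluded <- character(0)
  out <- rates
  for (cl in unique(rates$clade)) {
    i <- rates$clade == cl
    sl <- sum(rates$lambda[i]); sm <- sum(rates$mu[i])
    if (sl <= 0 || sm <= 0) {
      excluded <- c(excluded, cl)
      next
    }
    out$lambda[i] <- rates$lambda[i] / sl
    out$mu[i] <- rates$mu[i] / sm
  }
  out <- out[!out$clade %in% excluded, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Compare regions with ANOVA and Tukey HSD on normalized rates
#'
#' One-way ANOVA of the normalized rate across regions, treating clades as
#' observations, followed by Tukey honest-significant-difference pairwise
#' comparisons; run separately for speciation and extinction.
#'
#' @param normalized output of [normalize_rates()] (>= 2 regions and >= 2
#'   clades per region).
#' @return object of class `rate_comparison`: for each of `lambda` and `mu`,
#'   a list with `F`, `p`, `means` (per-region mean normalized rate), and
#'   `tukey` (data frame `comparison`, `diff`, `lwr`, `upr`, `p_adj`).
#' @export
compare_regions <- function(normalized) {
  regions <- unique(normalized$region)
  if (length(regions) < 2) stop("need >= 2 regions")
  per_region <- table(normalized$region)
  if (any(per_region < 2)) {
    stop("fewer than 2 clades in region: ",
         names(per_region)[which(per_region < 2)][1])
  }
  one <- function(value) {
    d <- data.frame(value = value, region = factor(normalized$region))
    fit <- aov(value ~ region, data = d)
    an <- summary(fit)[[1]]
    tk <- TukeyHSD(fit)$region
    list(
      F = an[["F value"]][1],
      p = an[["Pr(>F)"]][1],
      means = tapply(d$value, d$region, mean),
      tukey = data.frame(
        comparison = rownames(tk), diff = tk[, "diff"], lwr = tk[, "lwr"],
        upr = tk[, "upr"], p_adj = tk[, "p adj"], row.names = NULL,
        stringsAsFactors = FALSE
      )
    )
  }
  structure(list(lambda = one(normalized$lambda), mu = one(normalized$mu),
                 n_clades = length(unique(normalized$clade))),
            class = "rate_comparison")
}

#' @export
print.rate_comparison <- function(x, ...) {
  for (nm in c("lambda", "mu")) {
    cat(nm, ": F =", round(x[[nm]]$F, 4), ", p =", signif(x[[nm]]$p, 4), "\n")
    print(x[[nm]]$tukey[, c("comparison", "diff", "p_adj")])
  }
  invisible(x)
}

#' Extract crown subtrees for a clade table
#'
#' @param tree ultrametric `phylo`.
#' @param clades data frame (`tip_id`, `clade`).
#' @param min_tips clades with fewer tips are dropped with a message.
#' @return named list of `phylo` crown subtrees.
#' @export
clade_subtrees <- function(tree, clades, min_tips = 4) {
  tip2clade <- setNames(as.character(clades[[2]]), as.character(clades[[1]]))
  out <- list()
  for (cl in unique(tip2clade)) {
    tips <- intersect(names(tip2clade)[tip2clade == cl], tree$tip.label)
    if (length(tips) < min_tips) {
      message("clade ", cl, " has < ", min_tips, " tips in tree; skipped")
      next
    }
    out[[cl]] <- ape::keep.tip(tree, tips)
  }
  out
}

#' Derive a clade table by slicing the tree at a fixed lineage count
#'
#' Takes the `n` lineages crossing the earliest age at which at least `n`
#' lineages coexist and labels the tips of each crown subtree as one clade
#' (a synthetic stand-in for a named higher-taxon table).
#'
#' @param tree ultrametric `phylo`.
#' @param n target number of clades.
#' @return data frame (`tip_id`, `clade`).
#' @export
clades_from_tree <- function(tree, n = 4) {
  ages <- node_ages(tree)
  n_tip <- ape::Ntip(tree)
  node_age <- ages[(n_tip + 1L):(n_tip + tree$Nnode)]
  # slice just below the (n-1)-th oldest branching event
  cut_age <- sort(node_age, decreasing = TRUE)[min(n - 1, length(node_age))] - 1e-9
  spans <- branch_age_spans(tree)
  crossing <- which(spans$parent_age > cut_age & spans$child_age <= cut_age)
  out <- lapply(seq_along(crossing), function(i) {
    ch <- tree$edge[crossing[i], 2]
    tips <- if (ch <= n_tip) tree$tip.label[ch]
            else tree$tip.label[unlist(ape::prop.part(tree)[[ch - n_tip]])]
    data.frame(tip_id = tips, clade = paste0("clade", i),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
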