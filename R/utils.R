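# Shared helpers: age bookkeeping on chronograms, deterministic seed
# substreams, input checks. Ages are in Ma before present (present = 0,
# root = maximum age); branch lengths are in Myr throughout.

#' Node ages of a chronogram
#'
#' Ages are measured before present: tips of an ultrametric tree sit at
#' (numerically) 0 Ma and the root at the tree height.
#'
#' @param tree an ultrametric `phylo` object with branch lengths in Myr.
#' @return numeric vector of ages (Ma) indexed by node number
#'   (tips `1..n`, then internal nodes).
#' @export
node_ages <- function(tree) {
  depths <- ape::node.depth.edgelength(tree)
  ages <- max(depths) - depths
  # clamp round-off near the present (1e-6 Myr ~ 1 year)
  ages[abs(ages) < 1e-6] <- 0
  ages
}

#' Age span of every branch
#'
#' @param tree a `phylo` object.
#' @return data frame with one row per edge: `edge`, `parent_age`,
#'   `child_age` (Ma; `parent_age > child_age`).
#' @export
branch_age_spans <- function(tree) {
  ages <- node_ages(tree)
  data.frame(
    edge = seq_len(nrow(tree$edge)),
    parent_age = ages[tree$edge[, 1]],
    child_age = ages[tree$edge[, 2]]
  )
}

#' Check that a tree is ultrametric to a stated tolerance (in Myr)
#' @param tree a `phylo` object.
#' @param tol tolerance in Myr.
#' @return logical.
#' @export
is_ultrametric_chronogram <- function(tree, tol = 1e-6) {
  depths <- ape::node.depth.edgelength(tree)
  tip_depths <- depths[seq_len(ape::Ntip(tree))]
  diff(range(tip_depths)) <= tol
}

assert_chronogram <- function(tree, tol = 1e-6) {
  if (!inherits(tree, "phylo")) stop("`tree` must be a `phylo` object")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (!is_ultrametric_chronogram(tree, tol)) {
    stop("tree is not ultrametric within tolerance ", tol, " Myr")
  }
  invisible(tree)
}

#' Derive a reproducible sub-seed for a named stage
#'
#' One master seed drives a whole run; every stage draws its randomness from
#' a deterministic substream so stages can be re-run independently.
#'
#' @param seed master seed (integer).
#' @param label stage name (character scalar).
#' @return integer in `[1, 2^31 - 2]`.
#' @export
substream_seed <- function(seed, label) {
  m <- 2147483647 # 2^31 - 1, Mersenne prime (Lehmer modulus)
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% m
  as.integer((abs(as.numeric(seed)) %% m * 48271 + h) %% (m - 1) + 1)
}

# extract tip states as a character vector aligned to tree$tip.label,
# accepting a named vector or a 2-column data frame (tip_id, state)
align_tip_states <- function(tree, tip_states) {
  if (is.data.frame(tip_states)) {
    if (ncol(tip_states) < 2) stop("tip-state table needs 2 columns (tip_id, state)")
    x <- setNames(as.character(tip_states[[2]]), as.character(tip_states[[1]]))
  } else {
    x <- setNames(as.character(tip_states), names(tip_states))
  }
  if (is.null(names(x))) {
    if (length(x) != ape::Ntip(tree)) stop("unnamed tip states of wrong length")
    names(x) <- tree$tip.label
  }
  missing <- setdiff(tree$tip.label, names(x))
  if (length(missing) > 0) {
    stop("no state for tips: ", paste(head(missing, 5), collapse = ", "))
  }
  x[tree$tip.label]
}

#' Read a two-column tip-state TSV (tip_id, state)
#' @param path file path.
#' @return named character vector of states.
#' @export
read_tip_states <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  setNames(as.character(d[[2]]), as.character(d[[1]]))
}

#' Write a tip-state table as TSV
#' @param states named character vector.
#' @param path file path.
#' @export
write_tip_states <- function(states, path) {
  write.table(
    data.frame(tip_id = names(states), state = unname(states)),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
}

# stationary distribution of a CTMC rate matrix; uniform when Q has no
# information (all zero rows)
stationary_distribution <- function(Q) {
  k <- nrow(Q)
  if (k == 1L || all(abs(Q) < 1e-14)) return(rep(1 / k, k))
  A <- rbind(t(Q), rep(1, k))
  b <- c(rep(0, k), 1)
  pi <- tryCatch(qr.solve(A, b), error = function(e) rep(1 / k, k))
  pi[pi < 0] <- 0
  if (sum(pi) <= 0) return(rep(1 / k, k))
  pi / sum(pi)
}

validate_rate_matrix <- function(q, n_states) {
  q <- as.matrix(q)
  if (nrow(q) != n_states || ncol(q) != n_states) {
    stop("transition-rate matrix must be ", n_states, " x ", n_states)
  }
  off <- q
  diag(off) <- 0
  if (any(!is.finite(q)) || any(off < 0)) {
    stop("off-diagonal transition rates must be finite and >= 0")
  }
  if (any(abs(rowSums(q)) > 1e-8)) stop("rows of the rate matrix must sum to 0")
  q
}
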