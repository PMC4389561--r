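# Stochastic character mapping and the binned relative range-shift-rate
# statistic. Node states are sampled from their joint conditional
# distribution (pruning partials, root-to-tips), branch histories are drawn
# conditional on endpoint states by uniformization (dominating rate
# Lambda = max_i |Q_ii|), and mapped transitions are tallied into age bins
# and divided by a lineage-availability denominator.

#' Sample one stochastic character map
#'
#' @param tree ultrametric `phylo`.
#' @param tip_states named character vector or 2-column data frame.
#' @param model an [mk_model()] with finite rates.
#' @param seed integer seed (`NULL` leaves the RNG stream untouched).
#' @return object of class `c("stochastic_map", "branch_history")`: `events`
#'   (data frame `edge`, `age`, `from`, `to`, edges indexed as in `tree`),
#'   `node_states`, `root_state`, `states`.
#' @export
sample_stochastic_map <- function(tree, tip_states, model, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sv <- align_tip_states(tree, tip_states)
  pre <- simmap_precompute(tree, sv, model)
  draw_stochastic_map(pre)
}

# everything reusable across replicate maps: pruning partials, per-edge
# transition matrices, age spans, uniformization pieces
simmap_precompute <- function(tree, states_vec, model) {
  pr <- mk_pruning(tree, states_vec, model)
  po <- pr$postorder
  ages <- node_ages(tree)
  k <- length(model$states)
  Lam <- max(-diag(model$Q))
  Rmat <- if (Lam > 0) diag(k) + model$Q / Lam else diag(k)
  pow_env <- new.env()
  pow_env$pows <- list(diag(k)) # pows[[n + 1]] = Rmat^n
  # map postorder edge rows to the input tree's edge indices
  key <- function(m) paste(m[, 1], m[, 2])
  edge_map <- match(key(po$edge), key(tree$edge))
  list(tree = tree, model = model, partials = pr$partials, po = po,
       P = pr$P, ages = ages, Lam = Lam, Rmat = Rmat, pow_env = pow_env,
       edge_map = edge_map, states_vec = states_vec)
}

rpow <- function(pre, n) {
  pows <- pre$pow_env$pows
  while (length(pows) < n + 1L) {
    pows[[length(pows) + 1L]] <- pows[[length(pows)]] %*% pre$Rmat
  }
  pre$pow_env$pows <- pows
  pows[[n + 1L]]
}

draw_stochastic_map <- function(pre) {
  tree <- pre$tree
  model <- pre$model
  k <- length(model$states)
  n_tip <- ape::Ntip(tree)
  root <- n_tip + 1L
  s <- integer(n_tip + tree$Nnode)

  prior <- root_prior_vector(model, pre$partials[root, ])
  w <- prior * pre$partials[root, ]
  s[root] <- sample.int(k, 1, prob = w)

  po <- pre$po
  for (e in rev(seq_len(nrow(po$edge)))) {
    par <- po$edge[e, 1]; ch <- po$edge[e, 2]
    w <- pre$P[[e]][s[par], ] * pre$partials[ch, ]
    if (sum(w) <= 0) {
      stop("zero-probability endpoint pair on branch ", pre$edge_map[e])
    }
    s[ch] <- sample.int(k, 1, prob = w)
  }

  ev_edge <- integer(0); ev_age <- numeric(0)
  ev_from <- integer(0); ev_to <- integer(0)
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1]; ch <- po$edge[e, 2]
    len <- po$edge.length[e]
    path <- sample_bridge(pre, e, s[par], s[ch], len)
    if (length(path$times) > 0) {
      ev_edge <- c(ev_edge, rep(pre$edge_map[e], length(path$times)))
      ev_age <- c(ev_age, pre$ages[par] - path$times)
      ev_from <- c(ev_from, path$from)
      ev_to <- c(ev_to, path$to)
    }
  }
  events <- data.frame(
    edge = ev_edge, age = ev_age,
    from = model$states[ev_from], to = model$states[ev_to],
    stringsAsFactors = FALSE
  )
  o <- order(events$edge, -events$age)
  events <- events[o, , drop = FALSE]
  rownames(events) <- NULL
  structure(
    list(events = events, node_states = setNames(model$states[s],
                                                 c(tree$tip.label,
                                                   rep("", tree$Nnode))),
         root_state = model$states[s[root]], states = model$states),
    class = c("stochastic_map", "branch_history")
  )
}

# uniformization bridge: CTMC path on a branch of length `len` conditional
# on endpoint states a -> b; returns times (from the parent end) and the
# from/to state indices of the real (non-virtual) transitions
sample_bridge <- function(pre, e, a, b, len) {
  none <- list(times = numeric(0), from = integer(0), to = integer(0))
  if (pre$Lam <= 0 || len <= 0) return(none)
  p_ab <- pre$P[[e]][a, b]
  if (p_ab <= 0) stop("zero-probability endpoint pair on branch ", pre$edge_map[e])
  lt <- pre$Lam * len
  # number of uniformized (possibly virtual) jumps
  u <- runif(1)
  n <- -1L
  cum <- 0
  repeat {
    n <- n + 1L
    term <- dpois(n, lt) * rpow(pre, n)[a, b] / p_ab
    cum <- cum + term
    if (cum >= u || (n > 10 * lt + 100 && term < 1e-14)) break
    if (n > 100000L) stop("uniformization failed to converge on branch ",
                          pre$edge_map[e])
  }
  if (n == 0L) return(none)
  # bridge states
  path <- integer(n + 1L)
  path[1] <- a; path[n + 1L] <- b
  if (n > 1L) {
    for (m in seq_len(n - 1L)) {
      w <- pre$Rmat[path[m], ] * rpow(pre, n - m)[, b]
      path[m + 1L] <- sample.int(length(w), 1, prob = w)
    }
  }
  times <- sort(runif(n)) * len
  real <- which(path[-1] != path[-(n + 1L)])
  list(times = times[real], from = path[real], to = path[real + 1L])
}

#' Per-branch state segments implied by a history
#'
#' Propagates the root state through the recorded events to give, for every
#' branch, its ordered constant-state segments (ages in Ma). Consecutive
#' segments agree at shared endpoints by construction; a mismatch between an
#' event's `from` state and the running state is an error.
#'
#' @param tree the `phylo` the history refers to.
#' @param history a `branch_history` (true or mapped).
#' @return data frame `edge`, `age_start`, `age_end`, `state`
#'   (`age_start > age_end`, oldest first within a branch).
#' @export
history_segments <- function(tree, history) {
  ages <- node_ages(tree)
  n_node <- ape::Ntip(tree) + tree$Nnode
  state_at <- rep(NA_character_, n_node)
  state_at[ape::Ntip(tree) + 1L] <- history$root_state
  pre_order <- ape::reorder.phylo(tree, "cladewise")
  ev <- history$events
  out <- vector("list", nrow(pre_order$edge))
  key <- function(m) paste(m[, 1], m[, 2])
  edge_map <- match(key(pre_order$edge), key(tree$edge))
  for (e in seq_len(nrow(pre_order$edge))) {
    par <- pre_order$edge[e, 1]; ch <- pre_order$edge[e, 2]
    eid <- edge_map[e]
    cur <- state_at[par]
    sub <- ev[ev$edge == eid, , drop = FALSE]
    sub <- sub[order(-sub$age), , drop = FALSE]
    starts <- c(ages[par], sub$age)
    ends <- c(sub$age, ages[ch])
    segs <- c(cur, sub$to)
    if (nrow(sub) > 0 && !all(sub$from == c(cur, sub$to[-nrow(sub)]))) {
      stop("inconsistent event chain on edge ", eid)
    }
    out[[e]] <- data.frame(edge = eid, age_start = starts, age_end = ends,
                           state = segs, stringsAsFactors = FALSE)
    state_at[ch] <- segs[length(segs)]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Count mapped transitions per age bin
#'
#' @param history a `branch_history`.
#' @param bins numeric vector of bin edges in Ma, ascending (bins are
#'   `[e_i, e_{i+1})`; the oldest bin is closed on the right).
#' @param from,to optional state subsets selecting a direction or an
#'   aggregate direction (e.g. several tropical source states); `NULL`
#'   means any.
#' @return integer vector of counts, one per bin.
#' @export
count_transitions <- function(history, bins, from = NULL, to = NULL) {
  ev <- history$events
  if (!is.null(from)) ev <- ev[ev$from %in% from, , drop = FALSE]
  if (!is.null(to)) ev <- ev[ev$to %in% to, , drop = FALSE]
  counts <- integer(length(bins) - 1L)
  if (nrow(ev) == 0) return(counts)
  if (any(ev$age < bins[1]) || any(ev$age > bins[length(bins)])) {
    stop("event age outside the bin range; inconsistent age axis")
  }
  i <- findInterval(ev$age, bins, rightmost.closed = TRUE)
  tab <- tabulate(i, nbins = length(counts))
  as.integer(tab)
}

#' Lineages available in an age bin
#'
#' Default `"branches"` definition: the number of branches whose age span
#' intersects the bin's interior — the lineages alive during the bin.
#' Alternative `"nodes"`: the number of branching events (internal nodes)
#' with age inside the bin.
#'
#' @param tree ultrametric `phylo`.
#' @param bin numeric length-2 vector `c(young_edge, old_edge)` in Ma.
#' @param definition `"branches"` or `"nodes"`.
#' @return integer count.
#' @export
lineages_in_bin <- function(tree, bin, definition = c("branches", "nodes")) {
  definition <- match.arg(definition)
  lo <- min(bin); hi <- max(bin)
  ages <- node_ages(tree)
  if (definition == "branches") {
    spans <- branch_age_spans(tree)
    sum(spans$child_age < hi & spans$parent_age > lo)
  } else {
    node_a <- ages[(ape::Ntip(tree) + 1L):(ape::Ntip(tree) + tree$Nnode)]
    sum(node_a >= lo & node_a < hi)
  }
}

#' Binned relative range-shift rates from replicate stochastic maps
#'
#' Draws `n_maps` stochastic histories, counts directional transitions per
#' age bin, divides by the per-bin lineage-availability denominator, and
#' summarizes across replicates with the mean and the empirical 2.5-97.5
#' percentile band. Bins are anchored at the present (0-5, 5-10, ... Ma by
#' default); the oldest bin is truncated at the root age and its actual
#' width recorded in the metadata.
#'
#' @param tree ultrametric `phylo`.
#' @param tip_states named character vector or 2-column data frame.
#' @param model an [mk_model()].
#' @param n_maps number of replicate maps (>= 2; default 100).
#' @param bin_width bin width in Myr (default 5).
#' @param directions named list of directions, each `list(from=, to=)` with
#'   state subsets; default: every ordered pair of model states, named
#'   `"A->B"`.
#' @param denominator `"branches"` (default) or `"nodes"`.
#' @param seed integer seed.
#' @return data frame of class `binned_shift_rates`: `direction`,
#'   `bin_start`, `bin_end`, `mean`, `lo95`, `hi95`, `denominator` (bins
#'   with zero denominator have `NA` rates); attribute `"metadata"` records
#'   the denominator definition, replicate count and oldest-bin width.
#' @export
relative_shift_rates <- function(tree, tip_states, model, n_maps = 100,
                                 bin_width = 5, directions = NULL,
                                 denominator = c("branches", "nodes"),
                                 seed = NULL) {
  denominator <- match.arg(denominator)
  if (n_maps < 2) stop("`n_maps` must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  sv <- align_tip_states(tree, tip_states)
  pre <- simmap_precompute(tree, sv, model)
  root_age <- max(node_ages(tree))
  n_bins <- max(1L, ceiling(root_age / bin_width - 1e-9))
  edges <- c(seq(0, by = bin_width, length.out = n_bins), root_age)
  if (is.null(directions)) {
    st <- model$states
    directions <- list()
    for (a in st) for (b in st) {
      if (a != b) directions[[paste0(a, "->", b)]] <- list(from = a, to = b)
    }
  }
  denom <- vapply(seq_len(n_bins), function(i) {
    lineages_in_bin(tree, c(edges[i], edges[i + 1]), denominator)
  }, 1L)

  arr <- array(NA_real_, dim = c(n_maps, length(directions), n_bins))
  for (r in seq_len(n_maps)) {
    h <- draw_stochastic_map(pre)
    for (d in seq_along(directions)) {
      cnt <- count_transitions(h, edges, from = directions[[d]]$from,
                               to = directions[[d]]$to)
      arr[r, d, ] <- ifelse(denom > 0, cnt / denom, NA_real_)
    }
  }
  summ <- function(v, f) if (anyNA(v)) NA_real_ else f(v)
  rows <- list()
  for (d in seq_along(directions)) {
    m <- arr[, d, , drop = FALSE]
    rows[[d]] <- data.frame(
      direction = names(directions)[d],
      bin_start = edges[-length(edges)],
      bin_end = edges[-1],
      mean = apply(m, 3, summ, mean),
      lo95 = apply(m, 3, summ,
                   function(v) quantile(v, 0.025, names = FALSE)),
      hi95 = apply(m, 3, summ,
                   function(v) quantile(v, 0.975, names = FALSE)),
      denominator = denom,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "metadata") <- list(
    denominator_definition = denominator, n_maps = n_maps,
    bin_width = bin_width, oldest_bin_width = edges[length(edges)] -
      edges[length(edges) - 1L],
    bins_anchored_at = 0
  )
  class(out) <- c("binned_shift_rates", "data.frame")
  out
}
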