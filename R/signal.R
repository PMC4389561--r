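# Phylogenetic clustering of tip states: parsimony score (Fitch/Sankoff
# count), association index, and maximum exclusive single-state clade size,
# with tip-permutation null distributions and add-one p-values.

# postorder list of children per internal node (handles polytomies)
children_list <- function(tree) {
  n_tip <- ape::Ntip(tree)
  ch <- vector("list", n_tip + tree$Nnode)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]
    ch[[p]] <- c(ch[[p]], tree$edge[e, 2])
  }
  ch
}

postorder_nodes <- function(tree) {
  po <- ape::reorder.phylo(tree, "postorder")
  unique(po$edge[, 1])
}

#' Minimum number of state changes (parsimony score)
#'
#' Small-parsimony minimum over all internal-node state assignments, by
#' dynamic programming with unit change costs (Sankoff; equals the Fitch
#' count on binary trees and handles polytomies).
#'
#' @param tree a `phylo`.
#' @param tip_states named character vector or 2-column data frame.
#' @return integer minimum change count.
#' @export
parsimony_score <- function(tree, tip_states) {
  sv <- align_tip_states(tree, tip_states)
  states <- sort(unique(sv))
  k <- length(states)
  if (k == 1L) return(0L)
  n_tip <- ape::Ntip(tree)
  cost <- matrix(Inf, n_tip + tree$Nnode, k)
  cost[cbind(seq_len(n_tip), match(sv, states))] <- 0
  ch <- children_list(tree)
  for (nd in postorder_nodes(tree)) {
    acc <- numeric(k)
    for (c_nd in ch[[nd]]) {
      # min over child state of (child cost + 1[change])
      m <- min(cost[c_nd, ])
      acc <- acc + pmin(cost[c_nd, ], m + 1)
    }
    cost[nd, ] <- acc
  }
  as.integer(min(cost[n_tip + 1L, ]))
}

#' Association index
#'
#' Sum over internal nodes of `(1 - f) / 2^(n - 1)`, where `n` is the
#' number of descendant tips and `f` the frequency of the most common state
#' among them. Zero for perfectly clustered states; larger values mean less
#' clustering.
#'
#' @inheritParams parsimony_score
#' @return numeric index (>= 0).
#' @export
association_index <- function(tree, tip_states) {
  sv <- align_tip_states(tree, tip_states)
  states <- sort(unique(sv))
  n_tip <- ape::Ntip(tree)
  # per-node counts of descendant tips in each state
  cnt <- matrix(0, n_tip + tree$Nnode, length(states))
  cnt[cbind(seq_len(n_tip), match(sv, states))] <- 1
  ch <- children_list(tree)
  ai <- 0
  for (nd in postorder_nodes(tree)) {
    for (c_nd in ch[[nd]]) cnt[nd, ] <- cnt[nd, ] + cnt[c_nd, ]
    n_desc <- sum(cnt[nd, ])
    f <- max(cnt[nd, ]) / n_desc
    ai <- ai + (1 - f) / 2^(n_desc - 1)
  }
  ai
}

#' Maximum exclusive single-state clade size
#'
#' Tip count of the largest clade (including single tips) whose descendant
#' tips all carry the given state.
#'
#' @inheritParams parsimony_score
#' @param state the state of interest (must be observed at >= 1 tip).
#' @return integer clade size.
#' @export
max_state_clade <- function(tree, tip_states, state) {
  sv <- align_tip_states(tree, tip_states)
  if (!state %in% sv) stop("state not observed at any tip: ", state)
  n_tip <- ape::Ntip(tree)
  in_state <- as.numeric(sv == state)
  n_in <- c(in_state, numeric(tree$Nnode)) # tips in `state` below each node
  n_all <- c(rep(1, n_tip), numeric(tree$Nnode))
  ch <- children_list(tree)
  for (nd in postorder_nodes(tree)) {
    for (c_nd in ch[[nd]]) {
      n_in[nd] <- n_in[nd] + n_in[c_nd]
      n_all[nd] <- n_all[nd] + n_all[c_nd]
    }
  }
  pure <- n_in == n_all & n_in > 0
  as.integer(max(n_in[pure]))
}

#' Tip-permutation test of phylogenetic clustering
#'
#' Permutes tip states uniformly `n_reps` times and compares the observed
#' parsimony score (PS), association index (AI) and per-state maximum
#' exclusive single-state clade size (MC) against the permutation null.
#' p-values use the add-one formula `p = (1 + m) / (1 + n_reps)`, where `m`
#' counts null replicates at least as clustered as the observation
#' (<= observed for PS and AI, >= observed for MC).
#'
#' @inheritParams parsimony_score
#' @param n_reps number of permutations (>= 19; default 100).
#' @param seed integer seed.
#' @return object of class `clustering_stats`: per statistic the observed
#'   value, null mean, 2.5-97.5 percentile null band and p-value (MC entries
#'   are per state). Metadata records the statistic definitions.
#' @export
permutation_test <- function(tree, tip_states, n_reps = 100, seed = NULL) {
  if (n_reps < 19) stop("`n_reps` must be >= 19")
  if (!is.null(seed)) set.seed(seed)
  sv <- align_tip_states(tree, tip_states)
  states <- sort(unique(sv))

  obs <- list(
    PS = parsimony_score(tree, sv),
    AI = association_index(tree, sv),
    MC = vapply(states, function(s) max_state_clade(tree, sv, s), 1L)
  )
  null_ps <- integer(n_reps)
  null_ai <- numeric(n_reps)
  null_mc <- matrix(0L, n_reps, length(states),
                    dimnames = list(NULL, states))
  for (r in seq_len(n_reps)) {
    perm <- setNames(sample(sv), names(sv))
    null_ps[r] <- parsimony_score(tree, perm)
    null_ai[r] <- association_index(tree, perm)
    null_mc[r, ] <- vapply(states, function(s) max_state_clade(tree, perm, s), 1L)
  }
  band <- function(x) quantile(x, c(0.025, 0.975), names = FALSE)
  addone <- function(m) (1 + m) / (1 + n_reps)
  res <- list(
    PS = list(observed = obs$PS, null_mean = mean(null_ps),
              null_band = band(null_ps), p = addone(sum(null_ps <= obs$PS)),
              null = null_ps),
    AI = list(observed = obs$AI, null_mean = mean(null_ai),
              null_band = band(null_ai), p = addone(sum(null_ai <= obs$AI)),
              null = null_ai),
    MC = lapply(setNames(states, states), function(s) {
      list(observed = obs$MC[[s]], null_mean = mean(null_mc[, s]),
           null_band = band(null_mc[, s]),
           p = addone(sum(null_mc[, s] >= obs$MC[[s]])),
           null = null_mc[, s])
    }),
    n_reps = n_reps,
    definitions = c(
      PS = "minimum state changes (Fitch/Sankoff, unit costs)",
      AI = "sum over internal nodes of (1 - f_node)/2^(n_node - 1)",
      MC = "largest clade with all descendant tips in the state"
    )
  )
  class(res) <- "clustering_stats"
  res
}

#' @export
print.clustering_stats <- function(x, ...) {
  cat(sprintf("PS: observed %d, null mean %.2f, p = %.4g\n",
              x$PS$observed, x$PS$null_mean, x$PS$p))
  cat(sprintf("AI: observed %.4f, null mean %.4f, p = %.4g\n",
              x$AI$observed, x$AI$null_mean, x$AI$p))
  for (s in names(x$MC)) {
    cat(sprintf("MC[%s]: observed %d, null mean %.2f, p = %.4g\n",
                s, x$MC[[s]]$observed, x$MC[[s]]$null_mean, x$MC[[s]]$p))
  }
  invisible(x)
}

#' One-vs-rest clustering tests per region
#'
#' Recodes the tip states as `state` vs `"other"` for each region in turn
#' and runs [permutation_test()] — the default reporting mode for
#' region-wise clustering.
#'
#' @inheritParams permutation_test
#' @return named list of `clustering_stats`, one per observed state.
#' @export
clustering_by_region <- function(tree, tip_states, n_reps = 100, seed = NULL) {
  sv <- align_tip_states(tree, tip_states)
  states <- sort(unique(sv))
  seeds <- if (is.null(seed)) rep(list(NULL), length(states))
           else lapply(states, function(s) substream_seed(seed, s))
  out <- lapply(seq_along(states), function(i) {
    s <- states[i]
    binary <- setNames(ifelse(sv == s, s, "other"), names(sv))
    permutation_test(tree, binary, n_reps = n_reps, seed = seeds[[i]])
  })
  names(out) <- states
  out
}
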