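# State-dependent birth-death simulation (Gillespie) with full recording of
# the true character history on surviving branches. The simulator is the
# ground-truth generator for validating stochastic mapping and the MuSSE
# fits: trees are grown forward in time under per-state speciation and
# extinction rates and a CTMC of state transitions, extinct lineages are
# pruned, and every transition on a surviving branch is kept with its age.

#' Configuration for a state-dependent birth-death simulation
#'
#' @param lambda per-state speciation rates (events/lineage/Myr).
#' @param mu per-state extinction rates.
#' @param q k x k instantaneous transition-rate matrix (off-diagonal >= 0,
#'   rows summing to 0). A scalar is expanded to a symmetric matrix with that
#'   off-diagonal rate.
#' @param max_time maximum simulation time in Myr (or `NULL`).
#' @param max_taxa cap on the number of coexisting lineages; growth is
#'   truncated when the cap is reached (or `NULL`).
#' @param states optional state names (default `"1".."k"`).
#' @param root_state state at the root lineage; default `NULL` draws from the
#'   stationary distribution of `q`.
#' @param seed integer seed.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(lambda, mu, q, max_time = NULL, max_taxa = NULL,
                       states = NULL, root_state = NULL, seed = NULL) {
  k <- length(lambda)
  if (k < 1) stop("need at least one state")
  if (length(mu) != k) stop("`lambda` and `mu` must have equal length")
  if (any(!is.finite(lambda)) || any(lambda < 0) ||
      any(!is.finite(mu)) || any(mu < 0)) {
    stop("speciation and extinction rates must be finite and >= 0")
  }
  if (length(q) == 1L) {
    q <- matrix(q, k, k)
    diag(q) <- 0
    diag(q) <- -rowSums(q)
  }
  q <- validate_rate_matrix(q, k)
  if (is.null(max_time) && is.null(max_taxa)) {
    stop("at least one of `max_time`/`max_taxa` must be set")
  }
  if (!is.null(max_time) && max_time <= 0) stop("`max_time` must be > 0")
  if (!is.null(max_taxa) && max_taxa < 2) stop("`max_taxa` must be >= 2")
  if (is.null(states)) states <- as.character(seq_len(k))
  if (length(states) != k || anyDuplicated(states)) {
    stop("`states` must be ", k, " unique names")
  }
  if (!is.null(root_state)) {
    root_state <- as.character(root_state)
    if (!root_state %in% states) stop("unknown `root_state`")
  }
  structure(
    list(lambda = lambda, mu = mu, q = q, max_time = max_time,
         max_taxa = max_taxa, states = states, root_state = root_state,
         seed = seed),
    class = "sim_config"
  )
}

extinct_replicate <- function(n_survivors) {
  structure(
    class = c("geoshift_extinct", "error", "condition"),
    list(message = sprintf(
      "extinct replicate: %d surviving lineage(s), need >= 2", n_survivors),
      call = NULL, n_survivors = n_survivors)
  )
}

#' Simulate a state-dependent birth-death tree with its true history
#'
#' Forward Gillespie simulation from a single root lineage. Extinct lineages
#' are pruned, unifurcations suppressed (branch lengths and events merged),
#' and the surviving tree returned as an ultrametric chronogram with ages in
#' Ma before present. Every state transition on a surviving branch is
#' recorded in the returned history; transitions on the root stem (above the
#' crown node) are absorbed into the crown root state.
#'
#' @param config a [sim_config()].
#' @return a list with elements `tree` (`phylo`), `history` (class
#'   `branch_history`: events `(edge, age, from, to)` plus the crown root
#'   state), and `tip_states` (named character vector).
#'   Signals a classed condition `geoshift_extinct` if fewer than 2 lineages
#'   survive (callers retry).
#' @export
simulate_musse_tree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  k <- length(config$lambda)
  qout <- -diag(config$q)
  if (k == 1L) qout <- 0

  root_state <- if (is.null(config$root_state)) {
    sample.int(k, 1, prob = stationary_distribution(config$q))
  } else {
    match(config$root_state, config$states)
  }

  # per-lineage records (grown geometrically)
  cap <- 256L
  parent <- integer(cap); birth <- numeric(cap); death <- numeric(cap)
  fate <- integer(cap) # 0 alive, 1 speciation, 2 extinction
  state <- integer(cap)
  n_lin <- 1L
  parent[1] <- 0L; birth[1] <- 0; death[1] <- NA_real_
  fate[1] <- 0L; state[1] <- root_state

  grow <- function() {
    cap2 <- cap * 2L
    length(parent) <<- cap2; length(birth) <<- cap2
    length(death) <<- cap2; length(fate) <<- cap2; length(state) <<- cap2
    cap <<- cap2
  }

  ev_lin <- integer(0); ev_time <- numeric(0)
  ev_from <- integer(0); ev_to <- integer(0)

  alive <- 1L
  t <- 0
  n_events <- 0L
  repeat {
    rates <- config$lambda[state[alive]] + config$mu[state[alive]] +
      qout[state[alive]]
    total <- sum(rates)
    if (total <= 0) {
      t_end <- if (!is.null(config$max_time)) config$max_time else t
      break
    }
    dt <- rexp(1, total)
    if (!is.null(config$max_time) && t + dt >= config$max_time) {
      t_end <- config$max_time
      break
    }
    t <- t + dt
    n_events <- n_events + 1L
    if (n_events > 2e6) stop("simulation exceeded 2e6 events; set `max_taxa`")
    i <- alive[sample.int(length(alive), 1, prob = rates)]
    s <- state[i]
    u <- runif(1) * (config$lambda[s] + config$mu[s] + qout[s])
    if (u < config$lambda[s]) {
      # speciation: lineage i ends, two daughters inherit its state
      fate[i] <- 1L; death[i] <- t
      while (n_lin + 2L > cap) grow()
      c1 <- n_lin + 1L; c2 <- n_lin + 2L; n_lin <- n_lin + 2L
      parent[c(c1, c2)] <- i; birth[c(c1, c2)] <- t
      death[c(c1, c2)] <- NA_real_; fate[c(c1, c2)] <- 0L
      state[c(c1, c2)] <- s
      alive <- c(setdiff(alive, i), c1, c2)
      if (!is.null(config$max_taxa) && length(alive) >= config$max_taxa) {
        t_end <- t
        break
      }
    } else if (u < config$lambda[s] + config$mu[s]) {
      fate[i] <- 2L; death[i] <- t
      alive <- setdiff(alive, i)
      if (length(alive) == 0L) stop(extinct_replicate(0L))
    } else {
      # state transition
      w <- config$q[s, ]; w[s] <- 0
      s2 <- sample.int(k, 1, prob = w)
      ev_lin <- c(ev_lin, i); ev_time <- c(ev_time, t)
      ev_from <- c(ev_from, s); ev_to <- c(ev_to, s2)
      state[i] <- s2
    }
  }

  if (length(alive) < 2L) stop(extinct_replicate(length(alive)))

  build_pruned_tree(
    n_lin = n_lin, parent = parent, birth = birth, death = death,
    fate = fate, state = state, alive = alive, t_end = t_end,
    ev_lin = ev_lin, ev_time = ev_time, ev_from = ev_from, ev_to = ev_to,
    state_names = config$states
  )
}

# prune extinct lineages, suppress unifurcations, and assemble a phylo
# object plus the per-edge event history (ages in Ma before present)
build_pruned_tree <- function(n_lin, parent, birth, death, fate, state,
                              alive, t_end, ev_lin, ev_time, ev_from, ev_to,
                              state_names) {
  kept <- logical(n_lin)
  for (i in alive) {
    j <- i
    while (j > 0L && !kept[j]) {
      kept[j] <- TRUE
      j <- parent[j]
    }
  }
  children <- vector("list", n_lin)
  for (j in seq_len(n_lin)) {
    p <- parent[j]
    if (p > 0L && kept[j] && kept[p]) children[[p]] <- c(children[[p]], j)
  }

  events_by_lin <- split(seq_along(ev_lin), ev_lin)

  # descend from the root to the crown lineage (first with 2 kept children)
  cr <- 1L
  while (length(children[[cr]]) == 1L) cr <- children[[cr]]
  if (length(children[[cr]]) != 2L) stop(extinct_replicate(length(alive)))
  # crown root state: state of the crown lineage at its speciation
  root_state <- state[cr]

  env <- new.env()
  env$tips <- character(0)
  env$tip_state <- integer(0)
  env$rows <- list() # list of (start lineage, terminal time, terminal kind, children start lineages)

  # walk a chain of single-kept-child lineages starting at `start`;
  # returns list(kind, term_time, lineages, tip_label/children)
  walk_chain <- function(start) {
    lin <- start
    chain <- start
    repeat {
      kc <- children[[lin]]
      if (fate[lin] == 0L) {
        return(list(kind = "tip", term = t_end, chain = chain, lineage = lin))
      }
      if (length(kc) == 2L) {
        return(list(kind = "node", term = death[lin], chain = chain,
                    kids = kc))
      }
      lin <- kc
      chain <- c(chain, lin)
    }
  }

  # first pass: recursive structure
  build <- function(start) {
    ch <- walk_chain(start)
    ev_idx <- unlist(events_by_lin[as.character(ch$chain)], use.names = FALSE)
    node <- list(
      length = ch$term - birth[start],
      events = ev_idx,
      kind = ch$kind
    )
    if (ch$kind == "tip") {
      node$label <- paste0("t", ch$lineage)
      node$state <- state[ch$lineage]
    } else {
      node$children <- lapply(ch$kids, build)
    }
    node
  }
  crown_kids <- children[[cr]]
  root <- list(kind = "node", length = 0, events = integer(0),
               children = lapply(crown_kids, build))

  # count tips, then number nodes ape-style (tips 1..n, root n+1, preorder)
  count_tips <- function(nd) {
    if (nd$kind == "tip") 1L else sum(vapply(nd$children, count_tips, 1L))
  }
  n_tip <- count_tips(root)

  env$edge <- matrix(0L, 0, 2)
  env$edge_length <- numeric(0)
  env$edge_events <- list()
  env$tip_labels <- character(n_tip)
  env$tip_states <- integer(n_tip)
  env$next_tip <- 1L
  env$next_node <- n_tip + 1L

  assign_ids <- function(nd, parent_id) {
    if (nd$kind == "tip") {
      id <- env$next_tip; env$next_tip <- id + 1L
      env$tip_labels[id] <- nd$label
      env$tip_states[id] <- nd$state
    } else {
      id <- env$next_node; env$next_node <- id + 1L
    }
    if (!is.na(parent_id)) {
      env$edge <- rbind(env$edge, c(parent_id, id))
      env$edge_length <- c(env$edge_length, nd$length)
      env$edge_events <- c(env$edge_events, list(nd$events))
    }
    if (nd$kind == "node") {
      for (ch in nd$children) assign_ids(ch, id)
    }
    id
  }
  assign_ids(root, NA_integer_)

  tree <- structure(
    list(edge = env$edge, edge.length = env$edge_length,
         tip.label = env$tip_labels, Nnode = env$next_node - n_tip - 1L),
    class = "phylo", order = "cladewise"
  )

  ev_edge <- rep.int(seq_along(env$edge_events),
                     lengths(env$edge_events))
  ev_sel <- unlist(env$edge_events, use.names = FALSE)
  events <- data.frame(
    edge = ev_edge,
    age = t_end - ev_time[ev_sel],
    from = state_names[ev_from[ev_sel]],
    to = state_names[ev_to[ev_sel]],
    stringsAsFactors = FALSE
  )
  o <- order(events$edge, -events$age)
  events <- events[o, , drop = FALSE]
  rownames(events) <- NULL

  history <- structure(
    list(events = events, root_state = state_names[root_state],
         states = state_names),
    class = "branch_history"
  )
  tip_states <- setNames(state_names[env$tip_states], env$tip_labels)

  list(tree = tree, history = history, tip_states = tip_states)
}

#' Simulate until a replicate survives
#'
#' Convenience wrapper that retries [simulate_musse_tree()] on the
#' `geoshift_extinct` condition, advancing the seed deterministically.
#'
#' @param config a [sim_config()].
#' @param max_tries maximum number of attempts.
#' @param min_tips optionally also require at least this many surviving tips.
#' @return as [simulate_musse_tree()].
#' @export
simulate_surviving <- function(config, max_tries = 100, min_tips = 2) {
  seed0 <- if (is.null(config$seed)) 1L else config$seed
  for (i in seq_len(max_tries)) {
    config$seed <- substream_seed(seed0, paste0("try", i))
    res <- tryCatch(simulate_musse_tree(config),
                    geoshift_extinct = function(e) NULL)
    if (!is.null(res) && ape::Ntip(res$tree) >= min_tips) return(res)
  }
  stop("no surviving replicate in ", max_tries, " tries")
}

#' Subsample tips with state-specific retention probabilities
#'
#' Emulates incomplete taxonomic sampling: each tip is retained independently
#' with probability `rho` for its state, as assumed by the MuSSE sampling
#' fractions.
#'
#' @param tree a chronogram (`phylo`).
#' @param tip_states named character vector (or 2-column data frame) of tip
#'   states.
#' @param rho retention probability per state: a scalar, or a vector named by
#'   state.
#' @param seed integer seed.
#' @return list with `tree` (pruned chronogram), `tip_states` (retained
#'   tips), and `realized` (data frame: state, retained, total, fraction).
#' @export
subsample_tips <- function(tree, tip_states, rho, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  states <- align_tip_states(tree, tip_states)
  lev <- sort(unique(states))
  if (length(rho) == 1L && is.null(names(rho))) {
    rho <- setNames(rep(rho, length(lev)), lev)
  }
  if (any(!lev %in% names(rho))) stop("`rho` missing for some observed state")
  if (any(rho <= 0) || any(rho > 1)) stop("`rho` must be in (0, 1]")
  keep <- runif(length(states)) <= rho[states]
  if (sum(keep) < 2) stop("subsampling left fewer than 2 tips")
  kept_tips <- tree$tip.label[keep]
  pruned <- ape::keep.tip(tree, kept_tips)
  realized <- data.frame(
    state = lev,
    retained = as.integer(vapply(lev, function(s) sum(keep & states == s), 1L)),
    total = as.integer(vapply(lev, function(s) sum(states == s), 1L))
  )
  realized$fraction <- realized$retained / realized$total
  list(tree = pruned, tip_states = states[keep][pruned$tip.label],
       realized = realized)
}
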