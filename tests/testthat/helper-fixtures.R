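# Shared fixtures and independent oracles. Oracles here are deliberately
# brute-force (enumeration, fine-grid discretization, closed forms) and
# never call the code paths they check.

# frozen 10-tip ultrametric tree (height 10 Myr)
yule10_newick <- paste0(
  "((((t2:0.006215622777,t3:0.006215622777):0.157942076,t8:0.1641576987):",
  "0.6190429433,((t5:0.2609322016,(t9:0.008559284294,t1:0.008559284294):",
  "0.2523729173):0.1697413884,t4:0.43067359):0.3525270521):9.216799358,",
  "(t7:0.5345953358,(t10:0.01182981384,t6:0.01182981384):0.522765522):",
  "9.465404664);"
)
yule10_tree <- function() ape::read.tree(text = yule10_newick)

# 4-tip balanced toy chronogram: node ages 2 and 6, root age 10
toy4_tree <- function() ape::read.tree(text = "((A:2,B:2):8,(C:6,D:6):4);")

quartet_tree <- function() ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")

all_states <- function(tree, s) setNames(rep(s, ape::Ntip(tree)), tree$tip.label)

# exhaustive small-parsimony minimum over all internal labelings
brute_fitch <- function(tree, states_vec) {
  states <- sort(unique(states_vec))
  k <- length(states)
  n_tip <- ape::Ntip(tree)
  nn <- tree$Nnode
  tipidx <- match(states_vec[tree$tip.label], states)
  grid <- expand.grid(rep(list(seq_len(k)), nn))
  best <- Inf
  for (g in seq_len(nrow(grid))) {
    asn <- c(tipidx, as.integer(grid[g, ]))
    changes <- sum(asn[tree$edge[, 1]] != asn[tree$edge[, 2]])
    best <- min(best, changes)
  }
  as.integer(best)
}

# exhaustive Mk likelihood by enumeration over internal-node states
brute_mk_loglik <- function(tree, states_vec, model, prior) {
  states <- model$states
  n_tip <- ape::Ntip(tree)
  nn <- tree$Nnode
  tipidx <- match(states_vec[tree$tip.label], states)
  P <- lapply(seq_len(nrow(tree$edge)),
              function(e) ape::matexpo(model$Q * tree$edge.length[e]))
  grid <- expand.grid(rep(list(seq_along(states)), nn))
  tot <- 0
  for (g in seq_len(nrow(grid))) {
    asn <- c(tipidx, as.integer(grid[g, ]))
    lik <- prior[asn[n_tip + 1L]]
    for (e in seq_len(nrow(tree$edge))) {
      lik <- lik * P[[e]][asn[tree$edge[e, 1]], asn[tree$edge[e, 2]]]
    }
    tot <- tot + lik
  }
  log(tot)
}

# fine-grid discrete-time oracle: expected number of real state changes on
# a branch of length t, conditional on endpoint states, E[N | a, b]
grid_expected_changes <- function(Q, t, m = 2000) {
  k <- nrow(Q)
  dt <- t / m
  P1 <- ape::matexpo(Q * dt)
  Pl <- vector("list", m + 1)
  Pl[[1]] <- diag(k)
  for (i in seq_len(m)) Pl[[i + 1]] <- Pl[[i]] %*% P1
  Pt <- Pl[[m + 1]]
  EN <- matrix(0, k, k)
  for (i in 0:(m - 1)) {
    A <- Pl[[i + 1]] # P(0 -> i dt)
    B <- Pl[[m - i]] # P((i+1) dt -> t)
    for (x in seq_len(k)) for (y in seq_len(k)) {
      if (x == y) next
      # P(s_i = x, s_{i+1} = y | a, b), summed over the grid
      EN <- EN + outer(A[, x], B[y, ]) * P1[x, y]
    }
  }
  EN / Pt
}

# textbook one-way ANOVA from sums of squares (no aov)
anova_oracle <- function(value, group) {
  group <- as.factor(group)
  grand <- mean(value)
  ssb <- sum(tapply(value, group, function(v) length(v) * (mean(v) - grand)^2))
  ssw <- sum(tapply(value, group, function(v) sum((v - mean(v))^2)))
  df1 <- nlevels(group) - 1
  df2 <- length(value) - nlevels(group)
  F <- (ssb / df1) / (ssw / df2)
  list(F = F, p = pf(F, df1, df2, lower.tail = FALSE))
}

expect_no_extinction <- function(expr) {
  tryCatch(expr, geoshift_extinct = function(e) testthat::skip("extinct replicate"))
}
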