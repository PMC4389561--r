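# Stochastic mapping: degenerate cases, endpoint parity, convergence of
# sampled node states to exact marginals, conditional event counts against a
# fine-grid discrete-time oracle, unconditional event totals, and the binned
# relative-rate machinery.

musse_fixture <- function(seed = 9, n = 100, q = 0.04) {
  simulate_surviving(
    sim_config(lambda = c(.15, .15), mu = c(.02, .02), q = q,
               max_taxa = n, seed = seed),
    min_tips = n
  )
}

test_that("with Q = 0 and uniform tips the map has zero events", {
  tr <- yule10_tree()
  m <- mk_model(c("s", "t"), 0, root_prior = c(1, 0))
  h <- sample_stochastic_map(tr, all_states(tr, "s"), m, seed = 1)
  expect_equal(nrow(h$events), 0)
  expect_true(all(h$node_states == "s"))
})

test_that("branch histories have odd event parity when endpoints differ (k = 2)", {
  sim <- musse_fixture(3, 60)
  m <- mk_model(c("1", "2"), 0.04)
  for (s in 1:5) {
    h <- sample_stochastic_map(sim$tree, sim$tip_states, m, seed = s)
    seg <- history_segments(sim$tree, h) # errors if any chain is broken
    n_ev <- table(factor(h$events$edge, levels = seq_len(nrow(sim$tree$edge))))
    for (e in seq_len(nrow(sim$tree$edge))) {
      s_par <- seg$state[seg$edge == e][1]
      rows <- seg[seg$edge == e, ]
      s_ch <- rows$state[nrow(rows)]
      expect_equal(as.integer(n_ev[e]) %% 2L, as.integer(s_par != s_ch))
    }
  }
})

test_that("tip states of every map equal the observed states", {
  sim <- musse_fixture(5, 50)
  m <- mk_model(c("1", "2"), 0.05)
  h <- sample_stochastic_map(sim$tree, sim$tip_states, m, seed = 2)
  expect_equal(h$node_states[seq_len(ape::Ntip(sim$tree))],
               sim$tip_states[sim$tree$tip.label])
})

test_that("sampled node-state frequencies converge to the exact marginals", {
  sim <- musse_fixture(7, 50)
  tree <- sim$tree
  m <- mk_model(c("1", "2"), 0.04)
  marg <- mk_ancestral(tree, sim$tip_states, m)
  pre <- geoshift:::simmap_precompute(
    tree, geoshift:::align_tip_states(tree, sim$tip_states), m)
  n_maps <- 2000
  set.seed(31)
  cnt <- matrix(0, nrow(marg), 2)
  for (i in seq_len(n_maps)) {
    h <- geoshift:::draw_stochastic_map(pre)
    idx <- match(h$node_states, m$states)
    cnt[cbind(seq_along(idx), idx)] <- cnt[cbind(seq_along(idx), idx)] + 1
  }
  tv <- rowSums(abs(cnt / n_maps - marg)) / 2
  expect_lt(max(tv), 0.02 + 3 * sqrt(0.25 / n_maps))
})

test_that("per-branch event counts match the fine-grid conditional oracle", {
  sim <- musse_fixture(9, 100)
  tree <- sim$tree
  Q <- matrix(c(-0.05, 0.05, 0.03, -0.03), 2, 2, byrow = TRUE)
  m <- mk_model(c("1", "2"), Q)
  sv <- geoshift:::align_tip_states(tree, sim$tip_states)
  pre <- geoshift:::simmap_precompute(tree, sv, m)

  # three branches spanning short, medium and long lengths
  len <- tree$edge.length
  sel <- c(which.min(abs(len - stats::median(len))), which.max(len),
           which.min(abs(len - stats::quantile(len, .8))))
  sel <- unique(sel)

  n_maps <- 2000
  set.seed(17)
  counts <- matrix(0, n_maps, length(sel))
  endpoints <- array(0L, c(n_maps, length(sel), 2))
  spans <- branch_age_spans(tree)
  for (i in seq_len(n_maps)) {
    h <- geoshift:::draw_stochastic_map(pre)
    seg <- NULL
    for (j in seq_along(sel)) {
      e <- sel[j]
      counts[i, j] <- sum(h$events$edge == e)
      # endpoint states from the node-state vector
      endpoints[i, j, 1] <- match(h$node_states[tree$edge[e, 1]], m$states)
      endpoints[i, j, 2] <- match(h$node_states[tree$edge[e, 2]], m$states)
    }
  }
  for (j in seq_along(sel)) {
    e <- sel[j]
    EN <- grid_expected_changes(Q, tree$edge.length[e], m = 2000)
    # oracle expectation under the empirical endpoint distribution
    expected <- mean(EN[cbind(endpoints[, j, 1], endpoints[, j, 2])])
    mc_se <- stats::sd(counts[, j]) / sqrt(n_maps)
    expect_lt(abs(mean(counts[, j]) - expected), 3 * mc_se + 1e-4)
  }
})

test_that("total mapped events per unit length match the stationary-flow expectation", {
  Q <- matrix(c(-0.06, 0.06, 0.03, -0.03), 2, 2, byrow = TRUE)
  pi_q <- geoshift:::stationary_distribution(Q)
  flow <- sum(pi_q * c(0.06, 0.03))
  m <- mk_model(c("1", "2"), Q)
  set.seed(41)
  rates <- c()
  for (s in 1:25) {
    sim <- tryCatch(
      simulate_musse_tree(sim_config(lambda = c(.2, .2), mu = c(0, 0), q = Q,
                                     max_time = 18, seed = 600 + s)),
      geoshift_extinct = function(e) NULL
    )
    if (is.null(sim) || ape::Ntip(sim$tree) < 10) next
    pre <- geoshift:::simmap_precompute(
      sim$tree, geoshift:::align_tip_states(sim$tree, sim$tip_states), m)
    tl <- sum(sim$tree$edge.length)
    ev <- replicate(8, nrow(geoshift:::draw_stochastic_map(pre)$events))
    rates <- c(rates, mean(ev) / tl)
  }
  se <- stats::sd(rates) / sqrt(length(rates))
  expect_lt(abs(mean(rates) - flow), 3 * se)
})

test_that("transition counting bins events by age and conserves totals", {
  h <- structure(list(events = data.frame(
    edge = c(1L, 1L, 2L), age = c(2, 7, 7.5),
    from = c("a", "b", "a"), to = c("b", "a", "b"),
    stringsAsFactors = FALSE
  ), root_state = "a", states = c("a", "b")), class = "branch_history")
  bins <- c(0, 5, 10)
  expect_equal(count_transitions(h, bins), c(1L, 2L))
  expect_equal(count_transitions(h, bins, from = "a", to = "b"), c(1L, 1L))
  expect_equal(sum(count_transitions(h, bins, from = "a", to = "b")) +
                 sum(count_transitions(h, bins, from = "b", to = "a")),
               nrow(h$events))
  expect_equal(count_transitions(structure(list(events = h$events[0, ]),
                                           class = "branch_history"), bins),
               c(0L, 0L))
  expect_error(count_transitions(h, c(0, 5)), "outside the bin range")
})

test_that("lineage availability matches hand enumeration on the toy tree", {
  tr <- toy4_tree() # tip edges to ages 2 and 6, root at 10
  expect_equal(lineages_in_bin(tr, c(0, 5)), 5L) # A, B, C, D, AB-stem
  expect_equal(lineages_in_bin(tr, c(5, 10)), 4L) # C, D, AB-stem, CD-stem
  expect_equal(lineages_in_bin(tr, c(9, 10)), 2L) # the two root children
  expect_equal(lineages_in_bin(tr, c(0, 5), "nodes"), 1L)
  expect_equal(lineages_in_bin(tr, c(5, 10), "nodes"), 1L)
  # lineages alive at an instant never increase going back in time, and the
  # bin-intersection count dominates the instantaneous count at the bin's
  # young edge
  sim <- musse_fixture(13, 60)
  root_age <- max(node_ages(sim$tree))
  edges <- seq(0, root_age, length.out = 9)
  spans <- branch_age_spans(sim$tree)
  at_instant <- vapply(edges[-9] + 1e-9, function(a) {
    sum(spans$child_age <= a & spans$parent_age > a)
  }, 1)
  expect_true(all(diff(at_instant) <= 0))
  dens <- vapply(seq_len(8), function(i) {
    lineages_in_bin(sim$tree, c(edges[i], edges[i + 1]))
  }, 1L)
  expect_true(all(dens >= at_instant))
})

test_that("relative shift rates are zero with Q = 0 and carry metadata", {
  tr <- yule10_tree()
  m <- mk_model(c("s", "t"), 0, root_prior = c(1, 0))
  rs <- relative_shift_rates(tr, all_states(tr, "s"), m, n_maps = 10,
                             bin_width = 5, seed = 1)
  expect_true(all(rs$mean == 0))
  expect_true(all(rs$lo95 == 0) && all(rs$hi95 == 0))
  md <- attr(rs, "metadata")
  expect_equal(md$denominator_definition, "branches")
  expect_equal(md$bins_anchored_at, 0)
  expect_equal(md$oldest_bin_width, max(node_ages(tr)) - 5)
  expect_error(relative_shift_rates(tr, all_states(tr, "s"), m, n_maps = 1),
               "n_maps")
})

test_that("mapped-vs-true per-bin counts regress with slope near 1", {
  Q <- matrix(c(-0.05, 0.05, 0.05, -0.05), 2, 2, byrow = TRUE)
  m <- mk_model(c("1", "2"), Q)
  mapped <- true <- c()
  n_rep <- 0; s <- 0
  while (n_rep < 30 && s < 100) {
    s <- s + 1
    sim <- tryCatch(
      simulate_musse_tree(sim_config(lambda = c(.15, .15), mu = c(.02, .02),
                                     q = Q, max_taxa = 120, seed = 800 + s)),
      geoshift_extinct = function(e) NULL
    )
    if (is.null(sim) || ape::Ntip(sim$tree) < 60) next
    n_rep <- n_rep + 1
    root_age <- max(node_ages(sim$tree))
    bins <- c(seq(0, root_age - 1e-9, by = 5), root_age)
    tc <- count_transitions(sim$history, bins)
    pre <- geoshift:::simmap_precompute(
      sim$tree, geoshift:::align_tip_states(sim$tree, sim$tip_states), m)
    set.seed(900 + s)
    mc <- rowMeans(replicate(30, {
      count_transitions(geoshift:::draw_stochastic_map(pre), bins)
    }))
    mapped <- c(mapped, mc)
    true <- c(true, tc)
  }
  slope <- unname(coef(stats::lm(mapped ~ true))["true"])
  expect_gt(slope, 0.8)
  expect_lt(slope, 1.2)
})

test_that("shift-rate summaries are stable under tree rotation with matched seeds", {
  sim <- musse_fixture(19, 60)
  m <- mk_model(c("1", "2"), 0.05)
  rot <- ape::read.tree(text = ape::write.tree(ape::ladderize(sim$tree)))
  r1 <- relative_shift_rates(sim$tree, sim$tip_states, m, n_maps = 150,
                             bin_width = 5, seed = 4)
  r2 <- relative_shift_rates(rot, sim$tip_states, m, n_maps = 150,
                             bin_width = 5, seed = 4)
  expect_equal(r1$denominator, r2$denominator) # deterministic quantities equal
  keep <- !is.na(r1$mean) & r1$denominator >= 20
  # Monte-Carlo means agree within a generous replicate-level band
  expect_lt(max(abs(r1$mean[keep] - r2$mean[keep])), 0.05)
})

test_that("denominator definition changes scale but not the sign of net flow", {
  # strongly asymmetric q: emigration 1 -> 2 dominates
  Q <- matrix(c(-0.12, 0.12, 0.01, -0.01), 2, 2, byrow = TRUE)
  m <- mk_model(c("1", "2"), Q)
  sim <- musse_fixture(23, 80, q = 0.05)
  net <- function(denominator) {
    rs <- relative_shift_rates(sim$tree, sim$tip_states, m, n_maps = 60,
                               bin_width = 1e6, seed = 6,
                               denominator = denominator)
    rs$mean[rs$direction == "1->2"] - rs$mean[rs$direction == "2->1"]
  }
  expect_gt(net("branches"), 0)
  expect_gt(net("nodes"), 0)
})
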