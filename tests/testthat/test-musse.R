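# MuSSE likelihood: closed-form and independent-solver oracles, E-variable
# behaviour, constraint nesting, fit determinism and bias direction.

test_that("single-state pure-birth likelihood equals the Yule closed form", {
  tr <- yule10_tree()
  for (lam in c(0.05, 0.13, 0.3)) {
    ll <- musse_loglik(tr, all_states(tr, "1"),
                       musse_params(lam, 0, matrix(0, 1, 1)),
                       rtol = 1e-10, atol = 1e-12)
    yule <- (ape::Ntip(tr) - 1) * log(lam) - lam * sum(tr$edge.length)
    expect_equal(ll, yule, tolerance = 1e-10)
  }
})

test_that("E stays zero without extinction and grows monotonically with it", {
  lam <- c(0.2, 0.1)
  Q <- matrix(c(-0.02, 0.02, 0.02, -0.02), 2, 2, byrow = TRUE)
  # mu = 0, rho = 1: E(t) identically 0
  traj0 <- musse_branch_cpp(c(0, 0, 1, 0), 20, lam, c(0, 0), Q, 50,
                            1e-8, 1e-10)
  expect_true(all(abs(traj0[, 2:3]) < 1e-12))
  # mu > 0: E is non-decreasing along the branch
  traj <- musse_branch_cpp(c(0, 0, 1, 0), 20, lam, c(0.05, 0.08), Q, 200,
                           1e-8, 1e-10)
  expect_true(all(diff(traj[, 2]) > -1e-10))
  expect_true(all(diff(traj[, 3]) > -1e-10))
  expect_true(all(traj[, 2:3] >= 0 & traj[, 2:3] <= 1))
})

test_that("branch integration matches an independent ODE solver", {
  skip_if_not_installed("deSolve")
  lam <- c(0.2, 0.1); mu <- c(0.05, 0.08)
  Q <- matrix(c(-0.03, 0.03, 0.02, -0.02), 2, 2, byrow = TRUE)
  y0 <- c(0.1, 0.3, 1, 0)
  f <- function(t, y, parms) {
    E <- y[1:2]; D <- y[3:4]
    qout <- c(0.03, 0.02)
    dE <- mu - (lam + mu + qout) * E + lam * E^2 +
      c(Q[1, 2] * E[2], Q[2, 1] * E[1])
    dD <- -(lam + mu + qout) * D + c(Q[1, 2] * D[2], Q[2, 1] * D[1]) +
      2 * lam * E * D
    list(c(dE, dD))
  }
  ref <- deSolve::ode(y0, c(0, 7), f, NULL, rtol = 1e-10, atol = 1e-12)[2, -1]
  mine <- musse_branch_cpp(y0, 7, lam, mu, Q, 1, 1e-8, 1e-10)[2, -1]
  expect_equal(unname(mine), unname(ref), tolerance = 1e-7)
})

test_that("a two-state model with an unreachable empty state collapses to one state", {
  tr <- yule10_tree()
  sv <- all_states(tr, "1")
  ll2 <- musse_loglik(tr, sv,
                      musse_params(c(0.13, 0.13), c(0.02, 0.02), 0,
                                   states = c("1", "2")))
  ll1 <- musse_loglik(tr, sv, musse_params(0.13, 0.02, matrix(0, 1, 1)))
  expect_equal(ll2, ll1, tolerance = 1e-6)
})

test_that("the reported fit log-likelihood is reproducible at the fitted parameters", {
  sim <- simulate_surviving(sim_config(lambda = c(.25, .12), mu = c(.03, .03),
                                       q = 0.03, max_taxa = 120, seed = 31),
                            min_tips = 100)
  fit <- fit_musse(sim$tree, sim$tip_states, q_constraint = "equal")
  expect_equal(musse_loglik(sim$tree, sim$tip_states, fit$params,
                            fit$root_mode),
               fit$loglik, tolerance = 1e-6)
  # determinism: same inputs, same result
  fit2 <- fit_musse(sim$tree, sim$tip_states, q_constraint = "equal")
  expect_identical(fit$params, fit2$params)
  expect_identical(fit$loglik, fit2$loglik)
})

test_that("equality constraints never beat the free fit", {
  sim <- simulate_surviving(sim_config(lambda = c(.2, .2), mu = c(.03, .03),
                                       q = 0.04, max_taxa = 100, seed = 37),
                            min_tips = 80)
  free <- fit_musse(sim$tree, sim$tip_states, q_constraint = "equal")
  eqd <- fit_musse(sim$tree, sim$tip_states, lambda_constraint = "equal",
                   mu_constraint = "equal", q_constraint = "equal")
  expect_gte(free$loglik, eqd$loglik - 1e-4)
})

test_that("understating the sampling fraction inflates speciation estimates", {
  up <- 0
  for (s in 1:3) {
    sim <- simulate_surviving(
      sim_config(lambda = c(.2, .2), mu = c(.03, .03), q = 0.04,
                 max_taxa = 150, seed = 50 + s), min_tips = 120)
    f_true <- fit_musse(sim$tree, sim$tip_states, rho = 1,
                        lambda_constraint = "equal", mu_constraint = "equal",
                        q_constraint = "equal")
    f_mis <- fit_musse(sim$tree, sim$tip_states, rho = 0.5,
                       lambda_constraint = "equal", mu_constraint = "equal",
                       q_constraint = "equal")
    if (f_mis$params$lambda[1] > f_true$params$lambda[1]) up <- up + 1
  }
  expect_gte(up, 2)
})

test_that("invalid inputs are rejected", {
  tr <- yule10_tree()
  expect_error(musse_params(c(.1, .2), c(0, 0), 0, rho = c(1, 0)),
               "rho")
  p <- musse_params(c(.1, .2), c(0, 0), 0.01, states = c("a", "b"))
  sv <- all_states(tr, "a"); sv[1] <- "zz"
  expect_error(musse_loglik(tr, sv, p), "unknown tip state")
})

test_that("likelihood is smooth in the rates (stable central differences)", {
  sim <- simulate_surviving(sim_config(lambda = c(.2, .1), mu = c(.03, .03),
                                       q = 0.03, max_taxa = 30, seed = 77),
                            min_tips = 25)
  base <- c(lambda1 = 0.2, lambda2 = 0.1, mu = 0.03, q = 0.03)
  ll_at <- function(v) {
    musse_loglik(sim$tree, sim$tip_states,
                 musse_params(c(v[1], v[2]), c(v[3], v[3]), v[4],
                              states = c("1", "2")),
                 rtol = 1e-10, atol = 1e-12)
  }
  for (i in seq_along(base)) {
    grad_h <- function(h) {
      up <- base; up[i] <- up[i] + h
      dn <- base; dn[i] <- dn[i] - h
      (ll_at(up) - ll_at(dn)) / (2 * h)
    }
    g1 <- grad_h(1e-4 * base[i])
    g2 <- grad_h(1e-5 * base[i])
    expect_lt(abs(g1 - g2) / max(abs(g2), 1e-8), 1e-4)
  }
})
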