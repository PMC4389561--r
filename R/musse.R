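# R interface to the MuSSE likelihood core and maximum-likelihood fitting
# with state-specific sampling fractions.

#' MuSSE parameter set
#'
#' @param lambda per-state speciation rates (/lineage/Myr).
#' @param mu per-state extinction rates.
#' @param q k x k transition-rate matrix (scalar expands to symmetric).
#' @param rho per-state sampling fraction in (0, 1]; scalar recycled.
#' @param states optional state names (default `"1".."k"`).
#' @return object of class `musse_params`.
#' @export
musse_params <- function(lambda, mu, q, rho = 1, states = NULL) {
  k <- length(lambda)
  if (length(mu) != k) stop("`lambda` and `mu` must have equal length")
  if (any(lambda < 0) || any(mu < 0)) stop("rates must be >= 0")
  if (length(q) == 1L) {
    q <- matrix(q, k, k)
    diag(q) <- 0
    diag(q) <- -rowSums(q)
  }
  q <- validate_rate_matrix(q, k)
  if (length(rho) == 1L) rho <- rep(rho, k)
  if (length(rho) != k || any(rho <= 0) || any(rho > 1)) {
    stop("`rho` must be k values in (0, 1]")
  }
  if (is.null(states)) states <- as.character(seq_len(k))
  structure(list(lambda = setNames(lambda, states),
                 mu = setNames(mu, states), q = q,
                 rho = setNames(rho, states), states = states),
            class = "musse_params")
}

#' @export
print.musse_params <- function(x, ...) {
  cat("musse_params,", length(x$states), "states\n")
  print(data.frame(state = x$states, lambda = unname(x$lambda),
                   mu = unname(x$mu), rho = unname(x$rho)))
  invisible(x)
}

#' MuSSE log-likelihood
#'
#' Per-branch integration of the coupled E/D equations (adaptive
#' Runge-Kutta, relative/absolute tolerances 1e-8/1e-10), tip conditions
#' `D_i = rho_i 1[state = i]`, `E_i = 1 - rho_i`, node combination
#' `D_i <- D_L,i D_R,i lambda_i`, running log-compensation against
#' underflow.
#'
#' @param tree ultrametric `phylo`.
#' @param tip_states named character vector or 2-column data frame; states
#'   must be in `params$states`.
#' @param params a [musse_params()].
#' @param root_mode `"fitzjohn"` (weights proportional to the root D),
#'   `"flat"`, `"equilibrium"` (stationary distribution of `q`), or a
#'   numeric prior over states.
#' @param rtol,atol relative/absolute ODE tolerances (defaults 1e-8/1e-10;
#'   tighten when comparing against closed forms).
#' @return log-likelihood (scalar; `-Inf` signals numerical failure at
#'   degenerate parameters).
#' @export
musse_loglik <- function(tree, tip_states, params, root_mode = "fitzjohn",
                         rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "musse_params"))
  assert_chronogram(tree)
  sv <- align_tip_states(tree, tip_states)
  idx <- match(sv, params$states)
  if (anyNA(idx)) stop("unknown tip state: ", unique(sv[is.na(idx)])[1])
  obs <- unique(idx)
  if (any(params$rho[obs] <= 0)) stop("rho = 0 for an observed state")
  po <- ape::reorder.phylo(tree, "postorder")
  if (is.numeric(root_mode)) {
    mode <- 2L; prior <- root_mode
    if (length(prior) != length(params$states)) stop("bad root prior length")
  } else {
    mode <- switch(match.arg(root_mode, c("fitzjohn", "flat", "equilibrium")),
                   fitzjohn = 0L, flat = 1L, equilibrium = 2L)
    prior <- if (mode == 2L) stationary_distribution(params$q) else numeric(length(params$states))
  }
  musse_loglik_cpp(po$edge, po$edge.length, ape::Ntip(po), idx,
                   unname(params$lambda), unname(params$mu), params$q,
                   unname(params$rho), mode, prior, rtol, atol)
}

# parameter packing for the constrained fit: free parameters on log scale
musse_par_template <- function(k, lambda_constraint, mu_constraint,
                               q_constraint) {
  n_lambda <- if (lambda_constraint == "equal") 1L else k
  n_mu <- if (mu_constraint == "equal") 1L else k
  n_q <- switch(q_constraint, equal = 1L, symmetric = (k * (k - 1L)) %/% 2L,
                ard = k * (k - 1L))
  list(n_lambda = n_lambda, n_mu = n_mu, n_q = n_q,
       n = n_lambda + n_mu + n_q)
}

musse_unpack <- function(par, k, tmpl, q_constraint, rho, states) {
  lambda <- rep_len(par[seq_len(tmpl$n_lambda)], k)
  mu <- rep_len(par[tmpl$n_lambda + seq_len(tmpl$n_mu)], k)
  qpar <- par[tmpl$n_lambda + tmpl$n_mu + seq_len(tmpl$n_q)]
  q <- matrix(0, k, k)
  if (q_constraint == "equal") {
    q[row(q) != col(q)] <- qpar[1]
  } else if (q_constraint == "symmetric") {
    m <- 1L
    for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
      q[i, j] <- q[j, i] <- qpar[m]
      m <- m + 1L
    }
  } else {
    q[row(q) != col(q)] <- qpar
  }
  diag(q) <- -rowSums(q)
  musse_params(lambda, mu, q, rho, states)
}

#' Fit MuSSE rates by maximum likelihood
#'
#' Bounded optimization (rates in `[1e-6, 10]` /Myr, log scale, L-BFGS-B)
#' from three deterministic starts seeded by birth-death moment estimates
#' (net diversification from tip count and root age, at assumed relative
#' extinctions 0, 0.5 and 0.8).
#'
#' @param tree ultrametric `phylo` (a warning is issued below 20 tips).
#' @param tip_states named character vector or 2-column data frame.
#' @param rho per-state sampling fractions (scalar or named by state).
#' @param lambda_constraint,mu_constraint `"free"` or `"equal"` across
#'   states.
#' @param q_constraint `"equal"` (one shared rate), `"symmetric"`, or
#'   `"ard"`.
#' @param root_mode as in [musse_loglik()].
#' @param states optional state set (default: observed).
#' @param seed accepted for interface symmetry; the fit is deterministic.
#' @return object of class `musse_fit`: `params` (ML [musse_params()]),
#'   `loglik`, `convergence`, `starts` (per-start trace), `root_mode`.
#' @export
fit_musse <- function(tree, tip_states, rho = 1,
                      lambda_constraint = c("free", "equal"),
                      mu_constraint = c("free", "equal"),
                      q_constraint = c("equal", "symmetric", "ard"),
                      root_mode = "fitzjohn", states = NULL, seed = NULL) {
  lambda_constraint <- match.arg(lambda_constraint)
  mu_constraint <- match.arg(mu_constraint)
  q_constraint <- match.arg(q_constraint)
  sv <- align_tip_states(tree, tip_states)
  if (is.null(states)) states <- sort(unique(sv))
  k <- length(states)
  if (ape::Ntip(tree) < 20) {
    warning("fewer than 20 tips; rate estimates will be unreliable")
  }
  if (length(rho) == 1L) rho <- setNames(rep(rho, k), states)
  rho <- rho[states]
  if (anyNA(rho)) stop("`rho` missing for some state")

  tmpl <- musse_par_template(k, lambda_constraint, mu_constraint, q_constraint)
  lower <- log(1e-6); upper <- log(10)
  nll <- function(logp) {
    p <- musse_unpack(exp(logp), k, tmpl, q_constraint, rho, states)
    ll <- tryCatch(musse_loglik(tree, sv, p, root_mode),
                   error = function(e) -Inf)
    if (!is.finite(ll)) 1e10 else -ll
  }

  root_age <- max(node_ages(tree))
  n <- ape::Ntip(tree)
  r0 <- max((log(n) - log(2)) / root_age, 1e-4) # net diversification moment
  eps <- c(0, 0.5, 0.8)
  starts <- lapply(eps, function(e) {
    lam0 <- min(max(r0 / (1 - e), 2e-6), 5)
    mu0 <- max(lam0 * e, 2e-6)
    q0 <- min(max(0.1 * lam0, 2e-6), 5)
    log(c(rep(lam0, tmpl$n_lambda), rep(mu0, tmpl$n_mu), rep(q0, tmpl$n_q)))
  })
  fits <- lapply(starts, function(s0) {
    tryCatch(
      optim(s0, nll, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 500, factr = 1e8)),
      error = function(e) list(par = s0, value = 1e10, convergence = 99L)
    )
  })
  vals <- vapply(fits, `[[`, numeric(1), "value")
  if (all(vals >= 1e10)) {
    stop("fit_musse: no start converged; best trace attached\n",
         paste(utils::capture.output(print(vals)), collapse = "\n"))
  }
  best <- fits[[which.min(vals)]]
  params <- musse_unpack(exp(best$par), k, tmpl, q_constraint, rho, states)
  structure(
    list(params = params, loglik = -best$value,
         convergence = best$convergence,
         starts = data.frame(
           eps = eps, loglik = -vals,
           convergence = vapply(fits, function(f) as.integer(f$convergence), 1L)
         ),
         root_mode = if (is.numeric(root_mode)) "given" else root_mode,
         constraints = c(lambda = lambda_constraint, mu = mu_constraint,
                         q = q_constraint)),
    class = "musse_fit"
  )
}

#' @export
print.musse_fit <- function(x, ...) {
  cat("musse_fit: log-likelihood", round(x$loglik, 4), "\n")
  print(x$params)
  invisible(x)
}
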