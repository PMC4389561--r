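# Continuous-time Markov (Mk) models of region evolution on a chronogram:
# Felsenstein pruning likelihood, maximum-likelihood rate fitting for the
# equal-rates / symmetric / all-rates-different model classes, and marginal
# ancestral state reconstruction. Transition probabilities use ape's
# eigendecomposition-based matrix exponential.

#' Construct an Mk model
#'
#' @param states character vector of state (region) names.
#' @param Q k x k instantaneous rate matrix (off-diagonals >= 0, zero row
#'   sums). A scalar is expanded to an equal-rates matrix.
#' @param model_class one of `"ARD"`, `"SYM"`, `"ER"`.
#' @param root_prior `"stationary"` (stationary distribution of `Q`),
#'   `"uniform"`, `"fitzjohn"`, or a numeric prior over states.
#' @return object of class `mk_model`.
#' @export
mk_model <- function(states, Q, model_class = "ARD",
                     root_prior = "stationary") {
  k <- length(states)
  if (length(Q) == 1L) {
    Q <- matrix(Q, k, k)
    diag(Q) <- 0
    diag(Q) <- -rowSums(Q)
  }
  Q <- validate_rate_matrix(Q, k)
  dimnames(Q) <- list(states, states)
  if (is.numeric(root_prior)) {
    if (length(root_prior) != k || abs(sum(root_prior) - 1) > 1e-8) {
      stop("numeric root prior must sum to 1 over the states")
    }
  } else {
    root_prior <- match.arg(root_prior, c("stationary", "uniform", "fitzjohn"))
  }
  structure(
    list(states = states, Q = Q, model_class = model_class,
         root_prior = root_prior),
    class = "mk_model"
  )
}

#' @export
print.mk_model <- function(x, ...) {
  cat("mk_model (", x$model_class, "), ", length(x$states), " states: ",
      paste(x$states, collapse = ", "), "\n", sep = "")
  print(round(x$Q, 6))
  if (!is.null(x$loglik)) cat("log-likelihood:", x$loglik, "\n")
  invisible(x)
}

root_prior_vector <- function(model, root_partial = NULL) {
  if (is.numeric(model$root_prior)) return(model$root_prior)
  switch(model$root_prior,
    stationary = stationary_distribution(model$Q),
    uniform = rep(1 / length(model$states), length(model$states)),
    fitzjohn = {
      if (is.null(root_partial)) stop("fitzjohn prior needs root partials")
      if (sum(root_partial) <= 0) rep(1 / length(model$states), length(model$states))
      else root_partial / sum(root_partial)
    }
  )
}

# per-node scaled partial likelihoods by Felsenstein pruning;
# returns list(partials, logcomp, P = per-edge transition matrices)
mk_pruning <- function(tree, states_vec, model, tol = 1e-6) {
  assert_chronogram(tree, tol)
  k <- length(model$states)
  n_tip <- ape::Ntip(tree)
  idx <- match(states_vec, model$states)
  if (anyNA(idx)) {
    stop("unknown tip state: ",
         paste(unique(states_vec[is.na(idx)]), collapse = ", "))
  }
  po <- ape::reorder.phylo(tree, "postorder")
  L <- matrix(1, n_tip + tree$Nnode, k)
  L[seq_len(n_tip), ] <- 0
  L[cbind(seq_len(n_tip), idx)] <- 1
  P <- vector("list", nrow(po$edge))
  logcomp <- 0
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1]; ch <- po$edge[e, 2]
    Pe <- ape::matexpo(model$Q * po$edge.length[e])
    Pe[Pe < 0] <- 0 # eigendecomposition round-off
    P[[e]] <- Pe
    v <- as.vector(P[[e]] %*% L[ch, ])
    s <- sum(v)
    if (s <= 0 || !is.finite(s)) stop("numerical underflow in pruning")
    logcomp <- logcomp + log(s)
    L[par, ] <- L[par, ] * (v / s)
    # renormalize the parent row as well, folding the factor into logcomp
    sp <- max(L[par, ])
    if (sp > 0 && sp < 1e-12) {
      logcomp <- logcomp + log(sp)
      L[par, ] <- L[par, ] / sp
    }
  }
  list(partials = L, logcomp = logcomp, postorder = po, P = P)
}

#' Mk log-likelihood on a chronogram
#'
#' Felsenstein pruning with per-branch transition probabilities
#' `expm(Q * t)`; the root partials are combined with the model's root prior.
#'
#' @param tree ultrametric `phylo` (tolerance 1e-6 Myr).
#' @param tip_states named character vector or 2-column data frame.
#' @param model an [mk_model()].
#' @return log-likelihood (scalar).
#' @export
mk_loglik <- function(tree, tip_states, model) {
  sv <- align_tip_states(tree, tip_states)
  pr <- mk_pruning(tree, sv, model)
  root <- ape::Ntip(tree) + 1L
  prior <- root_prior_vector(model, pr$partials[root, ])
  ll <- log(sum(prior * pr$partials[root, ])) + pr$logcomp
  if (!is.finite(ll)) stop("non-finite Mk log-likelihood")
  ll
}

#' Marginal ancestral state probabilities under an Mk model
#'
#' Standard up-down algorithm: downward (pruning) partials are combined with
#' upward partials carrying the information from the rest of the tree, so
#' each node's vector is its true marginal posterior given all tip states.
#'
#' @inheritParams mk_loglik
#' @return matrix (tips + internal nodes) x states of marginal
#'   probabilities, rows summing to 1.
#' @export
mk_ancestral <- function(tree, tip_states, model) {
  sv <- align_tip_states(tree, tip_states)
  pr <- mk_pruning(tree, sv, model)
  po <- pr$postorder
  L <- pr$partials
  k <- length(model$states)
  n_node <- ape::Ntip(tree) + tree$Nnode
  root <- ape::Ntip(tree) + 1L

  # v_e = P_e %*% L[child] for every postorder edge; children per parent
  v <- vector("list", nrow(po$edge))
  kids_edges <- vector("list", n_node)
  for (e in seq_len(nrow(po$edge))) {
    v[[e]] <- as.vector(pr$P[[e]] %*% L[po$edge[e, 2], ])
    par <- po$edge[e, 1]
    kids_edges[[par]] <- c(kids_edges[[par]], e)
  }

  U <- matrix(0, n_node, k)
  U[root, ] <- root_prior_vector(model, L[root, ])
  for (e in rev(seq_len(nrow(po$edge)))) {
    par <- po$edge[e, 1]; ch <- po$edge[e, 2]
    ut <- U[par, ]
    for (o in kids_edges[[par]]) if (o != e) ut <- ut * v[[o]]
    u <- as.vector(ut %*% pr$P[[e]])
    s <- sum(u)
    U[ch, ] <- if (s > 0) u / s else rep(1 / k, k)
  }
  marg <- U * L
  marg <- marg / rowSums(marg)
  dimnames(marg) <- list(NULL, model$states)
  marg
}

build_Q <- function(rates, k, model_class) {
  Q <- matrix(0, k, k)
  off <- which(row(Q) != col(Q))
  if (model_class == "ER") {
    Q[off] <- rates[1]
  } else if (model_class == "SYM") {
    m <- 1L
    for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
      Q[i, j] <- Q[j, i] <- rates[m]
      m <- m + 1L
    }
  } else {
    Q[off] <- rates
  }
  diag(Q) <- -rowSums(Q)
  Q
}

n_free_rates <- function(k, model_class) {
  switch(model_class, ER = 1L, SYM = (k * (k - 1L)) %/% 2L,
         ARD = k * (k - 1L))
}

#' Fit an Mk model by maximum likelihood
#'
#' Rates are optimized on the log scale within `[1e-8, 100]` events/Myr with
#' three deterministic multi-starts scaled around a parsimony-informed
#' initial rate.
#'
#' @param tree ultrametric `phylo`.
#' @param tip_states named character vector or 2-column data frame.
#' @param model_class `"ARD"` (default; directional rates are the object of
#'   interest), `"SYM"` or `"ER"`.
#' @param root_prior as in [mk_model()].
#' @param states optional state set (default: observed states).
#' @return an [mk_model()] with elements `loglik`, `convergence` and
#'   `starts` added.
#' @export
fit_mk <- function(tree, tip_states, model_class = c("ARD", "SYM", "ER"),
                   root_prior = "stationary", states = NULL) {
  model_class <- match.arg(model_class)
  sv <- align_tip_states(tree, tip_states)
  if (is.null(states)) states <- sort(unique(sv))
  if (length(unique(sv)) < 2) {
    stop("character invariant; rates unidentifiable")
  }
  k <- length(states)
  np <- n_free_rates(k, model_class)
  lower <- log(1e-8); upper <- log(100)

  nll <- function(logr) {
    Q <- build_Q(exp(logr), k, model_class)
    m <- mk_model(states, Q, model_class, root_prior)
    ll <- tryCatch(mk_loglik(tree, sv, m), error = function(e) -Inf)
    if (!is.finite(ll)) 1e10 else -ll
  }
  # parsimony-informed rate scale: changes per unit of total branch length
  ps <- max(parsimony_score(tree, sv), 1L)
  r0 <- ps / sum(tree$edge.length)
  fits <- lapply(c(0.2, 1, 5), function(f) {
    start <- rep(log(pmin(pmax(r0 * f, 1.5e-8), 50)), np)
    optim(start, nll, method = "L-BFGS-B", lower = lower, upper = upper,
          control = list(maxit = 500))
  })
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  model <- mk_model(states, build_Q(exp(best$par), k, model_class),
                    model_class, root_prior)
  model$loglik <- -best$value
  model$convergence <- best$convergence
  model$starts <- data.frame(
    start = c(0.2, 1, 5) * r0,
    loglik = -vapply(fits, `[[`, numeric(1), "value"),
    convergence = vapply(fits, `[[`, integer(1), "convergence")
  )
  model
}
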