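#' Two-parameter logistic item response function
#'
#' Probability of endorsing an item given latent severity `theta`:
#' `P(theta) = 1 / (1 + exp(-a (theta - b)))`.  The logistic metric is
#' used directly, with no 1.7 scaling constant.  `a` governs how sharply
#' the item discriminates and `b` is the severity at which endorsement
#' probability reaches one half.
#'
#' @param a Discrimination, `a > 0`.
#' @param b Severity (location on the latent scale).
#' @param theta Latent trait value(s).
#' @return Endorsement probabilities in (0, 1), vectorized over the
#'   longest argument.
#' @export
#' @examples
#' irf(1.46, 0.99, 0.99)  # theta at the item's severity: exactly 0.5
#' irf(1.46, 0.99, 0)
irf <- function(a, b, theta) {
  if (any(!is.finite(a)) || any(a <= 0))
    stop("discrimination `a` must be positive", call. = FALSE)
  plogis(a * (theta - b))
}

#' Quadrature grid for marginal likelihood integration
#'
#' Equally spaced nodes on the latent scale with, per group, weights
#' proportional to that group's normal latent density, renormalized to sum
#' to one.  Dense equally spaced nodes keep re-weighting trivial when
#' focal-group moments are updated during estimation.
#'
#' @param latent A [latent_distribution()].
#' @param n_nodes Number of nodes (default 61).
#' @param bounds Grid end points (default `c(-6, 6)`).
#' @return An object of class `quadrature_grid`: list with `nodes`
#'   (increasing numeric vector) and `weights` (nodes x groups matrix,
#'   columns summing to 1).
#' @export
quadrature_grid <- function(latent, n_nodes = 61, bounds = c(-6, 6)) {
  stopifnot(inherits(latent, "latent_distribution"),
            n_nodes >= 3, bounds[1] < bounds[2])
  nodes <- seq(bounds[1], bounds[2], length.out = n_nodes)
  weights <- vapply(latent$groups, function(g) {
    w <- dnorm(nodes, latent$mean[g], sqrt(latent$variance[g]))
    w / sum(w)
  }, numeric(n_nodes))
  structure(list(nodes = nodes, weights = weights),
            class = "quadrature_grid")
}

# Collapse a binary matrix to its distinct response patterns with counts.
# Returns list(Y = patterns x items matrix, cnt = pattern counts, n).
collapse_patterns <- function(Y) {
  if (nrow(Y) == 0)
    return(list(Y = Y, cnt = numeric(0), n = 0L))
  key <- apply(Y, 1, paste, collapse = "")
  u <- !duplicated(key)
  cnt <- as.numeric(table(key)[key[u]])
  list(Y = Y[u, , drop = FALSE], cnt = cnt, n = nrow(Y))
}

# Per-group pattern-collapsed data for the EM engine / likelihood.
# data: response_matrix (complete); groups taken from its factor levels
# that are actually present.
prepare_patterns <- function(data) {
  stopifnot(inherits(data, "response_matrix"))
  if (anyNA(data$responses))
    stop("responses contain missing values; run filter_complete() first",
         call. = FALSE)
  present <- group_levels(data)[group_levels(data) %in%
                                  unique(as.character(data$group))]
  pats <- lapply(present, function(g)
    collapse_patterns(data$responses[data$group == g, , drop = FALSE]))
  names(pats) <- present
  pats
}

# Pattern-level marginal log-likelihood for one group.
# Y: patterns x J; P: J x Q endorsement probabilities; w: Q weights.
# Returns list(ll_pat = per-pattern log marginal likelihood,
#              A = patterns x Q joint density matrix).
pattern_lik <- function(Y, P, w) {
  LL <- Y %*% log(P) + (1 - Y) %*% log1p(-P)
  A <- sweep(exp(LL), 2, w, "*")
  list(ll_pat = log(rowSums(A)), A = A)
}

#' Marginal log-likelihood of a 2PL model
#'
#' Sum over respondents of the log of the latent-trait-integrated
#' likelihood of their response pattern, the integral being approximated
#' on a quadrature grid with group-specific normal density weights.
#'
#' @param data A complete [response_matrix()].
#' @param bank An [item_bank()] resolving every group present in `data`.
#' @param latent A [latent_distribution()] covering those groups.
#' @param grid A [quadrature_grid()] built from `latent` (default:
#'   61 nodes on `[-6, 6]`).
#' @return The marginal log-likelihood (a scalar).
#' @export
marginal_loglik <- function(data, bank, latent,
                            grid = quadrature_grid(latent)) {
  stopifnot(inherits(bank, "item_bank"),
            inherits(latent, "latent_distribution"),
            inherits(grid, "quadrature_grid"))
  if (!identical(data$item_ids, bank$item_ids))
    stop("data and bank must use the same items in the same order",
         call. = FALSE)
  pats <- prepare_patterns(data)
  ll <- 0
  for (g in names(pats)) {
    if (pats[[g]]$n == 0) next
    pars <- resolve_items(bank, g)
    P <- clamp_p(irf_grid(pars$a, pars$b, grid$nodes))
    pl <- pattern_lik(pats[[g]]$Y, P, grid$weights[, g])
    ll <- ll + sum(pats[[g]]$cnt * pl$ll_pat)
  }
  ll
}

# J x Q matrix of IRF values over quadrature nodes
irf_grid <- function(a, b, nodes) {
  plogis(outer(a, nodes) - a * b)
}
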