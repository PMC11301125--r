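# Bock-Aitkin EM internals.  Everything here works on pattern-collapsed
# data (list per group: Y patterns x J, cnt, n) and plain parameter
# matrices; the public wrappers in fit.R handle validation and packaging.

# clamp probabilities away from 0/1 so log terms stay finite even when
# optim explores extreme slopes
clamp_p <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

# box bounds for the M-step searches (log a, b); generous, only there to
# stop quasi-separable configurations from running away numerically
LOGA_LO <- log(0.05)
LOGA_HI <- log(50)
B_LO <- -12
B_HI <- 12

# weighted 2PL log-likelihood pieces on the quadrature grid
wll <- function(a, b, nodes, r, n) {
  P <- clamp_p(plogis(a * (nodes - b)))
  sum(r * log(P) + (n - r) * log1p(-P))
}

# M-step for one item given expected counts.
# rl, nl: lists (per group) of expected endorsements r (Q) and expected
# respondent counts n (Q).  For a single group, pass length-1 lists and
# a_sh = b_sh = TRUE.  Returns c(aR, bR, aF, bF) (focal = reference when
# shared or single-group).
mstep_item <- function(rl, nl, nodes, aR, bR, aF, bF, a_sh, b_sh, maxit) {
  two <- length(rl) == 2

  opt <- function(par, fn, gr) {
    lo <- rep(c(LOGA_LO, B_LO), c(attr(par, "n_a"), attr(par, "n_b")))
    hi <- rep(c(LOGA_HI, B_HI), c(attr(par, "n_a"), attr(par, "n_b")))
    o <- optim(as.numeric(par), fn, gr, method = "L-BFGS-B",
               lower = lo, upper = hi, control = list(maxit = maxit))
    o$par
  }
  pr <- function(x, n_a, n_b) structure(x, n_a = n_a, n_b = n_b)

  if (!two || (a_sh && b_sh)) {
    # pooled single curve
    r <- Reduce(`+`, rl); n <- Reduce(`+`, nl)
    fn <- function(p) -wll(exp(p[1]), p[2], nodes, r, n)
    gr <- function(p) {
      a <- exp(p[1]); P <- plogis(a * (nodes - p[2])); s <- r - n * P
      c(-a * sum(s * (nodes - p[2])), a * sum(s))
    }
    p <- opt(pr(c(log(aR), bR), 1, 1), fn, gr)
    a <- exp(p[1]); b <- p[2]
    return(c(a, b, a, b))
  }
  if (a_sh && !b_sh) {
    fn <- function(p) -wll(exp(p[1]), p[2], nodes, rl[[1]], nl[[1]]) -
      wll(exp(p[1]), p[3], nodes, rl[[2]], nl[[2]])
    gr <- function(p) {
      a <- exp(p[1])
      s1 <- rl[[1]] - nl[[1]] * plogis(a * (nodes - p[2]))
      s2 <- rl[[2]] - nl[[2]] * plogis(a * (nodes - p[3]))
      c(-a * (sum(s1 * (nodes - p[2])) + sum(s2 * (nodes - p[3]))),
        a * sum(s1), a * sum(s2))
    }
    # parameter order: log a, bR, bF  (bounds: 1 slope, 2 locations)
    p <- opt(pr(c(log(aR), bR, bF), 1, 2), fn, gr)
    return(c(exp(p[1]), p[2], exp(p[1]), p[3]))
  }
  if (!a_sh && b_sh) {
    fn <- function(p) -wll(exp(p[1]), p[3], nodes, rl[[1]], nl[[1]]) -
      wll(exp(p[2]), p[3], nodes, rl[[2]], nl[[2]])
    gr <- function(p) {
      a1 <- exp(p[1]); a2 <- exp(p[2])
      s1 <- rl[[1]] - nl[[1]] * plogis(a1 * (nodes - p[3]))
      s2 <- rl[[2]] - nl[[2]] * plogis(a2 * (nodes - p[3]))
      c(-a1 * sum(s1 * (nodes - p[3])), -a2 * sum(s2 * (nodes - p[3])),
        a1 * sum(s1) + a2 * sum(s2))
    }
    p <- opt(pr(c(log(aR), log(aF), bR), 2, 1), fn, gr)
    return(c(exp(p[1]), p[3], exp(p[2]), p[3]))
  }
  # both free: groups decouple
  one <- function(r, n, a0, b0) {
    fn <- function(p) -wll(exp(p[1]), p[2], nodes, r, n)
    gr <- function(p) {
      a <- exp(p[1]); P <- plogis(a * (nodes - p[2])); s <- r - n * P
      c(-a * sum(s * (nodes - p[2])), a * sum(s))
    }
    p <- opt(pr(c(log(a0), b0), 1, 1), fn, gr)
    c(exp(p[1]), p[2])
  }
  pR <- one(rl[[1]], nl[[1]], aR, bR)
  pF <- one(rl[[2]], nl[[2]], aF, bF)
  c(pR[1], pR[2], pF[1], pF[2])
}

# M-step for the focal latent moments: maximize sum(nq * log w(mu, s2))
# over the discretized, renormalized normal weights, warm-started at the
# posterior moments.
mstep_moments <- function(nq, nodes, mu0, s20, maxit = 25) {
  N <- sum(nq)
  m1 <- sum(nq * nodes) / N
  v <- max(sum(nq * nodes^2) / N - m1^2, 1e-4)
  fn <- function(p) {
    w <- dnorm(nodes, p[1], sqrt(exp(p[2])))
    sw <- sum(w)
    if (sw <= 0 || !is.finite(sw)) return(1e10)
    -sum(nq * (log(w) - log(sw)))
  }
  o <- optim(c(m1, log(v)), fn, method = "BFGS",
             control = list(maxit = maxit))
  c(mu = o$par[1], s2 = exp(o$par[2]))
}

# core EM loop.
# pats: named list per group (reference first) from prepare_patterns();
# a, b: J x G start matrices; a_sh/b_sh: logical J (all TRUE when G = 1);
# mu/s2: focal start moments; free_moments: update them?
# Returns params, trace of the marginal log-likelihood (one value per
# E-step, evaluated at the parameters entering that E-step, plus a final
# value at the converged parameters), iteration count and flag.
em_core <- function(pats, a, b, a_sh, b_sh, mu, s2, free_moments, control) {
  groups <- names(pats)
  G <- length(groups)
  J <- ncol(pats[[1]]$Y)
  nodes <- seq(control$bounds[1], control$bounds[2],
               length.out = control$n_nodes)
  Q <- length(nodes)
  w_ref <- dnorm(nodes); w_ref <- w_ref / sum(w_ref)

  trace <- numeric(0)
  converged <- FALSE
  it <- 0
  repeat {
    it <- it + 1
    wts <- list(w_ref)
    if (G == 2) {
      wf <- dnorm(nodes, mu, sqrt(s2))
      wts[[2]] <- wf / sum(wf)
    }
    # E-step
    ll <- 0
    rl_all <- vector("list", G)
    nl_all <- vector("list", G)
    post_f <- NULL
    for (g in seq_len(G)) {
      P <- clamp_p(irf_grid(a[, g], b[, g], nodes))
      pl <- pattern_lik(pats[[g]]$Y, P, wts[[g]])
      post <- pl$A / exp(pl$ll_pat)
      ll <- ll + sum(pats[[g]]$cnt * pl$ll_pat)
      nl_all[[g]] <- colSums(pats[[g]]$cnt * post)
      rl_all[[g]] <- crossprod(pats[[g]]$Y, pats[[g]]$cnt * post)
    }
    trace <- c(trace, ll)

    # M-step: items
    max_ch <- 0
    for (j in seq_len(J)) {
      rl <- lapply(rl_all, function(r) r[j, ])
      new <- mstep_item(rl, nl_all, nodes, a[j, 1], b[j, 1],
                        a[j, G], b[j, G], a_sh[j], b_sh[j],
                        control$m_maxit)
      max_ch <- max(max_ch, abs(new[1] - a[j, 1]), abs(new[2] - b[j, 1]),
                    if (G == 2) c(abs(new[3] - a[j, 2]),
                                  abs(new[4] - b[j, 2])))
      a[j, 1] <- new[1]; b[j, 1] <- new[2]
      if (G == 2) { a[j, 2] <- new[3]; b[j, 2] <- new[4] }
    }

    # M-step: focal latent moments (fresh posterior at updated items)
    if (G == 2 && free_moments) {
      P <- clamp_p(irf_grid(a[, 2], b[, 2], nodes))
      pl <- pattern_lik(pats[[2]]$Y, P, wts[[2]])
      post <- pl$A / exp(pl$ll_pat)
      nq <- colSums(pats[[2]]$cnt * post)
      mom <- mstep_moments(nq, nodes, mu, s2)
      max_ch <- max(max_ch, abs(mom[1] - mu), abs(mom[2] - s2))
      mu <- mom[[1]]; s2 <- mom[[2]]
    }

    if (it > 1 &&
        abs(trace[it] - trace[it - 1]) < control$tol_loglik &&
        max_ch < control$tol_param) {
      converged <- TRUE
      break
    }
    if (it >= control$max_iter) break
  }

  # final log-likelihood at the converged parameters
  wts <- list(w_ref)
  if (G == 2) {
    wf <- dnorm(nodes, mu, sqrt(s2)); wts[[2]] <- wf / sum(wf)
  }
  ll <- 0
  for (g in seq_len(G)) {
    P <- clamp_p(irf_grid(a[, g], b[, g], nodes))
    pl <- pattern_lik(pats[[g]]$Y, P, wts[[g]])
    ll <- ll + sum(pats[[g]]$cnt * pl$ll_pat)
  }
  trace <- c(trace, ll)

  list(a = a, b = b, mu = mu, s2 = s2, loglik = ll, trace = trace,
       n_iterations = it, converged = converged)
}

# ---- free-parameter bookkeeping (used by the SE machinery) ----

# Enumerate the freely estimated parameters of a fit as a data frame with
# columns name/what/item/group, in a fixed order.
param_map <- function(bank, free_moments) {
  G <- length(bank$groups)
  rows <- list()
  for (j in seq_along(bank$item_ids)) {
    id <- bank$item_ids[j]
    if (G == 1 || bank$a_shared[j]) {
      rows[[length(rows) + 1]] <- data.frame(
        name = paste0("a:", id), what = "a", item = id, group = "",
        stringsAsFactors = FALSE)
    } else {
      for (g in bank$groups)
        rows[[length(rows) + 1]] <- data.frame(
          name = paste0("a:", id, ":", g), what = "a", item = id,
          group = g, stringsAsFactors = FALSE)
    }
    if (G == 1 || bank$b_shared[j]) {
      rows[[length(rows) + 1]] <- data.frame(
        name = paste0("b:", id), what = "b", item = id, group = "",
        stringsAsFactors = FALSE)
    } else {
      for (g in bank$groups)
        rows[[length(rows) + 1]] <- data.frame(
          name = paste0("b:", id, ":", g), what = "b", item = id,
          group = g, stringsAsFactors = FALSE)
    }
  }
  if (G == 2 && free_moments) {
    foc <- bank$groups[2]
    rows[[length(rows) + 1]] <- data.frame(
      name = paste0("mean:", foc), what = "mean", item = "", group = foc,
      stringsAsFactors = FALSE)
    rows[[length(rows) + 1]] <- data.frame(
      name = paste0("variance:", foc), what = "variance", item = "",
      group = foc, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# bank/latent -> numeric vector along the map
pack_params <- function(map, bank, latent) {
  vapply(seq_len(nrow(map)), function(k) {
    m <- map[k, ]
    if (m$what %in% c("a", "b")) {
      j <- match(m$item, bank$item_ids)
      g <- if (m$group == "") 1L else match(m$group, bank$groups)
      if (m$what == "a") bank$a[j, g] else bank$b[j, g]
    } else if (m$what == "mean") latent$mean[m$group]
    else latent$variance[m$group]
  }, numeric(1))
}

# numeric vector -> updated bank/latent (values only, structure kept)
unpack_params <- function(x, map, bank, latent) {
  for (k in seq_len(nrow(map))) {
    m <- map[k, ]
    if (m$what %in% c("a", "b")) {
      j <- match(m$item, bank$item_ids)
      gs <- if (m$group == "") seq_along(bank$groups)
            else match(m$group, bank$groups)
      if (m$what == "a") bank$a[j, gs] <- x[k] else bank$b[j, gs] <- x[k]
    } else if (m$what == "mean") latent$mean[m$group] <- x[k]
    else latent$variance[m$group] <- x[k]
  }
  list(bank = bank, latent = latent)
}

# central-difference Hessian of a scalar function
num_hessian <- function(f, x, rel_step = 1e-3) {
  p <- length(x)
  h <- rel_step * (abs(x) + 1)
  H <- matrix(NA_real_, p, p)
  f0 <- f(x)
  shift <- function(i, d) { y <- x; y[i] <- y[i] + d; y }
  for (i in seq_len(p)) {
    H[i, i] <- (f(shift(i, h[i])) - 2 * f0 + f(shift(i, -h[i]))) / h[i]^2
    if (i < p) for (j in seq((i + 1), p)) {
      y <- x
      fpp <- f({ y2 <- x; y2[i] <- y2[i] + h[i]; y2[j] <- y2[j] + h[j]; y2 })
      fpm <- f({ y2 <- x; y2[i] <- y2[i] + h[i]; y2[j] <- y2[j] - h[j]; y2 })
      fmp <- f({ y2 <- x; y2[i] <- y2[i] - h[i]; y2[j] <- y2[j] + h[j]; y2 })
      fmm <- f({ y2 <- x; y2[i] <- y2[i] - h[i]; y2[j] <- y2[j] - h[j]; y2 })
      H[i, j] <- H[j, i] <- (fpp - fpm - fmp + fmm) / (4 * h[i] * h[j])
    }
  }
  H
}
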