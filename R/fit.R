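#' Estimation control settings
#'
#' Numerical settings of the Bock-Aitkin EM: quadrature density, stopping
#' rules and the per-item inner-maximization budget.
#'
#' @param n_nodes Quadrature nodes, equally spaced (default 61).
#' @param bounds Quadrature range on the latent scale (default `[-6, 6]`).
#' @param tol_loglik Stop when the log-likelihood improves by less than
#'   this between EM cycles (default 1e-5) ...
#' @param tol_param ... and no parameter moves by more than this
#'   (default 1e-4).
#' @param max_iter Maximum EM cycles (default 500).
#' @param m_maxit Inner L-BFGS-B iterations per item per M-step.
#' @return A list of class `irt_control`.
#' @export
irt_control <- function(n_nodes = 61, bounds = c(-6, 6),
                        tol_loglik = 1e-5, tol_param = 1e-4,
                        max_iter = 500, m_maxit = 30) {
  stopifnot(n_nodes >= 11, bounds[1] < bounds[2], tol_loglik > 0,
            tol_param > 0, max_iter >= 1)
  structure(list(n_nodes = n_nodes, bounds = bounds,
                 tol_loglik = tol_loglik, tol_param = tol_param,
                 max_iter = max_iter, m_maxit = m_maxit),
            class = "irt_control")
}

# items must show response variation wherever a parameter of theirs is
# estimated: per group for group-specific items, pooled for shared ones
check_boundaries <- function(pats, item_ids, a_sh, b_sh) {
  G <- length(pats)
  J <- length(item_ids)
  for (j in seq_len(J)) {
    per_group <- G == 2 && (!a_sh[j] || !b_sh[j])
    if (per_group) {
      for (g in names(pats)) {
        y <- rep(pats[[g]]$Y[, j], times = pats[[g]]$cnt)
        if (length(unique(y)) < 2)
          stop(sprintf(
            "item '%s' has all-%d responses in group '%s'; its group-specific parameters are not estimable",
            item_ids[j], y[1], g), call. = FALSE)
      }
    } else {
      y <- unlist(lapply(pats, function(p)
        rep(p$Y[, j], times = p$cnt)))
      if (length(unique(y)) < 2)
        stop(sprintf("item '%s' has all-%d responses; not estimable",
                     item_ids[j], y[1]), call. = FALSE)
    }
  }
  invisible(TRUE)
}

# shared start-value logic: neutral a = 1, b = 0 unless `start` supplies
# values (an item_bank or a previous irt_fit over the same items)
start_values <- function(start, item_ids, groups) {
  J <- length(item_ids); G <- length(groups)
  a <- matrix(1, J, G); b <- matrix(0, J, G)
  mu <- 0; s2 <- 1
  if (!is.null(start)) {
    sb <- if (inherits(start, "irt_fit")) start$bank else start
    stopifnot(inherits(sb, "item_bank"))
    if (!identical(sb$item_ids, item_ids))
      stop("`start` must cover the same items in the same order",
           call. = FALSE)
    idx <- match(groups, sb$groups)
    idx[is.na(idx)] <- 1L
    a <- sb$a[, idx, drop = FALSE]
    b <- sb$b[, idx, drop = FALSE]
    if (inherits(start, "irt_fit") && length(start$latent$groups) == 2) {
      foc <- start$latent$groups[2]
      mu <- unname(start$latent$mean[foc])
      s2 <- unname(start$latent$variance[foc])
    }
  }
  list(a = unname(a), b = unname(b), mu = mu, s2 = s2)
}

make_fit <- function(res, item_ids, groups, a_sh, b_sh, anchors,
                     free_moments, pats, control, se) {
  G <- length(groups)
  bank <- item_bank(item_ids, res$a, res$b, groups = groups,
                    a_shared = a_sh, b_shared = b_sh, anchors = anchors)
  latent <- if (G == 1) latent_distribution(groups)
  else latent_distribution(groups, mean = c(0, res$mu),
                           variance = c(1, res$s2))
  fit <- structure(
    list(bank = bank, latent = latent, loglik = res$loglik,
         n_iterations = res$n_iterations, converged = res$converged,
         trace = res$trace,
         free_moments = G == 2 && free_moments,
         n = vapply(pats, function(p) as.integer(p$n), integer(1)),
         control = control, standard_errors = NULL, vcov = NULL),
    class = "irt_fit")
  if (se) {
    if (!res$converged)
      warning("EM did not converge; standard errors not computed",
              call. = FALSE)
    else {
      ses <- se_from_patterns(fit, pats)
      fit$standard_errors <- ses$se
      fit$vcov <- ses$vcov
    }
  }
  fit
}

#' Fit the 2PL model to a single group
#'
#' Marginal maximum likelihood via Bock-Aitkin EM: the E-step computes
#' expected response counts at the quadrature nodes under the current
#' posterior, the M-step refits each item's two-parameter logistic curve
#' to those expected counts.  The latent trait is fixed at Normal(0, 1),
#' which identifies the scale.  The marginal log-likelihood is
#' nondecreasing across cycles.
#'
#' @param data A complete [response_matrix()] containing exactly one
#'   group.
#' @param start Optional starting values: an [item_bank()] or a previous
#'   `irt_fit` over the same items.  Default: `a = 1`, `b = 0`.
#' @param se Compute standard errors (square roots of the diagonal of the
#'   inverse observed information, by central finite differences)?
#' @param control An [irt_control()].
#' @return An object of class `irt_fit`: estimated [item_bank()] and
#'   [latent_distribution()], `loglik`, per-cycle log-likelihood `trace`,
#'   `n_iterations`, `converged`, and (if requested) `standard_errors`
#'   and `vcov` for every freely estimated parameter.
#' @export
#' @examples
#' cfg <- sim_config(
#'   bank = item_bank(c("i1", "i2", "i3"), a = c(1.5, 2, 2.5),
#'                    b = c(-0.5, 0, 0.5), groups = "g"),
#'   latent = latent_distribution("g"),
#'   n_per_group = c(g = 400), seed = 1)
#' fit <- fit_single_group(simulate_checklist(cfg), se = FALSE)
#' fit
fit_single_group <- function(data, start = NULL, se = TRUE,
                             control = irt_control()) {
  stopifnot(inherits(data, "response_matrix"),
            inherits(control, "irt_control"))
  pats <- prepare_patterns(data)
  if (length(pats) != 1)
    stop("data contain more than one group; use fit_multigroup()",
         call. = FALSE)
  groups <- names(pats)
  J <- length(data$item_ids)
  a_sh <- b_sh <- rep(TRUE, J)
  check_boundaries(pats, data$item_ids, a_sh, b_sh)
  sv <- start_values(start, data$item_ids, groups)
  res <- em_core(pats, sv$a, sv$b, a_sh, b_sh, sv$mu, sv$s2,
                 free_moments = FALSE, control = control)
  make_fit(res, data$item_ids, groups, a_sh, b_sh, character(),
           free_moments = FALSE, pats = pats, control = control, se = se)
}

#' Fit the 2PL model jointly to two groups
#'
#' Joint Bock-Aitkin EM over both groups.  Parameters marked shared in
#' `bank` are pooled across groups in the M-step; group-specific
#' parameters are estimated per group.  The reference group's latent
#' distribution is fixed at Normal(0, 1); the focal group's mean and
#' variance are (by default) freely estimated each cycle from the
#' posterior distribution of the latent trait in that group, and the
#' focal quadrature weights are re-normalized accordingly.  A nonempty
#' anchor set (items shared in both parameters by assertion) is required
#' for identification.
#'
#' @param data A complete [response_matrix()] containing both groups.
#' @param bank An [item_bank()] carrying the equality-constraint pattern
#'   (`a_shared`/`b_shared` per item) and the anchor set; its groups must
#'   match the data's groups.
#' @param anchors Anchor item ids; default: `bank$anchors`.
#' @param start Optional starting values (an [item_bank()] or previous
#'   `irt_fit`); default `a = 1`, `b = 0`, focal moments 0/1.
#' @param free_moments Estimate the focal group's latent mean and
#'   variance (default `TRUE`)?
#' @param se Compute standard errors?
#' @param control An [irt_control()].
#' @return An `irt_fit`; see [fit_single_group()].
#' @export
fit_multigroup <- function(data, bank, anchors = bank$anchors,
                           start = NULL, free_moments = TRUE, se = TRUE,
                           control = irt_control()) {
  stopifnot(inherits(data, "response_matrix"),
            inherits(bank, "item_bank"),
            inherits(control, "irt_control"))
  if (!identical(data$item_ids, bank$item_ids))
    stop("data and bank must use the same items in the same order",
         call. = FALSE)
  pats <- prepare_patterns(data)
  if (length(pats) == 1)
    stop("data contain a single group; use fit_single_group()",
         call. = FALSE)
  groups <- names(pats)   # reference first (factor level order)
  if (!identical(groups, bank$groups))
    stop(sprintf(
      "bank groups (%s) must match the data's groups in order (%s; reference first)",
      paste(bank$groups, collapse = ", "), paste(groups, collapse = ", ")),
      call. = FALSE)
  anchors <- as.character(anchors)
  if (length(anchors) == 0)
    stop(paste("empty anchor set: the latent metric is not identified",
               "across groups without at least one anchor item"),
         call. = FALSE)
  if (!all(anchors %in% bank$item_ids))
    stop("anchors must be items of the bank", call. = FALSE)
  anc <- bank$item_ids %in% anchors
  if (any(anc & (!bank$a_shared | !bank$b_shared)))
    stop("anchor items must be shared in both parameters", call. = FALSE)

  a_sh <- bank$a_shared; b_sh <- bank$b_shared
  check_boundaries(pats, bank$item_ids, a_sh, b_sh)
  sv <- start_values(start, bank$item_ids, groups)
  res <- em_core(pats, sv$a, sv$b, a_sh, b_sh, sv$mu, sv$s2,
                 free_moments = free_moments, control = control)
  make_fit(res, bank$item_ids, groups, a_sh, b_sh, anchors,
           free_moments = free_moments, pats = pats, control = control,
           se = se)
}

# observed-information SEs from pattern-collapsed data
se_from_patterns <- function(fit, pats) {
  map <- param_map(fit$bank, fit$free_moments)
  x0 <- pack_params(map, fit$bank, fit$latent)
  nodes <- seq(fit$control$bounds[1], fit$control$bounds[2],
               length.out = fit$control$n_nodes)
  groups <- names(pats)
  f <- function(x) {
    st <- unpack_params(x, map, fit$bank, fit$latent)
    if (any(st$bank$a <= 0) || any(st$latent$variance <= 0)) return(-Inf)
    ll <- 0
    for (g in seq_along(groups)) {
      w <- dnorm(nodes, st$latent$mean[groups[g]],
                 sqrt(st$latent$variance[groups[g]]))
      w <- w / sum(w)
      P <- clamp_p(irf_grid(st$bank$a[, g], st$bank$b[, g], nodes))
      pl <- pattern_lik(pats[[g]]$Y, P, w)
      ll <- ll + sum(pats[[g]]$cnt * pl$ll_pat)
    }
    ll
  }
  H <- num_hessian(f, x0)
  info <- -H
  V <- tryCatch(solve(info), error = function(e)
    stop(paste("observed information is not invertible; the model is",
               "likely empirically unidentified for these data"),
         call. = FALSE))
  d <- diag(V)
  if (any(!is.finite(d)) || any(d <= 0))
    stop(paste("observed information is not positive definite; the model",
               "is likely empirically unidentified for these data"),
         call. = FALSE)
  dimnames(V) <- list(map$name, map$name)
  list(se = setNames(sqrt(d), map$name), vcov = V)
}

#' Standard errors of a converged fit
#'
#' Recomputes the observed information of the marginal log-likelihood at
#' the estimates by central finite differences and returns the square
#' roots of the diagonal of its inverse.  One entry per freely estimated
#' parameter; constrained parameters have none.
#'
#' @param fit A converged `irt_fit`.
#' @param data The [response_matrix()] the fit was estimated from.
#' @return Named numeric vector of standard errors.
#' @export
standard_errors <- function(fit, data) {
  stopifnot(inherits(fit, "irt_fit"))
  if (!fit$converged)
    stop("fit did not converge; standard errors are not meaningful",
         call. = FALSE)
  se_from_patterns(fit, prepare_patterns(data))$se
}

#' @export
print.irt_fit <- function(x, digits = 3, ...) {
  G <- length(x$bank$groups)
  cat(sprintf("<irt_fit> 2PL, %s, %d item(s)\n",
              if (G == 1) "single group" else "two groups",
              length(x$bank$item_ids)))
  cat(sprintf("  n = %s;  loglik = %.3f;  %d EM cycles (%s)\n",
              paste(sprintf("%s: %d", names(x$n), x$n), collapse = ", "),
              x$loglik, x$n_iterations,
              if (x$converged) "converged" else "NOT converged"))
  print(x$bank, digits = digits)
  if (G == 2) {
    foc <- x$latent$groups[2]
    cat(sprintf("  focal latent moments (%s): mean = %.3f, variance = %.3f\n",
                foc, x$latent$mean[foc], x$latent$variance[foc]))
  }
  if (!is.null(x$standard_errors))
    cat(sprintf("  standard errors available for %d parameters\n",
                length(x$standard_errors)))
  invisible(x)
}

#' Export fit results to a delimited report
#'
#' Writes two files: `<stem>_parameters.csv` (one row per freely
#' estimated parameter with estimate and standard error) and
#' `<stem>_trace.csv` (per-cycle log-likelihood).
#'
#' @param fit An `irt_fit`.
#' @param stem Output path stem (no extension).
#' @return The parameter file path, invisibly.
#' @export
write_fit <- function(fit, stem) {
  stopifnot(inherits(fit, "irt_fit"))
  map <- param_map(fit$bank, fit$free_moments)
  est <- pack_params(map, fit$bank, fit$latent)
  out <- data.frame(parameter = map$name, what = map$what,
                    item = map$item, group = map$group,
                    estimate = est,
                    se = if (!is.null(fit$standard_errors))
                      fit$standard_errors[map$name] else NA_real_,
                    stringsAsFactors = FALSE)
  pfile <- paste0(stem, "_parameters.csv")
  write.csv(out, pfile, row.names = FALSE)
  write.csv(data.frame(cycle = seq_along(fit$trace), loglik = fit$trace),
            paste0(stem, "_trace.csv"), row.names = FALSE)
  invisible(pfile)
}
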