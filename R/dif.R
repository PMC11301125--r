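#' Bonferroni-corrected per-item significance threshold
#'
#' Divides the familywise alpha by the number of checklist items, so that
#' testing every item keeps the familywise error rate at `familywise`.
#' For an 11-item checklist at familywise 0.05 this gives 0.05 / 11 =
#' 0.004545..., conventionally displayed as .0045.
#'
#' @param familywise Familywise significance level in (0, 1).
#' @param m Number of items tested (>= 1).
#' @return The per-item threshold `familywise / m`.
#' @export
#' @examples
#' bonferroni_alpha(0.05, 11)
bonferroni_alpha <- function(familywise, m) {
  stopifnot(is.numeric(familywise), familywise > 0, familywise < 1,
            m >= 1)
  familywise / m
}

#' DIF testing configuration
#'
#' @param familywise_alpha Familywise significance level (default 0.05).
#' @param n_items_tested Bonferroni divisor.  By convention this is the
#'   full item count of the checklist (anchors included), so the
#'   threshold does not depend on the anchor choice; default `NULL`
#'   resolves to the item count of the data at test time.
#' @return A list of class `dif_config` with the derived
#'   `per_item_alpha` filled in at run time.
#' @export
dif_config <- function(familywise_alpha = 0.05, n_items_tested = NULL) {
  stopifnot(familywise_alpha > 0, familywise_alpha < 1)
  structure(list(familywise_alpha = familywise_alpha,
                 n_items_tested = n_items_tested),
            class = "dif_config")
}

# fit with item j's sharing pattern overridden; warm-started
refit_freed <- function(data, bank, item, free_a, free_b, anchors, start,
                        control) {
  j <- match(item, bank$item_ids)
  a_sh <- bank$a_shared; b_sh <- bank$b_shared
  if (free_a) a_sh[j] <- FALSE
  if (free_b) b_sh[j] <- FALSE
  newbank <- item_bank(bank$item_ids, bank$a, bank$b, groups = bank$groups,
                       a_shared = a_sh, b_shared = b_sh, anchors = anchors)
  fit_multigroup(data, newbank, anchors = anchors, start = start,
                 se = FALSE, control = control)
}

#' Likelihood-ratio DIF test for one item
#'
#' Compares a constrained model, in which the item's parameters are equal
#' across groups, to models freeing them.  The joint test frees both `a`
#' and `b` (2 df); when it is significant, 1-df follow-up tests freeing
#' `a` only and `b` only localize which parameter differs.  Statistics
#' are twice the log-likelihood difference, with p-values from the
#' chi-square distribution.
#'
#' @param data A complete two-group [response_matrix()].
#' @param bank Constraint pattern under the null (the item must be shared
#'   in both parameters); other items keep their pattern.
#' @param item Item id to test (must not be an anchor).
#' @param anchors Anchor item ids.
#' @param constrained Optional pre-computed constrained `irt_fit` (the
#'   fit of `bank` itself); supplied by [detect_dif()] to avoid refits.
#' @param localize Run the 1-df follow-ups whenever the joint test's
#'   p-value falls below this threshold (default 1: always).
#' @param control An [irt_control()].
#' @return A list of class `dif_test`: `item`, `joint`, and (when run)
#'   `a_only` / `b_only`, each a vector `(statistic, df, p)`, plus the
#'   fitted models.
#' @export
lr_test_item <- function(data, bank, item, anchors = bank$anchors,
                         constrained = NULL, localize = 1,
                         control = irt_control()) {
  stopifnot(inherits(bank, "item_bank"))
  j <- match(item, bank$item_ids)
  if (is.na(j)) stop(sprintf("unknown item '%s'", item), call. = FALSE)
  if (item %in% anchors)
    stop(sprintf("item '%s' is an anchor and cannot be tested", item),
         call. = FALSE)
  if (!bank$a_shared[j] || !bank$b_shared[j])
    stop(sprintf("item '%s' is already group-specific under the null",
                 item), call. = FALSE)
  if (is.null(constrained))
    constrained <- fit_multigroup(data, bank, anchors = anchors,
                                  se = FALSE, control = control)
  both <- refit_freed(data, bank, item, TRUE, TRUE, anchors,
                      start = constrained, control = control)
  if (!constrained$converged || !both$converged)
    stop(sprintf(
      "non-converged fit while testing item '%s' (constrained: %s, freed: %s)",
      item, constrained$converged, both$converged), call. = FALSE)
  lr_stat <- function(fit) max(0, 2 * (fit$loglik - constrained$loglik))
  tst <- function(stat, df) c(statistic = stat, df = df,
                              p = pchisq(stat, df, lower.tail = FALSE))
  out <- list(item = item, joint = tst(lr_stat(both), 2),
              fit_constrained = constrained, fit_both = both)
  if (out$joint[["p"]] < localize) {
    fa <- refit_freed(data, bank, item, TRUE, FALSE, anchors,
                      start = constrained, control = control)
    fb <- refit_freed(data, bank, item, FALSE, TRUE, anchors,
                      start = constrained, control = control)
    if (!fa$converged || !fb$converged)
      stop(sprintf("non-converged localization fit for item '%s'", item),
           call. = FALSE)
    out$a_only <- tst(lr_stat(fa), 1)
    out$b_only <- tst(lr_stat(fb), 1)
    out$fit_a <- fa
    out$fit_b <- fb
  }
  structure(out, class = "dif_test")
}

#' Iterative anchored DIF detection
#'
#' Stepwise purification procedure: starting from a model in which every
#' item is constrained equal across groups (with the focal group's latent
#' moments free), each non-anchor item still held equal is tested with a
#' 2-df likelihood-ratio test at the Bonferroni-corrected per-item level.
#' The most significant item (smallest p, ties broken by item order) has
#' its differing parameter(s) freed -- those individually significant in
#' 1-df follow-ups, or both when only the joint test is significant --
#' and all remaining items are re-tested against the updated model.  The
#' loop ends when no further item reaches significance; a final refit
#' with standard errors yields the report.
#'
#' Anchors are never tested, so the anchor set identifies the latent
#' metric throughout.  The procedure contains no randomness: a given
#' dataset always yields the same report.
#'
#' @param data A complete two-group [response_matrix()].
#' @param anchors Anchor item ids (nonempty).
#' @param config A [dif_config()].
#' @param control An [irt_control()].
#' @param quiet Suppress progress messages.
#' @return An object of class `dif_report`: `items` (per-item test
#'   table), `flagged` (item ids with DIF), `anchors`,
#'   `per_item_alpha`, `fit` (final multigroup `irt_fit` with standard
#'   errors) and `baseline_loglik`.
#' @export
detect_dif <- function(data, anchors, config = dif_config(),
                       control = irt_control(), quiet = FALSE) {
  stopifnot(inherits(data, "response_matrix"),
            inherits(config, "dif_config"))
  item_ids <- data$item_ids
  J <- length(item_ids)
  anchors <- as.character(anchors)
  if (!all(anchors %in% item_ids))
    stop("anchors must be items of the data", call. = FALSE)
  m <- if (is.null(config$n_items_tested)) J else config$n_items_tested
  alpha <- bonferroni_alpha(config$familywise_alpha, m)

  groups <- group_levels(data)
  bank <- item_bank(item_ids, a = rep(1, J), b = rep(0, J),
                    groups = groups, anchors = anchors)
  cur <- fit_multigroup(data, bank, anchors = anchors, se = FALSE,
                        control = control)
  baseline_loglik <- cur$loglik

  tests <- list()          # latest dif_test per item
  flagged <- character(0)
  flag_a <- flag_b <- setNames(rep(FALSE, J), item_ids)
  iteration <- setNames(rep(NA_integer_, J), item_ids)
  it <- 0
  repeat {
    it <- it + 1
    cand <- setdiff(item_ids, c(anchors, flagged))
    if (length(cand) == 0) break
    for (id in cand) {
      tests[[id]] <- lr_test_item(data, cur$bank, id, anchors = anchors,
                                  constrained = cur, localize = alpha,
                                  control = control)
      iteration[id] <- it
    }
    ps <- vapply(tests[cand], function(t) t$joint[["p"]], numeric(1))
    if (min(ps) >= alpha) break
    winner <- cand[which.min(ps)]     # which.min: first minimum wins ties
    tw <- tests[[winner]]
    fa <- tw$a_only[["p"]] < alpha
    fb <- tw$b_only[["p"]] < alpha
    if (!fa && !fb) fa <- fb <- TRUE  # joint-only significance: free both
    flag_a[winner] <- fa
    flag_b[winner] <- fb
    flagged <- c(flagged, winner)
    if (!quiet)
      message(sprintf(
        "iteration %d: freeing %s for '%s' (joint p = %.2e)", it,
        paste(c("a", "b")[c(fa, fb)], collapse = " and "), winner,
        tw$joint[["p"]]))
    cur <- if (fa && fb) tw$fit_both else if (fa) tw$fit_a else tw$fit_b
  }
  if (any(flagged %in% anchors))
    stop("internal consistency error: anchor item flagged", call. = FALSE)

  final <- fit_multigroup(data, cur$bank, anchors = anchors, start = cur,
                          se = TRUE, control = control)

  row1 <- function(id) {
    t <- tests[[id]]
    getp <- function(part, k) if (!is.null(t) && !is.null(t[[part]]))
      t[[part]][[k]] else NA_real_
    data.frame(
      item = id, anchor = id %in% anchors,
      lr_joint = getp("joint", "statistic"), df_joint = 2,
      p_joint = getp("joint", "p"),
      lr_a = getp("a_only", "statistic"), p_a = getp("a_only", "p"),
      lr_b = getp("b_only", "statistic"), p_b = getp("b_only", "p"),
      flag_a = flag_a[[id]], flag_b = flag_b[[id]],
      iteration = iteration[[id]],
      stringsAsFactors = FALSE)
  }
  items <- do.call(rbind, lapply(item_ids, row1))
  rownames(items) <- NULL

  structure(
    list(items = items, flagged = flagged, anchors = anchors,
         familywise_alpha = config$familywise_alpha,
         per_item_alpha = alpha, n_items_tested = m,
         fit = final, baseline_loglik = baseline_loglik),
    class = "dif_report")
}

#' @export
print.dif_report <- function(x, digits = 3, ...) {
  cat(sprintf(
    "<dif_report> %d item(s) with DIF at per-item alpha %.4g (familywise %.2g / %d)\n",
    length(x$flagged), x$per_item_alpha, x$familywise_alpha,
    x$n_items_tested))
  if (length(x$flagged) > 0)
    cat("  flagged:", paste(x$flagged, collapse = ", "), "\n")
  cat("  anchors:", paste(x$anchors, collapse = ", "), "\n")
  df <- x$items
  df$p_joint <- signif(df$p_joint, 3)
  df$lr_joint <- round(df$lr_joint, 2)
  print(df[, c("item", "anchor", "lr_joint", "p_joint", "flag_a",
               "flag_b", "iteration")], row.names = FALSE)
  cat(sprintf("  baseline loglik %.3f -> final %.3f\n",
              x$baseline_loglik, x$fit$loglik))
  invisible(x)
}

#' Export a DIF report to delimited files
#'
#' Writes `<stem>_tests.csv` (per-item statistics) and
#' `<stem>_parameters.csv` (final parameter table in the conventional
#' published layout: reference columns always filled, focal columns
#' dashed for parameters fixed equal across groups, anchors marked).
#'
#' @param report A `dif_report`.
#' @param stem Output path stem.
#' @return The parameter file path, invisibly.
#' @export
write_dif_report <- function(report, stem) {
  stopifnot(inherits(report, "dif_report"))
  write.csv(report$items, paste0(stem, "_tests.csv"), row.names = FALSE)
  bank <- report$fit$bank
  fmt <- function(v) format(round(v, 2))
  tab <- data.frame(
    item = bank$item_ids,
    anchor = ifelse(bank$item_ids %in% bank$anchors, "*", ""),
    stringsAsFactors = FALSE)
  tab[[paste0("a_", bank$groups[1])]] <- fmt(bank$a[, 1])
  tab[[paste0("b_", bank$groups[1])]] <- fmt(bank$b[, 1])
  tab[[paste0("a_", bank$groups[2])]] <-
    ifelse(bank$a_shared, "-", fmt(bank$a[, 2]))
  tab[[paste0("b_", bank$groups[2])]] <-
    ifelse(bank$b_shared, "-", fmt(bank$b[, 2]))
  pfile <- paste0(stem, "_parameters.csv")
  write.csv(tab, pfile, row.names = FALSE)
  invisible(pfile)
}
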