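#' DSM-5 severity rule for criteria counts
#'
#' Maps a criteria count to a diagnostic severity category.  The default
#' is the DSM-5 convention for an 11-criterion disorder: 0-1 criteria no
#' diagnosis, 2-3 mild, 4-5 moderate, 6-11 severe; the diagnostic
#' threshold is >= 2 criteria.
#'
#' @param breaks Lower bounds of the mild, moderate and severe categories
#'   (increasing integers).
#' @param labels Category labels (length `length(breaks) + 1`).
#' @param max_count Largest valid criteria count (the item count).
#' @return An object of class `severity_rule`.
#' @export
severity_rule <- function(breaks = c(2, 4, 6),
                          labels = c("no_aud", "mild", "moderate",
                                     "severe"),
                          max_count = 11) {
  stopifnot(all(diff(breaks) > 0), breaks[1] >= 1,
            breaks[length(breaks)] <= max_count,
            length(labels) == length(breaks) + 1)
  structure(list(breaks = breaks, labels = labels,
                 max_count = as.integer(max_count)),
            class = "severity_rule")
}

#' Count endorsed criteria
#'
#' Row sums of the binary responses; defined only for complete data.
#'
#' @param x A complete [response_matrix()], or a binary matrix.
#' @return Integer vector of counts in `0..J`.
#' @export
criteria_count <- function(x) {
  resp <- if (inherits(x, "response_matrix")) x$responses else as.matrix(x)
  if (anyNA(resp))
    stop("responses contain missing values; run filter_complete() first",
         call. = FALSE)
  as.integer(rowSums(resp))
}

#' Categorize criteria counts into severity levels
#'
#' @param count Integer vector of criteria counts.
#' @param rule A [severity_rule()].
#' @return Factor of severity categories (all rule labels as levels).
#' @export
#' @examples
#' severity_category(c(0, 1, 2, 4, 6, 11))
severity_category <- function(count, rule = severity_rule()) {
  stopifnot(inherits(rule, "severity_rule"))
  if (any(count < 0 | count > rule$max_count | count != floor(count)))
    stop(sprintf("criteria counts must be integers in 0..%d",
                 rule$max_count), call. = FALSE)
  cut(count, breaks = c(-Inf, rule$breaks - 0.5, Inf),
      labels = rule$labels)
}

# Wilson score interval for a binomial proportion
wilson_ci <- function(x, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  cbind(lower = pmax(0, ctr - hw), upper = pmin(1, ctr + hw))
}

#' Unadjusted severity and item-endorsement tabulation
#'
#' The descriptive layer of a checklist analysis: per group, item
#' endorsement counts and proportions, severity-category counts and
#' proportions (with Wilson 95% confidence intervals), and the mean
#' criteria count; plus, when two groups are present, a chi-square
#' comparison of the severity distributions.  All quantities are raw
#' (unadjusted for covariates).
#'
#' @param data A complete [response_matrix()].
#' @param rule A [severity_rule()].
#' @param conf Confidence level for the Wilson intervals.
#' @return An object of class `severity_summary`: `items` and
#'   `severity` data frames, `n` per group, `mean_criteria` per group,
#'   and `comparison` (the chi-square test, or `NULL` for one group).
#' @export
tabulate_severity <- function(data, rule = severity_rule(), conf = 0.95) {
  stopifnot(inherits(data, "response_matrix"))
  counts <- criteria_count(data)
  groups <- group_levels(data)
  present <- groups[groups %in% as.character(data$group)]
  if (length(present) == 0) stop("no data to tabulate", call. = FALSE)
  for (g in present)
    if (sum(data$group == g) == 0)
      stop(sprintf("group '%s' is empty", g), call. = FALSE)

  item_rows <- list(); sev_rows <- list()
  for (g in present) {
    sel <- data$group == g
    n <- sum(sel)
    x <- colSums(data$responses[sel, , drop = FALSE])
    ci <- wilson_ci(x, n, conf)
    item_rows[[g]] <- data.frame(
      group = g, item = data$item_ids, n = n, endorsed = as.integer(x),
      proportion = x / n, ci_lower = ci[, 1], ci_upper = ci[, 2],
      stringsAsFactors = FALSE)
    cat_tab <- table(severity_category(counts[sel], rule))
    ci2 <- wilson_ci(as.integer(cat_tab), n, conf)
    sev_rows[[g]] <- data.frame(
      group = g, category = names(cat_tab), n = n,
      count = as.integer(cat_tab),
      proportion = as.integer(cat_tab) / n,
      ci_lower = ci2[, 1], ci_upper = ci2[, 2],
      stringsAsFactors = FALSE)
  }
  comparison <- NULL
  if (length(present) == 2) {
    tab <- table(data$group, severity_category(counts, rule))
    comparison <- suppressWarnings(chisq.test(tab))
  }
  structure(
    list(items = do.call(rbind, c(item_rows, make.row.names = FALSE)),
         severity = do.call(rbind, c(sev_rows, make.row.names = FALSE)),
         n = vapply(present, function(g) sum(data$group == g), integer(1)),
         mean_criteria = vapply(present, function(g)
           mean(counts[data$group == g]), numeric(1)),
         rule = rule, comparison = comparison),
    class = "severity_summary")
}

#' @export
print.severity_summary <- function(x, digits = 3, ...) {
  cat("<severity_summary> (unadjusted tabulation)\n")
  df <- x$severity
  df$proportion <- round(df$proportion, digits)
  df$ci_lower <- round(df$ci_lower, digits)
  df$ci_upper <- round(df$ci_upper, digits)
  print(df, row.names = FALSE)
  cat("  mean criteria count:",
      paste(sprintf("%s = %.2f", names(x$mean_criteria),
                    x$mean_criteria), collapse = ", "), "\n")
  if (!is.null(x$comparison))
    cat(sprintf(
      "  severity distribution across groups: X2 = %.2f, df = %d, p = %.3g\n",
      unname(x$comparison$statistic), unname(x$comparison$parameter),
      x$comparison$p.value))
  invisible(x)
}

#' Export a severity summary to delimited files
#'
#' Writes `<stem>_severity.csv` and `<stem>_items.csv`.
#'
#' @param x A `severity_summary`.
#' @param stem Output path stem.
#' @return The severity file path, invisibly.
#' @export
write_severity_summary <- function(x, stem) {
  stopifnot(inherits(x, "severity_summary"))
  sfile <- paste0(stem, "_severity.csv")
  write.csv(x$severity, sfile, row.names = FALSE)
  write.csv(x$items, paste0(stem, "_items.csv"), row.names = FALSE)
  invisible(sfile)
}
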