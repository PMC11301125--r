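#' Expected test score at given latent severities
#'
#' The model-implied total score: at each latent value, the sum over
#' items of the endorsement probabilities the bank resolves for the
#' group.  Bounded by 0 and the item count, and strictly increasing in
#' the latent trait.
#'
#' @param bank An [item_bank()].
#' @param group Group name.
#' @param theta Numeric vector of latent values.
#' @return Numeric vector of expected scores.
#' @export
#' @examples
#' expected_test_score(asc_item_bank(), "in_clinic", c(-1, 0, 1))
expected_test_score <- function(bank, group, theta) {
  pars <- resolve_items(bank, group)
  colSums(irf_grid(pars$a, pars$b, theta))
}

#' Cumulative DIF impact on total scores
#'
#' Computes both groups' expected-test-score curves on a common latent
#' grid and their pointwise difference (focal minus reference).  The
#' headline summary is the maximum absolute difference over the grid: the
#' largest change in expected criteria count a respondent could see from
#' being assessed under one modality rather than the other at equal
#' latent severity.  When a [latent_distribution()] is supplied, a
#' secondary density-weighted mean absolute difference under the focal
#' latent distribution is also reported.
#'
#' @param bank A two-group [item_bank()].
#' @param theta_range Grid end points (default `c(-4, 4)`, covering
#'   essentially all of both latent distributions).
#' @param step Grid step (default 0.01).
#' @param latent Optional [latent_distribution()] for the weighted
#'   summary.
#' @return An object of class `impact_curve`: `table` (data frame with
#'   `theta`, one expected-score column per group, `difference`),
#'   `max_abs_difference`, `argmax_theta`, `groups`, and
#'   `weighted_mean_abs_difference` (NA when `latent` is absent).
#' @export
#' @examples
#' ic <- impact_curve(asc_item_bank(), latent = asc_latent())
#' ic
impact_curve <- function(bank, theta_range = c(-4, 4), step = 0.01,
                         latent = NULL) {
  stopifnot(inherits(bank, "item_bank"))
  if (length(bank$groups) != 2)
    stop("impact_curve() needs a two-group item bank", call. = FALSE)
  stopifnot(theta_range[1] < theta_range[2], step > 0)
  theta <- seq(theta_range[1], theta_range[2], by = step)
  es <- vapply(bank$groups, function(g)
    expected_test_score(bank, g, theta), numeric(length(theta)))
  diff <- es[, 2] - es[, 1]
  k <- which.max(abs(diff))
  wmad <- NA_real_
  if (!is.null(latent)) {
    stopifnot(inherits(latent, "latent_distribution"))
    foc <- bank$groups[2]
    w <- dnorm(theta, latent$mean[foc], sqrt(latent$variance[foc]))
    wmad <- sum(w * abs(diff)) / sum(w)
  }
  tab <- data.frame(theta = theta, es, difference = diff,
                    check.names = FALSE)
  names(tab)[2:3] <- paste0("expected_", bank$groups)
  structure(
    list(table = tab, groups = bank$groups,
         max_abs_difference = abs(diff[k]), argmax_theta = theta[k],
         weighted_mean_abs_difference = wmad,
         n_items = length(bank$item_ids)),
    class = "impact_curve")
}

#' @export
print.impact_curve <- function(x, ...) {
  cat(sprintf(
    "<impact_curve> groups %s vs %s over theta [%g, %g] (%d nodes)\n",
    x$groups[2], x$groups[1], min(x$table$theta), max(x$table$theta),
    nrow(x$table)))
  cat(sprintf(
    "  max |expected score difference| = %.4f of %d items (at theta = %.2f)\n",
    x$max_abs_difference, x$n_items, x$argmax_theta))
  if (!is.na(x$weighted_mean_abs_difference))
    cat(sprintf(
      "  focal-density-weighted mean |difference| = %.4f\n",
      x$weighted_mean_abs_difference))
  invisible(x)
}

#' Export an impact curve
#'
#' Writes the plot-ready table (`theta`, expected score per group,
#' `difference`) as delimited text, and optionally renders the two-line
#' expected-score figure to a PDF or PNG file chosen by extension.
#'
#' @param curve An [impact_curve()].
#' @param path Output path for the table.
#' @param figure Optional path for a rendered figure (`.pdf` or `.png`).
#' @return `path`, invisibly.
#' @export
export_curve <- function(curve, path, figure = NULL) {
  stopifnot(inherits(curve, "impact_curve"))
  write.csv(curve$table, path, row.names = FALSE)
  if (!is.null(figure)) {
    ext <- tolower(tools::file_ext(figure))
    switch(ext,
           pdf = grDevices::pdf(figure, width = 6, height = 4.5),
           png = grDevices::png(figure, width = 1200, height = 900,
                                res = 200),
           stop("figure extension must be .pdf or .png", call. = FALSE))
    on.exit(grDevices::dev.off())
    plot(curve)
  }
  invisible(path)
}

#' Plot an impact curve
#'
#' Expected total score against latent severity, one line per group --
#' near-overlapping lines indicate negligible cumulative DIF impact.
#'
#' @param x An [impact_curve()].
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.impact_curve <- function(x, ...) {
  graphics::matplot(
    x$table$theta, x$table[, 2:3], type = "l", lty = c(1, 2),
    col = c("black", "red3"), lwd = 1.6,
    xlab = "Latent severity", ylab = "Expected number of criteria",
    ylim = c(0, x$n_items), ...)
  graphics::legend("topleft", legend = x$groups, lty = c(1, 2),
                   col = c("black", "red3"), lwd = 1.6, bty = "n")
  invisible(x)
}
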