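#' Simulation configuration
#'
#' Bundles everything needed to generate a two-group binary response
#' matrix under the 2PL model: a generating [item_bank()], group latent
#' distributions, group sample sizes, a seed, and optional contamination
#' rates exercising the record-level filtering rules.
#'
#' The defaults reproduce the published study configuration: the
#' [asc_item_bank()] parameters, 1603 in-clinic and 1640 online
#' respondents, reference latent trait Normal(0, 1) and focal trait
#' Normal(-0.05, 0.90).  Contamination rates default to 0 so that the
#' default sample matches the published analyzed sample sizes exactly.
#'
#' @param bank Generating [item_bank()].
#' @param latent A [latent_distribution()] covering the bank's groups.
#' @param n_per_group Named (or bank-group-ordered) integer vector of
#'   respondents per group.
#' @param seed Integer seed.
#' @param missing_rate Probability in `[0, 1)` that a checklist has one
#'   item response blanked (missing completely at random).
#' @param duplicate_rate Probability in `[0, 1)` that a respondent
#'   contributes a second, independently generated checklist.
#' @return An object of class `sim_config`.
#' @seealso [simulate_checklist()], [simulate_latent()],
#'   [simulate_responses()], [contaminate()]
#' @export
sim_config <- function(bank = asc_item_bank(), latent = asc_latent(),
                       n_per_group = asc_n_per_group(), seed = 1L,
                       missing_rate = 0, duplicate_rate = 0) {
  stopifnot(inherits(bank, "item_bank"),
            inherits(latent, "latent_distribution"))
  if (!all(bank$groups %in% latent$groups))
    stop("`latent` must cover every group of `bank`", call. = FALSE)
  G <- length(bank$groups)
  if (is.null(names(n_per_group))) names(n_per_group) <- bank$groups
  n_per_group <- n_per_group[bank$groups]
  if (anyNA(n_per_group) || any(n_per_group < 1))
    stop("`n_per_group` must give a count >= 1 for every bank group",
         call. = FALSE)
  for (r in c(missing_rate, duplicate_rate))
    if (!is.finite(r) || r < 0 || r >= 1)
      stop("contamination rates must lie in [0, 1)", call. = FALSE)
  structure(
    list(bank = bank, latent = latent,
         n_per_group = setNames(as.integer(n_per_group), bank$groups),
         seed = as.integer(seed),
         missing_rate = missing_rate, duplicate_rate = duplicate_rate),
    class = "sim_config")
}

#' Draw latent trait values
#'
#' Samples each respondent's latent severity from their group's normal
#' distribution.
#'
#' @param config A [sim_config()].
#' @return A data frame with columns `patient_id`, `group`, `theta`.
#' @export
#' @examples
#' cfg <- sim_config(n_per_group = c(in_clinic = 5, online = 5), seed = 7)
#' simulate_latent(cfg)
simulate_latent <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  groups <- config$bank$groups
  out <- do.call(rbind, lapply(seq_along(groups), function(g) {
    n <- config$n_per_group[g]
    data.frame(
      patient_id = sprintf("%s_%05d", substr(groups[g], 1, 3), seq_len(n)),
      group = groups[g],
      theta = rnorm(n, config$latent$mean[groups[g]],
                    sqrt(config$latent$variance[groups[g]])),
      stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Generate binary responses from latent traits
#'
#' Each response is an independent Bernoulli draw with success probability
#' given by the 2PL item response function at the respondent's latent
#' value, using the parameters the bank resolves for the respondent's
#' group.  The output is complete; apply [contaminate()] separately to
#' introduce missingness or duplicate checklists.
#'
#' @param theta Data frame with columns `patient_id`, `group`, `theta`
#'   (as returned by [simulate_latent()]).
#' @param bank Generating [item_bank()].
#' @param seed Integer seed.
#' @return A [response_matrix()].
#' @export
simulate_responses <- function(theta, bank, seed) {
  stopifnot(is.data.frame(theta),
            all(c("patient_id", "group", "theta") %in% names(theta)),
            inherits(bank, "item_bank"))
  groups <- unique(theta$group)
  if (!all(groups %in% bank$groups))
    stop(sprintf("group(s) absent from bank: %s",
                 paste(setdiff(groups, bank$groups), collapse = ", ")),
         call. = FALSE)
  set.seed(as.integer(seed))
  n <- nrow(theta)
  J <- length(bank$item_ids)
  resp <- matrix(NA_integer_, n, J, dimnames = list(NULL, bank$item_ids))
  for (g in groups) {
    rows <- which(theta$group == g)
    pars <- resolve_items(bank, g)
    # n_g x J matrix of endorsement probabilities
    P <- plogis(outer(theta$theta[rows], pars$b, "-") *
                  rep(pars$a, each = length(rows)))
    resp[rows, ] <- rbinom(length(P), 1L, P)
  }
  response_matrix(theta$patient_id, theta$group, resp,
                  item_ids = bank$item_ids, reference = bank$reference)
}

#' Contaminate a response matrix with missing items and duplicates
#'
#' Exercises the record-level filtering rules: with probability
#' `missing_rate` a checklist has one uniformly chosen item blanked, and
#' with probability `duplicate_rate` a copy of the checklist is appended
#' as a second record under the same `patient_id`.
#'
#' @param data A [response_matrix()].
#' @param missing_rate,duplicate_rate Probabilities in `[0, 1)`.
#' @param seed Integer seed.
#' @return A [response_matrix()].
#' @export
contaminate <- function(data, missing_rate, duplicate_rate, seed) {
  stopifnot(inherits(data, "response_matrix"))
  for (r in c(missing_rate, duplicate_rate))
    if (!is.finite(r) || r < 0 || r >= 1)
      stop("contamination rates must lie in [0, 1)", call. = FALSE)
  set.seed(as.integer(seed))
  n <- nrow(data$responses)
  if (n == 0 || (missing_rate == 0 && duplicate_rate == 0)) return(data)

  dup <- which(runif(n) < duplicate_rate)
  idx <- c(seq_len(n), dup)
  out <- subset_rows(data, idx)
  m <- nrow(out$responses)
  hit <- which(runif(m) < missing_rate)
  if (length(hit) > 0) {
    cols <- sample.int(ncol(out$responses), length(hit), replace = TRUE)
    out$responses[cbind(hit, cols)] <- NA_integer_
  }
  out
}

#' Simulate a complete checklist dataset
#'
#' Convenience wrapper chaining [simulate_latent()],
#' [simulate_responses()] and [contaminate()] with seeds derived
#' deterministically from `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A [response_matrix()].
#' @export
#' @examples
#' cfg <- sim_config(n_per_group = c(in_clinic = 50, online = 50), seed = 3)
#' simulate_checklist(cfg)
simulate_checklist <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  th <- simulate_latent(config)
  rm <- simulate_responses(th, config$bank, seed = config$seed + 1L)
  contaminate(rm, config$missing_rate, config$duplicate_rate,
              seed = config$seed + 2L)
}
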