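#' The 11 items of the alcohol symptom checklist
#'
#' Canonical item order for the 11-item DSM-5 alcohol-use-disorder symptom
#' checklist: tolerance; withdrawal; drinking larger amounts or longer
#' than intended; unsuccessful attempts to quit or cut down; a great deal
#' of time spent; continued use despite physical or psychological
#' problems; neglect of major roles; hazardous use; social or
#' interpersonal problems; craving; and important activities given up.
#'
#' @return Character vector of 11 item ids.
#' @export
asc_items <- function() {
  c("tolerance", "withdrawal", "larger_longer", "quit_control",
    "time_spent", "phys_psych_problems", "neglect_roles",
    "hazardous_use", "social_interpersonal", "craving",
    "activities_given_up")
}

#' Published item bank for online vs in-clinic administration
#'
#' The final two-group 2PL parameter set from a published measurement
#' equivalence analysis of the 11-item alcohol symptom checklist completed
#' either in clinic (reference group) or through an online patient portal
#' (focal group).  Items `time_spent`, `phys_psych_problems` and
#' `neglect_roles` served as anchors; `tolerance`, `larger_longer` and
#' `quit_control` showed DIF in severity only, and
#' `social_interpersonal` in both discrimination and severity.  All other
#' parameters were fixed equal across modalities.
#'
#' This bank is the default configuration of [sim_config()] and the input
#' to the analytic branch of [replicate_reference_analysis()].
#'
#' @return A two-group [item_bank()] with groups `"in_clinic"` (reference)
#'   and `"online"`.
#' @seealso [asc_latent()], [asc_anchors()]
#' @export
#' @examples
#' asc_item_bank()
asc_item_bank <- function() {
  a_ref <- c(1.46, 2.19, 2.18, 2.68, 2.80, 2.74, 3.26, 1.54, 3.08, 2.51, 3.51)
  b_ref <- c(0.99, 1.25, 0.52, 0.73, 0.84, 0.44, 1.29, 1.86, 0.81, 0.68, 1.00)
  a_foc <- a_ref
  b_foc <- b_ref
  b_foc[1] <- 0.81   # tolerance: less severe online
  b_foc[3] <- 0.28   # larger_longer
  b_foc[4] <- 0.87   # quit_control: more severe online
  a_foc[9] <- 2.65   # social_interpersonal: a and b both differ
  b_foc[9] <- 1.07
  item_bank(asc_items(),
            a = cbind(in_clinic = a_ref, online = a_foc),
            b = cbind(in_clinic = b_ref, online = b_foc),
            groups = c("in_clinic", "online"),
            a_shared = replace(rep(TRUE, 11), 9, FALSE),
            b_shared = replace(rep(TRUE, 11), c(1, 3, 4, 9), FALSE),
            anchors = asc_anchors())
}

#' Published anchor items
#'
#' @return Character vector of the three anchor item ids used in the
#'   published modality comparison.
#' @export
asc_anchors <- function() {
  c("time_spent", "phys_psych_problems", "neglect_roles")
}

#' Published latent trait moments by administration modality
#'
#' In-clinic (reference) latent severity fixed at Normal(0, 1); the
#' online-portal group's moments were freely estimated at mean -0.05 and
#' variance 0.90.
#'
#' @return A [latent_distribution()].
#' @export
asc_latent <- function() {
  latent_distribution(c("in_clinic", "online"),
                      mean = c(0, -0.05), variance = c(1, 0.90))
}

#' Published analysis sample sizes by modality
#'
#' @return Named integer vector: 1603 in-clinic, 1640 online checklists
#'   (the analyzed samples after excluding incomplete checklists and
#'   selecting one checklist per patient).
#' @export
asc_n_per_group <- function() {
  c(in_clinic = 1603L, online = 1640L)
}
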