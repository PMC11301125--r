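# Shared fixtures.  Everything is generated in code; the study-scale
# simulations used by the acceptance tests are cached so several test
# blocks can share one set of replicates.

# three well-separated items, single group
bank3 <- function() {
  item_bank(c("x1", "x2", "x3"), a = c(1.2, 2.0, 2.6),
            b = c(-0.7, 0.1, 0.8), groups = "g")
}

# five-item two-group bank; item x5 carries severity DIF of size `dif_b`
bank5 <- function(dif_b = 0.6) {
  b_foc <- c(-0.8, -0.2, 0.3, 0.9, 0.2 + dif_b)
  item_bank(paste0("x", 1:5),
            a = c(1.5, 2.0, 2.5, 1.8, 2.2),
            b = cbind(ref = c(-0.8, -0.2, 0.3, 0.9, 0.2), foc = b_foc),
            groups = c("ref", "foc"),
            b_shared = c(rep(TRUE, 4), dif_b == 0),
            anchors = c("x1", "x2"))
}

sim_single <- function(bank, n, seed, mean = 0, variance = 1) {
  g <- bank$groups[1]
  lat <- latent_distribution(g)
  simulate_checklist(sim_config(bank, lat, setNames(n, g), seed = seed))
}

sim_two <- function(bank, n_ref, n_foc, seed, foc_mean = 0,
                    foc_var = 1) {
  lat <- latent_distribution(bank$groups, mean = c(0, foc_mean),
                             variance = c(1, foc_var))
  simulate_checklist(sim_config(bank, lat,
                                setNames(c(n_ref, n_foc), bank$groups),
                                seed = seed))
}

# a tiny handmade response matrix with known counts
toy_matrix <- function() {
  response_matrix(
    patient_id = c("p1", "p2", "p3", "p4"),
    group = c("clinic", "clinic", "online", "online"),
    responses = rbind(c(1, 1, 0), c(0, 0, 0), c(1, 0, 1), c(1, 1, 1)),
    item_ids = c("i1", "i2", "i3"),
    reference = "clinic")
}

# ---- study-scale cache (acceptance tests) ----------------------------
# 12 a-priori replicate seeds; simulations at the published configuration
study_seeds <- function() 101:112

.study_cache <- new.env(parent = emptyenv())

study_data <- function(seed) {
  key <- paste0("d", seed)
  if (is.null(.study_cache[[key]]))
    .study_cache[[key]] <- simulate_checklist(sim_config(seed = seed))
  .study_cache[[key]]
}

# full stepwise DIF detection per replicate
study_report <- function(seed) {
  key <- paste0("r", seed)
  if (is.null(.study_cache[[key]]))
    .study_cache[[key]] <- detect_dif(study_data(seed),
                                      anchors = asc_anchors(),
                                      quiet = TRUE)
  .study_cache[[key]]
}

# anchored multigroup fit under the published constraint pattern
study_mg_fit <- function(seed) {
  key <- paste0("m", seed)
  if (is.null(.study_cache[[key]]))
    .study_cache[[key]] <- fit_multigroup(study_data(seed),
                                          asc_item_bank(), se = TRUE)
  .study_cache[[key]]
}

# the published reference-group (in-clinic) column as a single-group bank
asc_reference_bank <- function() {
  full <- asc_item_bank()
  item_bank(full$item_ids, a = full$a[, 1], b = full$b[, 1],
            groups = full$groups[1])
}

study_sg_fit <- function(seed) {
  key <- paste0("s", seed)
  if (is.null(.study_cache[[key]])) {
    data <- sim_single(asc_reference_bank(), 1603, seed = seed)
    .study_cache[[key]] <- fit_single_group(data, se = TRUE)
  }
  .study_cache[[key]]
}
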