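#' TMT reporter ion m/z values
#'
#' Canonical reporter-ion m/z (Th) for the 11-plex TMT reagent series.
#' @format Named numeric vector.
#' @export
TMT11_REPORTER_MZ <- c(
  `126`  = 126.127726, `127N` = 127.124761, `127C` = 127.131081,
  `128N` = 128.128116, `128C` = 128.134436, `129N` = 129.131471,
  `129C` = 129.137790, `130N` = 130.134825, `130C` = 130.141145,
  `131N` = 131.138180, `131C` = 131.144500
)

#' Multiplexed channel design
#'
#' Describes the sample loaded into each isobaric channel: treatment
#' condition, organelle preparation, and whether the channel is a knockout
#' (APP-null style) background channel. The default reproduces an 11-plex
#' inhibitor experiment with triplicate vehicle (DMSO), triplicate BACE1
#' inhibitor (BSI), triplicate gamma-secretase inhibitor (GSI) channels and
#' duplicate knockout background channels on endosome IPs.
#'
#' @param conditions Character vector, one condition per channel, drawn from
#'   `"DMSO"`, `"BSI"`, `"GSI"`, `"GSM"`, `"KO"`.
#' @param organelle Organelle preparation per channel (recycled):
#'   `"ENDO"`, `"LYSO"` or `"PNS"`.
#' @param plex Reporter series to use; only 11-plex TMT supported, channels
#'   are assigned in reporter order.
#' @return Tibble of class `"channel_design"` with columns `channel_id`,
#'   `reporter_mz`, `condition`, `organelle`, `is_ko`, `replicate`.
#' @examples
#' channel_design()
#' @export
channel_design <- function(conditions = c(rep("DMSO", 3), rep("BSI", 3),
                                          rep("GSI", 3), rep("KO", 2)),
                           organelle = "ENDO",
                           plex = 11L) {
  stopifnot(plex == 11L)
  if (length(conditions) < 1) stop("design without channels", call. = FALSE)
  if (length(conditions) > plex) {
    stop("more conditions than plex channels", call. = FALSE)
  }
  bad <- setdiff(conditions, c("DMSO", "BSI", "GSI", "GSM", "KO"))
  if (length(bad) > 0) {
    stop("unknown condition(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  n <- length(conditions)
  out <- tibble::tibble(
    channel_id = names(TMT11_REPORTER_MZ)[seq_len(n)],
    reporter_mz = unname(TMT11_REPORTER_MZ[seq_len(n)]),
    condition = conditions,
    organelle = rep_len(organelle, n),
    is_ko = conditions == "KO"
  )
  out <- dplyr::mutate(out, replicate = dplyr::row_number(),
                       .by = c("condition", "organelle"))
  class(out) <- c("channel_design", class(out))
  out
}

#' Isotopic impurity matrix
#'
#' Square column-stochastic matrix whose entry (i, j) is the fraction of
#' channel j's reagent that reports in channel i. The default model leaks a
#' fixed fraction into the adjacent-mass channels (-1 and +1 reporter
#' positions), mimicking vendor lot sheets; channels at the series edges
#' lose the out-of-range fraction (columns then sum to < 1).
#'
#' @param n Number of channels.
#' @param minus,plus Fraction leaking to the previous/next reporter channel.
#' @param channel_ids Optional dimnames.
#' @return `n x n` matrix.
#' @examples
#' impurity_matrix(3, minus = 0.02, plus = 0.03)
#' @export
impurity_matrix <- function(n, minus = 0.02, plus = 0.03, channel_ids = NULL) {
  stopifnot(n >= 1, minus >= 0, plus >= 0, minus + plus < 0.5)
  M <- diag(1 - minus - plus, n)
  for (j in seq_len(n)) {
    if (j > 1) M[j - 1, j] <- minus
    if (j < n) M[j + 1, j] <- plus
  }
  if (!is.null(channel_ids)) dimnames(M) <- list(channel_ids, channel_ids)
  M
}

check_impurity <- function(M) {
  stopifnot(is.matrix(M), nrow(M) == ncol(M))
  if (any(colSums(M) > 1 + 1e-6)) {
    stop("impurity matrix columns must sum to <= 1", call. = FALSE)
  }
  if (any(diag(M) <= apply(M - diag(diag(M)), 2, max))) {
    stop("impurity matrix must be diagonally dominant", call. = FALSE)
  }
  invisible(M)
}

#' Forward reporter-ion mixing model
#'
#' Applies isotopic impurity mixing (and optional noise) to a vector of true
#' per-channel abundances: `observed = M %*% true + noise`. This is the
#' forward model that [impurity_correct()] inverts.
#'
#' @param true_abundances Numeric vector, one value per channel.
#' @param impurity Impurity matrix (see [impurity_matrix()]).
#' @param noise_sd Standard deviation of additive Gaussian noise (default 0).
#' @return Numeric vector of observed intensities.
#' @export
mix_reporters <- function(true_abundances, impurity, noise_sd = 0) {
  check_impurity(impurity)
  stopifnot(length(true_abundances) == nrow(impurity))
  obs <- drop(impurity %*% true_abundances)
  if (noise_sd > 0) obs <- obs + stats::rnorm(length(obs), 0, noise_sd)
  obs
}

#' Condition effect model
#'
#' Multiplicative effects of each treatment condition on the true abundance
#' of each monitored peptide class, relative to the vehicle (DMSO) baseline:
#' \describe{
#'   \item{BSI}{BACE1 inhibition: the uncleaved parent juxtamembrane peptide
#'     accumulates while both BACE1 half-tryptic products fall to the
#'     knockout background; downstream gamma-secretase products are also
#'     reduced (juxtamembrane cleavage precedes intramembrane cleavage).}
#'   \item{GSI}{gamma-secretase inhibition: all A-beta half-tryptic products
#'     fall to background; BACE1-site peptides are unaffected.}
#'   \item{GSM}{gamma-secretase modulation: long products (A-beta 39/40/42)
#'     fall to background while short products (A-beta 37/38) roughly
#'     double.}
#' }
#' Peptides are assigned to classes via the design table's `sim_group`
#' column: `bace1_parent`, `bace1_product`, `gamma_short`, `gamma_long`,
#' `other`. A multiplier of 0 sends the species to the knockout floor.
#' Lysosomal channels scale all absolute levels by `lyso_scale` (lysosomal
#' peptide pools run several-fold below endosomal ones).
#'
#' @param bsi_parent,bsi_product,bsi_gamma BSI multipliers for the parent
#'   peptide, the BACE1 half-tryptic products and the gamma products.
#' @param gsi_gamma GSI multiplier for all gamma products.
#' @param gsm_short,gsm_long GSM multipliers for short (37/38) and long
#'   (39/40/42) gamma products.
#' @param lyso_scale Absolute scaling of lysosomal vs endosomal channels.
#' @return List of class `"condition_effects"`.
#' @export
condition_effects <- function(bsi_parent = 2, bsi_product = 0, bsi_gamma = 0.25,
                              gsi_gamma = 0, gsm_short = 2, gsm_long = 0,
                              lyso_scale = 0.2) {
  eff <- list(bsi_parent = bsi_parent, bsi_product = bsi_product,
              bsi_gamma = bsi_gamma, gsi_gamma = gsi_gamma,
              gsm_short = gsm_short, gsm_long = gsm_long,
              lyso_scale = lyso_scale)
  if (any(unlist(eff) < 0)) stop("effect multipliers must be >= 0", call. = FALSE)
  structure(eff, class = "condition_effects")
}

#' Per-channel abundance multiplier for one peptide class
#' @keywords internal
effect_multiplier <- function(effects, sim_group, condition) {
  stopifnot(length(sim_group) == 1)
  m <- rep(1, length(condition))
  if (sim_group == "bace1_parent") {
    m[condition == "BSI"] <- effects$bsi_parent
  } else if (sim_group == "bace1_product") {
    m[condition == "BSI"] <- effects$bsi_product
  } else if (sim_group %in% c("gamma_short", "gamma_long")) {
    m[condition == "BSI"] <- effects$bsi_gamma
    m[condition == "GSI"] <- effects$gsi_gamma
    m[condition == "GSM"] <-
      if (sim_group == "gamma_short") effects$gsm_short else effects$gsm_long
  }
  m[condition == "KO"] <- 0
  m
}
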