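#' Extract reporter-ion intensities from an MS3 scan
#'
#' Sums peak intensity within +/- `tolerance_da` of each channel's reporter
#' m/z and converts to signal-to-noise against the scan's noise floor.
#' Overlapping extraction windows (tolerance too wide for the channel
#' spacing) are an error.
#'
#' @param peaks MS3 peak tibble (`mz`, `intensity`).
#' @param channel_mzs Named numeric vector of reporter m/z values.
#' @param tolerance_da Integration tolerance (Da); default 0.003.
#' @param noise Scan noise floor (counts) for the S/N conversion.
#' @return Tibble with `channel_id`, `intensity`, `sn`.
#' @export
extract_reporters <- function(peaks, channel_mzs, tolerance_da = 0.003,
                              noise = 1) {
  mzs <- sort(unname(channel_mzs))
  if (length(mzs) > 1 && min(diff(mzs)) <= 2 * tolerance_da) {
    stop("reporter extraction windows overlap at tolerance ", tolerance_da,
         " Da", call. = FALSE)
  }
  ints <- vapply(channel_mzs, function(m) {
    if (is.null(peaks) || nrow(peaks) == 0) return(0)
    sum(peaks$intensity[abs(peaks$mz - m) <= tolerance_da])
  }, 0)
  tibble::tibble(channel_id = names(channel_mzs), intensity = unname(ints),
                 sn = unname(ints) / noise)
}

#' Isotopic impurity correction
#'
#' Inverts the reporter mixing model by solving `M x = observed`; negative
#' solutions (noise pushing a channel below zero) are clamped to 0.
#'
#' @param observed Numeric vector (or matrix with channels in columns) of
#'   observed per-channel values.
#' @param impurity Impurity matrix ([impurity_matrix()]).
#' @return Corrected values, same shape as `observed`.
#' @export
impurity_correct <- function(observed, impurity) {
  check_impurity(impurity)
  if (abs(det(impurity)) < 1e-12) {
    stop("impurity matrix is singular", call. = FALSE)
  }
  if (is.matrix(observed)) {
    out <- t(solve(impurity, t(observed)))
  } else {
    out <- drop(solve(impurity, observed))
  }
  pmax(out, 0)
}

#' Assemble a quantification table from engine MS3 output
#'
#' Extracts reporter S/N from every emitted MS3 scan, sums S/N per peptide
#' across all qualifying scans within the scheduled elution window, and
#' applies isotopic impurity correction.
#'
#' @param acq An `"acquisition"` (see [run_engine()]).
#' @param channels A [channel_design()].
#' @param impurity Impurity matrix used for correction (should match the
#'   reagent lot, i.e. the one used in simulation).
#' @param tolerance_da Reporter integration tolerance (Da).
#' @param rt_window_min Optional half-width around each peptide's scheduled
#'   apex outside which MS3 scans are ignored (`Inf` keeps all).
#' @param scheduled_rt Optional named vector `peptide_id -> apex` for the
#'   window filter.
#' @return Object of class `"quant_table"`: list with `sn` (long tibble:
#'   `peptide_id`, `channel_id`, `condition`, `is_ko`, `sn_raw`, `sn`),
#'   `channels`, `n_scans` per peptide, `normalized` flag.
#' @export
quant_table <- function(acq, channels, impurity = NULL, tolerance_da = 0.003,
                        rt_window_min = Inf, scheduled_rt = NULL) {
  if (is.null(impurity)) {
    impurity <- impurity_matrix(nrow(channels),
                                channel_ids = channels$channel_id)
  }
  ms3 <- acq$ms3
  if (!is.infinite(rt_window_min) && !is.null(scheduled_rt)) {
    keep <- abs(ms3$rt_min - scheduled_rt[ms3$peptide_id]) <= rt_window_min
    ms3 <- ms3[keep, ]
  }
  mzv <- stats::setNames(channels$reporter_mz, channels$channel_id)
  sn_mat <- vapply(seq_len(nrow(ms3)), function(i) {
    extract_reporters(ms3$peaks[[i]], mzv, tolerance_da, ms3$noise[i])$sn
  }, numeric(length(mzv)))
  if (nrow(ms3) == 0) {
    sn <- tibble::tibble(peptide_id = character(0), channel_id = character(0),
                         condition = character(0), is_ko = logical(0),
                         sn_raw = numeric(0), sn = numeric(0))
    return(structure(list(sn = sn, channels = channels,
                          n_scans = tibble::tibble(peptide_id = character(0),
                                                   n_scans = integer(0)),
                          impurity = impurity, normalized = FALSE),
                     class = "quant_table"))
  }
  sn_mat <- matrix(sn_mat, nrow = length(mzv))   # channels x scans
  pids <- sort(unique(ms3$peptide_id))
  m <- t(vapply(pids, function(p) {
    rowSums(sn_mat[, ms3$peptide_id == p, drop = FALSE])
  }, numeric(length(mzv))))                      # peptides x channels
  corr <- impurity_correct(m, impurity)
  long <- tibble::tibble(
    peptide_id = rep(pids, each = nrow(channels)),
    channel_id = rep(channels$channel_id, length(pids)),
    condition = rep(channels$condition, length(pids)),
    is_ko = rep(channels$is_ko, length(pids)),
    sn_raw = as.vector(t(m)),
    sn = as.vector(t(corr))
  )
  n_scans <- dplyr::count(ms3, .data$peptide_id, name = "n_scans")
  structure(list(sn = long, channels = channels, n_scans = n_scans,
                 impurity = impurity, normalized = FALSE),
            class = "quant_table")
}

#' Total-reporter normalisation
#'
#' Scales each channel so that its column sum (over peptides) equals the
#' grand-mean column sum, the equal-loading assumption of multiplexed
#' designs. Idempotent; within-channel peptide ratios are preserved.
#'
#' @param qt A `"quant_table"`.
#' @return The normalised `"quant_table"` (`normalized = TRUE`).
#' @export
normalize_total <- function(qt) {
  stopifnot(inherits(qt, "quant_table"))
  totals <- dplyr::summarise(qt$sn, total = sum(.data$sn),
                             .by = "channel_id")
  if (any(totals$total <= 0)) {
    stop("cannot normalise: channel with zero total reporter signal",
         call. = FALSE)
  }
  target <- mean(totals$total)
  fac <- stats::setNames(target / totals$total, totals$channel_id)
  qt$sn$sn <- unname(qt$sn$sn * fac[qt$sn$channel_id])
  qt$normalized <- TRUE
  qt
}

#' Knockout-channel background subtraction
#'
#' For each peptide, the mean S/N over knockout (background) channels
#' defines the background; test channels are reported both raw and
#' background-adjusted (clamped at zero). Downstream condition statistics
#' use the unsubtracted values with the background alongside, matching how
#' knockout channels are displayed next to test samples.
#'
#' @param qt A `"quant_table"`.
#' @param ko_channels Optional character vector of background channel ids;
#'   defaults to the design's `is_ko` channels.
#' @return `qt` with columns `background` and `sn_adj` added to `$sn`.
#' @export
background_subtract <- function(qt, ko_channels = NULL) {
  stopifnot(inherits(qt, "quant_table"))
  if (is.null(ko_channels)) {
    ko_channels <- qt$channels$channel_id[qt$channels$is_ko]
  }
  if (length(ko_channels) == 0) {
    stop("no knockout background channels in design", call. = FALSE)
  }
  bg <- dplyr::summarise(qt$sn[qt$sn$channel_id %in% ko_channels, ],
                         background = mean(.data$sn), .by = "peptide_id")
  qt$sn <- dplyr::left_join(
    dplyr::select(qt$sn, -dplyr::any_of(c("background", "sn_adj"))),
    bg, by = "peptide_id")
  qt$sn$background[is.na(qt$sn$background)] <- 0
  qt$sn$sn_adj <- pmax(0, qt$sn$sn - qt$sn$background)
  qt
}

#' Two-sample condition test per peptide
#'
#' Classical two-sided Student's t-test (equal variances) comparing two
#' treatment groups on (normalised) reporter S/N, with significance stars
#' at 0.05 / 0.01 / 0.001.
#'
#' @param qt A `"quant_table"` (normalise first for cross-channel
#'   comparability).
#' @param group_a,group_b Condition labels (e.g. `"DMSO"`, `"BSI"`).
#' @param var_equal Use the pooled-variance Student test (default) rather
#'   than Welch.
#' @return Tibble with `peptide_id`, `mean_a`, `mean_b`, `t`, `df`, `p`,
#'   `stars`.
#' @export
condition_test <- function(qt, group_a, group_b, var_equal = TRUE) {
  stopifnot(inherits(qt, "quant_table"))
  d <- qt$sn[qt$sn$condition %in% c(group_a, group_b), ]
  purrr::map_dfr(unique(d$peptide_id), function(pid) {
    x <- d$sn[d$peptide_id == pid & d$condition == group_a]
    y <- d$sn[d$peptide_id == pid & d$condition == group_b]
    if (length(x) < 2 || length(y) < 2) {
      stop("condition_test requires at least 2 replicates per group",
           call. = FALSE)
    }
    degenerate <- function() {
      # no usable within-group variance (exactly or numerically constant)
      list(statistic = if (isTRUE(all.equal(mean(x), mean(y)))) 0 else
             sign(mean(x) - mean(y)) * Inf,
           parameter = length(x) + length(y) - 2,
           p.value = as.numeric(isTRUE(all.equal(mean(x), mean(y)))))
    }
    tt <- if (stats::sd(x) == 0 && stats::sd(y) == 0) degenerate() else
      tryCatch(stats::t.test(x, y, var.equal = var_equal),
               error = function(e) degenerate())
    tibble::tibble(peptide_id = pid, mean_a = mean(x), mean_b = mean(y),
                   t = unname(tt$statistic), df = unname(tt$parameter),
                   p = tt$p.value, stars = p_stars(tt$p.value))
  })
}

p_stars <- function(p) {
  dplyr::case_when(p <= 0.001 ~ "***", p <= 0.01 ~ "**", p <= 0.05 ~ "*",
                   .default = "n.s.")
}

#' Per-condition summary with background calls
#'
#' Summarises a quantification table per (peptide, condition): mean
#' corrected S/N, the knockout background level, and a call of whether the
#' species sits "at background" in that condition. A condition is at
#' background when its mean S/N is within `ko_ratio`-fold of the knockout
#' background, or when its background-subtracted signal falls below
#' `vehicle_frac` of the background-subtracted vehicle signal (the second
#' rule keeps the call well-posed when both compared means are at the
#' measurement floor, where their ratio is dominated by noise).
#'
#' @param qt A `"quant_table"` with knockout channels in the design.
#' @param vehicle Condition label of the vehicle/control channels.
#' @param ko_ratio Fold-of-background threshold (default 2).
#' @param vehicle_frac Fraction-of-vehicle threshold (default 0.05).
#' @return Tibble `peptide_id`, `condition`, `mean_sn`, `background`,
#'   `vs_vehicle`, `at_background`.
#' @export
condition_summary <- function(qt, vehicle = "DMSO", ko_ratio = 2,
                              vehicle_frac = 0.05) {
  stopifnot(inherits(qt, "quant_table"))
  qb <- background_subtract(qt)
  d <- dplyr::summarise(qb$sn, mean_sn = mean(.data$sn),
                        mean_adj = mean(.data$sn_adj),
                        background = .data$background[1],
                        .by = c("peptide_id", "condition"))
  veh <- d[d$condition == vehicle, c("peptide_id", "mean_adj")]
  names(veh)[2] <- "vehicle_adj"
  d <- dplyr::left_join(d, veh, by = "peptide_id")
  dplyr::transmute(
    d, .data$peptide_id, .data$condition, .data$mean_sn, .data$background,
    vs_vehicle = .data$mean_adj / pmax(.data$vehicle_adj, .Machine$double.eps),
    at_background = .data$mean_sn <= ko_ratio * .data$background |
      .data$mean_adj <= vehicle_frac * .data$vehicle_adj)
}
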