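#' Roll PSM-level quantitation up to proteins
#'
#' Sums reporter S/N across all PSMs matching each protein, per channel.
#'
#' @param psm_table Long tibble with columns `protein`, `channel_id`,
#'   `sn` (one row per PSM per channel).
#' @return Tibble `protein`, `channel_id`, `sn`.
#' @export
rollup <- function(psm_table) {
  dplyr::summarise(psm_table, sn = sum(.data$sn),
                   .by = c("protein", "channel_id"))
}

#' Two-stage Benjamini-Hochberg adjusted p-values
#'
#' The adaptive two-stage step-up procedure (Benjamini, Krieger &
#' Yekutieli 2006): a first BH pass at level `alpha / (1 + alpha)`
#' estimates the number of true nulls `m0`, and the final adjusted
#' p-values are the ordinary BH values scaled by `m0 / m`.
#'
#' @param p Numeric vector of raw p-values.
#' @param alpha Target FDR level of the procedure (default 0.05).
#' @return Vector of adjusted p-values (same order as `p`).
#' @export
p_adjust_tsbh <- function(p, alpha = 0.05) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  m <- sum(!is.na(p))
  bh <- stats::p.adjust(p, "BH")
  r1 <- sum(bh <= alpha / (1 + alpha), na.rm = TRUE)
  m0 <- m - r1
  pmin(1, bh * m0 / m)
}

#' Organelle-IP enrichment statistics
#'
#' Per-protein enrichment of bait IPs over control IPs on total-reporter
#' normalised values: log2 fold change of means, two-sided Student's
#' t-test, two-stage BH adjustment, and the enrichment flag
#' `log2FC > fc_threshold & p < p_threshold` (the flag uses the raw p, as
#' in the printed filter; the adjusted p is reported alongside).
#'
#' @param protein_quant Tibble `protein`, `channel_id`, `sn` (from
#'   [rollup()] or [read_protein_table()]).
#' @param bait_channels,control_channels Character vectors of channel ids
#'   (at least 2 each).
#' @param fc_threshold,p_threshold Enrichment flag thresholds.
#' @param normalize Total-reporter normalise channels first (default TRUE).
#' @param pseudocount Added to means to guard zero controls; default half
#'   the smallest nonzero value in the table.
#' @param alpha FDR level for the two-stage BH adjustment.
#' @param var_equal Pooled-variance Student test (default) vs Welch.
#' @return Tibble of class `"enrichment_result"`: `protein`, `log2fc`,
#'   `t`, `p`, `p_adj`, `enriched`.
#' @export
enrichment <- function(protein_quant, bait_channels, control_channels,
                       fc_threshold = 1.0, p_threshold = 0.02,
                       normalize = TRUE, pseudocount = NULL,
                       alpha = 0.05, var_equal = TRUE) {
  if (length(bait_channels) < 2 || length(control_channels) < 2) {
    stop("need at least 2 bait and 2 control channels", call. = FALSE)
  }
  wide <- tidyr::pivot_wider(protein_quant, names_from = "channel_id",
                             values_from = "sn", values_fill = 0)
  chans <- c(bait_channels, control_channels)
  miss <- setdiff(chans, names(wide))
  if (length(miss) > 0) {
    stop("channels absent from table: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  m <- as.matrix(wide[, chans, drop = FALSE])
  if (normalize) {
    tot <- colSums(m)
    if (any(tot <= 0)) stop("channel with zero total signal", call. = FALSE)
    m <- sweep(m, 2, mean(tot) / tot, `*`)
  }
  if (is.null(pseudocount)) {
    nz <- m[m > 0]
    pseudocount <- if (length(nz) > 0) min(nz) / 2 else 0.5
  }
  ib <- seq_along(bait_channels)
  ic <- length(bait_channels) + seq_along(control_channels)
  xb <- m[, ib, drop = FALSE]; xc <- m[, ic, drop = FALSE]
  nb <- ncol(xb); nc <- ncol(xc)
  mb <- rowMeans(xb); mc <- rowMeans(xc)
  vb <- rowSums((xb - mb)^2) / (nb - 1)
  vc <- rowSums((xc - mc)^2) / (nc - 1)
  if (var_equal) {
    sp2 <- ((nb - 1) * vb + (nc - 1) * vc) / (nb + nc - 2)
    se <- sqrt(sp2 * (1 / nb + 1 / nc))
    df <- nb + nc - 2
  } else {
    se <- sqrt(vb / nb + vc / nc)
    df <- (vb / nb + vc / nc)^2 /
      ((vb / nb)^2 / (nb - 1) + (vc / nc)^2 / (nc - 1))
  }
  tstat <- (mb - mc) / se
  p <- 2 * stats::pt(-abs(tstat), df)
  p[se == 0 & mb == mc] <- 1
  tstat[se == 0 & mb == mc] <- 0
  out <- tibble::tibble(
    protein = wide$protein,
    log2fc = log2((mb + pseudocount) / (mc + pseudocount)),
    t = tstat, p = p,
    p_adj = p_adjust_tsbh(p, alpha),
    enriched = log2((mb + pseudocount) / (mc + pseudocount)) > fc_threshold &
      p < p_threshold
  )
  class(out) <- c("enrichment_result", class(out))
  attr(out, "thresholds") <- c(fc = fc_threshold, p = p_threshold)
  out
}

#' Count proteins passing the enrichment filter
#'
#' @param results An [enrichment()] result.
#' @param fc_threshold,p_threshold Filter thresholds (log2FC strictly
#'   greater; raw p strictly smaller).
#' @return Integer count.
#' @export
filter_count <- function(results, fc_threshold = 1.0, p_threshold = 0.02) {
  sum(results$log2fc > fc_threshold & results$p < p_threshold, na.rm = TRUE)
}

harmonize_one <- function(ids) sub("-\\d+$", "", toupper(trimws(ids)))
harmonize_ids <- function(ids) unique(harmonize_one(ids))

#' Overlap of two protein sets
#'
#' Exact set intersection after identifier harmonisation (uppercase,
#' isoform suffixes such as `-2` stripped, deduplicated).
#'
#' @param a,b Character vectors of protein identifiers.
#' @return List with `count` and `members`.
#' @export
overlap <- function(a, b) {
  members <- sort(intersect(harmonize_ids(a), harmonize_ids(b)))
  list(count = length(members), members = members)
}

#' Per-annotation-class log2FC summaries
#'
#' Quartiles (type-7 linear interpolation) of log2 fold change within each
#' annotation class; classes absent from the results report `n = 0` with
#' missing quartiles.
#'
#' @param results An [enrichment()] result.
#' @param annotations Named list of character vectors (class -> protein
#'   ids), or a two-column tibble `class`, `protein`.
#' @return Tibble `class`, `n`, `q1`, `median`, `q3`.
#' @export
class_summary <- function(results, annotations) {
  if (is.data.frame(annotations)) {
    annotations <- split(annotations$protein, annotations$class)
  }
  ids <- harmonize_one(results$protein)
  purrr::imap_dfr(annotations, function(set, cls) {
    hit <- results$log2fc[ids %in% harmonize_ids(set)]
    if (length(hit) == 0) {
      tibble::tibble(class = cls, n = 0L, q1 = NA_real_,
                     median = NA_real_, q3 = NA_real_)
    } else {
      q <- stats::quantile(hit, c(0.25, 0.5, 0.75), type = 7)
      tibble::tibble(class = cls, n = length(hit), q1 = q[[1]],
                     median = q[[2]], q3 = q[[3]])
    }
  })
}

#' Read a protein-level quantitation table
#'
#' Reads a TSV with one `protein` column and one column per channel into
#' the long `protein`/`channel_id`/`sn` layout used by [enrichment()]. A
#' column-mapping can rename file columns to channel ids.
#'
#' @param path TSV path.
#' @param column_map Optional named character vector
#'   `file_column -> channel_id`.
#' @return Long tibble `protein`, `channel_id`, `sn`.
#' @export
read_protein_table <- function(path, column_map = NULL) {
  wide <- readr::read_tsv(path, show_col_types = FALSE)
  if (!"protein" %in% names(wide)) {
    stop("protein table must have a `protein` column", call. = FALSE)
  }
  if (!is.null(column_map)) {
    names(wide)[match(names(column_map), names(wide))] <- unname(column_map)
  }
  tidyr::pivot_longer(wide, -"protein", names_to = "channel_id",
                      values_to = "sn")
}
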