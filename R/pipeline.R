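#' Pipeline configuration
#'
#' Bundles every parameter of a full design -> simulate -> acquire ->
#' quantify -> report run. Fully serialisable: a config plus its seed
#' reproduces a run's outputs exactly.
#'
#' @param seed Master seed.
#' @param design Design table ([build_design()]).
#' @param channels Channel design ([channel_design()]).
#' @param effects Condition effects ([condition_effects()]).
#' @param engine Engine configuration ([engine_config()]).
#' @param params Simulation parameters ([sim_params()]).
#' @param impurity Impurity matrix; default banded [impurity_matrix()].
#' @param lmw_cutoff_da Filter cut-off for the A-beta branch (Da).
#' @param out_dir Optional output directory for TSV/JSON artefacts.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(seed = 1L,
                            design = build_design(demo_substrate()),
                            channels = channel_design(),
                            effects = condition_effects(),
                            engine = engine_config(),
                            params = sim_params(),
                            impurity = NULL,
                            lmw_cutoff_da = 5e4,
                            out_dir = NULL) {
  cfg <- as.list(environment())
  missing_fields <- names(cfg)[vapply(cfg[c("seed", "design", "channels",
                                            "effects", "engine", "params")],
                                      is.null, TRUE)]
  if (length(missing_fields) > 0) {
    stop("missing config fields: ", paste(missing_fields, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(cfg$impurity)) {
    cfg$impurity <- impurity_matrix(nrow(channels),
                                    channel_ids = channels$channel_id)
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the full targeted-quantification pipeline
#'
#' Mirrors the two-branch organelle workflow: non-A-beta peptides
#' (juxtamembrane parent and BACE1 half-tryptic products) are acquired
#' directly from the organelle IP, while A-beta peptides are acquired from
#' the low-molecular-weight filtrate, which removes the full-length
#' substrate and boosts their effective signal. Each branch is acquired
#' with the triggered engine and quantified (reporter extraction, impurity
#' correction); SIM-mode runs provide absolute totals which are
#' apportioned over channels. Condition statistics compare each treatment
#' against vehicle.
#'
#' @param config A [pipeline_config()].
#' @return List of class `"pipeline_result"`: `quant` (merged
#'   `"quant_table"`), `acq_direct`, `acq_lmw` (acquisition logs),
#'   `absolute` (per-channel amol), `stats` (condition tests vs DMSO),
#'   `report` (per-peptide per-condition summary), `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  design <- validate_design(config$design)
  gamma_ids <- unique(design$peptide_id[design$sim_group %in%
                                          c("gamma_short", "gamma_long")])

  empty_result <- function() {
    structure(list(quant = NULL, acq_direct = NULL, acq_lmw = NULL,
                   absolute = tibble::tibble(), stats = tibble::tibble(),
                   report = tibble::tibble(), config = config),
              class = "pipeline_result")
  }
  if (nrow(design) == 0) return(empty_result())

  run_branch <- function(run) {
    acq <- run_engine(run, config$engine)
    qt <- quant_table(acq, config$channels, impurity = config$impurity)
    list(acq = acq, qt = qt)
  }

  run_d <- simulate_run(design, config$channels, config$effects,
                        engine_mode = "triggered", seed = config$seed,
                        params = config$params, impurity = config$impurity)
  direct <- run_branch(run_d)
  lmw_truth <- apply_lmw_filtration(run_d$truth, config$lmw_cutoff_da)
  lmw <- run_branch(rebuild_run(run_d, lmw_truth))

  # merge: gamma products from the filtrate branch, the rest direct
  sn <- dplyr::bind_rows(
    direct$qt$sn[!direct$qt$sn$peptide_id %in% gamma_ids, ],
    lmw$qt$sn[lmw$qt$sn$peptide_id %in% gamma_ids, ])
  qt <- direct$qt
  qt$sn <- sn
  qt$n_scans <- dplyr::bind_rows(
    direct$qt$n_scans[!direct$qt$n_scans$peptide_id %in% gamma_ids, ],
    lmw$qt$n_scans[lmw$qt$n_scans$peptide_id %in% gamma_ids, ])
  qt <- background_subtract(qt)

  # SIM absolute branch (same two-branch structure)
  sim_d <- simulate_run(design, config$channels, config$effects,
                        engine_mode = "sim", seed = config$seed,
                        params = config$params, impurity = config$impurity)
  sim_l <- rebuild_run(sim_d, apply_lmw_filtration(sim_d$truth,
                                                   config$lmw_cutoff_da))
  areas <- dplyr::bind_rows(
    dplyr::filter(sim_peak_areas(sim_d), !.data$peptide_id %in% gamma_ids),
    dplyr::filter(sim_peak_areas(sim_l), .data$peptide_id %in% gamma_ids))
  absolute <- per_channel_absolute(sim_absolute(areas), qt)

  # Condition statistics run on impurity-corrected S/N. Total-reporter
  # normalisation assumes equal bulk loading visible in the stream; a
  # targeted-only stream has no bulk proteome, so loading factors are
  # unity here (they would come from a parallel global analysis).
  qn <- qt
  treatments <- setdiff(unique(config$channels$condition), c("DMSO", "KO"))
  stats_tbl <- purrr::map_dfr(treatments, function(tr) {
    dplyr::mutate(condition_test(qn, "DMSO", tr), contrast = paste0("DMSO_vs_", tr))
  })

  report <- dplyr::summarise(
    dplyr::left_join(qn$sn,
                     dplyr::select(absolute, "peptide_id", "channel_id",
                                   "amol"),
                     by = c("peptide_id", "channel_id")),
    mean_sn = mean(.data$sn), background = .data$background[1],
    mean_amol = mean(.data$amol),
    .by = c("peptide_id", "condition"))

  out <- structure(
    list(quant = qt, quant_norm = qn, acq_direct = direct$acq,
         acq_lmw = lmw$acq, absolute = absolute, stats = stats_tbl,
         report = report, config = config),
    class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_outputs(out, config$out_dir)
  out
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(result$quant$sn, file.path(out_dir, "quant_sn.tsv"))
  readr::write_tsv(result$absolute, file.path(out_dir, "absolute_amol.tsv"))
  readr::write_tsv(result$stats, file.path(out_dir, "condition_stats.tsv"))
  readr::write_tsv(result$report, file.path(out_dir, "report.tsv"))
  readr::write_tsv(result$acq_direct$log, file.path(out_dir, "acquisition_log.tsv"))
  cfg <- result$config
  jsonlite::write_json(
    list(seed = cfg$seed, engine = unclass(cfg$engine),
         params = unclass(cfg$params), effects = unclass(cfg$effects),
         lmw_cutoff_da = cfg$lmw_cutoff_da,
         channels = as.data.frame(cfg$channels)),
    file.path(out_dir, "config.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Write/read a simulated scan stream
#'
#' Columnar TSV pair: one table of scans, one of peaks keyed by `scan_id`.
#'
#' @param run A `"sim_run"`.
#' @param dir Directory for `scans.tsv` / `peaks.tsv`.
#' @return `write_scans()` the directory; `read_scans()` a list with
#'   `scans` and `peaks` matching the run layout.
#' @export
write_scans <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(run$scans, file.path(dir, "scans.tsv"))
  pk <- purrr::imap_dfr(run$peaks, function(p, i) {
    if (nrow(p) == 0) return(NULL)
    dplyr::mutate(p, scan_id = run$scans$scan_id[i], .before = 1)
  })
  readr::write_tsv(pk, file.path(dir, "peaks.tsv"))
  invisible(dir)
}

#' @rdname write_scans
#' @export
read_scans <- function(dir) {
  scans <- readr::read_tsv(file.path(dir, "scans.tsv"), show_col_types = FALSE)
  pk <- readr::read_tsv(file.path(dir, "peaks.tsv"), show_col_types = FALSE)
  peaks <- lapply(scans$scan_id, function(id) {
    dplyr::select(pk[pk$scan_id == id, ], -"scan_id")
  })
  list(scans = scans, peaks = peaks)
}
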