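#' Synthetic APP-like demo substrate
#'
#' A compact synthetic membrane-substrate construct used throughout the
#' package's examples and simulations. It is NOT the real APP sequence: it
#' embeds the genuine amyloid-beta region (so the half-tryptic
#' gamma-secretase products match the real A-beta 37/38/39/40/42/43
#' C-terminal peptides, e.g. `GAIIGLMVGGVVIA` for A-beta 42) inside short
#' synthetic flanking segments that reproduce the tryptic context of the
#' Swedish-mutant juxtamembrane region (`...NL | DAEFR...`), a transmembrane
#' continuation and a short cytosolic tail.
#'
#' @return A [protein_sequence()] with id `"APPsyn"`.
#' @export
demo_substrate <- function() {
  protein_sequence(
    "APPsyn",
    paste0(
      "SAMPLEK",            # 1-7   synthetic N-terminal stub
      "TEEISEVNL",          # 8-16  Swedish-mutant juxtamembrane (ends at BACE1 site)
      "DAEFRHDSGYEVHHQK",   # 17-32 A-beta 1-16
      "LVFFAEDVGSNK",       # 33-44 A-beta 17-28
      "GAIIGLMVGGVVIA",     # 45-58 A-beta 29-42
      "TVIVITLVMLK",        # 59-69 A-beta 43 + transmembrane continuation
      "GYENPTYK"            # 70-77 synthetic cytosolic tail
    )
  )
}

#' Cleavage sites monitored on the demo substrate
#'
#' The BACE1 juxtamembrane site plus the gamma-secretase sites generating
#' A-beta 37, 38, 39, 40, 42 and 43, in the demo construct's own 1-based
#' numbering.
#'
#' @return Tibble with columns `protein_id`, `position`, `protease`,
#'   `product_label`, `sim_group`.
#' @export
demo_sites <- function() {
  tibble::tibble(
    protein_id = "APPsyn",
    position = c(16L, 53L, 54L, 55L, 56L, 58L, 59L),
    protease = c("BACE1", rep("GAMMA_SECRETASE", 6)),
    product_label = c("CTFbeta", "Abeta37", "Abeta38", "Abeta39",
                      "Abeta40", "Abeta42", "Abeta43"),
    sim_group = c("bace1", "gamma_short", "gamma_short", "gamma_long",
                  "gamma_long", "gamma_long", "gamma_long")
  )
}

#' Build a trigger/target design table
#'
#' Expands cleavage sites into monitored peptide species: for each site the
#' parent tryptic peptide and the half-tryptic product(s), each as a
#' TRIGGER row (synthetic reference peptide, TMTsh label, spiked at a known
#' amount) paired with an identical-sequence TARGET row (endogenous,
#' standard label). For gamma-secretase sites only the N-half (the secreted
#' A-beta species ending at the cleavage) is monitored; for the BACE1 site
#' both halves and the parent are monitored.
#'
#' @param protein A [protein_sequence()].
#' @param sites Tibble like [demo_sites()].
#' @param target_label Label chemistry on endogenous targets (`"tmt"`).
#' @param charges Charge state assigned to each species (recycled).
#' @param rt_start,rt_spacing Scheduled retention apexes (minutes): peptides
#'   are laid out `rt_start, rt_start + rt_spacing, ...` in design order.
#' @param trigger_amount_amol Trigger spike amount per peptide (amol).
#' @param base_amount_amol Named baseline endogenous abundances (amol) per
#'   `peptide_id`; unnamed scalar recycles.
#' @return Tibble of class `"design_table"`; one row per (peptide, role)
#'   with columns `peptide_id`, `pair_id`, `sequence`, `termini`,
#'   `protein_id`, `site_position`, `protease`, `product_label`,
#'   `sim_group`, `label`, `n_label_sites`, `charge`, `scheduled_rt_min`,
#'   `role`, `amount_amol`.
#' @export
build_design <- function(protein, sites = demo_sites(),
                         target_label = "tmt", charges = 2L,
                         rt_start = 10, rt_spacing = 1,
                         trigger_amount_amol = 100,
                         base_amount_amol = NULL) {
  specs <- list()
  for (i in seq_len(nrow(sites))) {
    s <- sites[i, ]
    prods <- half_tryptic_products(protein, s$position,
                                   product_label = s$product_label)
    if (s$protease == "GAMMA_SECRETASE") {
      keep <- prods[prods$role == "n_half", ]
      keep$peptide_id <- s$product_label
      keep$sim_group <- s$sim_group
    } else {
      keep <- prods
      keep$peptide_id <- paste0(s$product_label, c("_parent", "_nhalf", "_chalf"))
      keep$sim_group <- c("bace1_parent", "bace1_product", "bace1_product")
    }
    keep$protease <- s$protease
    specs[[i]] <- keep
  }
  specs <- dplyr::bind_rows(specs)
  specs <- dplyr::distinct(specs, .data$sequence, .keep_all = TRUE)
  n <- nrow(specs)
  base <- if (is.null(base_amount_amol)) {
    default_base_amounts()[specs$peptide_id]
  } else if (is.null(names(base_amount_amol))) {
    rep_len(base_amount_amol, n)
  } else {
    base_amount_amol[specs$peptide_id]
  }
  base[is.na(base)] <- 100
  specs <- dplyr::mutate(
    specs,
    pair_id = .data$peptide_id,
    label = target_label,
    n_label_sites = n_label_sites(.data$sequence),
    charge = rep_len(as.integer(charges), n),
    scheduled_rt_min = rt_start + rt_spacing * (dplyr::row_number() - 1),
    base_amount_amol = unname(base)
  )
  target <- dplyr::mutate(specs, role = "TARGET",
                          amount_amol = .data$base_amount_amol)
  trigger <- dplyr::mutate(specs, role = "TRIGGER", label = "tmtsh",
                           amount_amol = rep_len(trigger_amount_amol, n))
  out <- dplyr::bind_rows(trigger, target)
  out <- dplyr::select(out, "peptide_id", "pair_id", "sequence", "termini",
                       "protein_id", "site_position", "protease",
                       "product_label", "sim_group", "label",
                       "n_label_sites", "charge", "scheduled_rt_min",
                       "role", "amount_amol")
  class(out) <- c("design_table", class(out))
  out
}

# Baseline endosomal abundances (amol) for the demo peptides; long A-beta
# species are most abundant, short ones detectable but lower.
default_base_amounts <- function() {
  c(CTFbeta_parent = 500, CTFbeta_nhalf = 300, CTFbeta_chalf = 300,
    Abeta37 = 60, Abeta38 = 80, Abeta39 = 150, Abeta40 = 200,
    Abeta42 = 180, Abeta43 = 40)
}

validate_design <- function(design) {
  need <- c("peptide_id", "pair_id", "sequence", "termini", "label",
            "n_label_sites", "charge", "scheduled_rt_min", "role")
  miss <- setdiff(need, names(design))
  if (length(miss) > 0) {
    stop("design table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  tr <- design[design$role == "TRIGGER", ]
  tg <- design[design$role == "TARGET", ]
  if (!all(tr$label == "tmtsh")) {
    stop("all TRIGGER rows must carry the tmtsh label", call. = FALSE)
  }
  m <- match(tg$pair_id, tr$pair_id)
  if (anyNA(m) || !all(tg$sequence == tr$sequence[m])) {
    stop("every TARGET must pair with one TRIGGER of identical sequence",
         call. = FALSE)
  }
  bad <- design$n_label_sites != n_label_sites(design$sequence)
  if (any(bad)) {
    stop("n_label_sites inconsistent with sequence for: ",
         paste(unique(design$peptide_id[bad]), collapse = ", "), call. = FALSE)
  }
  invisible(design)
}

#' Read/write design tables
#'
#' Lossless TSV round trip for the trigger/target design schema. Unknown
#' columns in a file are an explicit error, never silently dropped.
#'
#' @param design A design table (see [build_design()]).
#' @param path File path.
#' @return `read_design()` returns the design tibble; `write_design()` the
#'   path, invisibly.
#' @export
write_design <- function(design, path) {
  readr::write_tsv(design, path)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           charge = readr::col_integer(),
                           n_label_sites = readr::col_integer()))
  known <- c("peptide_id", "pair_id", "sequence", "termini", "protein_id",
             "site_position", "protease", "product_label", "sim_group",
             "label", "n_label_sites", "charge", "scheduled_rt_min", "role",
             "amount_amol", "base_amount_amol")
  unknown <- setdiff(names(out), known)
  if (length(unknown) > 0) {
    stop("unknown design column(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  validate_design(out)
  class(out) <- c("design_table", class(out))
  out
}

#' Read protein sequences from FASTA
#'
#' Uses Biostrings when available, otherwise a minimal reader that handles
#' wrapped or unwrapped records identically.
#'
#' @param path FASTA file path.
#' @param isoform_offset Numbering offset applied to every record.
#' @return Tibble with one [protein_sequence()] row per record.
#' @export
read_fasta <- function(path, isoform_offset = 0L) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    aa <- Biostrings::readAAStringSet(path)
    ids <- sub("\\s.*$", "", names(aa))
    seqs <- as.character(aa)
  } else {
    lines <- readLines(path)
    hdr <- grepl("^>", lines)
    ids <- sub("^>", "", sub("\\s.*$", "", lines[hdr]))
    grp <- cumsum(hdr)
    seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                   function(x) paste(x, collapse = ""), "")
  }
  dplyr::bind_rows(purrr::map2(ids, seqs, protein_sequence,
                               isoform_offset = isoform_offset))
}
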