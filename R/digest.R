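#' Construct a protein sequence record
#'
#' @param id Protein identifier.
#' @param residues Amino-acid string (canonical 20 letters).
#' @param isoform_offset Residue-numbering origin offset: positions are
#'   interpreted as `isoform_offset + i` for residue `i` of `residues`, so
#'   that sites quoted in a specific isoform's numbering (e.g. the 751-residue
#'   APP isoform) resolve correctly when only a fragment is supplied.
#' @return A tibble row of class `"protein_seq"` with columns `id`,
#'   `residues`, `isoform_offset`, `length`.
#' @export
protein_sequence <- function(id, residues, isoform_offset = 0L) {
  stopifnot(is.character(id), length(id) == 1, isoform_offset >= 0)
  if (!nzchar(residues)) stop("empty protein sequence", call. = FALSE)
  check_residues(residues)
  out <- tibble::tibble(id = id, residues = residues,
                        isoform_offset = as.integer(isoform_offset),
                        length = nchar(residues))
  class(out) <- c("protein_seq", class(out))
  out
}

cleavage_positions <- function(residues, protease = c("trypsin", "lysc")) {
  protease <- match.arg(protease)
  aa <- strsplit(residues, "")[[1]]
  n <- length(aa)
  if (protease == "trypsin") {
    # C-terminal to K/R, not before proline
    pos <- which(aa %in% c("K", "R"))
    pos <- pos[pos < n]
    pos[aa[pos + 1L] != "P"]
  } else {
    pos <- which(aa == "K")
    pos[pos < n]
  }
}

#' In-silico proteolytic digestion
#'
#' Digests a protein with trypsin (cleaving C-terminal to K/R except before
#' proline) or LysC (after K), returning all peptides with up to
#' `missed_cleavages` internal sites. The zero-missed-cleavage peptides
#' partition the sequence exactly.
#'
#' @param protein A [protein_sequence()] (or a plain string, given id "prot").
#' @param protease `"trypsin"` or `"lysc"`.
#' @param missed_cleavages Maximum number of internal uncleaved sites.
#' @return Tibble with columns `protein_id`, `sequence`, `start`, `end`
#'   (isoform numbering), `missed`, `termini` (`"full_tryptic"`).
#' @examples
#' digest(protein_sequence("p", "AKRG"))$sequence   # "AK" "R" "G"
#' digest(protein_sequence("p", "AKPR"))$sequence   # "AKPR"
#' @export
digest <- function(protein, protease = c("trypsin", "lysc"),
                   missed_cleavages = 0L) {
  protease <- match.arg(protease)
  if (is.character(protein)) protein <- protein_sequence("prot", protein)
  res <- protein$residues
  n <- nchar(res)
  cut_after <- cleavage_positions(res, protease)
  bounds <- c(0L, cut_after, n)           # peptide i spans bounds[i]+1 .. bounds[i+1]
  np <- length(bounds) - 1L
  rows <- list()
  for (i in seq_len(np)) {
    for (j in i:min(np, i + missed_cleavages)) {
      s <- bounds[i] + 1L
      e <- bounds[j + 1L]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        protein_id = protein$id,
        sequence = substr(res, s, e),
        start = s + protein$isoform_offset,
        end = e + protein$isoform_offset,
        missed = j - i
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  out$termini <- "full_tryptic"
  dplyr::arrange(out, .data$start, .data$missed)
}

#' Half-tryptic products of an internal cleavage site
#'
#' A protease cleavage site (e.g. a BACE1 or gamma-secretase site) that falls
#' strictly inside one tryptic peptide splits that parent into two
#' half-tryptic species: the N-half keeps the tryptic N-terminus and gains a
#' protease-generated C-terminus (`half_tryptic_c`), the C-half the reverse
#' (`half_tryptic_n`). A site coinciding with a tryptic boundary yields no
#' half-tryptic species and is an error.
#'
#' @param protein A [protein_sequence()].
#' @param site_position Cleavage position: the protease cuts after this
#'   residue, 1-based in isoform numbering (i.e. including `isoform_offset`).
#' @param protease Digestion protease, `"trypsin"` or `"lysc"`.
#' @param product_label Optional name for the cleavage product
#'   (e.g. `"Abeta42"`); stored on both halves.
#' @return Tibble with three rows (`role` = parent, n_half, c_half) and
#'   columns `protein_id`, `sequence`, `start`, `end`, `termini`,
#'   `site_position`, `product_label`.
#' @examples
#' half_tryptic_products(protein_sequence("toy", "AACDK"), 2)
#' @export
half_tryptic_products <- function(protein, site_position,
                                  protease = c("trypsin", "lysc"),
                                  product_label = NA_character_) {
  protease <- match.arg(protease)
  peps <- digest(protein, protease, missed_cleavages = 0L)
  hit <- peps[peps$start <= site_position & peps$end > site_position, ]
  if (nrow(hit) == 0) {
    stop("cleavage site at position ", site_position, " coincides with a ",
         protease, " boundary (or lies outside the sequence); no ",
         "half-tryptic species exists", call. = FALSE)
  }
  parent <- hit[1, ]
  k <- site_position - parent$start + 1L   # residues in the N-half
  tibble::tibble(
    protein_id = protein$id,
    role = c("parent", "n_half", "c_half"),
    sequence = c(parent$sequence,
                 substr(parent$sequence, 1L, k),
                 substr(parent$sequence, k + 1L, nchar(parent$sequence))),
    start = c(parent$start, parent$start, site_position + 1L),
    end = c(parent$end, site_position, parent$end),
    termini = c("full_tryptic", "half_tryptic_c", "half_tryptic_n"),
    site_position = site_position,
    product_label = product_label
  )
}
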