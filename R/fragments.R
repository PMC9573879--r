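#' Theoretical b/y fragment ions
#'
#' Enumerates singly-indexed b- and y-type fragment ions (b1..b(L-1),
#' y1..y(L-1)) for each requested charge state, with label-aware masses:
#' the peptide N-terminal label rides on every b ion, and lysine-side labels
#' ride on whichever fragment contains the lysine. `carries_label` is `TRUE`
#' iff the fragment contains at least one labelled site (always true for
#' b ions of a labelled peptide). Cysteines are carbamidomethylated
#' statically.
#'
#' @param sequence Single peptide sequence.
#' @param charges Integer vector of positive fragment charge states.
#' @param label Label chemistry (`"none"`, `"tmt"`, `"tmtpro"`, `"tmtsh"`).
#' @param mods A [mod_table()].
#' @return Tibble with columns `series` ("b"/"y"), `index`, `charge`,
#'   `mz` (Th), `carries_label`.
#' @examples
#' fragment_ions("GGR", charges = 1)
#' @export
fragment_ions <- function(sequence, charges = 1L, label = "none",
                          mods = mod_table()) {
  stopifnot(length(sequence) == 1, nzchar(sequence))
  if (any(charges <= 0)) stop("fragment charge must be positive", call. = FALSE)
  check_residues(sequence)
  aa <- strsplit(sequence, "")[[1]]
  L <- length(aa)
  lab <- label_mass_of(label, mods)
  res <- AA_MONO[aa] + ifelse(aa == "C", mods$carbamidomethyl_c, 0) +
    ifelse(aa == "K", lab, 0)
  csum <- cumsum(unname(res))
  idx <- seq_len(L - 1L)
  # neutral fragment masses
  b_neutral <- csum[idx] + lab                    # N-terminal label on b ions
  y_neutral <- (csum[L] - csum[L - idx]) + MASS_WATER
  y_lab <- (rev(cumsum(rev(aa == "K")))[L - idx + 1L] > 0)
  base <- dplyr::bind_rows(
    tibble::tibble(series = "b", index = idx, neutral = b_neutral,
                   carries_label = lab > 0),
    tibble::tibble(series = "y", index = idx, neutral = y_neutral,
                   carries_label = y_lab & lab > 0)
  )
  out <- tidyr::crossing(base, charge = as.integer(charges))
  out$mz <- (out$neutral + out$charge * MASS_PROTON) / out$charge
  dplyr::select(out, "series", "index", "charge", "mz", "carries_label")
}

# memoised fragment tables for the simulator/engine hot path; key includes
# the label masses so differently-configured mod tables never collide
.frag_memo <- new.env(parent = emptyenv())

fragments_cached <- function(sequence, label, mods) {
  key <- paste(sequence, label, paste(mods$label_mass, collapse = ","),
               sep = "|")
  hit <- .frag_memo[[key]]
  if (is.null(hit)) {
    hit <- fragment_ions(sequence, charges = 1L, label = label, mods = mods)
    .frag_memo[[key]] <- hit
  }
  hit
}
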