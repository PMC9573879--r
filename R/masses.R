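#' Monoisotopic residue masses
#'
#' Named vector of monoisotopic masses (Da) for the 20 canonical amino-acid
#' residues (i.e. the mass contributed by each residue inside a peptide
#' chain, excluding the terminal water).
#'
#' @format Named numeric vector of length 20.
#' @export
AA_MONO <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

#' Physical constants used throughout
#' @name constants
#' @keywords internal
MASS_WATER <- 18.010565
MASS_PROTON <- 1.007276

#' Modification and label mass table
#'
#' Builds the table of static/variable modification masses and isobaric
#' label masses used for peptide and fragment mass computation. Label
#' masses for TMT (+229.162 Da) and TMTpro (+304.207 Da) are the standard
#' reagent monoisotopic additions; the "super-heavy" TMTsh reagent used on
#' trigger peptides has no published monoisotopic mass and must be supplied
#' by the user before any TMTsh arithmetic is performed.
#'
#' @param tmtsh_mass Monoisotopic mass (Da) of the TMTsh label. Defaults to
#'   `NA`; operations that need it raise an error until it is set.
#' @param tmt_mass,tmtpro_mass Label masses (Da); override only for
#'   non-standard reagent lots.
#' @param carbamidomethyl_c Static cysteine alkylation mass (Da).
#' @param oxidation_m Variable methionine oxidation mass (Da).
#'
#' @return A list of class `"mod_table"` with elements `label_mass`
#'   (named vector for `tmt`, `tmtpro`, `tmtsh`, `none`),
#'   `carbamidomethyl_c` and `oxidation_m`.
#' @examples
#' mods <- mod_table(tmtsh_mass = 235.1767)
#' mods$label_mass[["tmt"]]
#' @export
mod_table <- function(tmtsh_mass = NA_real_,
                      tmt_mass = 229.162,
                      tmtpro_mass = 304.207,
                      carbamidomethyl_c = 57.021,
                      oxidation_m = 15.995) {
  stopifnot(tmt_mass > 0, tmtpro_mass > 0,
            carbamidomethyl_c > 0, oxidation_m > 0)
  if (!is.na(tmtsh_mass) && tmtsh_mass <= 0) {
    stop("`tmtsh_mass` must be a positive mass in Da", call. = FALSE)
  }
  structure(
    list(
      label_mass = c(tmt = tmt_mass, tmtpro = tmtpro_mass,
                     tmtsh = tmtsh_mass, none = 0),
      carbamidomethyl_c = carbamidomethyl_c,
      oxidation_m = oxidation_m
    ),
    class = "mod_table"
  )
}

label_mass_of <- function(label, mods) {
  label <- match.arg(tolower(label), c("tmt", "tmtpro", "tmtsh", "none"))
  m <- mods$label_mass[[label]]
  if (is.na(m)) {
    stop("TMTsh label mass is not configured; supply `tmtsh_mass` to ",
         "`mod_table()` (the reagent's monoisotopic mass is vendor-supplied).",
         call. = FALSE)
  }
  m
}

check_residues <- function(sequence) {
  bad <- setdiff(unique(strsplit(paste(sequence, collapse = ""), "")[[1]]),
                 names(AA_MONO))
  if (length(bad) > 0) {
    stop("unknown residue letter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(sequence)
}

#' Number of isobaric label sites on a peptide
#'
#' One site at the peptide N-terminus plus one per lysine residue.
#'
#' @param sequence Character vector of peptide sequences.
#' @return Integer vector.
#' @export
n_label_sites <- function(sequence) {
  1L + stringr::str_count(sequence, "K")
}

#' Monoisotopic peptide mass
#'
#' Computes the neutral monoisotopic mass of (optionally labelled) peptides:
#' the sum of residue masses plus water, plus one label mass per label site
#' (N-terminus + lysines), plus static carbamidomethylation on every
#' cysteine and optional methionine oxidations.
#'
#' @param sequence Character vector of peptide sequences (canonical letters).
#' @param label Isobaric label chemistry: `"none"`, `"tmt"`, `"tmtpro"` or
#'   `"tmtsh"` (recycled across `sequence`).
#' @param mods A [mod_table()].
#' @param cys_cam Apply static carbamidomethylation to cysteines?
#' @param n_ox_m Number of oxidised methionines per peptide (recycled).
#' @return Numeric vector of neutral masses (Da).
#' @examples
#' peptide_mass("GR")                       # 231.1332
#' peptide_mass("K", label = "tmt") - peptide_mass("K")  # 2 x 229.162
#' @export
peptide_mass <- function(sequence, label = "none", mods = mod_table(),
                         cys_cam = TRUE, n_ox_m = 0L) {
  if (any(!nzchar(sequence)) || length(sequence) == 0) {
    stop("peptide sequence must be non-empty", call. = FALSE)
  }
  check_residues(sequence)
  label <- rep_len(label, length(sequence))
  n_ox_m <- rep_len(n_ox_m, length(sequence))
  res_sum <- vapply(strsplit(sequence, ""), function(a) sum(AA_MONO[a]), 0,
                    USE.NAMES = FALSE)
  lab <- vapply(label, label_mass_of, 0, mods = mods, USE.NAMES = FALSE)
  n_sites <- n_label_sites(sequence)
  cam <- if (cys_cam) stringr::str_count(sequence, "C") * mods$carbamidomethyl_c else 0
  unname(res_sum + MASS_WATER + n_sites * lab + cam + n_ox_m * mods$oxidation_m)
}

#' Precursor m/z from neutral mass
#'
#' @param mass Neutral monoisotopic mass (Da).
#' @param charge Positive integer charge state.
#' @return m/z (Th).
#' @export
precursor_mz <- function(mass, charge) {
  stopifnot(all(charge >= 1))
  (mass + charge * MASS_PROTON) / charge
}

#' Trigger/target precursor mass offset
#'
#' Trigger peptides carry the super-heavy TMTsh label while the multiplexed
#' endogenous targets carry standard TMT/TMTpro; the identical sequence then
#' differs in mass by the per-site label difference times the number of
#' label sites. The target precursor sits below the trigger by
#' `offset / charge` Th.
#'
#' @param sequence Peptide sequence (determines label-site count), or
#'   alternatively supply `n_sites` directly.
#' @param target_label Label chemistry on the endogenous target
#'   (`"tmt"` or `"tmtpro"`).
#' @param mods A [mod_table()] with `tmtsh_mass` configured.
#' @param n_sites Optional explicit label-site count (overrides `sequence`).
#' @return Mass offset (Da), `n_sites * (mass_tmtsh - mass_target_label)`.
#' @export
trigger_target_offset <- function(sequence = NULL, target_label = "tmt",
                                  mods = mod_table(), n_sites = NULL) {
  if (is.null(n_sites)) n_sites <- n_label_sites(sequence)
  if (any(n_sites < 0)) stop("n_sites must be >= 0", call. = FALSE)
  delta <- label_mass_of("tmtsh", mods) - label_mass_of(target_label, mods)
  n_sites * delta
}
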