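# A peptidoform is a peptide sequence plus a modification string.  The
# modification string is ";"-separated; each entry is either
#   "<site>:<name>"  with <site> a 1-based position, "nterm" or "cterm", or
#   "<name>"         for a modification whose site is not localized.
# <name> is a registry modification name or a glycan composition string
# ("HexNAc1Hex1NeuAc1").  Unlocalized modifications contribute mass to the
# intact peptidoform but cannot be placed on a fragment ladder.

#' Parse a peptidoform modification string
#'
#' @param mods Modification string (see Details in [peptide_neutral_mass()]),
#'   `""` or `NA` for an unmodified peptide.
#' @param registry Modification registry, see [mod_registry()].
#' @return A tibble with columns `site` (integer position, `0` for N-term,
#'   `-1` for C-term, `NA` for unlocalized), `name`, `is_glycan`, `delta`.
#' @export
parse_mods <- function(mods, registry = mod_registry()) {
  empty <- tibble(
    site = integer(), name = character(),
    is_glycan = logical(), delta = numeric()
  )
  if (is.null(mods) || length(mods) == 0L || is.na(mods) || !nzchar(mods)) {
    return(empty)
  }
  entries <- stringr::str_split_1(mods, ";")
  entries <- stringr::str_trim(entries)
  entries <- entries[nzchar(entries)]
  if (length(entries) == 0L) return(empty)
  parsed <- purrr::map(entries, function(e) {
    parts <- stringr::str_split_1(e, ":")
    if (length(parts) == 2L) {
      site_raw <- stringr::str_trim(parts[1])
      name <- stringr::str_trim(parts[2])
      site <- switch(tolower(site_raw),
        nterm = 0L, cterm = -1L,
        {
          s <- suppressWarnings(as.integer(site_raw))
          if (is.na(s)) abort(paste0("Bad modification site '", site_raw, "'"))
          s
        }
      )
    } else if (length(parts) == 1L) {
      site <- NA_integer_
      name <- parts[1]
    } else {
      abort(paste0("Bad modification entry '", e, "'"))
    }
    is_gly <- is_glycan_composition(name)
    delta <- if (is_gly) glycan_mass(name) else .mod_delta(name, registry)
    tibble(site = site, name = name, is_glycan = is_gly, delta = delta)
  })
  dplyr::bind_rows(parsed)
}

.check_sequence <- function(sequence) {
  if (length(sequence) != 1L || is.na(sequence) || !nzchar(sequence)) {
    abort("Peptide sequence must be a non-empty string")
  }
  letters <- stringr::str_split_1(sequence, "")
  bad <- setdiff(letters, names(.AA_MASS))
  if (length(bad) > 0L) {
    abort(paste0(
      "Unknown residue letter(s) in '", sequence, "': ",
      paste(unique(bad), collapse = ", ")
    ))
  }
  letters
}

.validate_mod_sites <- function(letters, mods_tbl, registry = mod_registry()) {
  n <- length(letters)
  for (i in seq_len(nrow(mods_tbl))) {
    site <- mods_tbl$site[i]
    if (is.na(site) || site %in% c(0L, -1L)) next
    if (site < 1L || site > n) {
      abort(paste0("Modification site ", site, " outside peptide of length ", n))
    }
    res <- letters[site]
    if (mods_tbl$is_glycan[i]) {
      if (!res %in% c("S", "T", "N")) {
        abort(paste0("Glycan at position ", site, " requires S/T/N, found ", res))
      }
    } else {
      targets <- registry$targets[match(mods_tbl$name[i], registry$name)]
      if (!is.na(targets) && targets != "*" &&
          !stringr::str_detect(targets, stringr::fixed(res))) {
        abort(paste0(
          mods_tbl$name[i], " at position ", site,
          " requires one of [", targets, "], found ", res
        ))
      }
    }
  }
  invisible(TRUE)
}

#' Monoisotopic neutral mass of a peptidoform
#'
#' The neutral mass is the sum of residue masses plus one water plus the sum
#' of all modification deltas (registry modifications and glycans alike), so
#' it is additive in modifications.
#'
#' @param sequence Peptide sequence using the 20 standard one-letter codes.
#'   Vectorized; recycled against `mods`.
#' @param mods Modification string.  `";"`-separated entries of the form
#'   `"site:name"` (`site` 1-based, or `nterm`/`cterm`) or a bare `"name"`
#'   for an unlocalized modification; `name` is a [mod_registry()] name or a
#'   glycan composition such as `"HexNAc1Hex1NeuAc1"`.
#' @param registry Modification registry.
#' @return Numeric vector of neutral masses in Da.
#' @export
#' @examples
#' peptide_neutral_mass("VATVSLPR")                   # 841.5021
#' peptide_neutral_mass("TTEFWK", "Methyl")           # 824.4068
peptide_neutral_mass <- function(sequence, mods = "", registry = mod_registry()) {
  n <- max(length(sequence), length(mods))
  sequence <- rep_len(sequence, n)
  mods <- rep_len(mods, n)
  purrr::map2_dbl(sequence, mods, function(s, m) {
    letters <- .check_sequence(s)
    mt <- parse_mods(m, registry)
    .validate_mod_sites(letters, mt, registry)
    sum(.AA_MASS[letters]) + .WATER + sum(mt$delta)
  })
}

#' Precursor m/z of a peptidoform at a given charge
#'
#' @inheritParams peptide_neutral_mass
#' @param z Positive integer charge state.
#' @return `(neutral_mass + z * 1.007276) / z`, vectorized.
#' @export
#' @examples
#' precursor_mz("VATVSLPR", z = 2)  # 421.7584, the trypsin autolysis reference
precursor_mz <- function(sequence, mods = "", z = 2L, registry = mod_registry()) {
  if (any(z < 1) || any(z != as.integer(z))) {
    abort("Charge z must be a positive integer")
  }
  (peptide_neutral_mass(sequence, mods, registry) + z * .PROTON) / z
}

#' m/z from a neutral mass, and back
#'
#' Convenience converters used when a printed precursor m/z is the input
#' (e.g. recovering a peptide mass from an observed 2+ value before adding a
#' glycan and recomputing a 3+ value).
#'
#' @param mass Neutral monoisotopic mass in Da.
#' @param mz Observed or theoretical m/z.
#' @param z Charge state.
#' @return `mass_to_mz()` returns m/z; `mz_to_mass()` returns the neutral mass.
#' @export
mass_to_mz <- function(mass, z) (mass + z * .PROTON) / z

#' @rdname mass_to_mz
#' @export
mz_to_mass <- function(mz, z) mz * z - z * .PROTON

#' Immonium ion m/z for a (modified) residue
#'
#' Diagnostic low-mass fragment of a single residue, e.g. the phosphotyrosine
#' immonium ion near 216.04 m/z.
#'
#' @param residue Single amino acid letter.
#' @param mods Character vector of registry modification names carried by the
#'   residue (may be empty).
#' @param registry Modification registry.
#' @return `residue_mass + sum(mod deltas) - 26.98763`.
#' @export
#' @examples
#' immonium_mz("Y", "Phospho")  # 216.042
immonium_mz <- function(residue, mods = character(), registry = mod_registry()) {
  if (length(residue) != 1L || !residue %in% names(.AA_MASS)) {
    abort("residue must be a single standard amino acid letter")
  }
  delta <- if (length(mods)) sum(.mod_delta(mods, registry)) else 0
  .AA_MASS[[residue]] + delta - .IMMONIUM_DELTA
}
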