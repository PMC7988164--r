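#' Theoretical b/y fragment ion ladders of a peptidoform
#'
#' Computes the full b_i / y_i ladders with localized modification masses
#' included.  Unlocalized modifications (entered without a site) and glycans
#' contribute only to the full-length y_n/b_n ions, because they cannot be
#' placed on an internal fragment; glycopeptide fragments are instead covered
#' by [glycopeptide_y_ions()].
#'
#' Neutral-loss ladders are available for sulfopeptides (`"SO3"`, -79.95682
#' from fragments spanning a sulfated site) and gamma-carboxylated peptides
#' (`"CO2"`, -43.98983 from fragments spanning a Gla site); losing SO3 from a
#' sulfated fragment restores the unmodified ladder value, the behaviour seen
#' in CID spectra of sulfopeptides.
#'
#' @inheritParams peptide_neutral_mass
#' @param series Character vector from `c("b", "y")`.
#' @param z Fragment charge, 1 or 2.
#' @param neutral_loss `NULL`, `"SO3"` or `"CO2"`: adds a parallel ladder of
#'   loss variants for fragments spanning the relevant modified site(s).
#' @return A tibble with columns `label` (e.g. `"y3"`, `"y3-SO3"`), `series`,
#'   `index`, `z` and `mz`, ordered by series then index.
#' @export
#' @examples
#' fragment_ions("VATVSLPR", series = "y", z = 1)
fragment_ions <- function(sequence, mods = "", series = c("b", "y"), z = 1L,
                          neutral_loss = NULL, registry = mod_registry()) {
  series <- unique(series)
  bad <- setdiff(series, c("b", "y"))
  if (length(bad)) {
    abort(paste0("Unsupported fragment series: ", paste(bad, collapse = ", ")))
  }
  if (!z %in% c(1L, 2L)) abort("Fragment charge z must be 1 or 2")
  letters <- .check_sequence(sequence)
  mt <- parse_mods(mods, registry)
  .validate_mod_sites(letters, mt, registry)
  n <- length(letters)

  site_delta <- numeric(n)            # per-residue localized deltas
  nterm_delta <- 0; cterm_delta <- 0; floating_delta <- 0
  for (i in seq_len(nrow(mt))) {
    s <- mt$site[i]
    if (is.na(s)) floating_delta <- floating_delta + mt$delta[i]
    else if (s == 0L) nterm_delta <- nterm_delta + mt$delta[i]
    else if (s == -1L) cterm_delta <- cterm_delta + mt$delta[i]
    else site_delta[s] <- site_delta[s] + mt$delta[i]
  }

  loss_mass <- c(SO3 = 79.95682, CO2 = 43.98983)
  loss_sites <- integer(0)
  if (!is.null(neutral_loss)) {
    if (!neutral_loss %in% names(loss_mass)) {
      abort("neutral_loss must be NULL, 'SO3' or 'CO2'")
    }
    loss_mod <- if (neutral_loss == "SO3") "Sulfo" else "Gla"
    loss_sites <- mt$site[!is.na(mt$site) & mt$site > 0 & mt$name == loss_mod]
  }

  res_mass <- unname(.AA_MASS[letters]) + site_delta
  pre <- cumsum(res_mass)             # prefix sums for b ions
  suf <- rev(cumsum(rev(res_mass)))   # suffix sums for y ions

  rows <- list()
  for (ser in series) {
    for (i in seq_len(n)) {
      if (ser == "b") {
        # b_n spans the whole chain: include C-terminal and unlocalized deltas
        neutral <- pre[i] + nterm_delta +
          if (i == n) cterm_delta + floating_delta else 0
        spans <- loss_sites[loss_sites <= i]
      } else {
        start <- n - i + 1L
        neutral <- suf[start] + .WATER + cterm_delta +
          if (start == 1L) nterm_delta + floating_delta else 0
        spans <- loss_sites[loss_sites >= start]
      }
      mz <- (neutral + z * .PROTON) / z
      rows[[length(rows) + 1L]] <- tibble(
        label = paste0(ser, i), series = ser, index = i, z = z, mz = mz
      )
      if (length(spans)) {
        rows[[length(rows) + 1L]] <- tibble(
          label = paste0(ser, i, "-", neutral_loss), series = ser,
          index = i, z = z,
          mz = (neutral - loss_mass[[neutral_loss]] + z * .PROTON) / z
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Glycopeptide Y-ion series (peptide + partial glycan)
#'
#' Y0 is the protonated peptide stripped of all glycans, with non-glycan
#' modifications retained.  Monosaccharides are added back innermost-first:
#' all HexNAc residues, then Hex, then the distal residues (NeuAc, NeuGc,
#' Fuc, Xyl) — so for a core-1 style O-glycan Y1 = peptide + HexNAc and
#' Y2 = Y1 + Hex, matching the usual annotation of glycopeptide CID spectra.
#'
#' @inheritParams peptide_neutral_mass
#' @param z Charge of the Y ions (default 1).
#' @return A tibble with columns `label` (`"Y0"`, `"Y1"`, ...), `k`,
#'   `added` (monosaccharide added at that step, `NA` for Y0) and `mz`.
#'   A peptidoform carrying no glycan returns an empty tibble.
#' @export
#' @examples
#' glycopeptide_y_ions("TTEFWK", "Methyl;HexNAc1Hex1NeuAc1")
glycopeptide_y_ions <- function(sequence, mods = "", z = 1L,
                                registry = mod_registry()) {
  letters <- .check_sequence(sequence)
  mt <- parse_mods(mods, registry)
  .validate_mod_sites(letters, mt, registry)
  gly <- mt[mt$is_glycan, , drop = FALSE]
  if (nrow(gly) == 0L) {
    return(tibble(
      label = character(), k = integer(),
      added = character(), mz = numeric()
    ))
  }
  counts <- Reduce(`+`, purrr::map(gly$name, parse_glycan))
  order_names <- c("HexNAc", "Hex", "NeuAc", "NeuGc", "Fuc", "Xyl")
  sugars <- unlist(purrr::map(order_names, ~ rep(.x, counts[[.x]])))

  bare <- sum(.AA_MASS[letters]) + .WATER + sum(mt$delta[!mt$is_glycan])
  masses <- bare + cumsum(c(0, unname(.MONO_MASS[sugars])))
  tibble(
    label = paste0("Y", seq_along(masses) - 1L),
    k = seq_along(masses) - 1L,
    added = c(NA_character_, sugars),
    mz = (masses + z * .PROTON) / z
  )
}
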