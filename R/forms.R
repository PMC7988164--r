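#' Enumerate the carboxyforms of a GLA-domain peptide
#'
#' A carboxyform is the peptide variant class with k gamma-carboxylated
#' glutamates ("+44 x k").  Quantification treats carboxyforms by count, not
#' by site combination, so one representative peptidoform per k is emitted
#' (the first k sites carry the modification; all variants with equal k have
#' equal mass, making the representative exact for mass purposes).
#'
#' @inheritParams peptide_neutral_mass
#' @param gla_sites Integer positions of carboxylatable glutamates within the
#'   peptide (must be E residues). May be empty.
#' @return A tibble with columns `k`, `mods` (the representative modification
#'   string), `neutral_mass`.  Masses form an arithmetic sequence with step
#'   43.98983.
#' @export
#' @examples
#' enumerate_carboxyforms("LEEFVQGNLER", gla_sites = c(2, 3, 10))
enumerate_carboxyforms <- function(sequence, mods = "", gla_sites = integer(),
                                   registry = mod_registry()) {
  letters <- .check_sequence(sequence)
  gla_sites <- sort(unique(as.integer(gla_sites)))
  if (any(gla_sites < 1L | gla_sites > length(letters))) {
    abort("gla_sites outside the peptide")
  }
  not_e <- gla_sites[letters[gla_sites] != "E"]
  if (length(not_e)) {
    abort(paste0(
      "gla_sites must be glutamate (E) positions; position(s) ",
      paste(not_e, collapse = ", "), " are not"
    ))
  }
  base <- if (is.na(mods) || !nzchar(mods)) character(0) else mods
  purrr::map_dfr(0:length(gla_sites), function(k) {
    gla_part <- if (k > 0) paste0(gla_sites[seq_len(k)], ":Gla") else character(0)
    m <- paste(c(base, gla_part), collapse = ";")
    tibble(
      k = k, mods = m,
      neutral_mass = peptide_neutral_mass(sequence, m, registry)
    )
  })
}

#' Enumerate methyl-ester derivatization states of a peptidoform
#'
#' Methanolic HCl derivatization esterifies free carboxyl groups.  The free
#' carboxyl inventory of a peptidoform is the number of Asp side chains, plus
#' Glu side chains not gamma-carboxylated, plus two per gamma-carboxylated
#' Glu (a Gla residue carries two carboxyls), plus one for a free C-terminus.
#' Forms with 0..inventory methyl esters are emitted, capped at
#' `max_methyl` (default 6, the span a derivatized-GLA ion library typically
#' covers).
#'
#' @inheritParams peptide_neutral_mass
#' @param max_methyl Cap on the number of methyl groups enumerated.
#' @param c_term_free Does the peptide carry a free C-terminal carboxyl
#'   (default `TRUE`; set `FALSE` for an amidated C-terminus)?
#' @return A tibble with columns `n_methyl`, `inventory`, `mods`,
#'   `neutral_mass`; one row per 0..min(inventory, max_methyl) methyls.
#' @export
#' @examples
#' enumerate_methylforms("TTEFWK", "3:Gla")  # inventory 3 -> 4 forms
enumerate_methylforms <- function(sequence, mods = "", max_methyl = 6L,
                                  c_term_free = TRUE,
                                  registry = mod_registry()) {
  letters <- .check_sequence(sequence)
  mt <- parse_mods(mods, registry)
  .validate_mod_sites(letters, mt, registry)
  gla_sites <- mt$site[!is.na(mt$site) & mt$site > 0 & mt$name == "Gla"]
  n_gla <- length(unique(gla_sites))
  n_d <- sum(letters == "D")
  n_e_free <- sum(letters == "E") - n_gla
  inventory <- n_d + n_e_free + 2L * n_gla + as.integer(c_term_free)
  top <- min(inventory, as.integer(max_methyl))
  base <- if (is.na(mods) || !nzchar(mods)) character(0) else mods
  purrr::map_dfr(0:top, function(m) {
    methyl_part <- rep("Methyl", m)
    ms <- paste(c(base, methyl_part), collapse = ";")
    tibble(
      n_methyl = m, inventory = inventory, mods = ms,
      neutral_mass = peptide_neutral_mass(sequence, ms, registry)
    )
  })
}
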