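# Monoisotopic constants. Residue masses are the standard amino acid residue
# (chain) masses; proton and water to the precision used throughout the field.

.AA_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

.PROTON <- 1.007276
.WATER <- 18.010565
# residue mass minus this constant gives the immonium ion m/z (loss of CO + H,
# gain of proton folded together)
.IMMONIUM_DELTA <- 26.98763

.MONO_MASS <- c(
  Hex = 162.05282, HexNAc = 203.07937, Fuc = 146.05791, dHex = 146.05791,
  NeuAc = 291.09542, NeuGc = 307.09033, Xyl = 132.04226, Pent = 132.04226
)

#' Monoisotopic residue masses of the twenty standard amino acids
#'
#' @return A named numeric vector of residue (chain) masses in Da.
#' @export
#' @examples
#' amino_acid_masses()[["G"]]
amino_acid_masses <- function() .AA_MASS

#' Monoisotopic residue masses of the supported monosaccharides
#'
#' `Fuc`/`dHex` and `Xyl`/`Pent` are synonyms.
#'
#' @return A named numeric vector of glycan residue masses in Da.
#' @export
monosaccharide_masses <- function() .MONO_MASS

#' Mass of a proton in Da
#' @return A length-one numeric.
#' @export
proton_mass <- function() .PROTON

#' Default registry of posttranslational and chemical modifications
#'
#' Covers the modifications needed to describe a recombinant factor IX
#' peptidoform: gamma-carboxylation of Glu ("Gla", the "+44" class),
#' methyl esterification of free carboxyl groups introduced by methanolic
#' HCl derivatization, Cys propionamide from acrylamide alkylation,
#' Asp oxidation/beta-hydroxylation, Asn/Gln deamidation (including the
#' deamidation left by PNGase F de-N-glycosylation), Tyr sulfation and
#' Ser/Thr/Tyr phosphorylation.  Sulfation and phosphorylation are kept as
#' distinct entries (their deltas differ by 0.0095 Da) even where a spectrum
#' cannot distinguish them.
#'
#' @return A tibble with columns `name`, `delta_mass` (Da, monoisotopic),
#'   `targets` (string of residue letters, `"nterm"`/`"cterm"`, or `"*"` for
#'   unrestricted) and `max_per_site`.
#' @export
#' @examples
#' mod_registry()
mod_registry <- function() {
  tibble::tribble(
    ~name,          ~delta_mass, ~targets,  ~max_per_site,
    "Gla",            43.98983,  "E",       1L,
    "Methyl",         14.01565,  "*",       1L,
    "Propionamide",   71.03711,  "C",       1L,
    "Oxidation",      15.99491,  "D",       1L,
    "Deamidation",     0.98402,  "NQ",      1L,
    "Sulfo",          79.95682,  "Y",       1L,
    "Phospho",        79.96633,  "YST",     1L
  )
}

.mod_delta <- function(name, registry = mod_registry()) {
  i <- match(name, registry$name)
  if (anyNA(i)) {
    abort(paste0(
      "Unknown modification name(s): ",
      paste(unique(name[is.na(i)]), collapse = ", ")
    ))
  }
  registry$delta_mass[i]
}

# ---- glycan compositions ----------------------------------------------------

# A glycan composition string is a run of monosaccharide tokens each followed
# by a count, e.g. "HexNAc1Hex1NeuAc2".  Count zero is allowed.

.GLYCAN_RE <- "^((Hex(NAc)?|Fuc|dHex|Neu(Ac|Gc)|Xyl|Pent)[0-9]+)+$"

is_glycan_composition <- function(x) {
  grepl(.GLYCAN_RE, x)
}

#' Parse a glycan composition string into monosaccharide counts
#'
#' @param composition A string such as `"HexNAc1Hex1NeuAc1NeuGc1"`. Token
#'   order is free; `Fuc`/`dHex` and `Xyl`/`Pent` are interchangeable.
#' @return A named integer vector over the canonical monosaccharide names.
#' @export
#' @examples
#' parse_glycan("HexNAc1Hex1NeuAc2")
parse_glycan <- function(composition) {
  stopifnot(length(composition) == 1L, is.character(composition))
  if (!is_glycan_composition(composition)) {
    abort(paste0("Not a glycan composition string: '", composition, "'"))
  }
  m <- gregexpr("(Hex(NAc)?|Fuc|dHex|Neu(Ac|Gc)|Xyl|Pent)([0-9]+)", composition)
  toks <- regmatches(composition, m)[[1]]
  res <- setNames(integer(length(.MONO_MASS)), names(.MONO_MASS))
  for (tok in toks) {
    name <- sub("[0-9]+$", "", tok)
    count <- as.integer(sub("^[A-Za-z]+", "", tok))
    if (count < 0) abort("Negative monosaccharide count")
    res[[name]] <- res[[name]] + count
  }
  # collapse synonyms onto the canonical names
  res[["Fuc"]] <- res[["Fuc"]] + res[["dHex"]]; res[["dHex"]] <- 0L
  res[["Xyl"]] <- res[["Xyl"]] + res[["Pent"]]; res[["Pent"]] <- 0L
  res[c("Hex", "HexNAc", "Fuc", "NeuAc", "NeuGc", "Xyl")]
}

#' Monoisotopic mass of a glycan composition
#'
#' The mass is the count-weighted sum of monosaccharide residue masses; the
#' empty composition has mass zero.  The nominal form (rounded to the nearest
#' integer) is the "+656"/"+947" shorthand used when labelling glycoforms.
#'
#' @param composition A composition string (see [parse_glycan()]) or a named
#'   count vector. Vectorized over character input.
#' @param nominal If `TRUE`, return the integer-rounded mass.
#' @return Numeric mass in Da (or integer when `nominal = TRUE`).
#' @export
#' @examples
#' glycan_mass("HexNAc1Hex1NeuAc1")              # 656.2276
#' glycan_mass("HexNAc1Hex1NeuAc2", nominal = TRUE)  # 947
glycan_mass <- function(composition, nominal = FALSE) {
  if (is.character(composition)) {
    out <- vapply(composition, function(x) {
      counts <- parse_glycan(x)
      sum(counts * .MONO_MASS[names(counts)])
    }, numeric(1), USE.NAMES = FALSE)
  } else {
    counts <- composition
    if (is.null(names(counts)) || !all(names(counts) %in% names(.MONO_MASS))) {
      abort("Named counts must use monosaccharide names")
    }
    if (any(counts < 0)) abort("Negative monosaccharide count")
    out <- sum(counts * .MONO_MASS[names(counts)])
  }
  if (nominal) round(out) else out
}
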