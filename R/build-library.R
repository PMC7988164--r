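# Construction of synthetic ion libraries matched to a bioprocess scenario:
# product GLA carboxyforms, product PTM variant peptides, product backbone
# peptides, the trypsin autolysis reference, and surrogate HCP peptides.

.entry_transitions <- function(protein, sequence, mods, charge, rt, confidence,
                               family = NA_character_, class = NA_character_,
                               carboxyl_count = NA_integer_, n_transitions = 6L) {
  frags <- fragment_ions(sequence, mods, series = "y", z = 1L)
  frags <- frags %>% filter(.data$index < nchar(sequence))
  frags <- utils::tail(frags, n_transitions)
  if (nrow(frags) == 0L) frags <- fragment_ions(sequence, mods, "y", 1L)[1, ]
  rel <- exp(-0.35 * (seq_len(nrow(frags)) - 1))   # deterministic decay shape
  tibble(
    protein = protein, sequence = sequence, mods = mods,
    precursor_mz = precursor_mz(sequence, mods, charge),
    charge = as.integer(charge),
    fragment = frags$label, fragment_mz = frags$mz,
    rel_intensity = rev(rel) / max(rel),
    rt = rt, confidence = confidence,
    family = family, class = class, carboxyl_count = carboxyl_count
  )
}

#' Build the product-and-reference ion library for a scenario
#'
#' Entries cover: the four GLA tryptic peptide families with all their
#' carboxyforms (annotated with `family`, `class = "k<k>"` and
#' `carboxyl_count` for the stoichiometry module); the PTM variant stand-in
#' peptides for the T38/39 glycoforms, D64 oxidation, D85 and the S141
#' glycosite; three unmodified product backbone peptides used for
#' protein-level rollup; and the trypsin autolysis reference peptide
#' `VATVSLPR` (421.7584 2+), entered with confidence 0.99 as it is added to
#' a library manually rather than identified by search.
#'
#' @param sc A [bioprocess_scenario()].
#' @return An ion library tibble (one transition per row) with annotation
#'   columns `family`, `class`, `carboxyl_count`.
#' @export
build_product_library <- function(sc = bioprocess_scenario()) {
  rows <- list()
  # GLA carboxyform families (underivatized 2+ precursors)
  for (i in seq_len(nrow(sc$gla_families))) {
    fam <- sc$gla_families$family[i]
    seq_ <- sc$gla_families$sequence[i]
    sites <- sc$gla_families$gla_sites[[i]]
    forms <- enumerate_carboxyforms(seq_, gla_sites = sites)
    for (j in seq_len(nrow(forms))) {
      rows[[length(rows) + 1L]] <- .entry_transitions(
        "rFIX", seq_, forms$mods[j], 2L,
        rt = sc$gla_families$rt[i] + 0.3 * forms$k[j], confidence = 0.99,
        family = fam, class = paste0("k", forms$k[j]),
        carboxyl_count = forms$k[j]
      )
    }
  }
  # PTM variant stand-ins (synthetic tryptic peptides; site labels follow
  # mature-product numbering)
  ptm <- tibble::tribble(
    ~site,     ~class,       ~sequence,            ~mods,                          ~charge, ~rt,
    "T38/39",  "+656",       "TTEFWK",             "1:HexNAc1Hex1NeuAc1",          2L, 29.0,
    "T38/39",  "+947/+963",  "TTEFWK",             "1:HexNAc1Hex1NeuAc2",          2L, 29.5,
    "D64",     "unmod",      "DDINSYECWCPFGFEGK",  "",                             2L, 35.0,
    "D64",     "ox",         "DDINSYECWCPFGFEGK",  "1:Oxidation",                  2L, 31.0,
    "D85",     "unmod",      "NCELDVTCNIK",        "",                             2L, 25.0,
    "S141",    "none",       "VSVSQTSK",           "",                             2L, 14.0,
    "S141",    "+656",       "VSVSQTSK",           "4:HexNAc1Hex1NeuAc1",          3L, 14.1,
    "S141",    "+947",       "VSVSQTSK",           "4:HexNAc1Hex1NeuAc2",          3L, 15.6
  )
  for (j in seq_len(nrow(ptm))) {
    rows[[length(rows) + 1L]] <- .entry_transitions(
      "rFIX", ptm$sequence[j], ptm$mods[j], ptm$charge[j],
      rt = ptm$rt[j], confidence = 0.99,
      family = ptm$site[j], class = ptm$class[j]
    )
  }
  # Product backbone peptides (protein-level quantification)
  backbone <- tibble::tribble(
    ~sequence,      ~rt,
    "SALVLQYLR",    38.0,
    "FGSGYVSGWGR",  33.0,
    "VVGGEDAK",     12.0
  )
  for (j in seq_len(nrow(backbone))) {
    rows[[length(rows) + 1L]] <- .entry_transitions(
      "rFIX", backbone$sequence[j], "", 2L,
      rt = backbone$rt[j], confidence = 0.99
    )
  }
  # Trypsin autolysis reference
  rows[[length(rows) + 1L]] <- .entry_transitions(
    "TRYPSIN", "VATVSLPR", "", 2L, rt = 20.0, confidence = 0.99
  )
  dplyr::bind_rows(rows)
}

.random_tryptic_peptide <- function(len) {
  inner <- sample(setdiff(names(.AA_MASS), c("K", "R")), len - 1L, replace = TRUE)
  paste(c(inner, sample(c("K", "R"), 1L)), collapse = "")
}

#' Build surrogate HCP peptide entries for a scenario's panel
#'
#' Each HCP in the panel receives `peptides_per_protein` random tryptic-like
#' peptide entries (6 y-ion transitions each) at random retention times
#' across the gradient.  Deterministic given `seed`.
#'
#' @param sc A [bioprocess_scenario()].
#' @param peptides_per_protein Entries per HCP (default 2).
#' @param seed Seed for sequence/RT draws (default: the scenario seed + 1).
#' @return An ion library tibble.
#' @export
build_hcp_library <- function(sc = bioprocess_scenario(),
                              peptides_per_protein = 2L,
                              seed = sc$seed + 1L) {
  .with_seed(seed, {
    rows <- list()
    for (p in sc$hcp$protein) {
      for (j in seq_len(peptides_per_protein)) {
        seq_ <- .random_tryptic_peptide(sample(7:12, 1L))
        rows[[length(rows) + 1L]] <- .entry_transitions(
          p, seq_, "", 2L,
          rt = round(runif(1, 8, 55), 2), confidence = round(runif(1, 0.95, 1), 3)
        )
      }
    }
    dplyr::bind_rows(rows)
  })
}

#' Build decoy entries carrying high FDR scores when rendered
#'
#' @param n Number of decoy precursors.
#' @param seed Seed.
#' @return An ion library tibble with proteins named `DECOY_<i>`.
#' @export
build_decoy_entries <- function(n = 10L, seed = 99L) {
  .with_seed(seed, {
    rows <- purrr::map(seq_len(n), function(i) {
      .entry_transitions(
        sprintf("DECOY_%03d", i), .random_tryptic_peptide(sample(7:10, 1L)),
        "", 2L, rt = round(runif(1, 8, 55), 2), confidence = 0.95
      )
    })
    dplyr::bind_rows(rows)
  })
}

#' Build the complete scenario ion library
#'
#' Product, reference and HCP entries combined; see
#' [build_product_library()] and [build_hcp_library()].
#'
#' @inheritParams build_hcp_library
#' @return An ion library tibble.
#' @export
build_scenario_library <- function(sc = bioprocess_scenario(),
                                   peptides_per_protein = 2L,
                                   seed = sc$seed + 1L) {
  dplyr::bind_rows(
    build_product_library(sc),
    build_hcp_library(sc, peptides_per_protein, seed)
  )
}
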