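# In-silico proteolysis.  Each rule is (cleavage residues, side, suppression).
# Trypsin's classical "not before Pro" suppression is on by default but
# configurable, since some workflows treat K/R-P bonds as cleavable.

.PROTEASE_RULES <- list(
  trypsin = list(residues = c("K", "R"), side = "C", no_pro = TRUE),
  gluc = list(residues = "E", side = "C", no_pro = FALSE),
  aspn = list(residues = "D", side = "N", no_pro = FALSE),
  chymotrypsin = list(residues = c("F", "W", "Y"), side = "C", no_pro = TRUE)
)

#' Supported protease rules
#' @return Character vector of protease names accepted by [digest()].
#' @export
protease_names <- function() names(.PROTEASE_RULES)

.cleavage_sites <- function(letters, rule, not_before_proline) {
  n <- length(letters)
  if (rule$side == "C") {
    sites <- which(letters %in% rule$residues)
    sites <- sites[sites < n]
    if (not_before_proline && rule$no_pro) {
      sites <- sites[letters[sites + 1L] != "P"]
    }
  } else {
    # N-terminal: cleave before the residue -> boundary after position i-1
    sites <- which(letters %in% rule$residues) - 1L
    sites <- sites[sites >= 1L & sites < n]
  }
  sort(unique(sites))
}

#' Fully specific in-silico digestion of a protein sequence
#'
#' Enumerates all fully specific peptides with at most `max_missed` internal
#' (missed) cleavage sites, carrying their 1-based coordinates in the input
#' protein.  Deterministic: the same protein, protease and cap always yield
#' the same peptide set.
#'
#' @param protein Protein sequence (standard one-letter codes).
#' @param enzyme One of [protease_names()]: `"trypsin"` (C-terminal of K/R),
#'   `"gluc"` (C-terminal of E), `"aspn"` (N-terminal of D),
#'   `"chymotrypsin"` (C-terminal of F/W/Y).
#' @param max_missed Maximum number of missed cleavages (default 0).
#' @param not_before_proline Suppress cleavage when the following residue is
#'   proline, for the proteases that classically obey it (default `TRUE`).
#' @param min_length Drop peptides shorter than this (default 1, keep all).
#' @return A tibble with columns `peptide`, `start`, `end`, `n_missed`,
#'   ordered by `start` then `end`.
#' @export
#' @examples
#' digest("YNSGKLEEFVQGNLER", "trypsin")
digest <- function(protein, enzyme = "trypsin", max_missed = 0L,
                   not_before_proline = TRUE, min_length = 1L) {
  if (!enzyme %in% names(.PROTEASE_RULES)) {
    abort(paste0(
      "Unknown protease '", enzyme, "'; supported: ",
      paste(names(.PROTEASE_RULES), collapse = ", ")
    ))
  }
  letters <- .check_sequence(protein)
  n <- length(letters)
  rule <- .PROTEASE_RULES[[enzyme]]
  sites <- .cleavage_sites(letters, rule, not_before_proline)
  bounds <- c(0L, sites, n)            # peptide spans (bounds[i], bounds[j]]
  k <- length(bounds)
  rows <- list()
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):min(k, i + 1L + max_missed)) {
      start <- bounds[i] + 1L
      end <- bounds[j]
      if (end - start + 1L < min_length) next
      rows[[length(rows) + 1L]] <- tibble(
        peptide = paste(letters[start:end], collapse = ""),
        start = start, end = end, n_missed = j - i - 1L
      )
    }
  }
  dplyr::bind_rows(rows) %>% arrange(.data$start, .data$end)
}

#' Read protein sequences from a FASTA file
#'
#' Thin wrapper around `Biostrings::readAAStringSet()` returning a tibble.
#' Coordinates used downstream are 1-based in the record as given (mature
#' protein numbering is whatever the FASTA provides).
#'
#' @param path Path to a FASTA file of amino acid sequences.
#' @return A tibble with columns `id` (first word of the header),
#'   `description` (full header) and `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  aa <- Biostrings::readAAStringSet(path)
  headers <- names(aa)
  tibble(
    id = stringr::str_extract(headers, "^\\S+"),
    description = headers,
    sequence = as.character(aa)
  )
}
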