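# DIA ion libraries are long tab-separated tables, one transition per row.
# Required columns (extra columns such as family/carboxyl annotations are
# carried through unchanged):
#   protein, sequence, mods, precursor_mz, charge, fragment, fragment_mz,
#   rel_intensity, rt, confidence

.LIB_COLS <- c(
  "protein", "sequence", "mods", "precursor_mz", "charge",
  "fragment", "fragment_mz", "rel_intensity", "rt", "confidence"
)

#' Key identifying a peptidoform precursor (library entry)
#'
#' @param sequence,mods,charge Vectors describing precursors.
#' @return Character key `sequence/mods/charge`.
#' @export
entry_key <- function(sequence, mods, charge) {
  mods <- ifelse(is.na(mods), "", mods)
  paste(sequence, mods, charge, sep = "/")
}

#' Validate an ion library table
#'
#' Checks the required column set and per-row sanity: finite positive
#' precursor and fragment m/z, non-negative relative intensity, confidence
#' in \[0, 1\], charge a positive integer, non-empty sequence.  Optionally
#' checks each entry's stated precursor m/z against the value recomputed
#' from its sequence and modifications.
#'
#' @param lib A library tibble.
#' @param check_mz Recompute precursor m/z from the peptidoform and flag
#'   disagreements beyond `mz_tol`? (default `FALSE`; synthetic or external
#'   libraries may carry observed rather than theoretical values).
#' @param mz_tol Tolerance in m/z for the recomputation check.
#' @return A list with `ok` (the valid rows), `bad` (a tibble of rejected
#'   rows with columns `line` and `reason`).
#' @export
validate_library <- function(lib, check_mz = FALSE, mz_tol = 0.02) {
  missing_cols <- setdiff(.LIB_COLS, names(lib))
  if (length(missing_cols)) {
    abort(paste0(
      "Ion library is missing column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  reasons <- rep(NA_character_, nrow(lib))
  flag <- function(bad, why) {
    bad[is.na(bad)] <- FALSE
    reasons[bad & is.na(reasons)] <<- why
  }
  flag(!nzchar(lib$sequence) | is.na(lib$sequence), "empty sequence")
  flag(!is.finite(lib$precursor_mz) | lib$precursor_mz <= 0, "bad precursor_mz")
  flag(!is.finite(lib$fragment_mz) | lib$fragment_mz <= 0, "bad fragment_mz")
  flag(!is.finite(lib$rel_intensity) | lib$rel_intensity < 0, "bad rel_intensity")
  flag(is.na(lib$confidence) | lib$confidence < 0 | lib$confidence > 1,
       "confidence outside [0, 1]")
  flag(is.na(lib$charge) | lib$charge < 1 | lib$charge != round(lib$charge),
       "bad charge")
  flag(!is.finite(lib$rt), "bad rt")
  if (check_mz) {
    ok_now <- is.na(reasons)
    theo <- rep(NA_real_, nrow(lib))
    theo[ok_now] <- purrr::pmap_dbl(
      list(lib$sequence[ok_now], lib$mods[ok_now], lib$charge[ok_now]),
      function(s, m, z) {
        tryCatch(precursor_mz(s, m %||% "", z), error = function(e) NA_real_)
      }
    )
    flag(ok_now & (is.na(theo) | abs(theo - lib$precursor_mz) > mz_tol),
         "precursor_mz inconsistent with peptidoform")
  }
  bad <- which(!is.na(reasons))
  list(
    ok = lib[is.na(reasons), , drop = FALSE],
    bad = tibble(line = bad, reason = reasons[bad])
  )
}

#' Read / write a DIA ion library (tab-separated, one transition per row)
#'
#' Malformed rows are dropped with a per-row warning naming the offending
#' line numbers; valid rows still load.  Writing then reading a valid
#' library round-trips exactly.
#'
#' @param path File path.
#' @param check_mz,mz_tol Passed to [validate_library()].
#' @return `read_ion_library()` returns the library tibble (valid rows only,
#'   with the rejected-row report in attribute `"rejected"`).
#' @export
read_ion_library <- function(path, check_mz = FALSE, mz_tol = 0.02) {
  if (!file.exists(path)) abort(paste0("Ion library not found: ", path))
  lib <- readr::read_tsv(
    path,
    col_types = readr::cols(
      protein = readr::col_character(),
      sequence = readr::col_character(),
      mods = readr::col_character(),
      precursor_mz = readr::col_double(),
      charge = readr::col_integer(),
      fragment = readr::col_character(),
      fragment_mz = readr::col_double(),
      rel_intensity = readr::col_double(),
      rt = readr::col_double(),
      confidence = readr::col_double(),
      .default = readr::col_guess()
    ),
    progress = FALSE
  )
  lib$mods[is.na(lib$mods)] <- ""
  v <- validate_library(lib, check_mz = check_mz, mz_tol = mz_tol)
  if (nrow(v$bad) > 0L) {
    warn(paste0(
      "Dropped ", nrow(v$bad), " malformed library row(s) at line(s) ",
      paste(utils::head(v$bad$line, 20L) + 1L, collapse = ", "),
      " (line numbers include the header): ",
      paste(unique(v$bad$reason), collapse = "; ")
    ))
  }
  out <- v$ok
  attr(out, "rejected") <- v$bad
  out
}

#' @rdname read_ion_library
#' @param lib A library tibble with the required columns.
#' @export
write_ion_library <- function(lib, path) {
  missing_cols <- setdiff(.LIB_COLS, names(lib))
  if (length(missing_cols)) {
    abort(paste0(
      "Ion library is missing column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  readr::write_tsv(lib, path, progress = FALSE)
  invisible(path)
}

#' Summarise an ion library to one row per precursor entry
#'
#' @param lib A library tibble (one transition per row).
#' @return A tibble with one row per entry: `entry` key, `protein`,
#'   `sequence`, `mods`, `precursor_mz`, `charge`, `rt`, `confidence`,
#'   `n_transitions`, plus any annotation columns (`family`, `carboxyl_count`,
#'   `variant`) present in the library.
#' @export
library_entries <- function(lib) {
  extra <- intersect(c("family", "carboxyl_count", "variant"), names(lib))
  lib %>%
    mutate(entry = entry_key(.data$sequence, .data$mods, .data$charge)) %>%
    group_by(.data$entry) %>%
    summarise(
      protein = first(.data$protein),
      sequence = first(.data$sequence),
      mods = first(.data$mods),
      precursor_mz = first(.data$precursor_mz),
      charge = first(.data$charge),
      rt = first(.data$rt),
      confidence = first(.data$confidence),
      n_transitions = dplyr::n(),
      across(dplyr::all_of(extra), first),
      .groups = "drop"
    )
}
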