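# Label-free quantification from transition tables: RT-windowed transition
# summation per peptidoform class (conflict groups pooled), peptide-level
# FDR filtering, protein intensity rollup, and reference normalization.

#' Sum transitions into peptidoform-class quantities
#'
#' For every sample x library entry, sums the top `max_transitions`
#' transitions (by intensity) whose observed RT lies within
#' `rt_window / 2` of the library reference RT; members of a conflict group
#' are pooled into one merged class, mirroring the treatment of co-isolated
#' co-eluting precursors that can only be quantified together.  When the
#' transition table carries a `fragment_mz` column, transitions are
#' additionally required to match the library fragment m/z within
#' `mz_tol_ppm` (the XIC width).
#'
#' @param transitions Transition table: columns `sample`, `sequence`,
#'   `mods`, `charge`, `fragment`, `intensity`, `rt`, `fdr` (and optionally
#'   `fragment_mz`, `condition`, `day`, `replicate`).
#' @param library Ion library tibble; annotation columns (`family`,
#'   `carboxyl_count`, `class`) are propagated to the output.
#' @param conflicts Optional output of [detect_conflicts()]; member entries
#'   of a group are pooled under a merged class id.
#' @param rt_window Full width of the RT acceptance window in minutes
#'   (default 2; the derivatized-GLA profile uses 6 for all families except
#'   `CSFEEAR`).
#' @param max_transitions Number of top transitions summed per entry
#'   (default 6; `Inf` means all transitions, as in the PTM profile).
#' @param mz_tol_ppm Fragment m/z match tolerance in ppm (default 75).
#' @return A tibble with one row per sample x class: `sample`, `class`
#'   (entry key, or `"a+b"` merged key for conflict groups), `protein`,
#'   `intensity`, `fdr` (best member score), `n_transitions` and `detected`
#'   (`FALSE` when an entry present in the table had no in-window
#'   transitions, reported with intensity 0), plus library annotations.
#' @export
sum_transitions <- function(transitions, library, conflicts = NULL,
                            rt_window = 2, max_transitions = 6L,
                            mz_tol_ppm = 75) {
  lib <- library %>%
    mutate(entry = entry_key(.data$sequence, .data$mods, .data$charge))
  lib_tr <- lib %>%
    select("entry", "fragment",
           lib_fragment_mz = "fragment_mz", ref_rt = "rt")
  tr <- transitions %>%
    mutate(
      entry = entry_key(.data$sequence, .data$mods, .data$charge)
    ) %>%
    inner_join(lib_tr, by = c("entry", "fragment"),
               relationship = "many-to-many")
  if ("fragment_mz" %in% names(transitions)) {
    tr <- tr %>% filter(
      abs(.data$fragment_mz - .data$lib_fragment_mz) /
        .data$lib_fragment_mz * 1e6 <= mz_tol_ppm
    )
  }
  tr <- tr %>% mutate(in_window = abs(.data$rt - .data$ref_rt) <= rt_window / 2)

  # class id: merged key for conflict-group members, entry key otherwise
  class_map <- lib %>% distinct(.data$entry) %>% mutate(class_id = .data$entry)
  if (!is.null(conflicts) && nrow(conflicts) > 0L) {
    merged <- conflicts %>%
      group_by(.data$group) %>%
      mutate(class_id = paste(sort(.data$entry), collapse = "+")) %>%
      ungroup() %>%
      select("entry", "class_id")
    class_map <- class_map %>%
      dplyr::rows_update(merged, by = "entry", unmatched = "ignore")
  }

  # library "class" annotation is renamed "variant" so the output's class id
  # column keeps the conventional name
  anno_cols <- intersect(c("family", "class", "carboxyl_count"), names(lib))
  anno <- lib %>%
    distinct(.data$entry, .data$protein,
             across(dplyr::all_of(anno_cols)))
  if ("class" %in% anno_cols) {
    anno <- anno %>% rename(variant = "class")
    anno_cols[anno_cols == "class"] <- "variant"
  }

  quant <- tr %>%
    left_join(class_map, by = "entry") %>%
    group_by(.data$sample, .data$class_id) %>%
    summarise(
      intensity = {
        x <- sort(.data$intensity[.data$in_window], decreasing = TRUE)
        sum(utils::head(x, max_transitions))
      },
      fdr = if (length(.data$fdr)) min(.data$fdr) else NA_real_,
      n_transitions = sum(.data$in_window),
      detected = any(.data$in_window),
      .groups = "drop"
    ) %>%
    left_join(
      class_map %>%
        left_join(anno, by = "entry") %>%
        group_by(.data$class_id) %>%
        summarise(
          members = paste(sort(unique(.data$entry)), collapse = "+"),
          protein = paste(sort(unique(.data$protein)), collapse = ";"),
          across(dplyr::all_of(anno_cols), first),
          .groups = "drop"
        ),
      by = "class_id"
    ) %>%
    rename(class = "class_id")
  quant
}

#' Filter peptidoform quantities at a peptide FDR threshold
#'
#' Keeps rows with `fdr <= threshold` (default 0.01, the 1% peptide FDR
#' cutoff), logging the number removed.  The output is always a subset of
#' the input and the operation is idempotent.
#'
#' @param quant Output of [sum_transitions()].
#' @param threshold Peptide FDR threshold (default 0.01).
#' @return The filtered tibble, with attribute `"n_removed"`.
#' @export
filter_fdr <- function(quant, threshold = 0.01) {
  out <- quant %>% filter(.data$fdr <= threshold)
  n_removed <- nrow(quant) - nrow(out)
  if (n_removed > 0L) {
    inform(paste0("filter_fdr: removed ", n_removed, " peptide value(s) with FDR > ",
                  format(threshold)))
  }
  attr(out, "n_removed") <- n_removed
  out
}

#' Roll peptidoform quantities up to protein intensities
#'
#' Protein intensity is the sum of FDR-passing peptide intensities of that
#' protein.  Shared peptides (classes mapping to more than one protein) are
#' excluded under the default `"exclude"` policy so that total passing
#' intensity is conserved; `"all"` assigns a shared peptide's full intensity
#' to every mapped protein.  Proteins whose peptides were all filtered are
#' absent from the result (not reported as zero).
#'
#' @param quant Filtered output of [sum_transitions()] / [filter_fdr()].
#' @param shared Shared-peptide policy, `"exclude"` (default) or `"all"`.
#' @return A tibble with columns `sample`, `protein`, `intensity`,
#'   `n_peptides`.
#' @export
protein_intensity <- function(quant, shared = c("exclude", "all")) {
  shared <- match.arg(shared)
  q <- quant
  is_shared <- stringr::str_detect(q$protein, stringr::fixed(";"))
  if (shared == "exclude") {
    if (any(is_shared)) {
      inform(paste0(
        "protein_intensity: excluded ", sum(is_shared),
        " shared peptide class value(s)"
      ))
    }
    q <- q[!is_shared, , drop = FALSE]
  } else {
    q <- q %>%
      mutate(protein = stringr::str_split(.data$protein, stringr::fixed(";"))) %>%
      tidyr::unnest_longer("protein")
  }
  q %>%
    group_by(.data$sample, .data$protein) %>%
    summarise(
      intensity = sum(.data$intensity),
      n_peptides = dplyr::n(),
      .groups = "drop"
    )
}

#' Normalize protein intensities to a reference peptidoform
#'
#' Divides each protein's intensity in a sample by the intensity of the
#' reference peptidoform (default the trypsin autolysis peptide `VATVSLPR`)
#' in the same sample, removing sample-to-sample loading differences:
#' multiplying every raw transition of a sample by a constant leaves the
#' normalized abundances unchanged.  Samples where the reference was not
#' quantified (or has zero intensity) are flagged and excluded.
#'
#' @param proteins Output of [protein_intensity()].
#' @param peptides Peptidoform quantities (the same table the proteins were
#'   rolled up from) in which to look up the reference.
#' @param reference Sequence of the reference peptidoform (default
#'   `"VATVSLPR"`).
#' @return `proteins` with an added `normalized` column; excluded samples
#'   are reported in attribute `"missing_reference"` and a warning.
#' @export
normalize_to_reference <- function(proteins, peptides,
                                   reference = "VATVSLPR") {
  ref <- peptides %>%
    filter(stringr::str_detect(.data$class,
                               stringr::fixed(paste0(reference, "/")))) %>%
    group_by(.data$sample) %>%
    summarise(ref_intensity = sum(.data$intensity), .groups = "drop") %>%
    filter(.data$ref_intensity > 0)
  missing <- setdiff(unique(proteins$sample), ref$sample)
  if (length(missing) > 0L) {
    warn(paste0(
      "Reference peptidoform '", reference, "' not quantified in sample(s): ",
      paste(missing, collapse = ", "), "; excluded from normalized output"
    ))
  }
  out <- proteins %>%
    inner_join(ref, by = "sample") %>%
    mutate(normalized = .data$intensity / .data$ref_intensity) %>%
    select(-"ref_intensity")
  attr(out, "missing_reference") <- missing
  out
}
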