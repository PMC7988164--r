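# Site-specific PTM stoichiometry: carboxyform percentage profiles per GLA
# peptide family, PTM variant abundance relative to product abundance, and
# variant x day time-course matrices.

#' Carboxyform percentage profile per GLA peptide family
#'
#' Within each sample x family, peptide variant intensities are summed by
#' carboxyl count k (marginalizing over methyl and glycan states), and each
#' k's percentage of the family total is computed.  Percentages sum to 100
#' for detected families; a family whose total intensity is zero is
#' reported with `NA` percentages and `defined = FALSE` rather than
#' fabricating a stoichiometry.  Percentages are invariant to uniform
#' rescaling of the member intensities, and summing finer variant strata
#' before or after the percentage computation gives identical profiles.
#'
#' Note that the profile is conditional on detectable carboxyforms: where a
#' fully carboxylated form does not ionize (underivatized GLA peptides),
#' percentages describe the detectable forms only.
#'
#' @param quant Peptidoform quantities carrying `family` and
#'   `carboxyl_count` annotations (e.g. from [sum_transitions()] against a
#'   [build_product_library()] library).
#' @return A tibble of class `carboxyform_profile`: `sample`, `family`, `k`,
#'   `intensity`, `pct`, `defined`.
#' @export
carboxyform_profile <- function(quant) {
  stopifnot(all(c("family", "carboxyl_count") %in% names(quant)))
  fam <- quant %>% filter(!is.na(.data$carboxyl_count))
  if (nrow(fam) == 0L) {
    abort("No rows carry a carboxyl_count annotation")
  }
  out <- fam %>%
    group_by(.data$sample, .data$family, k = .data$carboxyl_count) %>%
    summarise(intensity = sum(.data$intensity), .groups = "drop_last") %>%
    mutate(
      total = sum(.data$intensity),
      defined = .data$total > 0,
      pct = ifelse(.data$defined, 100 * .data$intensity / .data$total, NA_real_)
    ) %>%
    ungroup() %>%
    select("sample", "family", "k", "intensity", "pct", "defined") %>%
    arrange(.data$sample, .data$family, .data$k)
  class(out) <- c("carboxyform_profile", class(out))
  out
}

#' Mean carboxyl count of carboxyform profiles
#'
#' @param profile A [carboxyform_profile()].
#' @return A tibble `sample`, `family`, `mean_k` (`NA` where undefined).
#' @export
mean_carboxyl_count <- function(profile) {
  profile %>%
    group_by(.data$sample, .data$family) %>%
    summarise(
      mean_k = if (any(.data$defined)) sum(.data$k * .data$pct) / 100 else NA_real_,
      .groups = "drop"
    )
}

#' PTM variant abundance relative to product abundance
#'
#' Normalizes each PTM variant's intensity to the product protein's
#' abundance in the same sample, the per-sample relative abundance plotted
#' across a bioreactor time course.  Conflict-group variants keep their
#' merged composition labels (e.g. `"+947/+963"`).  Samples where the
#' product is absent or non-positive are omitted with a warning.
#'
#' @param variants Peptidoform quantities for the PTM variants (rows with a
#'   `family`/`class` annotation).
#' @param proteins Output of [protein_intensity()].
#' @param product Protein id of the product (default `"rFIX"`).
#' @return A tibble `sample`, `variant` (`family` + class label), `family`,
#'   `class`, `intensity`, `product_intensity`, `relative_abundance`.
#' @export
ptm_relative_abundance <- function(variants, proteins, product = "rFIX") {
  prod <- proteins %>%
    filter(.data$protein == product, .data$intensity > 0) %>%
    select("sample", product_intensity = "intensity")
  missing <- setdiff(unique(variants$sample), prod$sample)
  if (length(missing) > 0L) {
    warn(paste0(
      "Product '", product, "' not quantified (or zero) in sample(s): ",
      paste(missing, collapse = ", "), "; omitted"
    ))
  }
  variants %>%
    filter(!is.na(.data$family)) %>%
    inner_join(prod, by = "sample") %>%
    mutate(
      variant = paste(.data$family,
                      dplyr::coalesce(.data$variant, .data$members), sep = " "),
      relative_abundance = .data$intensity / .data$product_intensity
    ) %>%
    select("sample", "variant", "family", "class", "intensity",
           "product_intensity", "relative_abundance")
}

#' Variant-by-sample time-course matrix
#'
#' Pivots a long per-sample series into a variant x sample matrix (days in
#' order, purified endpoint last), with explicit `NA` for variants missing
#' in a sample — a variant filtered in a sample is missing, not zero.
#'
#' @param series Long tibble with columns `variant` (or `family`), `sample`
#'   and a value column.
#' @param value Name of the value column (default
#'   `"relative_abundance"`).
#' @param log10 Log10-transform the values for display parity with
#'   heatmaps (default `FALSE`)?
#' @return A wide tibble, one row per variant, one column per sample.
#'   Duplicate (variant, sample) pairs are an error.
#' @export
timecourse_matrix <- function(series, value = "relative_abundance",
                              log10 = FALSE) {
  key <- if ("variant" %in% names(series)) "variant" else "family"
  dup <- series %>%
    dplyr::count(.data[[key]], .data$sample) %>%
    filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    abort(paste0(
      "Duplicate (variant, sample) value(s), e.g. ",
      dup[[key]][1], " / ", dup$sample[1]
    ))
  }
  vals <- series[[value]]
  if (log10) vals <- log10(vals)
  series %>%
    mutate(.value = vals) %>%
    select(dplyr::all_of(key), "sample", ".value") %>%
    arrange(.data$sample) %>%
    tidyr::pivot_wider(names_from = "sample", values_from = ".value")
}
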