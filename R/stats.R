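# Statistical comparisons: one-tailed pooled-variance two-sample t tests,
# two-stage linear step-up FDR screening across many tests, and a
# protein-level differential-abundance procedure (log2 features, median
# polish run summarization, equal-variance t, BH adjustment).

#' One-tailed pooled-variance two-sample t test
#'
#' Classic equal-variance two-sample t, one-tailed in the stated direction.
#' When both groups have zero variance and equal means the test is
#' uninformative and p = 0.5 is returned with a flag (the symmetric-null
#' convention); identical non-degenerate groups also give p = 0.5.
#'
#' @param a,b Numeric replicate vectors, each of length >= 2.
#' @param direction `"greater"` tests a > b, `"less"` tests a < b.
#' @return A one-row tibble: `statistic`, `df`, `p`, `direction`,
#'   `degenerate`.
#' @export
#' @examples
#' one_tailed_t(c(5, 6, 7), c(1, 2, 3), "greater")
one_tailed_t <- function(a, b, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L) {
    abort("Both groups need at least 2 finite values")
  }
  df <- length(a) + length(b) - 2L
  sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) / df
  if (sp2 == 0) {
    if (mean(a) == mean(b)) {
      return(tibble(
        statistic = 0, df = df, p = 0.5,
        direction = direction, degenerate = TRUE
      ))
    }
    tstat <- sign(mean(a) - mean(b)) * Inf
  } else {
    tstat <- (mean(a) - mean(b)) /
      sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  }
  p <- if (direction == "greater") pt(tstat, df, lower.tail = FALSE)
       else pt(tstat, df, lower.tail = TRUE)
  tibble(
    statistic = tstat, df = df, p = p,
    direction = direction, degenerate = !is.finite(tstat)
  )
}

#' Two-stage linear step-up FDR (Benjamini-Krieger-Yekutieli) discoveries
#'
#' Stage 1 runs Benjamini-Hochberg at level `q / (1 + q)` to estimate the
#' number of true nulls `m0 = m - r1`; stage 2 runs Benjamini-Hochberg at
#' the inflated level `q * m / m0`.  When stage 1 rejects nothing, stage 2
#' reduces to plain BH at `q`, so the discovery set always contains the
#' plain BH discoveries at the same `q`; when stage 1 rejects everything,
#' everything is discovered.
#'
#' @param p Numeric vector of p-values (length >= 1).
#' @param q Target FDR level (default 0.01, i.e. a Q of 1 percent).
#' @return A tibble with columns `p`, `discovery` (logical), plus
#'   attributes `m0` and `stage2_level`.
#' @export
#' @examples
#' multi_t_bky(c(0.001, 0.02, 0.8), q = 0.05)
multi_t_bky <- function(p, q = 0.01) {
  stopifnot(length(p) >= 1L, all(p >= 0 & p <= 1), q > 0, q < 1)
  m <- length(p)
  bh_reject <- function(p, level) {
    o <- order(p)
    thresh <- level * seq_len(m) / m
    passed <- p[o] <= thresh
    k <- if (any(passed)) max(which(passed)) else 0L
    reject <- logical(m)
    if (k > 0L) reject[o[seq_len(k)]] <- TRUE
    reject
  }
  r1 <- sum(bh_reject(p, q / (1 + q)))
  m0 <- m - r1
  if (m0 == 0L) {
    out <- tibble(p = p, discovery = TRUE)
    attr(out, "m0") <- 0L
    attr(out, "stage2_level") <- Inf
    return(out)
  }
  level2 <- q * m / m0
  out <- tibble(p = p, discovery = bh_reject(p, level2))
  attr(out, "m0") <- m0
  attr(out, "stage2_level") <- level2
  out
}

#' Protein-level differential abundance between two groups
#'
#' A transparent label-free differential-abundance procedure: per protein,
#' feature (peptide class) intensities are log2 transformed, summarized to
#' run level by Tukey median polish over the feature x run matrix, and the
#' run-level summaries are compared between the two groups with an
#' equal-variance t test; p-values are Benjamini-Hochberg adjusted across
#' proteins and flagged at `alpha`.  Intended for directional screening of
#' host-cell-protein and product abundance shifts; it is deliberately
#' simpler than full mixed-model summarization tools.
#'
#' Proteins observed (with >= `min_rep` runs) in only one group cannot be
#' tested: they are reported with an infinite log2 fold change, flagged
#' `one_group_only`, and excluded from testing and adjustment.
#'
#' @param features Long tibble: `protein`, `feature`, `sample`, `intensity`
#'   (positive; zero/missing rows may simply be absent).
#' @param design Tibble mapping `sample` to `group` (exactly two groups).
#' @param alpha Significance threshold on the adjusted p (default 1e-5).
#' @param min_rep Minimum runs per group for a protein to be testable
#'   (default 2).
#' @return An object of class `protein_diff`: a list with `results` (tibble:
#'   `protein`, `log2fc`, `statistic`, `p`, `p_adj`, `significant`, `n_a`,
#'   `n_b`, `one_group_only`), `groups` (the two group labels, fold change
#'   is group1 - group2 in log2), `alpha`.
#' @export
protein_diff <- function(features, design, alpha = 1e-5, min_rep = 2L) {
  stopifnot(all(c("protein", "feature", "sample", "intensity") %in% names(features)),
            all(c("sample", "group") %in% names(design)))
  groups <- sort(unique(design$group))
  if (length(groups) != 2L) abort("design must contain exactly two groups")
  dat <- features %>%
    filter(.data$intensity > 0) %>%
    inner_join(design, by = "sample")

  res <- dat %>%
    group_by(.data$protein) %>%
    dplyr::group_map(function(d, key) {
      mat <- d %>%
        mutate(l2 = log2(.data$intensity)) %>%
        select("feature", "sample", "l2") %>%
        tidyr::pivot_wider(names_from = "sample", values_from = "l2") %>%
        tibble::column_to_rownames("feature") %>%
        as.matrix()
      runs <- if (nrow(mat) == 1L) {
        setNames(as.numeric(mat[1, ]), colnames(mat))
      } else {
        mp <- suppressWarnings(medpolish(mat, trace.iter = FALSE, na.rm = TRUE))
        setNames(mp$overall + mp$col, colnames(mat))
      }
      runs <- runs[is.finite(runs)]
      ga <- runs[names(runs) %in% design$sample[design$group == groups[1]]]
      gb <- runs[names(runs) %in% design$sample[design$group == groups[2]]]
      n_a <- length(ga); n_b <- length(gb)
      if (n_a >= min_rep && n_b >= min_rep) {
        tt <- stats::t.test(ga, gb, var.equal = TRUE)
        tibble(
          protein = key$protein, log2fc = mean(ga) - mean(gb),
          statistic = unname(tt$statistic), p = tt$p.value,
          n_a = n_a, n_b = n_b, one_group_only = FALSE
        )
      } else if ((n_a >= min_rep) != (n_b >= min_rep) &&
                 (n_a + n_b) >= min_rep) {
        tibble(
          protein = key$protein,
          log2fc = if (n_a >= min_rep) Inf else -Inf,
          statistic = NA_real_, p = NA_real_,
          n_a = n_a, n_b = n_b, one_group_only = TRUE
        )
      } else {
        NULL
      }
    }) %>%
    dplyr::bind_rows()
  if (nrow(res) == 0L) abort("No testable proteins")
  testable <- !res$one_group_only
  res$p_adj <- NA_real_
  res$p_adj[testable] <- p.adjust(res$p[testable], method = "BH")
  res$significant <- !is.na(res$p_adj) & res$p_adj < alpha
  structure(
    list(results = res, groups = groups, alpha = alpha),
    class = "protein_diff"
  )
}

#' @export
print.protein_diff <- function(x, ...) {
  cat("Protein differential abundance: ", x$groups[1], " vs ", x$groups[2],
      "\n", sep = "")
  cat("  ", nrow(x$results), " proteins (",
      sum(x$results$one_group_only), " one-group-only), ",
      sum(x$results$significant), " significant at adjusted p < ",
      format(x$alpha), "\n", sep = "")
  invisible(x)
}

#' Tidy a protein differential-abundance fit
#'
#' @param x A [protein_diff()] object.
#' @param ... Unused.
#' @return The per-protein results tibble with a `neg_log10_p_adj` column,
#'   volcano-ready.
#' @method tidy protein_diff
#' @export
tidy.protein_diff <- function(x, ...) {
  x$results %>%
    mutate(neg_log10_p_adj = -log10(.data$p_adj))
}

#' Glance at a protein differential-abundance fit
#'
#' @inheritParams tidy.protein_diff
#' @return A one-row tibble: counts of proteins, testable proteins,
#'   significant proteins, and the alpha used.
#' @method glance protein_diff
#' @export
glance.protein_diff <- function(x, ...) {
  tibble(
    n_proteins = nrow(x$results),
    n_testable = sum(!x$results$one_group_only),
    n_one_group_only = sum(x$results$one_group_only),
    n_significant = sum(x$results$significant),
    alpha = x$alpha
  )
}
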