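# Shared fixtures and independent oracles.

# Brute-force digestion oracle: enumerate every substring window and keep the
# ones whose boundaries are valid cleavage points and whose interior has at
# most `max_missed` cleavage points.  Independent of the production code's
# bound-pair construction.
brute_force_digest <- function(protein, residues, side = "C",
                               max_missed = 0L, no_pro = FALSE) {
  letters <- strsplit(protein, "")[[1]]
  n <- length(letters)
  is_cut <- function(i) {            # boundary after position i (0..n)
    if (i == 0L || i == n) return(TRUE)
    if (side == "C") {
      ok <- letters[i] %in% residues
      if (ok && no_pro && letters[i + 1L] == "P") ok <- FALSE
      ok
    } else {
      letters[i + 1L] %in% residues
    }
  }
  out <- list()
  for (s in seq_len(n)) {
    for (e in s:n) {
      if (!is_cut(s - 1L) || !is_cut(e)) next
      interior <- if (s <= e - 1L) sum(vapply((s:(e - 1L)), is_cut, logical(1)))
                  else 0L
      if (interior > max_missed) next
      out[[length(out) + 1L]] <- data.frame(
        peptide = paste(letters[s:e], collapse = ""),
        start = s, end = e, n_missed = interior
      )
    }
  }
  do.call(rbind, out)
}

# Plain BH discovery oracle at level q (direct step-up definition).
brute_force_bh <- function(p, q) {
  m <- length(p)
  o <- order(p)
  k <- which(p[o] <= q * seq_len(m) / m)
  reject <- logical(m)
  if (length(k)) reject[o[seq_len(max(k))]] <- TRUE
  reject
}

# Small scenario used across the simulator/quant tests (fast but full-shaped).
tiny_scenario <- function(seed = 11L, n_days = 5L, n_hcp = 6L, ...) {
  bioprocess_scenario(n_days = n_days, n_hcp = n_hcp, seed = seed, ...)
}

# A hand-built four-entry ion library for quant unit tests: one protein with
# two peptides, one shared-looking second protein, one reference peptide.
toy_library <- function() {
  mk <- function(protein, sequence, rt, frags, mzs, rel) {
    tibble::tibble(
      protein = protein, sequence = sequence, mods = "",
      precursor_mz = precursor_mz(sequence, "", 2L), charge = 2L,
      fragment = frags, fragment_mz = mzs, rel_intensity = rel,
      rt = rt, confidence = 0.99
    )
  }
  dplyr::bind_rows(
    mk("P1", "LESGK", 10, c("y1", "y2", "y3"), c(147.11, 234.14, 363.19),
       c(0.5, 1, 0.8)),
    mk("P1", "VVGGEDAK", 12, c("y2", "y3"), c(218.15, 333.18), c(1, 0.6)),
    mk("P2", "SALVLQYLR", 30, c("y2", "y3"), c(288.20, 401.29), c(1, 0.9)),
    mk("TRYPSIN", "VATVSLPR", 20, c("y2", "y3"), c(272.17, 359.20), c(1, 0.7))
  )
}

# Transition table matching toy_library exactly at reference RT, unit FDR 0.
toy_transitions <- function(samples = c("s1", "s2"), scale = 1) {
  lib <- toy_library()
  purrr::map_dfr(seq_along(samples), function(i) {
    lib |>
      dplyr::transmute(
        sample = samples[i], sequence, mods, charge, fragment, fragment_mz,
        intensity = rel_intensity * 100 * scale[[min(i, length(scale))]],
        rt = rt, fdr = 0
      )
  })
}
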