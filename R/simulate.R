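# Synthetic fed-batch generator.  Two bioreactor conditions are simulated
# over a 13-day fed-batch: condition A ("H1-like") keeps viability high and
# gamma-carboxylation efficient; condition B ("H2-like") yields more product
# but loses viability late and carboxylates less completely.  States are
# rendered into transition-level DIA observations against an ion library.

.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# GLA-domain tryptic peptide families of the product, with the positions of
# carboxylatable glutamates inside each peptide.
.GLA_FAMILIES <- tibble::tibble(
  family = c("LEEFVQGNLER", "CSFEEAR", "EVFENTER", "TTEFWK"),
  sequence = c("LEEFVQGNLER", "CSFEEAR", "EVFENTER", "TTEFWK"),
  gla_sites = list(c(2L, 3L, 10L), c(4L, 5L), c(1L, 4L, 7L), 3L),
  rt = c(32, 16, 22, 27)
)

#' Define a fed-batch bioprocess scenario
#'
#' Generative parameters for a two-condition fed-batch time course with a
#' purified endpoint.  Defaults describe an "H1/H2-like" contrast: condition
#' B secretes more product but ends at lower viability (0.77 vs 0.93),
#' carboxylates the GLA domain less completely, and releases a larger
#' intracellular host-cell-protein (HCP) load.  All trajectory values are
#' fixture choices for a realistic CHO fed-batch, not measurements.
#'
#' Carboxyform occupancy is binomial per family: each carboxylatable Glu is
#' modified independently with a per-day probability that follows a logistic
#' trajectory; PTM variant shares within a site follow normalized logistic
#' trajectories.  Purification reweights carboxyform shares by a retention
#' probability logistic in the carboxyl count k (flat for the single-site
#' E40 family, which anion exchange does not strongly select on), and
#' carries each HCP over with a probability elevated for calcium binders.
#'
#' @param n_days Length of the fed batch in days (default 13).
#' @param n_hcp Size of the HCP panel (default 40).
#' @param viability_final Named vector, final-day viability per condition.
#' @param secretion_scale Named vector, product secretion scale per condition.
#' @param carboxy_a,carboxy_b Named vectors: intercept and per-day slope of
#'   the logistic per-site carboxylation probability per condition.
#' @param lysis_coef Proportionality between integrated viability loss and
#'   intracellular HCP release (default 10).
#' @param retention_r0,retention_r1 Purification retention logistic
#'   `plogis(r0 + r1 * k)`; `r1` applies to all families except `TTEFWK`
#'   (retention flat in k there).
#' @param product_recovery Fraction of final-day product retained by
#'   purification.
#' @param seed Seed used to draw the HCP panel (part of the scenario, so the
#'   scenario is a complete, reproducible description).
#' @return A list of class `bioprocess_scenario`.
#' @export
bioprocess_scenario <- function(n_days = 13L,
                                n_hcp = 40L,
                                viability_final = c(A = 0.93, B = 0.77),
                                secretion_scale = c(A = 1.0, B = 1.45),
                                carboxy_a = c(A = 1.8, B = 1.1),
                                carboxy_b = c(A = -0.02, B = -0.09),
                                lysis_coef = 10,
                                retention_r0 = -2,
                                retention_r1 = 1.6,
                                product_recovery = 0.6,
                                seed = 42L) {
  stopifnot(n_days >= 2L, n_hcp >= 1L)
  conds <- c("A", "B")
  days <- seq_len(n_days)
  drop_day <- min(7L, n_days - 1L)

  viability <- purrr::map(setNames(conds, conds), function(cc) {
    v <- rep(0.98, n_days)
    late <- days > drop_day
    v[late] <- 0.98 + (viability_final[[cc]] - 0.98) *
      (days[late] - drop_day) / (n_days - drop_day)
    v
  })

  secretion <- purrr::map(setNames(conds, conds), function(cc) {
    base <- stats::plogis((days - 4) / 1.2)
    if (cc == "A") base[days > 8] <- 0.05   # plateau after day 8
    secretion_scale[[cc]] * base
  })

  hcp <- .with_seed(seed, {
    tibble(
      protein = sprintf("HCP%03d", seq_len(n_hcp)),
      secreted = runif(n_hcp) < 0.4,
      calcium_binder = runif(n_hcp) < 0.15,
      baseline = rlnorm(n_hcp, meanlog = log(5), sdlog = 1)
    ) %>% mutate(
      carryover = ifelse(.data$calcium_binder, 0.30, 0.02)
    )
  })

  # PTM site classes: normalized logistic share trajectories per condition.
  # a/b give plogis(a + b * day); shares are renormalized within a site.
  ptm_classes <- tibble::tribble(
    ~site,     ~class,          ~a_A,  ~b_A,  ~a_B,  ~b_B,
    "T38/39",  "+656",          -2.0,  0.10,  -1.5,  0.18,
    "T38/39",  "+947/+963",     -1.6,  0.12,  -1.1,  0.20,
    "D64",     "unmod",          2.0, -0.02,   2.0, -0.05,
    "D64",     "ox",            -2.5,  0.08,  -2.2,  0.16,
    "D85",     "unmod",          2.0,  0.00,   2.0,  0.00,
    "S141",    "none",           1.0, -0.35,   1.2, -0.50,
    "S141",    "+656",          -1.0,  0.25,  -0.8,  0.30,
    "S141",    "+947",          -1.5,  0.28,  -1.8,  0.22
  )

  structure(
    list(
      n_days = n_days, conditions = conds, days = days,
      viability = viability, secretion = secretion,
      carboxy_a = carboxy_a, carboxy_b = carboxy_b,
      lysis_coef = lysis_coef, hcp = hcp,
      gla_families = .GLA_FAMILIES,
      ptm_classes = ptm_classes,
      retention_r0 = retention_r0, retention_r1 = retention_r1,
      product_recovery = product_recovery,
      trypsin_abundance = 1000,
      seed = seed
    ),
    class = "bioprocess_scenario"
  )
}

.carboxy_shares <- function(sc, condition, day) {
  p <- stats::plogis(sc$carboxy_a[[condition]] + sc$carboxy_b[[condition]] * day)
  purrr::pmap_dfr(sc$gla_families, function(family, sequence, gla_sites, rt) {
    K <- length(gla_sites)
    tibble(
      family = family, class = paste0("k", 0:K), k = 0:K,
      share = dbinom(0:K, K, p)
    )
  })
}

.ptm_shares <- function(sc, condition, day) {
  a <- sc$ptm_classes[[paste0("a_", condition)]]
  b <- sc$ptm_classes[[paste0("b_", condition)]]
  raw <- stats::plogis(a + b * day)
  sc$ptm_classes %>%
    mutate(raw = raw) %>%
    group_by(.data$site) %>%
    mutate(share = .data$raw / sum(.data$raw)) %>%
    ungroup() %>%
    transmute(
      family = .data$site, class = .data$class, k = NA_integer_,
      share = .data$share
    )
}

#' Simulate the supernatant time course of a fed-batch scenario
#'
#' Product and secreted HCPs accumulate in the supernatant; intracellular
#' HCPs are released in proportion to the integrated viability loss (so a
#' zero lysis coefficient means no intracellular HCP at any day, and the
#' lower-viability condition always ends with the larger intracellular
#' load).  Deterministic given the scenario (whose seed fixed the HCP
#' panel).
#'
#' @param sc A [bioprocess_scenario()].
#' @return A list of class `sample_states` with tibbles `proteins`
#'   (`condition`, `day`, `sample`, `protein`, `type`, `abundance`) and
#'   `shares` (`condition`, `day`, `sample`, `family`, `class`, `k`,
#'   `share`); within each (sample, family) the shares sum to 1.
#' @export
simulate_timecourse <- function(sc) {
  stopifnot(inherits(sc, "bioprocess_scenario"))
  rows_p <- list(); rows_s <- list()
  for (cc in sc$conditions) {
    viab <- sc$viability[[cc]]
    loss <- cumsum(pmax(0, c(0.98, viab[-sc$n_days]) - viab))
    product <- cumsum(sc$secretion[[cc]])
    for (d in sc$days) {
      sample_id <- paste0(cc, "_d", sprintf("%02d", d))
      hcp_ab <- ifelse(
        sc$hcp$secreted,
        sc$hcp$baseline * d / sc$n_days,
        sc$hcp$baseline * sc$lysis_coef * loss[d]
      )
      rows_p[[length(rows_p) + 1L]] <- dplyr::bind_rows(
        tibble(
          condition = cc, day = d, sample = sample_id,
          protein = "rFIX", type = "product", abundance = 100 * product[d]
        ),
        tibble(
          condition = cc, day = d, sample = sample_id,
          protein = "TRYPSIN", type = "reference",
          abundance = sc$trypsin_abundance
        ),
        tibble(
          condition = cc, day = d, sample = sample_id,
          protein = sc$hcp$protein,
          type = ifelse(sc$hcp$secreted, "secreted", "intracellular"),
          abundance = hcp_ab
        )
      )
      rows_s[[length(rows_s) + 1L]] <- dplyr::bind_rows(
        .carboxy_shares(sc, cc, d), .ptm_shares(sc, cc, d)
      ) %>% mutate(condition = cc, day = d, sample = sample_id, .before = 1)
    }
  }
  structure(
    list(
      proteins = dplyr::bind_rows(rows_p),
      shares = dplyr::bind_rows(rows_s)
    ),
    class = "sample_states"
  )
}

.retention <- function(sc, family, k) {
  r1 <- ifelse(family == "TTEFWK", 0, sc$retention_r1)
  stats::plogis(sc$retention_r0 + r1 * k)
}

#' Simulate purification of the final-day supernatant
#'
#' Anion-exchange purification model: carboxyform shares are reweighted by a
#' retention probability increasing in the carboxyl count k (flat for the
#' `TTEFWK` family), HCPs carry over with their panel probabilities
#' (elevated for calcium binders), and the product is recovered at the
#' scenario's recovery fraction.  When retention strictly increases in k the
#' purified profile's mean carboxyl count strictly exceeds the supernatant
#' profile's; uniform retention leaves shares unchanged.
#'
#' @param states A `sample_states` object from [simulate_timecourse()].
#' @param sc The same [bioprocess_scenario()].
#' @return A `sample_states` object holding one `"purified"` sample per
#'   condition (`day = NA`).
#' @export
simulate_purification <- function(states, sc) {
  stopifnot(inherits(states, "sample_states"), inherits(sc, "bioprocess_scenario"))
  final_day <- max(states$proteins$day)
  rows_p <- list(); rows_s <- list()
  for (cc in unique(states$proteins$condition)) {
    sample_id <- paste0(cc, "_purified")
    fin_p <- states$proteins %>%
      filter(.data$condition == cc, .data$day == final_day)
    hcp_join <- fin_p %>%
      left_join(select(sc$hcp, "protein", "carryover"), by = "protein") %>%
      mutate(
        carry = dplyr::case_when(
          .data$type == "product" ~ sc$product_recovery,
          .data$type == "reference" ~ 1,
          TRUE ~ .data$carryover
        ),
        abundance = .data$abundance * .data$carry,
        condition = cc, day = NA_integer_, sample = sample_id
      ) %>%
      select(-"carryover", -"carry")
    rows_p[[length(rows_p) + 1L]] <- hcp_join

    fin_s <- states$shares %>%
      filter(.data$condition == cc, .data$day == final_day)
    gla <- fin_s %>%
      filter(!is.na(.data$k)) %>%
      group_by(.data$family) %>%
      mutate(
        w = .data$share * .retention(sc, .data$family, .data$k),
        share = .data$w / sum(.data$w)
      ) %>%
      ungroup() %>% select(-"w")
    ptm <- fin_s %>% filter(is.na(.data$k))
    rows_s[[length(rows_s) + 1L]] <- dplyr::bind_rows(gla, ptm) %>%
      mutate(condition = cc, day = NA_integer_, sample = sample_id)
  }
  structure(
    list(
      proteins = dplyr::bind_rows(rows_p),
      shares = dplyr::bind_rows(rows_s)
    ),
    class = "sample_states"
  )
}

#' Combine sample-state objects
#'
#' @param ... `sample_states` objects.
#' @return A single `sample_states` object with the rows of all inputs.
#' @export
combine_states <- function(...) {
  xs <- list(...)
  stopifnot(all(purrr::map_lgl(xs, inherits, "sample_states")))
  structure(
    list(
      proteins = dplyr::bind_rows(purrr::map(xs, "proteins")),
      shares = dplyr::bind_rows(purrr::map(xs, "shares"))
    ),
    class = "sample_states"
  )
}

#' Observation noise model for DIA rendering
#'
#' @param sigma Multiplicative log-normal sd per transition (default 0.2).
#' @param baseline Additive baseline intensity (default 0).
#' @param censor_limit Transitions below this intensity are censored
#'   (dropped) as missing-below-threshold (default 0.05).
#' @param loading_sigma Log-normal sd of the per-sample loading factor.
#' @param rt_jitter SD in minutes of observed-RT jitter around the library
#'   reference RT.
#' @param fdr_true_max Upper bound of the uniform FDR score drawn for true
#'   signals (decoys draw above 0.01 by construction).
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(sigma = 0.2, baseline = 0, censor_limit = 0.05,
                        loading_sigma = 0.1, rt_jitter = 0.02,
                        fdr_true_max = 0.005) {
  stopifnot(sigma >= 0, censor_limit >= 0, loading_sigma >= 0)
  structure(
    list(
      sigma = sigma, baseline = baseline, censor_limit = censor_limit,
      loading_sigma = loading_sigma, rt_jitter = rt_jitter,
      fdr_true_max = fdr_true_max
    ),
    class = "noise_model"
  )
}

#' Render sample states into a transition-level DIA table
#'
#' Each library entry is matched to its protein's abundance (and, for
#' annotated entries, its peptidoform class share) in each sample; each
#' transition's intensity is `share x abundance x normalized library
#' relative intensity`, perturbed by per-transition log-normal noise and a
#' per-sample loading factor, then censored below the noise model's limit.
#' True entries draw low FDR scores; injected decoy entries always draw
#' FDR > 0.01.  Library entries whose protein or class is absent from the
#' states are skipped with one warning.
#'
#' @param states A `sample_states` object.
#' @param library An ion library tibble; entries for annotated peptidoform
#'   classes must carry `family` and `class` columns (`NA` for plain
#'   protein-level entries).
#' @param noise A [noise_model()].
#' @param seed Integer seed; all randomness in the render flows from it.
#' @param replicates Technical replicates per sample (default 3).
#' @param decoys Optional library-format tibble of decoy entries to inject.
#' @return A list of class `dia_render` with `transitions` (sample,
#'   condition, day, replicate, protein, sequence, mods, charge, fragment,
#'   fragment_mz, intensity, rt, fdr), `truth` (per sample x entry true
#'   intensity and loading factor) and `manifest` (scenario/states hash and
#'   seed).
#' @export
render_dia <- function(states, library, noise = noise_model(), seed = 1L,
                       replicates = 3L, decoys = NULL) {
  stopifnot(inherits(states, "sample_states"), inherits(noise, "noise_model"))
  if (!all(c("family", "class") %in% names(library))) {
    library$family <- library$family %||% NA_character_
    library$class <- library$class %||% NA_character_
  }
  lib <- library %>%
    mutate(entry = entry_key(.data$sequence, .data$mods, .data$charge)) %>%
    group_by(.data$entry) %>%
    mutate(rel_norm = .data$rel_intensity / sum(.data$rel_intensity)) %>%
    ungroup()

  samples <- states$proteins %>% distinct(.data$condition, .data$day, .data$sample)
  reps <- tidyr::crossing(samples, replicate = seq_len(replicates)) %>%
    mutate(sample_rep = paste0(.data$sample, "_r", .data$replicate))

  grid <- tidyr::crossing(reps, lib) %>%
    left_join(
      states$proteins %>% select("sample", "protein", "abundance"),
      by = c("sample", "protein")
    ) %>%
    left_join(
      states$shares %>% select("sample", "family", "class", "share"),
      by = c("sample", "family", "class")
    )

  unmatched <- grid %>%
    filter(is.na(.data$abundance) |
             (!is.na(.data$family) & is.na(.data$share))) %>%
    distinct(.data$entry)
  if (nrow(unmatched) > 0L) {
    warn(paste0(
      nrow(unmatched), " library entr(ies) had no matching protein/class in",
      " the sample states and were skipped"
    ))
    grid <- grid %>% anti_join(unmatched, by = "entry")
  }
  grid <- grid %>% mutate(
    true_entry = .data$abundance * dplyr::coalesce(.data$share, 1)
  )

  out <- .with_seed(seed, {
    loading <- reps %>%
      mutate(loading = exp(rnorm(dplyr::n(), 0, noise$loading_sigma)))
    fdr_tbl <- grid %>%
      distinct(.data$sample_rep, .data$entry) %>%
      mutate(fdr = runif(dplyr::n(), 0, noise$fdr_true_max))
    tr <- grid %>%
      left_join(select(loading, "sample_rep", "loading"), by = "sample_rep") %>%
      left_join(fdr_tbl, by = c("sample_rep", "entry")) %>%
      mutate(
        intensity = .data$true_entry * .data$rel_norm * .data$loading *
          exp(rnorm(dplyr::n(), 0, noise$sigma)) + noise$baseline,
        rt_obs = .data$rt + rnorm(dplyr::n(), 0, noise$rt_jitter)
      ) %>%
      filter(.data$intensity >= noise$censor_limit)
    dec <- NULL
    if (!is.null(decoys) && nrow(decoys) > 0L) {
      dgrid <- tidyr::crossing(reps, decoys %>%
        mutate(entry = entry_key(.data$sequence, .data$mods, .data$charge)))
      dfdr <- dgrid %>%
        distinct(.data$sample_rep, .data$entry) %>%
        mutate(fdr = runif(dplyr::n(), 0.02, 0.3))
      dec <- dgrid %>%
        left_join(dfdr, by = c("sample_rep", "entry")) %>%
        mutate(
          intensity = noise$censor_limit * runif(dplyr::n(), 1, 10),
          rt_obs = .data$rt
        )
    }
    list(tr = tr, dec = dec, loading = loading)
  })

  keep <- c(
    "sample_rep", "condition", "day", "replicate", "protein", "sequence",
    "mods", "charge", "fragment", "fragment_mz", "intensity", "rt_obs", "fdr"
  )
  transitions <- dplyr::bind_rows(
    out$tr %>% select(dplyr::all_of(keep)),
    if (!is.null(out$dec)) out$dec %>% select(dplyr::all_of(keep))
  ) %>%
    rename(sample = "sample_rep", rt = "rt_obs") %>%
    arrange(.data$sample, .data$protein, .data$sequence, .data$fragment)

  truth <- grid %>%
    distinct(
      .data$sample_rep, .data$condition, .data$day, .data$replicate,
      .data$entry, .data$protein, .data$family, .data$class, .data$true_entry
    ) %>%
    left_join(select(out$loading, "sample_rep", "loading"), by = "sample_rep") %>%
    rename(sample = "sample_rep")

  structure(
    list(
      transitions = transitions, truth = truth,
      manifest = list(
        states_hash = rlang::hash(states), library_hash = rlang::hash(library),
        seed = seed, replicates = replicates, noise = unclass(noise)
      )
    ),
    class = "dia_render"
  )
}
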