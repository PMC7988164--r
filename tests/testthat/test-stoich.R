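# Carboxyform stoichiometry, PTM relative abundance, and time-course
# matrices.

fake_family_quant <- function(intens, sample = "s1", family = "FAM") {
  tibble::tibble(
    sample = sample, class = paste0(family, "_k", seq_along(intens) - 1L),
    protein = "rFIX", intensity = intens, fdr = 0,
    family = family, carboxyl_count = seq_along(intens) - 1L
  )
}

test_that("carboxyform percentages normalize within the family", {
  p <- carboxyform_profile(fake_family_quant(c(0, 0, 0, 100)))
  expect_equal(p$pct, c(0, 0, 0, 100))
  p2 <- carboxyform_profile(fake_family_quant(c(25, 25, 25, 25)))
  expect_equal(p2$pct, rep(25, 4))
  expect_equal(sum(p2$pct), 100, tolerance = 1e-9)
  # uniform rescaling leaves percentages unchanged
  p3 <- carboxyform_profile(fake_family_quant(17.3 * c(25, 25, 25, 25)))
  expect_equal(p3$pct, p2$pct, tolerance = 1e-12)
  # zero-total family is undefined, not 0%
  p0 <- carboxyform_profile(fake_family_quant(c(0, 0)))
  expect_true(all(!p0$defined))
  expect_true(all(is.na(p0$pct)))
})

test_that("marginalizing variant strata before or after percentages is
           identical", {
  # two methyl strata per k, summed into one family
  fine <- dplyr::bind_rows(
    fake_family_quant(c(10, 20, 30, 40)),
    fake_family_quant(c(5, 10, 15, 20))
  )
  coarse <- fake_family_quant(c(15, 30, 45, 60))
  expect_equal(carboxyform_profile(fine)$pct, carboxyform_profile(coarse)$pct,
               tolerance = 1e-12)
})

test_that("noiseless simulated data recovers scenario carboxyform truth
           exactly", {
  sc <- tiny_scenario()
  lib <- build_product_library(sc)
  st <- simulate_timecourse(sc)
  r <- render_dia(st, lib,
                  noise_model(sigma = 0, censor_limit = 0, loading_sigma = 0,
                              rt_jitter = 0),
                  seed = 1, replicates = 1)
  q <- suppressMessages(filter_fdr(sum_transitions(r$transitions, lib,
                                                   max_transitions = Inf)))
  prof <- carboxyform_profile(q)
  truth <- st$shares |>
    dplyr::filter(!is.na(k)) |>
    dplyr::mutate(sample = paste0(sample, "_r1"), pct_true = 100 * share)
  j <- dplyr::inner_join(prof, truth, by = c("sample", "family", "k"))
  expect_equal(nrow(j), nrow(prof))
  expect_equal(j$pct, j$pct_true, tolerance = 1e-9)
})

test_that("purified profiles have higher mean carboxyl count than final-day
           supernatant when retention increases in k", {
  sc <- tiny_scenario()
  lib <- build_product_library(sc)
  st <- simulate_timecourse(sc)
  all <- combine_states(st, simulate_purification(st, sc))
  r <- render_dia(all, lib, noise_model(sigma = 0.1), seed = 8, replicates = 2)
  q <- suppressMessages(filter_fdr(sum_transitions(r$transitions, lib,
                                                   max_transitions = Inf)))
  mk <- mean_carboxyl_count(carboxyform_profile(q)) |>
    dplyr::mutate(
      condition = substr(sample, 1, 1),
      stage = ifelse(grepl("purified", sample), "purified", "supernatant"),
      day = sub("^._d?([0-9]+|purified)_r.$", "\\1", sample)
    )
  fin <- mk |> dplyr::filter(stage == "purified" |
                               day == sprintf("%02d", sc$n_days))
  agg <- fin |>
    dplyr::group_by(condition, family, stage) |>
    dplyr::summarise(mk = mean(mean_k, na.rm = TRUE), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "stage", values_from = "mk")
  enr <- agg |> dplyr::filter(family != "TTEFWK")
  expect_true(all(enr$purified >= enr$supernatant))
})

test_that("PTM relative abundance is a product-normalized ratio", {
  variants <- tibble::tibble(
    sample = c("s1", "s1", "s2"),
    class = "v", members = "v", protein = "rFIX",
    family = "S141", variant = c("+656", "+947", "+656"),
    intensity = c(50, 25, 80), fdr = 0, carboxyl_count = NA_integer_
  )
  proteins <- tibble::tibble(
    sample = c("s1", "s2", "s3"), protein = "rFIX", intensity = c(100, 40, 0)
  )
  ptm <- ptm_relative_abundance(variants, proteins)
  expect_equal(ptm$relative_abundance, c(0.5, 0.25, 2))
  # variant equal to product intensity gives ratio one; doubling both is
  # invariant
  v2 <- variants[1, ]; v2$intensity <- 100
  expect_equal(ptm_relative_abundance(v2, proteins)$relative_abundance, 1)
  v3 <- v2; v3$intensity <- 200
  p3 <- proteins; p3$intensity <- p3$intensity * 2
  expect_equal(ptm_relative_abundance(v3, p3)$relative_abundance, 1)
  # product absent -> sample omitted with a warning
  v4 <- variants; v4$sample[3] <- "s3"
  expect_warning(out <- ptm_relative_abundance(v4, proteins), "s3")
  expect_false("s3" %in% out$sample)
})

test_that("occupancy ramps in the scenario surface as monotone relative
           abundance series", {
  sc <- tiny_scenario(n_days = 8)
  lib <- build_scenario_library(sc)
  st <- simulate_timecourse(sc)
  r <- render_dia(st, lib, noise_model(sigma = 0.05), seed = 4, replicates = 3)
  q <- suppressMessages(filter_fdr(sum_transitions(r$transitions, lib,
                                                   max_transitions = Inf)))
  prot <- suppressMessages(protein_intensity(q))
  variants <- q |> dplyr::filter(!is.na(family), is.na(carboxyl_count))
  ptm <- ptm_relative_abundance(variants, prot)
  # S141 glycan occupancy rises with day: its "none" class share falls
  s141 <- ptm |>
    dplyr::filter(variant == "S141 none", grepl("^B_", sample)) |>
    dplyr::mutate(day = as.integer(sub("^B_d(\\d+)_r\\d$", "\\1", sample))) |>
    dplyr::group_by(day) |>
    dplyr::summarise(v = mean(relative_abundance), .groups = "drop") |>
    dplyr::arrange(day)
  expect_lt(s141$v[nrow(s141)], s141$v[1])
})

test_that("time-course matrices mark missing values and reject duplicates", {
  series <- tibble::tibble(
    variant = c("a", "a", "b"), sample = c("d1", "d2", "d1"),
    relative_abundance = c(1, 2, 3)
  )
  m <- timecourse_matrix(series)
  expect_equal(dim(m), c(2L, 3L))
  expect_true(is.na(m$d2[m$variant == "b"]))
  expect_equal(m$d1, c(1, 3))
  m10 <- timecourse_matrix(series, log10 = TRUE)
  expect_equal(m10$d2[m10$variant == "a"], log10(2))
  dup <- dplyr::bind_rows(series, series[1, ])
  expect_error(timecourse_matrix(dup), "Duplicate")
  single <- series[1, ]
  expect_equal(dim(timecourse_matrix(single)), c(1L, 2L))
})
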