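# Monoisotopic mass calculus: neutral masses, precursor/fragment/diagnostic
# ions, glycan arithmetic, digestion, carboxyform and methylform enumeration.

test_that("neutral mass matches frozen residue-sum values and is additive", {
  # frozen from an independent residue-table sum: sum(AA) + water
  expect_equal(peptide_neutral_mass("VATVSLPR"), 841.50214, tolerance = 1e-6)
  expect_equal(peptide_neutral_mass("TTEFWK", "Methyl"), 824.40684,
               tolerance = 1e-6)
  # additivity in modifications, to 1e-6 Da
  reg <- mod_registry()
  for (i in seq_len(nrow(reg))) {
    seqs <- c(Gla = "PEPTIDE", Methyl = "PEPTIDE", Propionamide = "ACDEFK",
              Oxidation = "ADGK", Deamidation = "ANQK", Sulfo = "AYK",
              Phospho = "ASYK")
    s <- seqs[[reg$name[i]]]
    site <- regexpr(substr(reg$targets[i], 1, 1), s)
    m <- if (reg$targets[i] == "*") reg$name[i] else paste0(site, ":", reg$name[i])
    expect_equal(
      peptide_neutral_mass(s, m) - peptide_neutral_mass(s),
      reg$delta_mass[i],
      tolerance = 1e-6, label = reg$name[i]
    )
  }
})

test_that("invalid peptidoforms are rejected with informative errors", {
  expect_error(peptide_neutral_mass(""), "non-empty")
  expect_error(peptide_neutral_mass("PEPTIDEZ"), "Z")
  expect_error(peptide_neutral_mass("PEPTIDE", "99:Gla"), "outside")
  expect_error(peptide_neutral_mass("PAPTIDE", "2:Gla"), "requires")
  expect_error(peptide_neutral_mass("PEPTIDE", "1:NotAMod"), "Unknown modification")
  expect_error(precursor_mz("VATVSLPR", z = 0), "positive")
})

test_that("precursor m/z follows the proton relation at every charge", {
  for (s in c("VATVSLPR", "TTEFWK", "LEEFVQGNLER")) {
    m <- peptide_neutral_mass(s)
    expect_equal(precursor_mz(s, z = 1) - m, 1.007276, tolerance = 1e-9)
    # z * mz - z * proton is charge-invariant (equals the neutral mass)
    for (z in 1:4) {
      expect_equal(z * precursor_mz(s, z = z) - z * 1.007276, m,
                   tolerance = 1e-9)
    }
  }
})

test_that("glycan masses are count-weighted sums with exact substitutions", {
  expect_equal(glycan_mass("HexNAc1Hex1NeuAc1"), 656.22761, tolerance = 1e-5)
  expect_equal(glycan_mass("HexNAc1Hex1NeuAc1", nominal = TRUE), 656)
  expect_equal(glycan_mass("HexNAc1Hex1NeuAc2", nominal = TRUE), 947)
  expect_equal(glycan_mass("Hex0"), 0)
  # NeuGc-for-NeuAc swap is exactly +15.99491 (the printed glycoform pairs
  # differ by this at the composition level)
  expect_equal(
    glycan_mass("HexNAc1Hex1NeuAc1NeuGc1") - glycan_mass("HexNAc1Hex1NeuAc2"),
    307.09033 - 291.09542,
    tolerance = 1e-9
  )
  expect_equal(glycan_mass("Fuc1Xyl1"), glycan_mass("dHex1Pent1"))
  expect_error(glycan_mass("NotAGlycan"), "composition")
  expect_error(glycan_mass(c(Hex = -1)), "Negative")
})

test_that("fragment ladders follow standard b/y arithmetic", {
  # independent oracle: cumulative residue sums
  aa <- amino_acid_masses()
  s <- "VATVSLPR"
  letters <- strsplit(s, "")[[1]]
  y_expected <- cumsum(rev(unname(aa[letters]))) + 18.010565 + 1.007276
  b_expected <- cumsum(unname(aa[letters])) + 1.007276
  fr <- fragment_ions(s, series = c("b", "y"), z = 1)
  expect_equal(fr$mz[fr$series == "y"], unname(y_expected), tolerance = 1e-6)
  expect_equal(fr$mz[fr$series == "b"], unname(b_expected), tolerance = 1e-6)
  # full-length y equals neutral mass + proton, for a modified form too
  fr2 <- fragment_ions("TTEFWK", "3:Gla", series = "y", z = 1)
  expect_equal(
    max(fr2$mz), peptide_neutral_mass("TTEFWK", "3:Gla") + 1.007276,
    tolerance = 1e-9
  )
  # b1 of a glycine-initial peptide: residue + proton (frozen from the oracle)
  frg <- fragment_ions("GASK", series = "b", z = 1)
  expect_equal(frg$mz[frg$index == 1], 58.028736, tolerance = 1e-5)
  expect_error(fragment_ions("GASK", series = "c"), "Unsupported")
})

test_that("SO3 neutral-loss ladder restores the unmodified ladder", {
  s <- "FWKQYVDGDQCE"
  plain <- fragment_ions(s, "11:Propionamide", series = "y", z = 1)
  sulfo <- fragment_ions(s, "11:Propionamide;5:Sulfo", series = "y", z = 1,
                         neutral_loss = "SO3")
  loss <- sulfo[grepl("-SO3", sulfo$label), ]
  # fragments spanning Y5 (y8..y12) lose SO3 back to the unmodified value
  expect_equal(nrow(loss), 5L)
  for (i in loss$index) {
    expect_equal(
      loss$mz[loss$index == i],
      plain$mz[plain$index == i],
      tolerance = 1e-9
    )
  }
})

test_that("glycopeptide Y ions strip HexNAc-first and match printed values", {
  y <- glycopeptide_y_ions("TTEFWK", "Methyl;1:HexNAc1Hex1NeuAc1")
  expect_equal(y$mz[y$k == 0], 825.4141, tolerance = 0.002)
  expect_equal(y$mz[y$k == 1], 1028.4935, tolerance = 0.002)
  expect_equal(y$mz[y$k == 2], 1190.5463, tolerance = 0.002)
  expect_equal(y$added[2:4], c("HexNAc", "Hex", "NeuAc"))
  # no glycan -> empty
  expect_equal(nrow(glycopeptide_y_ions("TTEFWK", "Methyl")), 0L)
})

test_that("immonium ions follow residue arithmetic and modification additivity", {
  expect_equal(immonium_mz("Y"), 136.0757, tolerance = 1e-4)
  expect_equal(immonium_mz("Y", "Phospho"), 216.042, tolerance = 0.002)
  expect_equal(immonium_mz("Y", "Phospho") - immonium_mz("Y"), 79.96633,
               tolerance = 1e-9)
})

test_that("digestion reproduces the GLA-domain tryptic peptides", {
  gla <- read_fasta(system.file("extdata", "rfix_gla_synthetic.fasta",
                                package = "glaquant"))$sequence[1]
  p0 <- digest(gla, "trypsin", max_missed = 0)$peptide
  expect_true(all(c("LEEFVQGNLER", "CSFEEAR", "EVFENTER", "TTEFWK") %in% p0))
  p1 <- digest(gla, "trypsin", max_missed = 1)$peptide
  expect_true("CSFEEAREVFENTER" %in% p1)
  expect_true(all(p0 %in% p1))
  # a sequence with no cleavage site is returned whole
  expect_equal(digest("AGGAGG", "trypsin")$peptide, "AGGAGG")
  expect_error(digest("AGGAGG", "papain"), "Unknown protease")
})

test_that("digestion equals the brute-force oracle on random sequences", {
  set.seed(401)
  aa <- names(amino_acid_masses())
  cases <- list(
    list(enzyme = "trypsin", residues = c("K", "R"), side = "C", no_pro = TRUE),
    list(enzyme = "gluc", residues = "E", side = "C", no_pro = FALSE),
    list(enzyme = "aspn", residues = "D", side = "N", no_pro = FALSE),
    list(enzyme = "chymotrypsin", residues = c("F", "W", "Y"), side = "C",
         no_pro = TRUE)
  )
  for (rep in 1:12) {
    s <- paste(sample(aa, sample(10:60, 1), replace = TRUE), collapse = "")
    for (cs in cases) {
      for (mm in c(0L, 2L)) {
        got <- digest(s, cs$enzyme, max_missed = mm)
        want <- brute_force_digest(s, cs$residues, cs$side, mm, cs$no_pro)
        got_k <- sort(paste(got$peptide, got$start, got$end, got$n_missed))
        want_k <- sort(paste(want$peptide, want$start, want$end, want$n_missed))
        expect_identical(got_k, want_k,
                         label = paste(cs$enzyme, "mm", mm, "on", s))
      }
    }
  }
})

test_that("carboxyform families form an arithmetic mass ladder", {
  cf <- enumerate_carboxyforms("LEEFVQGNLER", gla_sites = c(2, 3, 10))
  expect_equal(cf$k, 0:3)
  expect_equal(diff(cf$neutral_mass), rep(43.98983, 3), tolerance = 1e-9)
  expect_equal(nrow(enumerate_carboxyforms("TTEFWK", gla_sites = 3)), 2L)
  # empty site set returns the input alone
  noop <- enumerate_carboxyforms("TTEFWK", "Methyl", integer())
  expect_equal(nrow(noop), 1L)
  expect_equal(noop$mods, "Methyl")
  expect_error(enumerate_carboxyforms("TTEFWK", gla_sites = 1), "glutamate")
})

test_that("methylform inventory counts free carboxyl groups", {
  # gamma-carboxylated TTEFWK: 2 carboxyls from Gla + C-terminus = 3 -> 4 forms
  mf <- enumerate_methylforms("TTEFWK", "3:Gla")
  expect_equal(unique(mf$inventory), 3L)
  expect_equal(nrow(mf), 4L)
  expect_equal(diff(mf$neutral_mass), rep(14.01565, 3), tolerance = 1e-9)
  # fully carboxylated LEEFVQGNLER: 3 Gla -> inventory 7, capped at 6
  mf2 <- enumerate_methylforms("LEEFVQGNLER", "2:Gla;3:Gla;10:Gla")
  expect_equal(unique(mf2$inventory), 7L)
  expect_equal(nrow(mf2), 7L)          # 0..6 methyls
  # no D/E and amidated C-terminus -> single unmethylated form
  expect_equal(nrow(enumerate_methylforms("AGGK", c_term_free = FALSE)), 1L)
})
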