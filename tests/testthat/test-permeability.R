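test_that("corrected rate ratios reproduce the published worked examples", {
  # labeling comparison series: AqpZ, AqpZ-GFP, AqpZ-Atto594 vs empty
  r1 <- corrected_rate_ratios(c(153.0, 102.4, 59.2), 33.3, reference = 3)
  expect_equal(round(r1, 1), c(4.6, 2.7, 1.0))
  expect_identical(r1[[3]], 1)
  # concentration series: 0.05 / 0.1 / 0.2 mg/ml vs empty
  r2 <- corrected_rate_ratios(c(96.0, 152.5, 254.1), 26.7, reference = 1)
  expect_equal(round(r2, 2), c(1.00, 1.82, 3.28))
  # all equal to the reference gives exactly one
  expect_equal(corrected_rate_ratios(c(50, 50, 50), 20), c(1, 1, 1))
})

test_that("rate ratios flag non-positive activity and bad references", {
  expect_warning(r <- corrected_rate_ratios(c(100, 25), 30, reference = 1),
                 "non-positive")
  expect_true(is.na(r[2]))
  expect_error(corrected_rate_ratios(c(100, 50), 120, reference = 1),
               "does not exceed")
  # invariance under common rescaling of the corrected rates
  K <- c(96.0, 152.5, 254.1)
  base <- corrected_rate_ratios(K, 26.7)
  expect_equal(corrected_rate_ratios(26.7 + 3 * (K - 26.7), 26.7), base)
})

test_that("osmotic permeability matches a hand unit conversion", {
  # K r / (3 V_w dosm): 100/s * 62.35e-7 cm / (3 * 18 cm3/mol * 5e-4
  # mol/cm3) = 2.3093e-2 cm/s = 230.93 um/s
  hand <- 100 * (62.35e-7) / (3 * 18 * 0.5e-3) * 1e4
  expect_equal(osmotic_permeability(100, 124.7, 0.5, 18), hand,
               tolerance = 1e-12)
  expect_equal(osmotic_permeability(0, 124.7), 0)
  expect_equal(osmotic_permeability(200, 124.7),
               2 * osmotic_permeability(100, 124.7))
  expect_error(osmotic_permeability(100, -1), "positive")
  # the formula slot is pluggable
  plug <- function(K, d, dosm, Vw) K * 0.2245
  expect_equal(osmotic_permeability(96, 124.7, formula = plug), 96 * 0.2245)
})

test_that("channel counting follows the stoichiometric chain", {
  # arithmetic oracle, step by step: area -> lipids -> tetramers -> pores
  r <- 62.35                       # nm
  area <- 4 * pi * r^2             # one leaflet, nm^2
  lipids <- 2 * area / 0.7
  tetramers <- lipids / 18713
  hand <- 4 * tetramers
  n <- channels_per_vesicle(7.5, 0.05, vesicle_diameter = 124.7,
                            lpr = 18713)
  expect_equal(as.numeric(n), hand, tolerance = 1e-12)
  expect_equal(attr(n, "tetramers"), tetramers)
  # doubling protein doubles channels (concentration route)
  n1 <- channels_per_vesicle(7.5, 0.05, vesicle_diameter = 124.7)
  n2 <- channels_per_vesicle(7.5, 0.10, vesicle_diameter = 124.7)
  expect_equal(as.numeric(n2) / as.numeric(n1), 2, tolerance = 1e-12)
  expect_warning(n0 <- channels_per_vesicle(7.5, 0, vesicle_diameter = 124.7),
                 "zero channels")
  expect_equal(as.numeric(n0), 0)
})

test_that("single-channel permeability reproduces the published table values", {
  # control-corrected membrane permeabilities (printed values minus the
  # empty-liposome control), extruded diameters and molar ratios from the
  # concentration series; expected per-channel values as printed
  pf_corr <- c(21.55, 39.23, 62.52) - 6.39       # um/s
  diam <- c(124.7, 142.9, 136.7)                 # nm
  lpr <- c(18713, 9356, 4678)
  printed <- c(2.48, 2.69, 2.29) * 1e-14         # cm^3/s
  for (i in 1:3) {
    n <- channels_per_vesicle(7.5, 0, vesicle_diameter = diam[i],
                              lpr = lpr[i])
    p <- single_channel_permeability(pf_corr[i], diam[i], n)
    expect_equal(p, printed[i], tolerance = 0.005)
  }
  # inverse proportionality in the channel count and zero propagation
  expect_equal(single_channel_permeability(10, 124.7, 60),
               single_channel_permeability(10, 124.7, 30) / 2)
  expect_equal(single_channel_permeability(0, 124.7, 30), 0)
  expect_error(single_channel_permeability(10, 124.7, 0), "undefined")
})

test_that("the permeability record chains all stages consistently", {
  rec <- permeability_record(K = 96.0, K_empty = 26.7,
                             vesicle_diameter = 124.7, protein_conc = 0.05,
                             label = "aqpz_0.05")
  expect_equal(rec$K_corrected, 69.3)
  expect_equal(rec$P_f_corrected,
               osmotic_permeability(69.3, 124.7))
  expect_equal(rec$p_f,
               single_channel_permeability(rec$P_f_corrected, 124.7,
                                           rec$channels))
  expect_gt(rec$channels, 25)
  expect_lt(rec$channels, 35)
})
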