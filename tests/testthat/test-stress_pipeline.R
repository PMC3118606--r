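fixture_summaries <- function(reference = "auto") {
  normalize_stress(summarize_chambers(toadfish_fixture()), reference = reference)
}

test_that("thinness ratios use the stress-extremal pairings", {
  fx <- toadfish_fixture()$chambers
  canal <- fx[[1]]; ampulla <- fx[[2]]; utricle <- fx[[3]]
  expect_equal(thinness_ratio(canal, "mean"), 307 / 70)
  expect_equal(thinness_ratio(ampulla, "mean"), 697 / 58)
  # max pairs r_max with w_min; verified as the maximum of all four
  # extreme pairings by enumeration
  pairings <- c(654 / 20, 654 / 42, 469 / 20, 469 / 42)
  expect_equal(thinness_ratio(utricle, "max"), max(pairings))
  expect_equal(thinness_ratio(utricle, "min"), min(pairings))
})

test_that("thin-membrane criterion flags thin, approaching and below bands", {
  fx <- toadfish_fixture()$chambers
  canal <- thin_membrane_check(fx[[1]])
  expect_false(canal$thin_ok)
  expect_identical(canal$band, "approaches")  # 4.4 sits in [4, 5)
  utricle <- thin_membrane_check(fx[[3]])
  expect_true(utricle$thin_ok)
  expect_identical(utricle$band, "thin")
  thick <- chamber_measurement("thick", "cylinder", 10, 10, 10, 20, 20, 20)
  expect_identical(thin_membrane_check(thick)$band, "below")
  tenfold <- chamber_measurement("x", "cylinder", 1, 1, 1, 10, 10, 10)
  expect_true(thin_membrane_check(tenfold)$thin_ok)
  expect_equal(thin_membrane_check(tenfold)$ratio, 10)
})

test_that("chamber summaries reproduce the published mean GSFs", {
  s <- summarize_chambers(toadfish_fixture())
  expect_equal(s$s, c(1, 0.5, 1))
  expect_equal(round(s$gsf_mean, 1), c(4.4, 6.0, 17.4))
  expect_equal(round(s$thinness_mean, 1), c(4.4, 12.0, 17.4))
  # pipeline consistency: gsf == s * thinness for every statistic
  expect_identical(s$gsf_mean, s$s * s$thinness_mean)
  expect_identical(s$gsf_max, s$s * s$thinness_max)
  expect_identical(s$gsf_min, s$s * s$thinness_min)
  expect_true(all(s$gsf_min <= s$gsf_mean & s$gsf_mean <= s$gsf_max))
})

test_that("summaries hold for degenerate and ellipsoid chambers", {
  flat <- summarize_chamber(
    chamber_measurement("flat", "sphere", 5, 5, 5, 50, 50, 50))
  expect_equal(flat$gsf_min, flat$gsf_mean)
  expect_equal(flat$gsf_max, flat$gsf_mean)
  ell <- summarize_chamber(
    chamber_measurement("ell", "ellipsoid", 1, 2, 0.5, 10, 12, 8, a = 10, b = 20))
  expect_equal(ell$s, 0.875)
  tor <- summarize_chamber(
    chamber_measurement("tor", "torus", 1, 2, 0.5, 10, 12, 8,
                        r_tube = 10, R_loop = 110))
  expect_equal(tor$s, 1.05)  # inner-equator excess at R = 11 r
})

test_that("auto normalization picks the minimum-GSF chamber and pins it at 1", {
  s <- fixture_summaries()
  expect_identical(attr(s, "reference"), "Anterior Canal")
  expect_identical(s$t_n_mean[1], 1)
  expect_true(all(s$t_n_mean >= 1))
  expect_equal(s$t_n_mean[2], 6.008621 / 4.385714, tolerance = 1e-6)
  expect_equal(s$t_n_mean_display, c(1.0, 1.4, 3.9))
  # permuting chamber order never changes any chamber's t_n
  fx <- toadfish_fixture()
  perm <- measurement_set(fx$chambers[c(3, 1, 2)], fx$provenance)
  sp <- normalize_stress(summarize_chambers(perm))
  expect_equal(sp$t_n_mean[match(s$chamber, sp$chamber)], s$t_n_mean)
})

test_that("explicit reference normalization and errors behave", {
  s <- fixture_summaries(reference = "Utricle")
  expect_identical(attr(s, "reference"), "Utricle")
  expect_identical(s$t_n_mean[3], 1)
  expect_equal(s$t_n_mean[1], 4.385714 / 17.375, tolerance = 1e-6)
  expect_error(fixture_summaries(reference = "Saccule"), "lookup error")
  single <- normalize_stress(summarize_chambers(measurement_set(list(
    chamber_measurement("only", "sphere", 1, 2, 0.5, 10, 12, 8)))))
  expect_identical(single$t_n_mean, 1)
})

test_that("fixture ordering and individual overlap match the qualitative findings", {
  s <- fixture_summaries()
  g <- s$gsf_mean
  expect_true(g[1] < g[2] && g[2] < g[3])          # canal < ampulla < utricle
  expect_lt(s$gsf_min[2], s$gsf_max[1])            # ampulla can undercut a canal
})

test_that("extremes analysis reports the splay and both disparity conventions", {
  s <- fixture_summaries()
  e <- extremes_analysis(s)
  expect_identical(names(e), c("chamber", "t_n_min", "t_n_mean", "t_n_max"))
  # utricle shows the widest splay of the three
  expect_identical(e$chamber[which.max(e$t_n_max)], "Utricle")
  spread <- e$t_n_max - e$t_n_min
  expect_identical(e$chamber[which.max(spread)], "Utricle")
  expect_lt(spread[1], spread[3] / 4)  # canal values cluster near 1
  # envelope disparity: ~7.5-fold vs the reference mean, ~10.4 vs its minimum
  expect_equal(attr(e, "disparity_vs_reference_mean"), 32.7 / (307 / 70),
               tolerance = 1e-12)
  expect_equal(attr(e, "disparity_vs_reference_min"), 32.7 / (270 / 86),
               tolerance = 1e-12)
  expect_error(extremes_analysis(summarize_chambers(toadfish_fixture())),
               "normalize_stress")
})

test_that("joint rescaling of all lengths leaves every output unchanged", {
  fx <- toadfish_fixture()
  for (k in c(0.01, 3.7, 1000)) {
    scaled <- measurement_set(lapply(fx$chambers, function(m) {
      chamber_measurement(m$name, m$shape_model,
                          m$w_mean * k, m$w_max * k, m$w_min * k,
                          m$r_mean * k, m$r_max * k, m$r_min * k)
    }), fx$provenance)
    s0 <- fixture_summaries()
    s1 <- normalize_stress(summarize_chambers(scaled))
    for (col in c("gsf_mean", "gsf_max", "gsf_min", "t_n_mean", "t_n_max", "t_n_min")) {
      expect_equal(s1[[col]], s0[[col]], tolerance = 1e-12)
    }
  }
})

test_that("reports render in all three formats and round-trip through JSON", {
  s <- fixture_summaries()
  tab <- build_report(s, "table")
  expect_match(tab[2], "Anterior Canal.*1\\.0.*4\\.4.*4\\.4.*1\\.0")
  expect_match(tab[4], "Utricle.*17\\.4.*17\\.4.*3\\.9")
  expect_match(tab[length(tab)], "Anterior Canal")
  csv <- build_report(s, "csv")
  got <- utils::read.csv(text = csv)
  expect_equal(got$gsf_mean, s$gsf_mean)
  js <- build_report(s, "json")
  back <- jsonlite::fromJSON(js)
  expect_identical(back$reference, "Anterior Canal")
  expect_equal(back$summaries$t_n_mean, s$t_n_mean)
  expect_error(build_report(s[0, ], "table"), "empty")
  expect_error(build_report(s, "yaml"))
})
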