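test_that("the FDR filter keeps records at or below the cutoff", {
  tab <- dplyr::bind_rows(
    psm_row("APK", 1, q = 0.001),
    psm_row("APK", 1, q = 0.009),
    psm_row("APK", 1, q = 0.011)
  )
  expect_identical(nrow(filter_psms(tab)), 2L)
  expect_identical(nrow(filter_psms(tab, fdr = 1)), 3L)
  expect_identical(nrow(filter_psms(tab[0, ])), 0L)
})

test_that("the sibling rule qualifies mistranslated peptides", {
  with_sib <- dplyr::bind_rows(
    psm_row("APK", 3, site = 2),
    psm_row("APK", 57)
  )
  q1 <- qualify_siblings(with_sib)
  expect_identical(nrow(q1), 2L)
  expect_identical(attr(q1, "excluded_no_sibling"), 0L)

  no_sib <- dplyr::bind_rows(
    psm_row("APK", 3, site = 2),
    psm_row("KLMR", 10)
  )
  q2 <- qualify_siblings(no_sib)
  expect_identical(nrow(q2), 1L)
  expect_identical(q2$peptide, "KLMR")
  expect_identical(attr(q2, "excluded_no_sibling"), 1L)
})

test_that("frequency is mistranslated counts over all Pro-containing counts", {
  tab <- dplyr::bind_rows(
    psm_row("APK", 3, site = 2),
    psm_row("APK", 40),
    psm_row("PLLR", 17),
    psm_row("KLMR", 100) # no proline: not in the denominator
  )
  out <- mistranslation_frequency(tab)
  expect_identical(out$n_mistranslated, 3L)
  expect_identical(out$n_pro_total, 60L)
  expect_equal(out$frequency_pct, 5)

  none <- mistranslation_frequency(dplyr::bind_rows(
    psm_row("APK", 40), psm_row("PLLR", 20)
  ))
  expect_equal(none$frequency_pct, 0)

  expect_error(
    mistranslation_frequency(psm_row("KLMR", 5)),
    "frequency undefined"
  )
})

test_that("excluded mistranslated peptides leave numerator and denominator", {
  tab <- dplyr::bind_rows(
    psm_row("APK", 3, site = 2),
    psm_row("APK", 57),
    psm_row("GPGR", 5, site = 2) # no unmodified GPGR observed
  )
  out <- mistranslation_frequency(tab)
  expect_identical(out$n_mistranslated, 3L)
  expect_identical(out$n_pro_total, 60L)
  expect_identical(out$excluded_no_sibling, 1L)
})

test_that("frequency is invariant under duplicating every record", {
  tab <- dplyr::bind_rows(
    psm_row("APK", 3, site = 2),
    psm_row("APK", 57),
    psm_row("PLLR", 40)
  )
  a <- mistranslation_frequency(tab)
  b <- mistranslation_frequency(dplyr::bind_rows(tab, tab))
  expect_equal(a$frequency_pct, b$frequency_pct)
})

test_that("a two-site peptide counts once unless per-site counting is on", {
  two_site <- tibble::tibble(
    peptide = "APAPK", protein = "p", q = 0.001, count = 2L,
    mods = list(tibble::tibble(
      position = c(2L, 4L), delta = -10.0207, name = "pro_to_ser"
    )),
    n_sub = 2L, is_mistranslated = TRUE
  )
  tab <- dplyr::bind_rows(two_site, psm_row("APAPK", 38))
  once <- mistranslation_frequency(tab)
  expect_identical(once$n_mistranslated, 2L)
  expect_equal(once$frequency_pct, 5)
  per_site <- mistranslation_frequency(tab, per_site = TRUE)
  expect_identical(per_site$n_mistranslated, 4L)
})

test_that("unique-peptide counting ignores spectral depth", {
  tab <- dplyr::bind_rows(
    psm_row("APK", 1, site = 2),
    psm_row("APK", 99),
    psm_row("PLLR", 900)
  )
  spectral <- mistranslation_frequency(tab, counting = "spectral")
  uniq <- mistranslation_frequency(tab, counting = "unique")
  expect_equal(spectral$frequency_pct, 100 * 1 / 1000)
  expect_equal(uniq$frequency_pct, 100 * 1 / 3)
})

test_that("the planted substitution rate is recovered from simulated tables", {
  sim <- simulate_psms(proteome_scenario(f = 0.049, seed = 404))
  psms <- suppressWarnings(validate_psm_tbl(sim$psms))
  out <- mistranslation_frequency(psms)
  expect_gte(out$n_pro_total, 10000)
  expect_lt(abs(out$frequency_pct - 4.9), 0.5)
})

test_that("full sibling dropout forces the estimate to zero", {
  sim <- simulate_psms(proteome_scenario(
    f = 0.049, sibling_dropout = 1, seed = 405
  ))
  psms <- suppressWarnings(validate_psm_tbl(sim$psms))
  out <- mistranslation_frequency(psms)
  expect_equal(out$frequency_pct, 0)
  expect_gt(out$excluded_no_sibling, 0)
})

test_that("the estimator is consistent across repeated simulations", {
  errs <- vapply(1:15, function(s) {
    sim <- simulate_psms(proteome_scenario(
      f = 0.049, total_counts = 5000, seed = 500 + s
    ))
    psms <- suppressWarnings(validate_psm_tbl(sim$psms))
    mistranslation_frequency(psms)$frequency_pct - 4.9
  }, numeric(1))
  # mean error within Monte-Carlo error of zero (se of mean ~ 0.3/sqrt(15))
  expect_lt(abs(mean(errs)), 3 * stats::sd(errs) / sqrt(length(errs)) + 0.05)
})
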