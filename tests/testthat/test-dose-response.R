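spots_from_means <- function(means, n_reps = 3) {
  # means: strain, construct, mu
  tidyr::expand_grid(means, replicate = seq_len(n_reps)) |>
    dplyr::mutate(intensity = mu) |>
    dplyr::select(strain, construct, replicate, intensity)
}

test_that("normalized growth divides by the wild-type tRNA construct", {
  means <- tidyr::expand_grid(
    strain = "BY4742", construct = mistranslation_levels()$construct
  ) |>
    dplyr::mutate(mu = c(100, 71, 55, 37))
  prof <- normalized_growth(spots_from_means(means), n_boot = 0)
  expect_equal(
    prof$pct[order(prof$level)],
    c(71, 55, 37)[order(factor(c("low", "medium", "high"),
      levels = c("low", "medium", "high")
    ))]
  )
  high <- prof[prof$level == "high", ]
  expect_equal(high$pct, 37)
  expect_identical(high$construct, "tS(UGG)")
})

test_that("equal constructs give 100% and a dead construct gives 0%", {
  means <- tidyr::expand_grid(
    strain = "s", construct = mistranslation_levels()$construct
  ) |>
    dplyr::mutate(mu = 80)
  prof <- normalized_growth(spots_from_means(means), n_boot = 0)
  expect_equal(prof$pct, rep(100, 3))

  means$mu[means$construct == "tS(UGG)"] <- 0
  prof0 <- normalized_growth(spots_from_means(means), n_boot = 0)
  expect_equal(prof0$pct[prof0$level == "high"], 0)
})

test_that("normalized growth demands the reference construct and replicates", {
  means <- tidyr::expand_grid(
    strain = "s",
    construct = setdiff(mistranslation_levels()$construct, "WT-tS")
  ) |>
    dplyr::mutate(mu = 50)
  expect_error(normalized_growth(spots_from_means(means)), "WT-tS")
  full <- tidyr::expand_grid(
    strain = "s", construct = mistranslation_levels()$construct
  ) |>
    dplyr::mutate(mu = 50)
  expect_error(
    normalized_growth(spots_from_means(full, n_reps = 2)),
    "fewer than 3"
  )
})

test_that("relative effect of the wild-type strain against itself is 100", {
  means <- tidyr::expand_grid(
    strain = c("BY4742", "twin"),
    construct = mistranslation_levels()$construct
  ) |>
    dplyr::mutate(mu = rep(c(100, 71, 55, 37), 2))
  prof <- normalized_growth(spots_from_means(means), n_boot = 0)
  rel <- relative_synthetic_effect(prof)
  expect_equal(rel$rel_pct, rep(100, 3))
  # and plain ratios: strain at 20% vs wild type at 40% -> 50%
  prof2 <- prof
  prof2$pct[prof2$strain == "twin"] <- prof2$pct[prof2$strain == "twin"] / 2
  rel2 <- relative_synthetic_effect(prof2)
  expect_equal(rel2$rel_pct, rep(50, 3))
})

test_that("classification reproduces the anchor profiles", {
  expect_identical(classify_triple(95, 70, 40), "proportional")
  expect_identical(classify_triple(80, 50, 48), "threshold")
  expect_identical(classify_triple(60, 58, 55), "uniform")
  # relatively strong impact already at the lowest level
  expect_identical(classify_triple(65, 55, 45), "low_sensitive")
})

test_that("classification is total and single-valued over the grid", {
  grid <- tidyr::expand_grid(
    low = seq(0, 120, by = 4),
    medium = seq(0, 120, by = 4),
    high = seq(0, 120, by = 4)
  )
  cats <- classify_triple(grid$low, grid$medium, grid$high)
  expect_identical(length(cats), nrow(grid))
  expect_false(any(is.na(cats)))
  expect_true(all(cats %in% c(
    "proportional", "threshold", "uniform", "low_sensitive"
  )))
})

test_that("worsening the high-level effect never turns threshold proportional", {
  set.seed(5)
  for (i in 1:500) {
    tri <- stats::runif(3, 0, 120)
    if (classify_triple(tri[1], tri[2], tri[3]) != "threshold") next
    lowered <- max(0, tri[3] - stats::runif(1, 0, tri[3]))
    expect_false(
      classify_triple(tri[1], tri[2], lowered) == "proportional",
      info = paste(c(tri, lowered), collapse = ",")
    )
  }
  # and a proportional profile stays proportional as high falls
  expect_identical(classify_triple(95, 70, 20), "proportional")
  expect_identical(classify_triple(95, 70, 5), "proportional")
})

test_that("classify_profiles works end-to-end from long format", {
  rel <- tidyr::expand_grid(
    strain = c("ctf8-like", "arc35-like", "act1-like"),
    level = c("low", "medium", "high")
  ) |>
    dplyr::mutate(rel_pct = c(95, 70, 40, 80, 50, 48, 60, 58, 55))
  out <- classify_profiles(rel) |> dplyr::arrange(strain)
  expect_identical(
    out$category[match(
      c("ctf8-like", "arc35-like", "act1-like"), out$strain
    )],
    c("proportional", "threshold", "uniform")
  )
  expect_error(
    classify_profiles(rel[rel$level != "high", ]),
    "low, medium, high"
  )
})

test_that("planted interaction factors are classified as planted", {
  cases <- list(
    list(rel = c(95, 70, 40) / 100, want = "proportional"),
    list(rel = c(60, 58, 55) / 100, want = "uniform"),
    list(rel = c(50, 50, 50) / 100, want = "uniform")
  )
  for (cs in cases) {
    fac <- tibble::tibble(
      strain = "ts-x", level = c("low", "medium", "high"), factor = cs$rel
    )
    sim <- simulate_spots(fac, noise_sdlog = 0.02, seed = 99)
    prof <- normalized_growth(sim$spots, n_boot = 0)
    rel <- relative_synthetic_effect(prof)
    got <- classify_profiles(rel)
    expect_identical(got$category, cs$want)
  }
})

test_that("Welch comparisons use unequal variances and the Bonferroni cap", {
  g1 <- c(84, 85, 83, 84)
  g2 <- c(98, 97, 99, 98)
  df <- tibble::tibble(
    value = c(g1, g2),
    group = rep(c("a", "b"), each = 4)
  )
  out <- welch_bonferroni(df, m = 1)
  ref <- stats::t.test(g1, g2, var.equal = FALSE)
  expect_equal(out$p_raw, ref$p.value, tolerance = 1e-12)
  expect_equal(out$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(out$df, unname(ref$parameter), tolerance = 1e-12)
  expect_lt(out$p_raw, 0.001)

  # identical constant groups: no evidence, p = 1
  same <- tibble::tibble(value = rep(5, 6), group = rep(c("a", "b"), each = 3))
  expect_equal(welch_bonferroni(same)$p_raw, 1)

  # Bonferroni cap at 1
  capped <- welch_bonferroni(df, m = 3)
  expect_equal(capped$p_adj, min(1, 3 * capped$p_raw))
  mild <- tibble::tibble(
    value = c(1, 2, 3, 1.5, 2.5, 3.5), group = rep(c("a", "b"), each = 3)
  )
  expect_equal(welch_bonferroni(mild, m = 3)$p_adj, 1)
})
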