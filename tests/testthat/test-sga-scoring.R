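test_that("epsilon is the multiplicative-model deviation", {
  expect_equal(epsilon(0.72, 0.8, 0.9), 0)
  expect_equal(epsilon(0.5, 1.0, 1.0), -0.5)
  expect_equal(epsilon(0.52, 0.9, 0.8), -0.2)
  expect_error(epsilon(-0.1, 1, 1), "non-negative")
  # vectorized
  expect_equal(epsilon(c(0.4, 0.9), c(0.8, 1), c(0.5, 0.9)), c(0, 0))
})

test_that("fitness_from_block keeps replicate resolution and flags unscorable", {
  expect_equal(fitness_from_block(c(500, 500, 500, 500), 500), c(1, 1, 1, 1))
  expect_equal(fitness_from_block(c(250, 250, NA, 250), 500), c(0.5, 0.5, 0.5))
  expect_equal(fitness_from_block(c(0, 0, 0, 0), 500), c(0, 0, 0, 0))
  expect_null(fitness_from_block(c(400, NA, NA, NA), 500))
  expect_error(fitness_from_block(c(1, 2), 0), "positive")
})

test_that("scale normalization maps a uniform plate onto the reference", {
  plates <- make_plate(n_rows = 16, n_cols = 24, size = 400)
  out <- normalize_plates(plates, mode = "scale", reference_median = 500)
  expect_equal(out$size, rep(500, nrow(out)))
  # identity when the plate already sits at the reference median
  same <- normalize_plates(plates, mode = "scale", reference_median = 400)
  expect_equal(same$size, plates$size)
  # no-op mode
  expect_equal(normalize_plates(plates, mode = "none")$size, plates$size)
})

test_that("median polish inverts a multiplicative column gradient", {
  plates <- make_plate(n_rows = 32, n_cols = 48, size = 500)
  gradient <- seq(0.8, 1.2, length.out = 48)
  plates$size <- 500 * gradient[plates$col]
  key <- make_key(n_rows = 32, n_cols = 48, n_alleles = 380)
  out <- normalize_plates(plates, mode = "medpolish", key = key)
  inner <- out[!validate_array_key(key)$is_border, ]
  expect_true(all(abs(inner$size - 500) / 500 < 0.01))
})

test_that("normalization rejects degenerate plates", {
  plates <- make_plate(n_rows = 8, n_cols = 12, size = 100)
  gone <- plates
  gone$size <- NA
  expect_error(normalize_plates(gone), "all-missing")
  holey <- plates
  holey$size[seq_len(60)] <- NA
  expect_error(normalize_plates(holey), "50%")
})

test_that("BH adjustment reproduces the hand-computed step-up", {
  # step-up with m = 4: (0.04, 0.04, 0.0533..., 0.8)
  expect_equal(
    bh_adjust(c(0.01, 0.02, 0.04, 0.8)),
    c(0.04, 0.04, 0.04 * 4 / 3, 0.8)
  )
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.2, NA, 0.01)), c(0.2, NA, 0.02))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("score_alleles matches a brute-force oracle on small screens", {
  for (seed in c(11, 12)) {
    set.seed(seed)
    n <- 8
    key <- make_key(n_rows = 8, n_cols = 12, n_alleles = n)
    w_a <- stats::runif(n, 0.5, 1)
    names(w_a) <- sprintf("ts%03d", seq_len(n))
    w_b <- 0.86
    eps_true <- c(-0.3, rep(0, n - 1))
    ctl <- plates_from_fitness(key, w_a)
    dbl <- plates_from_fitness(key, w_a * w_b + eps_true)
    # per-colony jitter so replicate scores differ
    ctl$size <- ctl$size * exp(stats::rnorm(nrow(ctl), 0, 0.03))
    dbl$size <- dbl$size * exp(stats::rnorm(nrow(dbl), 0, 0.03))

    fit <- fitness_table(dbl, ctl, validate_array_key(key), reference = 500)
    got <- score_alleles(fit, w_query = w_b) |> dplyr::arrange(allele)
    want <- brute_force_scores(dbl, ctl, validate_array_key(key), 500, w_b)

    expect_equal(got$w_a, want$w_a, tolerance = 1e-12)
    expect_equal(got$eps_mean, want$eps_mean, tolerance = 1e-12)
    expect_equal(got$p_raw, want$p_raw, tolerance = 1e-12)
  }
})

test_that("interaction calls respect the joint magnitude and FDR gates", {
  recs <- tibble::tibble(
    allele = c("a", "b", "c", "d", "e"),
    gene = allele,
    eps_reps = list(0, 0, 0, 0, 0),
    eps_mean = c(-0.25, -0.25, -0.15, 0.3, NA),
    n_rep = 4L,
    p_raw = c(0.001, 0.1, 0.0001, 0.0001, NA),
    scorable = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    call = "none"
  )
  # q values: BH of (0.001, 0.1, 0.0001, 0.0001) = (.00133, .1, .0004, .0004)
  out <- call_interactions(recs)
  expect_identical(
    out$call,
    c("negative", "none", "none", "positive", "none")
  )
  expect_true(all(out$q_bh >= out$p_raw, na.rm = TRUE))
  expect_error(call_interactions(recs, eps_threshold = 0.2), "negative")
})

test_that("an exactly multiplicative noiseless screen scores epsilon = 0", {
  sc <- screen_scenario(
    n_alleles = 50, noise_sdlog = 0, gradient_row = 0, gradient_col = 0,
    seed = 5
  )
  sim <- simulate_screen(sc)
  fit <- fitness_table(sim$doubles, sim$controls, sim$key, reference = 500)
  recs <- score_alleles(fit, w_query = sc$w_query)
  expect_true(all(abs(recs$eps_mean) < 1e-12))
})

test_that("epsilon is invariant under joint rescaling of sizes and reference", {
  sc <- screen_scenario(n_alleles = 40, seed = 21)
  sim <- simulate_screen(sc)
  score_with <- function(fac) {
    d <- sim$doubles
    c2 <- sim$controls
    d$size <- d$size * fac
    c2$size <- c2$size * fac
    score_screen(d, c2, sim$key, reference = 500 * fac, w_query = 0.86)
  }
  a <- score_with(1)
  b <- score_with(7.3)
  expect_equal(a$eps_mean, b$eps_mean, tolerance = 1e-9)
  expect_identical(a$call, b$call)
})

test_that("the query fitness estimate recovers the planted value", {
  sc <- screen_scenario(n_alleles = 400, w_query = 0.86, seed = 31)
  sim <- simulate_screen(sc)
  dbl <- normalize_plates(sim$doubles, key = sim$key)
  ctl <- normalize_plates(sim$controls, key = sim$key)
  fit <- fitness_table(dbl, ctl, sim$key, reference = 500)
  expect_equal(estimate_query_fitness(fit), 0.86, tolerance = 0.02)
})

test_that("planted negative interactions are recovered through the pipeline", {
  set.seed(77)
  idx <- sample(500, 12)
  sc <- screen_scenario(
    n_alleles = 500,
    interactions = tibble::tibble(allele = idx, eps = -0.4),
    seed = 78
  )
  sim <- simulate_screen(sc)
  hits <- score_screen(sim$doubles, sim$controls, sim$key, reference = 500)
  joined <- dplyr::left_join(hits, sim$truth, by = c("allele", "gene"))
  planted <- dplyr::filter(joined, eps < 0)
  expect_gte(mean(planted$call == "negative"), 0.95)
  expect_lt(abs(mean(planted$eps_mean) + 0.4), 0.05)
  nulls <- dplyr::filter(joined, eps == 0)
  expect_lte(sum(nulls$call == "negative"), 2)
})
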