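# Shared fixture builders and independent oracles.

# A complete plate table of the given format filled with `size`.
make_plate <- function(plate_id = "p1", n_rows = 32, n_cols = 48, size = 400) {
  tidyr::expand_grid(row = seq_len(n_rows), col = seq_len(n_cols)) |>
    dplyr::mutate(plate = plate_id, size = size, .before = 1) |>
    dplyr::select(plate, row, col, size)
}

# Minimal key: alleles laid out in 2x2 blocks row-major; remaining blocks blank.
make_key <- function(plate_id = "p1", n_rows = 32, n_cols = 48, n_alleles) {
  nbr <- n_rows %/% 2
  nbc <- n_cols %/% 2
  stopifnot(n_alleles <= nbr * nbc)
  blocks <- tidyr::expand_grid(br = seq_len(nbr), bc = seq_len(nbc)) |>
    dplyr::mutate(i = dplyr::row_number())
  tidyr::expand_grid(blocks, dr = 0:1, dc = 0:1) |>
    dplyr::mutate(
      plate = plate_id,
      row = 2L * (br - 1L) + 1L + dr,
      col = 2L * (bc - 1L) + 1L + dc,
      allele = ifelse(i <= n_alleles, sprintf("ts%03d", i), NA_character_),
      gene = ifelse(i <= n_alleles, sprintf("G%03d", i), NA_character_),
      block = ifelse(i <= n_alleles, sprintf("b%03d", i), NA_character_)
    ) |>
    dplyr::select(plate, row, col, allele, gene, block) |>
    dplyr::arrange(plate, row, col)
}

# Plates whose colony sizes are reference * fitness with no noise or gradient,
# given per-allele fitness values in key order.
plates_from_fitness <- function(key, fitness_by_allele, reference = 500) {
  key |>
    dplyr::mutate(
      size = ifelse(
        is.na(allele), 0,
        reference * unname(fitness_by_allele[allele])
      )
    ) |>
    dplyr::select(plate, row, col, size)
}

# Independent brute-force recomputation of interaction scores: plain loops,
# stats::t.test, no shared code with score_alleles().
brute_force_scores <- function(double_plates, control_plates, key, reference,
                               w_b) {
  key2 <- key[!is.na(key$allele), ]
  alleles <- sort(unique(key2$allele))
  out <- data.frame(
    allele = alleles, w_a = NA_real_, eps_mean = NA_real_, p_raw = NA_real_
  )
  for (j in seq_along(alleles)) {
    kk <- key2[key2$allele == alleles[j], ]
    ctl <- numeric(0)
    dbl <- numeric(0)
    for (i in seq_len(nrow(kk))) {
      sc <- control_plates$size[control_plates$plate == kk$plate[i] &
        control_plates$row == kk$row[i] & control_plates$col == kk$col[i]]
      sd_ <- double_plates$size[double_plates$plate == kk$plate[i] &
        double_plates$row == kk$row[i] & double_plates$col == kk$col[i]]
      if (!is.na(sc)) ctl <- c(ctl, sc / reference)
      if (!is.na(sd_)) dbl <- c(dbl, sd_ / reference)
    }
    if (length(ctl) < 2 || length(dbl) < 2) next
    w_a <- mean(ctl)
    eps <- dbl - w_a * w_b
    out$w_a[j] <- w_a
    out$eps_mean[j] <- mean(eps)
    if (stats::sd(eps) > 1e-12) {
      out$p_raw[j] <- stats::t.test(eps, mu = 0)$p.value
    } else {
      out$p_raw[j] <- if (abs(mean(eps)) < 1e-12) 1 else 0
    }
  }
  out
}

# Noiseless logistic curve on the standard plate-reader schedule.
logistic_series <- function(K = 1.4, N0 = 0.1, td = 90,
                            interval = 15, duration = 1440) {
  t <- seq(0, duration, by = interval)
  r <- log(2) / td
  list(time = t, od = K / (1 + ((K - N0) / N0) * exp(-r * t)))
}

# Small annotated PSM tibble built directly (already parsed form).
psm_row <- function(peptide, count, site = NA, q = 0.001,
                    protein = "prot1") {
  mis <- !is.na(site)
  tibble::tibble(
    peptide = peptide, protein = protein, q = q, count = as.integer(count),
    mods = list(if (mis) {
      tibble::tibble(
        position = as.integer(site), delta = -10.0207, name = "pro_to_ser"
      )
    } else {
      tibble::tibble(
        position = integer(), delta = double(), name = character()
      )
    }),
    n_sub = as.integer(mis),
    is_mistranslated = mis
  )
}
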