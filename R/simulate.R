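#' Screen-simulation scenario
#'
#' Describes a synthetic genetic array screen with known ground truth:
#' temperature-sensitive single-mutant fitnesses drawn uniformly (default
#' \[0.5, 1\]), a shared query-strain fitness (default 0.86, the relative
#' growth rate of the mistranslating strain against its control), a set of
#' alleles with planted interaction scores, multiplicative lognormal colony
#' noise, linear row/column gradients, and 2x2 quadruplicate layout on
#' 1,536-position plates with blank corner blocks (380 alleles + 4 blank
#' blocks = 384 blocks per plate).
#'
#' @param n_alleles Number of temperature-sensitive alleles (default 1000).
#' @param w_a_range Range of the uniform single-mutant fitness distribution.
#' @param w_query Query single-mutant fitness W_B.
#' @param interactions Tibble with columns `allele` (integer index in
#'   `1:n_alleles`) and `eps` (planted interaction score), or `NULL` for an
#'   all-null screen.
#' @param noise_sdlog Lognormal sd of multiplicative colony-size noise
#'   (default 0.05).
#' @param gradient_row,gradient_col Amplitude of the linear multiplicative
#'   spatial gradient across rows/columns (default 0.10, i.e. 0.9x to 1.1x).
#' @param reference Colony size of a fitness-1 strain in arbitrary area
#'   units (default 500).
#' @param seed Random seed (mandatory; default 1729).
#' @return A `screen_scenario` list, validated (planted scores must keep
#'   every double-mutant fitness non-negative: eps >= -min(W_A) * W_B).
#' @export
screen_scenario <- function(n_alleles = 1000,
                            w_a_range = c(0.5, 1.0),
                            w_query = 0.86,
                            interactions = NULL,
                            noise_sdlog = 0.05,
                            gradient_row = 0.10,
                            gradient_col = 0.10,
                            reference = 500,
                            seed = 1729) {
  if (is.null(seed)) abort_bad_input("seed is mandatory")
  if (n_alleles < 1) abort_bad_input("n_alleles must be >= 1")
  if (w_query < 0) abort_bad_input("w_query must be >= 0")
  if (!is.null(interactions)) {
    assert_cols(interactions, c("allele", "eps"), "interaction truth")
    feas <- -min(w_a_range) * w_query
    if (any(interactions$eps < feas)) {
      abort_bad_input(
        "infeasible planted eps: must be >= -min(W_A)*W_B = ", round(feas, 4)
      )
    }
    if (any(interactions$allele < 1 | interactions$allele > n_alleles)) {
      abort_bad_input("interaction allele index out of range")
    }
  }
  structure(
    list(
      n_alleles = as.integer(n_alleles), w_a_range = w_a_range,
      w_query = w_query, interactions = interactions,
      noise_sdlog = noise_sdlog, gradient_row = gradient_row,
      gradient_col = gradient_col, reference = reference,
      seed = as.integer(seed)
    ),
    class = "screen_scenario"
  )
}

# Quadruplicate layout: 16 x 24 blocks of 2x2 on a 32x48 plate; the four
# corner blocks are blank (border), leaving 380 alleles per plate.
screen_layout <- function(n_alleles) {
  nbr <- 16L
  nbc <- 24L
  corner <- c(1L, nbc, (nbr - 1L) * nbc + 1L, nbr * nbc)
  per_plate <- nbr * nbc - length(corner)
  n_plates <- ceiling(n_alleles / per_plate)
  blocks <- tidyr::expand_grid(
    plate_i = seq_len(n_plates), block_i = seq_len(nbr * nbc)
  ) |>
    dplyr::mutate(
      br = (.data$block_i - 1L) %/% nbc + 1L,
      bc = (.data$block_i - 1L) %% nbc + 1L,
      is_corner = .data$block_i %in% corner
    )
  usable <- which(!blocks$is_corner)
  blocks$allele_i <- NA_integer_
  blocks$allele_i[usable[seq_len(n_alleles)]] <- seq_len(n_alleles)
  blocks
}

#' Simulate a synthetic genetic array screen
#'
#' Generates the double-mutant (query cross) and single-mutant (control
#' cross) colony arrays for a [screen_scenario()], plus the array key and a
#' machine-readable truth table. Colony sizes follow
#' `reference x fitness x gradient(row, col) x lognormal noise`, with
#' `fitness = W_A * W_B + eps` on the double plates and `W_A` on the control
#' plates, laid out in 2x2 quadruplicate blocks. The generator is a pure
#' function of its scenario (same scenario, same output).
#'
#' @param sc A [screen_scenario()].
#' @return List with `doubles` and `controls` (plate tibbles), `key`
#'   (array-key tibble), `truth` (tibble with `allele`, `gene`, `w_a`,
#'   `eps`, plus `w_query` and `reference` attributes as columns) and the
#'   scenario.
#' @export
simulate_screen <- function(sc) {
  stopifnot(inherits(sc, "screen_scenario"))
  withr::with_seed(sc$seed, {
    blocks <- screen_layout(sc$n_alleles)
    w_a <- stats::runif(sc$n_alleles, sc$w_a_range[1], sc$w_a_range[2])
    eps <- rep(0, sc$n_alleles)
    if (!is.null(sc$interactions)) {
      eps[sc$interactions$allele] <- sc$interactions$eps
    }
    if (any(w_a * sc$w_query + eps < 0)) {
      # feasibility was checked in the scenario for the worst case;
      # numerically guard anyway
      abort_bad_input("planted eps drives a double-mutant fitness below 0")
    }

    # expand blocks to 4 positions each
    pos <- blocks |>
      tidyr::expand_grid(dr = 0:1, dc = 0:1) |>
      dplyr::mutate(
        plate = sprintf("plate%02d", .data$plate_i),
        row = 2L * (.data$br - 1L) + 1L + .data$dr,
        col = 2L * (.data$bc - 1L) + 1L + .data$dc
      )

    grad <- function(row, col) {
      nr <- 32L
      nc <- 48L
      (1 + sc$gradient_row * (2 * (row - 1) / (nr - 1) - 1)) *
        (1 + sc$gradient_col * (2 * (col - 1) / (nc - 1) - 1))
    }

    make_plate <- function(fitness_of) {
      f <- ifelse(is.na(pos$allele_i), NA_real_, fitness_of(pos$allele_i))
      noise <- exp(stats::rnorm(nrow(pos), 0, sc$noise_sdlog))
      size <- sc$reference * f * grad(pos$row, pos$col) * noise
      size[is.na(pos$allele_i)] <- 0 # blank border blocks: no colony
      tibble::tibble(
        plate = pos$plate, row = pos$row, col = pos$col, size = size
      ) |>
        dplyr::arrange(.data$plate, .data$row, .data$col)
    }

    doubles <- make_plate(function(i) w_a[i] * sc$w_query + eps[i])
    controls <- make_plate(function(i) w_a[i])

    key <- pos |>
      dplyr::mutate(
        allele = ifelse(is.na(.data$allele_i), NA_character_,
          sprintf("ts%04d", .data$allele_i)
        ),
        gene = ifelse(is.na(.data$allele_i), NA_character_,
          sprintf("GENE%04d", (.data$allele_i - 1L) %/% 1L + 1L)
        ),
        block = ifelse(is.na(.data$allele_i), NA_character_,
          sprintf("%s_b%03d", .data$plate, .data$block_i)
        )
      ) |>
      dplyr::select("plate", "row", "col", "allele", "gene", "block") |>
      dplyr::arrange(.data$plate, .data$row, .data$col)
    key <- validate_array_key(key)

    truth <- tibble::tibble(
      allele = sprintf("ts%04d", seq_len(sc$n_alleles)),
      gene = sprintf("GENE%04d", seq_len(sc$n_alleles)),
      w_a = w_a,
      eps = eps,
      w_query = sc$w_query,
      reference = sc$reference
    )

    list(
      doubles = validate_plate_tbl(doubles),
      controls = validate_plate_tbl(controls),
      key = key, truth = truth, scenario = sc
    )
  })
}

#' Proteome-simulation scenario
#'
#' Describes a synthetic peptide-spectrum-match table with a planted
#' per-observation substitution rate: random peptide sequences with tunable
#' proline content, spectral counts spread over peptides, substitution of
#' serine for proline at a uniformly chosen proline site with probability
#' `f` per observation, q-values placed so the 1% FDR filter retains the
#' intended records (plus decoy-like records above the cutoff), and an
#' optional sibling dropout removing the unmodified form of some
#' mistranslated peptides.
#'
#' @param n_proteins Number of proteins (default 60).
#' @param peptides_per_protein Average peptides per protein (default 8).
#' @param length_range Peptide length range (default 8-25 residues).
#' @param pro_content Per-residue proline probability (default 0.12).
#' @param f Per-observation Pro->Ser substitution probability, in
#'   \[0, 0.15\] (default 0.049, the regime of the integrated mistranslating
#'   strain).
#' @param total_counts Total spectral counts over all peptides (default
#'   20000).
#' @param decoy_frac Fraction of additional decoy-like records with q above
#'   the 1% cutoff (default 0.05).
#' @param sibling_dropout Probability that a mistranslated peptide's
#'   unmodified sibling is removed from the table, in \[0, 1\] (default 0).
#' @param seed Random seed (mandatory; default 1729).
#' @return A `proteome_scenario` list.
#' @export
proteome_scenario <- function(n_proteins = 60,
                              peptides_per_protein = 8,
                              length_range = c(8L, 25L),
                              pro_content = 0.12,
                              f = 0.049,
                              total_counts = 20000,
                              decoy_frac = 0.05,
                              sibling_dropout = 0,
                              seed = 1729) {
  if (is.null(seed)) abort_bad_input("seed is mandatory")
  if (f < 0 || f > 0.15) {
    abort_bad_input("substitution probability f must lie in [0, 0.15]")
  }
  if (sibling_dropout < 0 || sibling_dropout > 1) {
    abort_bad_input("sibling_dropout must lie in [0, 1]")
  }
  structure(
    list(
      n_proteins = n_proteins, peptides_per_protein = peptides_per_protein,
      length_range = length_range, pro_content = pro_content, f = f,
      total_counts = total_counts, decoy_frac = decoy_frac,
      sibling_dropout = sibling_dropout, seed = as.integer(seed)
    ),
    class = "proteome_scenario"
  )
}

#' Simulate a peptide-spectrum-match table
#'
#' @param sc A [proteome_scenario()].
#' @return List with `psms` (raw PSM tibble with columns `peptide`,
#'   `protein`, `mods`, `q`, `count`, parseable by [validate_psm_tbl()]) and
#'   `truth` (planted rate and per-peptide counts).
#' @export
simulate_psms <- function(sc) {
  stopifnot(inherits(sc, "proteome_scenario"))
  withr::with_seed(sc$seed, {
    aa_pool <- setdiff(strsplit("ACDEFGHIKLMNQRSTVWY", "")[[1]], "P")
    n_pep <- sc$n_proteins * sc$peptides_per_protein
    lens <- sample(seq(sc$length_range[1], sc$length_range[2]), n_pep,
      replace = TRUE
    )
    peptide <- vapply(lens, function(L) {
      is_p <- stats::runif(L) < sc$pro_content
      paste(ifelse(is_p, "P", sample(aa_pool, L, replace = TRUE)),
        collapse = ""
      )
    }, character(1))
    peptide <- unique(peptide)
    n_pep <- length(peptide)
    protein <- sprintf("prot%03d", sample(sc$n_proteins, n_pep, replace = TRUE))

    # spread total spectral counts over peptides (at least 1 each)
    ab <- stats::rgamma(n_pep, shape = 1.2)
    counts <- pmax(1L, as.integer(round(sc$total_counts * ab / sum(ab))))

    pro_sites <- stringr::str_locate_all(peptide, "P")
    rows <- purrr::pmap(
      list(peptide, protein, counts, pro_sites),
      function(pep, prot, n, sites) {
        sites <- sites[, 1]
        if (length(sites) == 0) {
          return(tibble::tibble(
            peptide = pep, protein = prot, mods = "", count = n
          ))
        }
        k <- stats::rbinom(1, n, sc$f)
        out <- list()
        if (n - k > 0) {
          out$unmod <- tibble::tibble(
            peptide = pep, protein = prot, mods = "", count = n - k
          )
        }
        if (k > 0) {
          site <- sample(rep(sites, 2), k, replace = TRUE) # uniform site choice
          tab <- table(site)
          out$mis <- tibble::tibble(
            peptide = pep, protein = prot,
            mods = sprintf("%d:-10.0207", as.integer(names(tab))),
            count = as.integer(tab)
          )
        }
        dplyr::bind_rows(out)
      }
    )
    psms <- dplyr::bind_rows(rows)

    # sibling dropout: remove the unmodified form of some mistranslated peptides
    if (sc$sibling_dropout > 0) {
      mis_peps <- unique(psms$peptide[psms$mods != ""])
      dropped <- mis_peps[stats::runif(length(mis_peps)) < sc$sibling_dropout]
      psms <- psms[!(psms$peptide %in% dropped & psms$mods == ""), ]
    }

    # q-values: real records below the 1% cutoff
    psms$q <- stats::runif(nrow(psms), 0, 0.009)

    # decoy-like records above the cutoff, removed by the FDR filter
    n_decoy <- ceiling(sc$decoy_frac * nrow(psms))
    if (n_decoy > 0) {
      decoys <- tibble::tibble(
        peptide = vapply(
          sample(8:20, n_decoy, replace = TRUE),
          function(L) {
            paste(sample(c(aa_pool, "P"), L, replace = TRUE), collapse = "")
          },
          character(1)
        ),
        protein = "decoy",
        mods = "",
        count = 1L,
        q = stats::runif(n_decoy, 0.011, 0.5)
      )
      psms <- dplyr::bind_rows(psms, decoys)
    }
    psms <- psms[sample(nrow(psms)), c("peptide", "protein", "mods", "q", "count")]

    has_pro <- vapply(pro_sites, nrow, integer(1)) > 0
    truth <- list(f = sc$f, n_pro_counts = sum(counts[has_pro]))
    list(psms = tibble::as_tibble(psms), truth = truth, scenario = sc)
  })
}

#' Simulate OD600 growth curves
#'
#' Logistic curves sampled on the plate-reader schedule (every 15 min for
#' 24 h by default) with additive Gaussian OD noise.
#'
#' @param specs Tibble with one row per strain: `strain`, `doubling_time`
#'   (minutes), optional `K` (default 1.4), `N0` (default 0.1), `noise_sd`
#'   (OD units, default 0.01).
#' @param replicates Biological replicates per strain (default 1).
#' @param interval_min Sampling interval in minutes (default 15).
#' @param duration_min Total duration in minutes (default 1440).
#' @param seed Random seed (default 1729).
#' @return List with `od` (tibble `strain`, `replicate`, `time_min`, `od`)
#'   and `truth` (the specs with implied rates `r = ln(2)/doubling_time`).
#' @export
simulate_growth <- function(specs, replicates = 1, interval_min = 15,
                            duration_min = 1440, seed = 1729) {
  assert_cols(specs, c("strain", "doubling_time"), "growth specs")
  if (any(specs$doubling_time <= 0)) {
    abort_bad_input("doubling times must be positive")
  }
  if (!"K" %in% names(specs)) specs$K <- 1.4
  if (!"N0" %in% names(specs)) specs$N0 <- 0.1
  if (!"noise_sd" %in% names(specs)) specs$noise_sd <- 0.01
  specs$r <- log(2) / specs$doubling_time

  withr::with_seed(as.integer(seed), {
    times <- seq(0, duration_min, by = interval_min)
    od <- specs |>
      tidyr::expand_grid(replicate = seq_len(replicates)) |>
      dplyr::rowwise() |>
      dplyr::reframe(
        strain = .data$strain,
        replicate = .data$replicate,
        time_min = times,
        od = pmax(
          1e-4,
          .data$K / (1 + ((.data$K - .data$N0) / .data$N0) *
            exp(-.data$r * times)) +
            stats::rnorm(length(times), 0, .data$noise_sd)
        )
      )
    list(od = tibble::as_tibble(od), truth = specs)
  })
}

#' Simulate a dose-response spot assay
#'
#' Generates replicate spot intensities for strains carrying the four tRNA
#' constructs. The wild-type strain follows the near-linear dose profile of
#' normalized growth (defaults 71%, 55%, 37% of its wild-type-tRNA growth at
#' low, medium and high mistranslation); every other strain's growth is
#' additionally multiplied by its planted interaction factor per level, so
#' its planted relative synthetic effect is `100 x factor`.
#'
#' @param factors Tibble with columns `strain`, `level` (low/medium/high)
#'   and `factor` in (0, 1.5\]; the wild-type strain is added automatically
#'   with factor 1.
#' @param wt_strain Wild-type strain identifier (default `"BY4742"`).
#' @param wt_profile Normalized growth (fractions) of the wild-type strain
#'   at low/medium/high (default `c(0.71, 0.55, 0.37)`).
#' @param n_reps Replicates per strain and construct (default 3).
#' @param base Mean wild-type-construct spot intensity; per-strain baselines
#'   are drawn lognormally around it.
#' @param noise_sdlog Lognormal sd of multiplicative intensity noise
#'   (default 0.05).
#' @param seed Random seed (default 1729).
#' @return List with `spots` (tibble `strain`, `construct`, `replicate`,
#'   `intensity`) and `truth` (planted relative synthetic effect per strain
#'   and level).
#' @export
simulate_spots <- function(factors, wt_strain = "BY4742",
                           wt_profile = c(low = 0.71, medium = 0.55, high = 0.37),
                           n_reps = 3, base = 1000, noise_sdlog = 0.05,
                           seed = 1729) {
  assert_cols(factors, c("strain", "level", "factor"), "interaction factors")
  if (any(factors$factor <= 0 | factors$factor > 1.5)) {
    abort_bad_input("interaction factors must lie in (0, 1.5]")
  }
  if (any(!factors$level %in% dose_levels)) {
    abort_bad_input("levels must be low, medium, high")
  }
  lv <- mistranslation_levels()
  all_factors <- dplyr::bind_rows(
    factors,
    tidyr::expand_grid(strain = wt_strain, level = dose_levels, factor = 1)
  )

  withr::with_seed(as.integer(seed), {
    strains <- unique(all_factors$strain)
    baselines <- tibble::tibble(
      strain = strains,
      base_i = base * exp(stats::rnorm(length(strains), 0, 0.2))
    )
    grid <- tidyr::expand_grid(
      strain = strains,
      construct = lv$construct,
      replicate = seq_len(n_reps)
    ) |>
      dplyr::left_join(lv, by = "construct") |>
      dplyr::left_join(baselines, by = "strain") |>
      dplyr::left_join(all_factors, by = c("strain", "level")) |>
      dplyr::mutate(
        growth = dplyr::case_when(
          .data$level == "reference" ~ 1,
          TRUE ~ unname(wt_profile[.data$level]) * .data$factor
        ),
        intensity = .data$base_i * .data$growth *
          exp(stats::rnorm(dplyr::n(), 0, noise_sdlog))
      )
    spots <- dplyr::select(
      grid, "strain", "construct", "replicate", "intensity"
    )
    truth <- all_factors |>
      dplyr::mutate(rel_pct = 100 * .data$factor) |>
      dplyr::arrange(.data$strain, .data$level)
    list(spots = spots, truth = truth)
  })
}
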