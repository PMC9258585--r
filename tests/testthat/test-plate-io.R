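test_that("plate tables round-trip through TSV with missing values intact", {
  plates <- make_plate(n_rows = 16, n_cols = 24, size = 0)
  plates$size <- seq_len(nrow(plates)) * 1.000000001
  plates$size[c(5, 100)] <- NA
  path <- withr::local_tempfile(fileext = ".tsv")
  write_plate_table(plates, path)
  back <- read_plate_table(path)
  expect_equal(back$size, plates$size, tolerance = 1e-9)
  expect_identical(back$row, plates$row)
  expect_true(all(is.na(back$size[c(5, 100)])))
})

test_that("plate reader enforces format, uniqueness and bounds", {
  plates <- make_plate(n_rows = 32, n_cols = 48)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_plate_table(plates, path)
  grids <- read_plate_table(path)
  dims <- attr(grids, "dims")
  expect_identical(c(dims$n_rows, dims$n_cols), c(32L, 48L))

  dup <- dplyr::bind_rows(plates, plates[1, ])
  expect_error(validate_plate_tbl(dup), "duplicate")

  oob <- plates
  oob$row[1] <- 40L
  expect_error(validate_plate_tbl(oob), "96, 384 or 1536|out-of-range")

  neg <- plates
  neg$size[1] <- -5
  expect_error(validate_plate_tbl(neg), "non-negative")

  partial <- plates[-1, ]
  expect_error(validate_plate_tbl(partial), "96, 384 or 1536")
})

test_that("a missing size is missing, not zero, and plate_matrix reflects it", {
  plates <- make_plate(n_rows = 8, n_cols = 12, size = 100)
  plates$size[3] <- NA
  m <- plate_matrix(validate_plate_tbl(plates))
  expect_identical(dim(m), c(8L, 12L))
  expect_true(is.na(m[plates$row[3], plates$col[3]]))
  expect_false(any(m == 0, na.rm = TRUE))
})

test_that("array keys require exactly one 2x2 quadruplicate block per allele", {
  key <- make_key(n_rows = 8, n_cols = 12, n_alleles = 10)
  ok <- validate_array_key(key)
  expect_identical(sum(!ok$is_border), 40L)

  # 380 alleles x 4 + 16 border positions fill a 1,536 array exactly
  key1536 <- make_key(n_rows = 32, n_cols = 48, n_alleles = 380)
  ok2 <- validate_array_key(key1536)
  expect_identical(nrow(ok2), 1536L)
  expect_identical(sum(!ok2$is_border), 1520L)
  expect_identical(sum(ok2$is_border), 16L)

  # drop one replicate -> 3 positions for an allele
  broken <- key[-which(key$allele == "ts001")[1], ]
  expect_error(validate_array_key(broken), "ts001")

  # right count, wrong geometry (not a contiguous 2x2 block)
  scattered <- key
  i <- which(scattered$allele == "ts001")[1]
  j <- which(is.na(scattered$allele))[1]
  scattered$row[i] <- scattered$row[j]
  scattered$col[i] <- scattered$col[j]
  expect_error(validate_array_key(scattered), "2x2")
})

test_that("array keys round-trip through TSV", {
  key <- validate_array_key(make_key(n_rows = 16, n_cols = 24, n_alleles = 20))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_array_key(key, path)
  back <- read_array_key(path)
  expect_identical(back$allele, key$allele)
  expect_identical(back$is_border, key$is_border)
})

test_that("PSM parsing matches deltas to the catalogue and sites to residues", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "peptide\tprotein\tmods\tq\tcount",
    "APEPTIDEK\tp1\t\t0.001\t10",
    "APKPR\tp1\t3:-10.0207\t0.002\t3", # wrong residue: K at 3
    "APRPK\tp1\t2:-10.0207\t0.002\t3"
  ), path)
  expect_error(read_psm_table(path), "requires 'P'")

  writeLines(c(
    "peptide\tprotein\tmods\tq\tcount",
    "APRPK\tp1\t2:-10.0207\t0.002\t3"
  ), path)
  psms <- read_psm_table(path)
  expect_identical(psms$n_sub, 1L)
  expect_identical(psms$mods[[1]]$name, "pro_to_ser")

  writeLines(c(
    "peptide\tprotein\tmods\tq\tcount",
    "APRPK\tp1\t2:-3.99\t0.002\t3"
  ), path)
  expect_error(read_psm_table(path), "no catalogued modification")
})

test_that("more than two of one variable modification rejects the record", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "peptide\tprotein\tmods\tq\tcount",
    "PAPAPAK\tp1\t1:-10.0207;3:-10.0207;5:-10.0207\t0.001\t2",
    "PAPAPAK\tp1\t1:-10.0207;3:-10.0207\t0.001\t2",
    "PAPAPAK\tp1\t\t0.001\t5"
  ), path)
  expect_warning(psms <- read_psm_table(path), "rejected")
  expect_identical(nrow(psms), 2L)
  rejected <- attr(psms, "rejected")
  expect_identical(nrow(rejected), 1L)
  # no silent drops: accepted + rejected = input rows
  expect_identical(nrow(psms) + nrow(rejected), 3L)
  expect_match(rejected$reason, "more than 2")
})

test_that("PSM tables round-trip through TSV", {
  tab <- dplyr::bind_rows(
    psm_row("APKPR", 7, site = 4),
    psm_row("APKPR", 11),
    psm_row("KLMNR", 2)
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_psm_table(tab, path)
  back <- read_psm_table(path)
  expect_identical(back$count, tab$count)
  expect_identical(back$n_sub, tab$n_sub)
  expect_equal(back$q, tab$q, tolerance = 1e-9)
})

test_that("OD series validation needs >= 10 increasing time points", {
  od <- tibble::tibble(
    strain = "s", replicate = 1L,
    time_min = seq(0, 135, by = 15), od = seq(0.1, 1, length.out = 10)
  )
  expect_silent(validate_od_tbl(od))
  expect_error(validate_od_tbl(od[1:9, ]), "10 time points")
  bad <- od
  bad$time_min[5] <- bad$time_min[4]
  expect_error(validate_od_tbl(bad), "non-increasing")
  neg <- od
  neg$od[2] <- 0
  expect_error(validate_od_tbl(neg), "positive")
})

test_that("spot and OD tables round-trip", {
  spots <- tidyr::expand_grid(
    strain = c("BY4742", "act1-4"),
    construct = mistranslation_levels()$construct,
    replicate = 1:3
  ) |>
    dplyr::mutate(intensity = seq_len(dplyr::n()) * 10.5)
  sp <- withr::local_tempfile(fileext = ".tsv")
  write_spot_table(spots, sp)
  expect_equal(read_spot_table(sp)$intensity, spots$intensity, tolerance = 1e-9)

  od <- tibble::tibble(
    strain = "s", replicate = 1L,
    time_min = seq(0, 1440, by = 15),
    od = logistic_series()$od
  )
  op <- withr::local_tempfile(fileext = ".csv")
  write_od_table(od, op)
  expect_equal(read_od_table(op)$od, od$od, tolerance = 1e-9)
})
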