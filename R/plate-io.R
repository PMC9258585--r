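#' Read a colony-size plate table
#'
#' Reads a tab-separated table of colony sizes for one or more plates in a
#' standard rectangular pinning format (96, 384 or 1,536 positions). Each row
#' gives one array position; missing colonies (contamination, pinning failure)
#' are encoded as an empty `size` field or the literal `NA` and come back as
#' first-class `NA` values, never as zeroes.
#'
#' @param path Path to a TSV file with header columns `plate`, `row`, `col`,
#'   `size`. Coordinates are 1-based, row-major (bench convention).
#' @return A tibble with columns `plate` (character), `row`, `col` (integer,
#'   1-based), `size` (double, `NA` = missing colony), validated so that every
#'   plate is a complete 8x12, 16x24 or 32x48 grid with no duplicate
#'   positions. Plate dimensions are recorded in the `dims` attribute.
#' @seealso [write_plate_table()], [plate_matrix()], [normalize_plates()]
#' @export
read_plate_table <- function(path) {
  raw <- readr::read_tsv(
    path,
    col_types = readr::cols(
      plate = readr::col_character(),
      row = readr::col_integer(),
      col = readr::col_integer(),
      size = readr::col_double()
    ),
    na = c("", "NA"),
    progress = FALSE
  )
  assert_cols(raw, c("plate", "row", "col", "size"), "plate table")
  validate_plate_tbl(raw)
}

#' Validate a long plate table
#'
#' Enforces the colony-array invariants on an in-memory plate table: complete
#' grid in a supported format, 1-based in-bounds coordinates, unique
#' positions, non-negative sizes. Called by [read_plate_table()] and usable
#' directly on programmatically built tables.
#'
#' @param plates Tibble with columns `plate`, `row`, `col`, `size`.
#' @return The validated tibble (invisibly classed with a `dims` attribute
#'   giving rows/cols per plate).
#' @export
validate_plate_tbl <- function(plates) {
  assert_cols(plates, c("plate", "row", "col", "size"), "plate table")
  plates <- dplyr::mutate(
    plates,
    plate = as.character(.data$plate),
    row = as.integer(.data$row),
    col = as.integer(.data$col),
    size = as.double(.data$size)
  )
  if (any(is.na(plates$plate) | is.na(plates$row) | is.na(plates$col))) {
    abort_bad_input("plate table has missing plate/row/col identifiers")
  }
  assert_nonneg(plates$size, "colony size")

  dup <- plates |>
    dplyr::count(.data$plate, .data$row, .data$col) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort_bad_input(
      "duplicate plate positions: ",
      paste0(dup$plate, "[", dup$row, ",", dup$col, "]", collapse = "; ")
    )
  }

  fmts <- plate_formats()
  dims <- plates |>
    dplyr::group_by(.data$plate) |>
    dplyr::summarise(n = dplyr::n(), .groups = "drop") |>
    dplyr::left_join(fmts, by = "n")
  if (any(is.na(dims$n_rows))) {
    bad <- dims$plate[is.na(dims$n_rows)]
    abort_bad_input(
      "plate(s) ", paste(bad, collapse = ", "),
      " do not contain 96, 384 or 1536 positions"
    )
  }
  chk <- plates |>
    dplyr::left_join(dplyr::select(dims, "plate", "n_rows", "n_cols"),
      by = "plate"
    )
  bad <- chk$row < 1L | chk$row > chk$n_rows | chk$col < 1L | chk$col > chk$n_cols
  if (any(bad)) {
    i <- which(bad)[1]
    abort_bad_input(
      "out-of-range position at line ", i, ": ",
      chk$plate[i], "[", chk$row[i], ",", chk$col[i], "]"
    )
  }
  # Completeness: n rows with unique in-bounds coordinates imply a full grid.
  attr(plates, "dims") <- dplyr::select(dims, "plate", "n_rows", "n_cols")
  plates
}

#' Extract one plate as a size matrix
#'
#' @param plates A validated plate table (see [read_plate_table()]).
#' @param plate_id Plate identifier; defaults to the first plate.
#' @return A numeric `n_rows` x `n_cols` matrix of colony sizes with `NA` for
#'   missing colonies.
#' @export
plate_matrix <- function(plates, plate_id = NULL) {
  plate_id <- plate_id %||% plates$plate[1]
  one <- dplyr::filter(plates, .data$plate == plate_id)
  if (nrow(one) == 0) abort_bad_input("no such plate: ", plate_id)
  nr <- max(one$row)
  nc <- max(one$col)
  m <- matrix(NA_real_, nr, nc)
  m[cbind(one$row, one$col)] <- one$size
  m
}

#' Write a plate table
#'
#' @param plates Plate tibble as returned by [read_plate_table()].
#' @param path Output TSV path. Missing sizes are written as `NA`.
#' @return `path`, invisibly.
#' @export
write_plate_table <- function(plates, path) {
  readr::write_tsv(plates[c("plate", "row", "col", "size")], path, na = "NA")
  invisible(path)
}

#' Read an array-key file
#'
#' The array key maps each position of a colony array to the temperature
#' sensitive allele pinned there. In the 384-to-1,536 condensation each allele
#' occupies one 2x2 block of four positions (technical quadruplicate); border
#' or blank positions carry an empty allele field.
#'
#' @param path TSV with header columns `plate`, `row`, `col`, `allele`,
#'   `gene`, `block`. Empty `allele` (or the literal `border`/`blank`) marks
#'   an unmapped border/blank position.
#' @return Tibble with columns `plate`, `row`, `col`, `allele`, `gene`,
#'   `block` and logical `is_border`; verified so each allele occupies exactly
#'   one 2x2 block of 4 positions per plate.
#' @export
read_array_key <- function(path) {
  key <- readr::read_tsv(
    path,
    col_types = readr::cols(
      plate = readr::col_character(),
      row = readr::col_integer(),
      col = readr::col_integer(),
      allele = readr::col_character(),
      gene = readr::col_character(),
      block = readr::col_character()
    ),
    na = c("", "NA"),
    progress = FALSE
  )
  validate_array_key(key)
}

#' Validate an array key
#'
#' @param key Tibble with columns `plate`, `row`, `col`, `allele`, `gene`,
#'   `block` (`allele` `NA`/`"border"`/`"blank"` for unmapped positions).
#' @return The key with an `is_border` logical column, after verifying the
#'   quadruplicate 2x2 block structure of every mapped allele.
#' @export
validate_array_key <- function(key) {
  assert_cols(key, c("plate", "row", "col", "allele", "gene", "block"),
    "array key"
  )
  key <- dplyr::mutate(
    key,
    is_border = is.na(.data$allele) |
      tolower(.data$allele) %in% c("border", "blank")
  )
  mapped <- dplyr::filter(key, !.data$is_border)
  bad <- mapped |>
    dplyr::group_by(.data$plate, .data$allele) |>
    dplyr::summarise(
      n = dplyr::n(),
      ok_block = {
        r <- sort(unique(.data$row))
        cc <- sort(unique(.data$col))
        dplyr::n() == 4L && length(r) == 2L && length(cc) == 2L &&
          r[2] - r[1] == 1L && cc[2] - cc[1] == 1L
      },
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n != 4L | !.data$ok_block)
  if (nrow(bad) > 0) {
    abort_bad_input(
      "allele(s) without a 2x2 quadruplicate block: ",
      paste0(bad$allele, " (", bad$n, " positions on plate ", bad$plate, ")",
        collapse = "; "
      )
    )
  }
  key
}

#' Write an array key
#' @param key Array-key tibble (see [read_array_key()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_array_key <- function(key, path) {
  readr::write_tsv(
    key[c("plate", "row", "col", "allele", "gene", "block")],
    path,
    na = ""
  )
  invisible(path)
}

#' Default variable/constant modification catalogue
#'
#' Monoisotopic mass shifts recognised when parsing peptide-spectrum-match
#' tables: serine-for-proline substitution (-10.0207 Da), methionine
#' oxidation (+15.9949 Da) and cysteine carbamidomethylation (+57.0215 Da).
#' Additional substitutions can be appended for other tRNA variants.
#'
#' @return Tibble with columns `name`, `delta` (Da), `residue` (one-letter
#'   amino acid the modification must sit on) and `variable`.
#' @export
mod_catalog <- function() {
  tibble::tibble(
    name = c("pro_to_ser", "met_ox", "cys_cam"),
    delta = c(-10.0207, 15.9949, 57.0215),
    residue = c("P", "M", "C"),
    variable = c(TRUE, TRUE, FALSE)
  )
}

parse_mods <- function(mods) {
  # "3:-10.0207;7:15.9949" -> tibble(position, delta); "" / NA -> empty
  if (is.na(mods) || mods == "") {
    return(tibble::tibble(position = integer(), delta = double()))
  }
  parts <- strsplit(mods, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  tibble::tibble(
    position = as.integer(vapply(kv, `[`, "", 1)),
    delta = as.double(vapply(kv, `[`, "", 2))
  )
}

#' Read a peptide-spectrum-match table
#'
#' Parses a post-search PSM table (one row per distinct peptide form) and
#' matches each reported mass shift against a modification catalogue. Records
#' violating the search constraint of at most two occurrences of one variable
#' modification per peptide are rejected with a warning and reported in the
#' `rejected` attribute, so that input rows = accepted + rejected.
#'
#' @param path TSV with header columns `peptide` (reference amino-acid
#'   sequence), `protein`, `mods` (semicolon-separated `position:delta` pairs,
#'   empty for the unmodified form), `q` (PSM-level q-value) and `count`
#'   (spectral count).
#' @param catalog Modification catalogue, see [mod_catalog()].
#' @param tol Matching tolerance in Da for reported deltas (default 0.01).
#' @return Tibble with columns `peptide`, `protein`, `q`, `count`, a `mods`
#'   list-column of per-site tibbles (`position`, `delta`, `name`), `n_sub`
#'   (number of substitution sites, catalogue entry `pro_to_ser` or whichever
#'   substitution the catalogue marks) and `is_mistranslated`. Rejected rows
#'   (with reasons) are in `attr(, "rejected")`.
#' @export
read_psm_table <- function(path, catalog = mod_catalog(), tol = 0.01) {
  raw <- readr::read_tsv(
    path,
    col_types = readr::cols(
      peptide = readr::col_character(),
      protein = readr::col_character(),
      mods = readr::col_character(),
      q = readr::col_double(),
      count = readr::col_integer()
    ),
    na = c("NA"),
    progress = FALSE
  )
  raw$mods[is.na(raw$mods)] <- ""
  validate_psm_tbl(raw, catalog = catalog, tol = tol)
}

#' Validate and annotate a PSM table
#'
#' @inheritParams read_psm_table
#' @param psms Tibble with columns `peptide`, `protein`, `mods` (string or
#'   list-column), `q`, `count`.
#' @return Annotated tibble; see [read_psm_table()].
#' @export
validate_psm_tbl <- function(psms, catalog = mod_catalog(), tol = 0.01) {
  assert_cols(psms, c("peptide", "protein", "mods", "q", "count"), "PSM table")
  assert_prob(psms$q, "PSM q-value")
  if (any(is.na(psms$count) | psms$count < 1)) {
    abort_bad_input("spectral counts must be positive integers")
  }

  mods_parsed <- if (is.list(psms$mods)) psms$mods else lapply(psms$mods, parse_mods)

  annotate_one <- function(i) {
    pep <- psms$peptide[i]
    m <- mods_parsed[[i]]
    if (nrow(m) == 0) {
      return(list(
        mods = tibble::tibble(
          position = integer(), delta = double(), name = character()
        ),
        n_sub = 0L, reject = NA_character_
      ))
    }
    if (any(m$position < 1L | m$position > nchar(pep))) {
      abort_bad_input(
        "PSM row ", i, " (", pep, "): modification position out of range"
      )
    }
    idx <- vapply(
      m$delta,
      function(d) {
        j <- which(abs(catalog$delta - d) <= tol)
        if (length(j) == 0) {
          abort_bad_input(
            "PSM row ", i, " (", pep, "): mass shift ", d,
            " Da matches no catalogued modification within ", tol, " Da"
          )
        }
        j[which.min(abs(catalog$delta[j] - d))]
      },
      integer(1)
    )
    name <- catalog$name[idx]
    residue <- catalog$residue[idx]
    at <- substring(pep, m$position, m$position)
    if (any(at != residue)) {
      k <- which(at != residue)[1]
      abort_bad_input(
        "PSM row ", i, " (", pep, "): ", name[k], " (", m$delta[k],
        " Da) placed on '", at[k], "' at position ", m$position[k],
        " but requires '", residue[k], "'"
      )
    }
    over <- table(name[catalog$variable[idx]])
    reject <- NA_character_
    if (any(over > 2)) {
      reject <- paste0(
        "more than 2 occurrences of variable modification ",
        paste(names(over)[over > 2], collapse = ", ")
      )
    }
    list(
      mods = tibble::tibble(position = m$position, delta = m$delta, name = name),
      n_sub = sum(name == "pro_to_ser"),
      reject = reject
    )
  }

  ann <- lapply(seq_len(nrow(psms)), annotate_one)
  out <- psms
  out$mods <- lapply(ann, `[[`, "mods")
  out$n_sub <- vapply(ann, `[[`, integer(1), "n_sub")
  out$is_mistranslated <- out$n_sub > 0L
  reject <- vapply(ann, `[[`, character(1), "reject")

  rejected <- tibble::tibble(
    line = which(!is.na(reject)),
    peptide = psms$peptide[!is.na(reject)],
    reason = reject[!is.na(reject)]
  )
  if (nrow(rejected) > 0) {
    rlang::warn(paste0(
      nrow(rejected), " PSM record(s) rejected: ",
      paste(unique(rejected$reason), collapse = "; ")
    ))
    out <- out[is.na(reject), ]
  }
  out <- tibble::as_tibble(out)
  attr(out, "rejected") <- rejected
  out
}

#' Write a PSM table
#' @param psms Annotated PSM tibble (list `mods` column) or raw table with a
#'   character `mods` column.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_psm_table <- function(psms, path) {
  mods_chr <- if (is.list(psms$mods)) {
    vapply(
      psms$mods,
      function(m) paste(sprintf("%d:%.4f", m$position, m$delta), collapse = ";"),
      character(1)
    )
  } else {
    psms$mods
  }
  out <- tibble::tibble(
    peptide = psms$peptide, protein = psms$protein,
    mods = mods_chr, q = psms$q, count = psms$count
  )
  readr::write_tsv(out, path, na = "")
  invisible(path)
}

#' Read a spot-intensity table
#'
#' @param path TSV with header columns `strain`, `construct`, `replicate`,
#'   `intensity` (net, background-subtracted spot intensity).
#' @return Validated tibble (non-negative intensities).
#' @export
read_spot_table <- function(path) {
  spots <- readr::read_tsv(
    path,
    col_types = readr::cols(
      strain = readr::col_character(),
      construct = readr::col_character(),
      replicate = readr::col_integer(),
      intensity = readr::col_double()
    ),
    progress = FALSE
  )
  assert_cols(spots, c("strain", "construct", "replicate", "intensity"),
    "spot table"
  )
  assert_nonneg(spots$intensity, "spot intensity")
  spots
}

#' Write a spot-intensity table
#' @param spots Spot tibble (see [read_spot_table()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_spot_table <- function(spots, path) {
  readr::write_tsv(
    spots[c("strain", "construct", "replicate", "intensity")], path
  )
  invisible(path)
}

#' Read an OD600 time-series table
#'
#' @param path CSV with header columns `strain`, optional `replicate`,
#'   `time_min` (minutes) and `od`; one row per reading.
#' @return Tibble validated so every (strain, replicate) series has strictly
#'   increasing times, positive OD readings, and at least 10 time points.
#' @export
read_od_table <- function(path) {
  od <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  assert_cols(od, c("strain", "time_min", "od"), "OD table")
  if (!"replicate" %in% names(od)) od$replicate <- 1L
  od <- dplyr::mutate(od,
    strain = as.character(.data$strain),
    replicate = as.integer(.data$replicate),
    time_min = as.double(.data$time_min),
    od = as.double(.data$od)
  )
  validate_od_tbl(od)
}

#' Validate an OD table
#' @param od Tibble with columns `strain`, `replicate`, `time_min`, `od`.
#' @return The validated tibble.
#' @export
validate_od_tbl <- function(od) {
  assert_cols(od, c("strain", "replicate", "time_min", "od"), "OD table")
  if (any(is.na(od$od) | od$od <= 0)) {
    abort_bad_input("OD readings must be positive")
  }
  chk <- od |>
    dplyr::group_by(.data$strain, .data$replicate) |>
    dplyr::summarise(
      n = dplyr::n(),
      increasing = all(diff(.data$time_min) > 0),
      .groups = "drop"
    )
  if (any(chk$n < 10)) {
    abort_bad_input(
      "OD series with < 10 time points: ",
      paste(chk$strain[chk$n < 10], collapse = ", ")
    )
  }
  if (any(!chk$increasing)) {
    abort_bad_input(
      "non-increasing time values in OD series: ",
      paste(chk$strain[!chk$increasing], collapse = ", ")
    )
  }
  od
}

#' Write an OD table
#' @param od OD tibble (see [read_od_table()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_od_table <- function(od, path) {
  readr::write_csv(od[c("strain", "replicate", "time_min", "od")], path)
  invisible(path)
}
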