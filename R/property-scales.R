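# Per-amino-acid physicochemical property scales: reading, validation,
# unit scaling. A collection is a tibble with one row per scale and one
# column per canonical residue, in the canonical AAindex residue order.

# Canonical AAindex residue order: first I-line row A..I, second row L..V.
AA_ORDER <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
)

#' Canonical amino-acid alphabet
#'
#' The 20 canonical amino-acid one-letter codes in the order used by the
#' AAindex database (the order of the two value rows of an AAindex1 record:
#' A, R, N, D, C, Q, E, G, H, I, L, K, M, F, P, S, T, W, Y, V). All property
#' collections in this package store residue columns in this order.
#'
#' @return A character vector of length 20.
#' @export
#' @examples
#' aa_residues()
aa_residues <- function() AA_ORDER

#' Construct a property-scale collection
#'
#' A property collection is a tibble with columns `scale_id`, `description`,
#' `origin` (`"aaindex"` or `"literature"`), `provenance` (opaque text kept
#' from the source record) and one numeric column per canonical residue
#' (see [aa_residues()]). `NA` marks a residue with no value on that scale.
#'
#' @param x A data frame with at least `scale_id` and the 20 residue columns.
#'   `description`, `origin` and `provenance` are filled with defaults when
#'   absent.
#' @param unit_scaled Logical; whether the residue values are already on the
#'   unit interval (see [scale_unit()]). Stored as an attribute and checked
#'   by the encoder.
#' @return A `prop_scales` tibble.
#' @export
prop_scales <- function(x, unit_scaled = FALSE) {
  x <- tibble::as_tibble(x)
  if (!"scale_id" %in% names(x)) {
    stop("a property collection needs a `scale_id` column", call. = FALSE)
  }
  if (!"description" %in% names(x)) x$description <- ""
  if (!"origin" %in% names(x)) x$origin <- "aaindex"
  if (!"provenance" %in% names(x)) x$provenance <- ""
  missing_res <- setdiff(AA_ORDER, names(x))
  if (length(missing_res) > 0) {
    stop(
      "missing residue columns: ", paste(missing_res, collapse = ", "),
      call. = FALSE
    )
  }
  x <- x[, c("scale_id", "description", "origin", "provenance", AA_ORDER)]
  validate_prop_scales(x)
  structure(
    x,
    unit_scaled = isTRUE(unit_scaled),
    class = c("prop_scales", class(tibble::tibble()))
  )
}

validate_prop_scales <- function(x) {
  if (any(!nzchar(x$scale_id) | is.na(x$scale_id))) {
    stop("scale_id must be non-empty", call. = FALSE)
  }
  dup <- unique(x$scale_id[duplicated(x$scale_id)])
  if (length(dup) > 0) {
    stop(
      "duplicate scale_id: ", paste(dup, collapse = ", "),
      call. = FALSE
    )
  }
  vals <- as.matrix(x[, AA_ORDER])
  if (!is.numeric(vals)) {
    stop("residue columns must be numeric", call. = FALSE)
  }
  all_missing <- rowSums(!is.na(vals)) == 0
  if (any(all_missing)) {
    stop(
      "scale(s) with no non-missing residue value: ",
      paste(x$scale_id[all_missing], collapse = ", "),
      call. = FALSE
    )
  }
  bad_origin <- setdiff(unique(x$origin), c("aaindex", "literature"))
  if (length(bad_origin) > 0) {
    stop("origin must be 'aaindex' or 'literature'", call. = FALSE)
  }
  invisible(x)
}

is_unit_scaled <- function(scales) isTRUE(attr(scales, "unit_scaled"))

#' Read property scales from an AAindex1 flat file
#'
#' Parses the standard AAindex1 record layout: an `H` line with the
#' accession, `D` description lines, an `I` section whose two following
#' lines carry ten values each in the canonical residue order
#' (A R N D C Q E G H I / L K M F P S T W Y V), records terminated by
#' `//`. The token `NA` marks a residue with no value on that scale.
#' All sections other than H, D and I are retained verbatim in the
#' `provenance` column.
#'
#' @param path Path to an AAindex1-format file.
#' @return A `prop_scales` tibble with `origin = "aaindex"`.
#' @export
read_aaindex <- function(path) {
  lines <- readLines(path, warn = FALSE)
  recs <- split_aaindex_records(lines)
  if (length(recs) == 0) {
    stop("no AAindex1 records found in ", path, call. = FALSE)
  }
  rows <- purrr::map(recs, parse_aaindex_record)
  prop_scales(dplyr::bind_rows(rows))
}

split_aaindex_records <- function(lines) {
  lines <- lines[!grepl("^\\s*$", lines) | TRUE] # keep blanks inside records
  ends <- grep("^//\\s*$", lines)
  if (length(ends) == 0) return(list())
  starts <- c(1L, utils::head(ends, -1) + 1L)
  recs <- purrr::map2(starts, ends, function(s, e) lines[s:(e - 1L)])
  recs <- purrr::map(recs, function(r) r[!grepl("^\\s*$", r)])
  recs[lengths(recs) > 0]
}

parse_aaindex_record <- function(rec) {
  keyed <- grepl("^[A-Z*] ", rec) | grepl("^[A-Z*]$", rec)
  key <- ifelse(keyed, substr(rec, 1, 1), NA_character_)
  # continuation lines (leading whitespace) belong to the last keyed section
  key <- vapply(seq_along(key), function(i) {
    if (!is.na(key[i])) key[i] else if (i == 1) "?" else NA_character_
  }, character(1))
  for (i in seq_along(key)) if (is.na(key[i])) key[i] <- key[i - 1]

  h_lines <- rec[key == "H"]
  if (length(h_lines) == 0) {
    stop("AAindex1 record without an H (accession) line", call. = FALSE)
  }
  accession <- stringr::str_trim(sub("^H\\s*", "", h_lines[1]))
  if (!nzchar(accession)) {
    stop("AAindex1 record with an empty accession", call. = FALSE)
  }

  d_lines <- rec[key == "D"]
  description <- stringr::str_trim(
    paste(sub("^D\\s*", "", d_lines), collapse = " ")
  )

  i_at <- which(key == "I" & keyed)
  if (length(i_at) != 1) {
    stop(
      "record ", accession, ": expected exactly one I section",
      call. = FALSE
    )
  }
  value_lines <- rec[key == "I"][-1] # drop the I header line itself
  tokens <- unlist(stringr::str_split(stringr::str_trim(value_lines), "\\s+"))
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) != 20) {
    stop(
      "record ", accession, ": expected 20 value tokens, got ",
      length(tokens), call. = FALSE
    )
  }
  values <- suppressWarnings(as.numeric(tokens))
  bad <- is.na(values) & tokens != "NA"
  if (any(bad)) {
    stop(
      "record ", accession, ": non-numeric value token(s): ",
      paste(unique(tokens[bad]), collapse = ", "), call. = FALSE
    )
  }

  other <- rec[!key %in% c("H", "D", "I")]
  row <- tibble::tibble(
    scale_id = accession,
    description = description,
    origin = "aaindex",
    provenance = paste(other, collapse = "\n")
  )
  row[AA_ORDER] <- as.list(values)
  row
}

#' Write a property collection as an AAindex1 flat file
#'
#' Inverse of [read_aaindex()]: emits one record per scale with H, D,
#' retained provenance lines, the I section (two rows of ten values,
#' `NA` for missing residues) and the `//` terminator. `read_aaindex()`
#' on the output reproduces the collection.
#'
#' @param scales A `prop_scales` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_aaindex <- function(scales, path) {
  vals <- as.matrix(scales[, AA_ORDER])
  fmt <- function(v) {
    ifelse(is.na(v), "NA", formatC(v, format = "g", digits = 15))
  }
  out <- purrr::map(seq_len(nrow(scales)), function(i) {
    c(
      paste0("H ", scales$scale_id[i]),
      if (nzchar(scales$description[i])) paste0("D ", scales$description[i]),
      if (nzchar(scales$provenance[i])) {
        strsplit(scales$provenance[i], "\n", fixed = TRUE)[[1]]
      },
      "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
      paste0("   ", paste(fmt(vals[i, 1:10]), collapse = "  ")),
      paste0("   ", paste(fmt(vals[i, 11:20]), collapse = "  ")),
      "//"
    )
  })
  writeLines(unlist(out), path)
  invisible(path)
}

#' Read literature-derived property scales from a delimited table
#'
#' Reads a TSV or CSV table with columns `id`, `description`, then the 20
#' residue columns in canonical AAindex order (see [aa_residues()]). Cells
#' equal to `NA` mark missing residue values. Used for per-residue scales
#' collected from publications rather than from the AAindex distribution.
#'
#' @param path Path to the table; the delimiter is taken from the file
#'   extension (`.csv` for comma, anything else tab).
#' @return A `prop_scales` tibble with `origin = "literature"`.
#' @export
read_literature_scales <- function(path) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- readr::read_delim(
    path,
    delim = delim, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  if (!"id" %in% names(tab)) {
    stop("literature scale table needs an `id` column", call. = FALSE)
  }
  res_cols <- setdiff(names(tab), c("id", "description"))
  unknown <- setdiff(res_cols, AA_ORDER)
  if (length(unknown) > 0) {
    stop(
      "unknown residue column(s): ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  missing_res <- setdiff(AA_ORDER, res_cols)
  if (length(missing_res) > 0) {
    stop(
      "missing residue column(s): ", paste(missing_res, collapse = ", "),
      call. = FALSE
    )
  }
  num <- purrr::map(AA_ORDER, function(a) {
    v <- suppressWarnings(as.numeric(tab[[a]]))
    bad <- is.na(v) & !(is.na(tab[[a]]) | tab[[a]] == "NA")
    if (any(bad)) {
      stop(
        "non-numeric cell for residue ", a, " in scale(s) ",
        paste(tab$id[bad], collapse = ", "), call. = FALSE
      )
    }
    v
  })
  names(num) <- AA_ORDER
  out <- tibble::tibble(
    scale_id = tab$id,
    description = if ("description" %in% names(tab)) {
      dplyr::coalesce(tab$description, "")
    } else "",
    origin = "literature"
  )
  out[AA_ORDER] <- num
  prop_scales(out)
}

#' Combine property collections
#'
#' Row-binds collections, enforcing unique scale ids across the result
#' (e.g. merging an AAindex collection with literature scales).
#'
#' @param ... `prop_scales` tibbles.
#' @return A `prop_scales` tibble; unit-scaled only if every input was.
#' @export
bind_scales <- function(...) {
  parts <- list(...)
  scaled <- all(vapply(parts, is_unit_scaled, logical(1)))
  prop_scales(dplyr::bind_rows(parts), unit_scaled = scaled)
}

#' Min-max scale each property to the unit interval
#'
#' Linearly maps each scale's non-missing residue values so that the
#' minimum over the 20 residues becomes 0 and the maximum becomes 1;
#' missing values are preserved. A constant scale (no contrast between
#' residues) maps to 0.5 everywhere, keeping its values in range without
#' fabricating contrast. Scaling each property over its own 20 residue
#' values (rather than over any peptide dataset) makes peptide encodings
#' independent of training-set composition.
#'
#' @param scales A `prop_scales` tibble.
#' @return A `prop_scales` tibble flagged as unit-scaled.
#' @export
scale_unit <- function(scales) {
  vals <- as.matrix(scales[, AA_ORDER])
  lo <- apply(vals, 1, min, na.rm = TRUE)
  hi <- apply(vals, 1, max, na.rm = TRUE)
  rng <- hi - lo
  const <- rng == 0
  scaled <- (vals - lo) / ifelse(const, 1, rng)
  scaled[const, ] <- 0.5
  scaled[is.na(vals)] <- NA_real_
  out <- scales
  out[AA_ORDER] <- as.data.frame(scaled)
  prop_scales(out, unit_scaled = TRUE)
}

#' @export
print.prop_scales <- function(x, ...) {
  cat(
    "# Property collection: ", nrow(x), " scale(s)",
    if (is_unit_scaled(x)) " (unit-scaled)", "\n",
    sep = ""
  )
  NextMethod()
}
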