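# Peptide encoding: each peptide becomes one feature per property scale,
# the arithmetic mean of the scale's unit values over the peptide's
# residues. Residues missing on a scale are excluded from that scale's
# mean, so the denominator varies per (peptide, scale).

# keep the unit_scaled flag through row subsetting
scales_subset <- function(scales, ids) {
  miss <- setdiff(ids, scales$scale_id)
  if (length(miss) > 0) {
    stop(
      "scale(s) not in collection: ", paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  prop_scales(
    scales[match(ids, scales$scale_id), , drop = FALSE],
    unit_scaled = is_unit_scaled(scales)
  )
}

residue_counts <- function(sequences) {
  # n x 20 matrix of canonical-residue counts; non-canonical letters
  # (B/J/O/U/X/Z) contribute to no column and so drop out of every mean
  m <- vapply(
    AA_ORDER,
    function(a) stringr::str_count(sequences, stringr::fixed(a)),
    numeric(length(sequences))
  )
  matrix(m, nrow = length(sequences), ncol = 20,
         dimnames = list(NULL, AA_ORDER))
}

#' Encode peptides as averaged property features
#'
#' Encodes each peptide as one feature per property scale: the arithmetic
#' mean of the scale's unit-scaled residue values over the peptide's
#' residues. A residue with a missing value on a scale is excluded from
#' that scale's mean (the denominator shrinks); if every residue of a
#' peptide is missing on a scale, the cell falls back to 0.5 (the midpoint
#' of the unit range) with a warning. The averaging rule depends only on
#' residue composition, not order, and every feature lies in \[0, 1\]
#' because unit-scaled values are averaged.
#'
#' @param peptides A data frame with a `sequence` column (other columns,
#'   e.g. `label` and `protein_group`, are carried through), or a character
#'   vector of sequences.
#' @param scales A unit-scaled `prop_scales` collection (see
#'   [scale_unit()]).
#' @return A tibble: the input columns followed by one numeric column per
#'   scale, with attribute `"features"` holding the scale ids.
#' @export
#' @examples
#' sc <- scale_unit(sim_scales(fixture_spec(n_scales = 5, seed = 1)))
#' encode_peptides(c("ACDK", "WYV"), sc)
encode_peptides <- function(peptides, scales) {
  if (is.character(peptides)) {
    peptides <- tibble::tibble(sequence = peptides)
  }
  peptides <- tibble::as_tibble(peptides)
  if (!"sequence" %in% names(peptides)) {
    stop("`peptides` needs a `sequence` column", call. = FALSE)
  }
  if (!inherits(scales, "prop_scales")) scales <- prop_scales(scales)
  if (!is_unit_scaled(scales)) {
    stop(
      "`scales` must be unit-scaled; call scale_unit() first",
      call. = FALSE
    )
  }
  seqs <- toupper(peptides$sequence)
  if (any(is.na(seqs) | !nzchar(seqs))) {
    stop(
      "empty sequence at row ",
      paste(which(is.na(seqs) | !nzchar(seqs)), collapse = ", "),
      call. = FALSE
    )
  }
  bad <- !grepl("^[A-Z]+$", seqs)
  if (any(bad)) {
    stop(
      "invalid residue letters at row ", paste(which(bad), collapse = ", "),
      call. = FALSE
    )
  }

  counts <- residue_counts(seqs)
  vals <- t(as.matrix(scales[, AA_ORDER]))      # 20 x S
  observed <- !is.na(vals)
  vals0 <- ifelse(observed, vals, 0)
  numer <- counts %*% vals0                     # n x S
  denom <- counts %*% observed
  feats <- numer / denom
  if (any(denom == 0)) {
    warning(
      sum(denom == 0), " peptide/scale cell(s) had no residue with an ",
      "observed value; set to 0.5",
      call. = FALSE
    )
    feats[denom == 0] <- 0.5
  }
  colnames(feats) <- scales$scale_id

  out <- dplyr::bind_cols(peptides, tibble::as_tibble(feats))
  attr(out, "features") <- scales$scale_id
  out
}

#' Encode a single peptide
#'
#' Convenience wrapper around [encode_peptides()] for one sequence.
#'
#' @inheritParams encode_peptides
#' @param sequence A single peptide sequence.
#' @return A named numeric vector, one value per scale.
#' @export
encode_peptide <- function(sequence, scales) {
  stopifnot(length(sequence) == 1)
  enc <- encode_peptides(tibble::tibble(sequence = sequence), scales)
  v <- as.numeric(enc[1, attr(enc, "features")])
  names(v) <- attr(enc, "features")
  v
}

#' Feature columns of an encoded dataset
#'
#' @param x A tibble returned by [encode_peptides()].
#' @return Character vector of feature (scale id) column names.
#' @export
feature_names <- function(x) {
  f <- attr(x, "features")
  if (is.null(f)) {
    stop("`x` has no feature attribute; was it made by encode_peptides()?",
         call. = FALSE)
  }
  f
}

POSITIVE_TOKENS <- c("1", "pos", "positive", "agg", "aggregating",
                     "aggregation", "yes", "true")
NEGATIVE_TOKENS <- c("0", "neg", "negative", "non", "non_aggregating",
                     "nonaggregating", "no", "false")

normalize_labels <- function(label) {
  tok <- tolower(stringr::str_trim(as.character(label)))
  out <- dplyr::case_when(
    tok %in% POSITIVE_TOKENS ~ "aggregating",
    tok %in% NEGATIVE_TOKENS ~ "non_aggregating",
    TRUE ~ NA_character_
  )
  if (any(is.na(out) & !is.na(tok))) {
    stop(
      "unknown label token(s): ",
      paste(unique(tok[is.na(out) & !is.na(tok)]), collapse = ", "),
      call. = FALSE
    )
  }
  factor(out, levels = c("non_aggregating", "aggregating"))
}

# logical positives; accepts the label factor, 0/1, or logical
as_positive <- function(label) {
  if (is.logical(label)) return(label)
  if (is.numeric(label)) return(label > 0)
  normalize_labels(label) == "aggregating"
}

#' Read a labeled peptide dataset
#'
#' Reads a delimited table of peptides with aggregation labels and source
#' proteins: required columns `sequence`, `label`, `protein_group`;
#' optional `source_note`. Labels may use any of the common dialects
#' (`1`/`0`, `pos`/`neg`, `agg`/`non`, ...) and are normalized to a factor
#' with levels `non_aggregating` < `aggregating`; `aggregating` is the
#' positive class throughout the package. Peptides with no source protein
#' use the reserved group token `"de_novo"`.
#'
#' @param path Path to the table (`.csv` comma, otherwise tab-delimited).
#' @return A tibble with columns `sequence`, `label`, `protein_group`,
#'   `source_note`.
#' @export
read_peptides <- function(path) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- readr::read_delim(
    path,
    delim = delim, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  need <- setdiff(c("sequence", "label", "protein_group"), names(tab))
  if (length(need) > 0) {
    stop("missing column(s): ", paste(need, collapse = ", "), call. = FALSE)
  }
  seqs <- toupper(dplyr::coalesce(tab$sequence, ""))
  bad <- !grepl("^[A-Z]+$", seqs)
  if (any(bad)) {
    stop(
      "invalid or empty sequence at row ", paste(which(bad), collapse = ", "),
      call. = FALSE
    )
  }
  grp <- stringr::str_trim(dplyr::coalesce(tab$protein_group, ""))
  if (any(!nzchar(grp))) {
    stop(
      "blank protein_group at row ",
      paste(which(!nzchar(grp)), collapse = ", "),
      call. = FALSE
    )
  }
  tibble::tibble(
    sequence = seqs,
    label = normalize_labels(tab$label),
    protein_group = grp,
    source_note = if ("source_note" %in% names(tab)) {
      dplyr::coalesce(tab$source_note, "")
    } else ""
  )
}

#' Write a labeled peptide dataset
#'
#' Inverse of [read_peptides()]; writes a tab-delimited table.
#'
#' @param peptides A tibble with `sequence`, `label`, `protein_group` (and
#'   optionally `source_note`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peptides <- function(peptides, path) {
  out <- tibble::tibble(
    sequence = peptides$sequence,
    label = as.character(peptides$label),
    protein_group = peptides$protein_group,
    source_note = if ("source_note" %in% names(peptides)) {
      peptides$source_note
    } else ""
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
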