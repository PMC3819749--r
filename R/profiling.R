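# Whole-protein scanning: a symmetric sliding window (default 7 residues)
# is encoded like any short peptide and its propensity assigned to the
# central residue, producing a per-residue profile from which
# aggregation-prone regions are called at a strict threshold.

#' Read protein sequences from a FASTA file
#'
#' Ids are taken from the header up to the first whitespace and must be
#' unique; sequences are uppercased, and alignment gaps (`-`) or stop
#' marks (`*`) are stripped with a warning.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` and `sequence`.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0) {
    stop("no sequences in ", path, call. = FALSE)
  }
  ids <- stringr::str_extract(names(set), "^\\S+")
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  if (any(grepl("[-*]", seqs))) {
    warning("stripped gap/stop characters from sequence(s)", call. = FALSE)
    seqs <- gsub("[-*]", "", seqs)
  }
  empty <- !nzchar(seqs)
  if (any(empty)) {
    stop("record(s) with no sequence: ",
         paste(ids[empty], collapse = ", "), call. = FALSE)
  }
  tibble::tibble(id = unname(ids), sequence = unname(seqs))
}

#' Sliding-window aggregation propensity profile
#'
#' Scans each protein with a symmetric window of `window` residues
#' (odd, default 7): every full window is encoded by residue-composition
#' averaging on the predictor's feature subset, its propensity predicted,
#' and the score assigned to the window's central residue. The first and
#' last `(window - 1) / 2` residues receive no score — windows are never
#' truncated or padded, which would silently change the averaging
#' denominator. Positions are 1-based.
#'
#' @param proteins A tibble from [read_fasta()] (columns `id`,
#'   `sequence`), or a single sequence string.
#' @param model A `propensity_model`.
#' @param scales The unit-scaled `prop_scales` collection the model's
#'   features come from.
#' @param window Odd window size >= 3 (default 7).
#' @return A `propensity_profile` tibble: `id`, `position` (central
#'   residue), `residue`, `score`; attributes `window` and `method`.
#' @export
profile_protein <- function(proteins, model, scales, window = 7) {
  if (is.character(proteins)) {
    proteins <- tibble::tibble(
      id = if (!is.null(names(proteins))) names(proteins) else
        paste0("seq", seq_along(proteins)),
      sequence = proteins
    )
  }
  if (window < 3 || window %% 2 == 0) {
    stop("`window` must be an odd integer >= 3", call. = FALSE)
  }
  scales <- scales_subset(scales, model$features)
  half <- (window - 1) / 2

  out <- purrr::map_dfr(seq_len(nrow(proteins)), function(i) {
    s <- toupper(proteins$sequence[i])
    len <- nchar(s)
    if (len < window) {
      stop(
        "sequence '", proteins$id[i], "' (length ", len, ") is shorter ",
        "than the window (", window, "); use classify_peptides() for ",
        "short peptides", call. = FALSE
      )
    }
    starts <- seq_len(len - window + 1)
    centers <- starts + half
    wins <- stringr::str_sub(s, starts, starts + window - 1)
    enc <- encode_peptides(wins, scales)
    tibble::tibble(
      id = proteins$id[i],
      position = centers,
      residue = stringr::str_sub(s, centers, centers),
      score = predict(model, enc)
    )
  })
  structure(
    out,
    window = window, method = model$method,
    class = c("propensity_profile", class(tibble::tibble()))
  )
}

#' Call aggregation-prone regions from a profile
#'
#' Maximal runs of consecutive scored positions whose score is strictly
#' above the threshold become regions; a position scoring exactly the
#' threshold is excluded. Coordinates are 1-based inclusive central
#' residue positions.
#'
#' @param profile A `propensity_profile`.
#' @param threshold Propensity threshold (default 0.5; strict).
#' @param min_length Minimum region length in residues.
#' @return A tibble with `id`, `start`, `end`, `length`, `peak` (maximum
#'   score) and `mean` (mean score) per region.
#' @export
call_regions <- function(profile, threshold = 0.5, min_length = 1) {
  if (nrow(profile) == 0) stop("empty profile", call. = FALSE)
  if (!any(profile$score > threshold)) {
    return(tibble::tibble(
      id = character(), start = numeric(), end = numeric(),
      length = integer(), peak = numeric(), mean = numeric()
    ))
  }
  profile |>
    dplyr::group_by(.data$id) |>
    dplyr::arrange(.data$position, .by_group = TRUE) |>
    dplyr::mutate(
      above = .data$score > threshold,
      new_run = .data$above & (
        !dplyr::lag(.data$above, default = FALSE) |
          dplyr::lag(.data$position, default = -1) != .data$position - 1
      ),
      run = cumsum(.data$new_run)
    ) |>
    dplyr::filter(.data$above) |>
    dplyr::group_by(.data$id, .data$run) |>
    dplyr::summarise(
      start = min(.data$position),
      end = max(.data$position),
      length = dplyr::n(),
      peak = max(.data$score),
      mean = mean(.data$score),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$length >= min_length) |>
    dplyr::select(-"run") |>
    dplyr::arrange(.data$id, .data$start)
}

#' Export called regions as BED intervals
#'
#' Converts the 1-based inclusive region coordinates to BED's 0-based
#' half-open convention.
#'
#' @param regions A tibble from [call_regions()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  bed <- tibble::tibble(
    chrom = regions$id,
    start = regions$start - 1L,
    end = regions$end,
    name = sprintf("APR_%s_%d_%d", regions$id, regions$start, regions$end),
    score = round(1000 * regions$peak)
  )
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Classify short peptides
#'
#' Encodes whole peptides (intended length 3-25 residues; longer inputs
#' warn and should normally be profiled instead) and thresholds their
#' propensity: strictly above `threshold` is aggregating.
#'
#' @param peptides Character vector of sequences or a tibble with a
#'   `sequence` column.
#' @inheritParams profile_protein
#' @param threshold Decision threshold (default 0.5; strict).
#' @return A tibble with `sequence`, `score` and `predicted` (label
#'   factor).
#' @export
classify_peptides <- function(peptides, model, scales, threshold = 0.5) {
  if (is.character(peptides)) {
    peptides <- tibble::tibble(sequence = peptides)
  }
  len <- nchar(peptides$sequence)
  if (any(len < 3)) {
    stop("peptide(s) shorter than 3 residues: row ",
         paste(which(len < 3), collapse = ", "), call. = FALSE)
  }
  if (any(len > 25)) {
    warning("peptide(s) longer than 25 residues; consider ",
            "profile_protein() for whole-sequence scanning", call. = FALSE)
  }
  scales <- scales_subset(scales, model$features)
  enc <- encode_peptides(peptides, scales)
  score <- predict(model, enc)
  tibble::tibble(
    sequence = peptides$sequence,
    score = score,
    predicted = factor(
      ifelse(score > threshold, "aggregating", "non_aggregating"),
      levels = c("non_aggregating", "aggregating")
    )
  )
}

#' Write a propensity profile as TSV
#'
#' @param profile A `propensity_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  readr::write_tsv(tibble::as_tibble(profile), path, progress = FALSE)
  invisible(path)
}
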