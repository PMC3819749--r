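# Synthetic fixtures with planted, known structure. Class signal is
# planted through residue-composition bias — positives prefer residues
# with high values on the informative scales — so the encoding step is
# genuinely exercised rather than having feature values written directly.
# Noise scales are made exactly orthogonal (over their observed
# residues) to the class difference of the planted residue
# distributions, so they carry no class signal in expectation.

#' Specification for a synthetic fixture
#'
#' Defaults mirror the AP1 aggregation-peptide dataset the pipeline was
#' developed on: 354 peptides (184 aggregating, 170 not), 37 source
#' proteins plus a de novo pool of 57 peptides, lengths around 12.7
#' residues (sd 7, clamped to 4-30), and a 560-scale property collection.
#'
#' @param n_scales Number of property scales.
#' @param n_informative Number of informative scales carrying the class
#'   signal (the first `n_informative` scales of the collection).
#' @param effect_size Planted effect: mean shift of the informative-scale
#'   peptide averages between classes, in units of the within-class
#'   standard deviation of those averages.
#' @param n_peptides Number of peptides.
#' @param positive_fraction Fraction of aggregating peptides.
#' @param length_mean,length_sd Normal length distribution (rounded).
#' @param length_range Inclusive length bounds.
#' @param n_protein_groups Number of source-protein groups (besides the
#'   de novo pool).
#' @param de_novo_fraction Fraction of peptides in the reserved
#'   `"de_novo"` group.
#' @param missing_rate Fraction of residue cells set missing per scale.
#' @param confound_groups If `TRUE`, plant the signal in the source
#'   protein instead of the class: labels are constant within each
#'   protein group and each group has its own residue composition, so the
#'   class is only learnable by memorizing proteins. Used to demonstrate
#'   that leave-one-protein-out validation blocks within-protein leakage.
#' @param seed Integer seed; everything downstream is deterministic in it.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_scales = 560, n_informative = 2, effect_size = 2,
                         n_peptides = 354, positive_fraction = 184 / 354,
                         length_mean = 12.7, length_sd = 7,
                         length_range = c(4, 30),
                         n_protein_groups = 37,
                         de_novo_fraction = 57 / 354,
                         missing_rate = 0.02,
                         confound_groups = FALSE,
                         seed = 1) {
  stopifnot(
    n_scales >= 1, n_informative >= 0, n_informative <= n_scales,
    effect_size >= 0, n_peptides >= 1,
    positive_fraction > 0, positive_fraction < 1,
    length_range[1] >= 1, length_range[2] >= length_range[1],
    n_protein_groups >= 1,
    de_novo_fraction >= 0, de_novo_fraction <= 1,
    missing_rate >= 0, missing_rate < 1
  )
  structure(
    list(
      n_scales = as.integer(n_scales),
      n_informative = as.integer(n_informative),
      effect_size = effect_size,
      n_peptides = as.integer(n_peptides),
      positive_fraction = positive_fraction,
      length_mean = length_mean, length_sd = length_sd,
      length_range = as.integer(length_range),
      n_protein_groups = as.integer(n_protein_groups),
      de_novo_fraction = de_novo_fraction,
      missing_rate = missing_rate,
      confound_groups = isTRUE(confound_groups),
      seed = as.integer(seed)
    ),
    class = "fixture_spec"
  )
}

# Planted-signal design, a deterministic function of the informative
# scales and the spec: residue distributions for the two classes are the
# uniform distribution exponentially tilted along the centered mean of
# the unit-scaled informative values, p+/- proportional to
# exp(+/- (t/2) w). The tilt magnitude t is solved so that the mean
# standardized between-class gap of the informative-scale peptide
# averages equals effect_size, using the theoretical length distribution
# (so the design is identical wherever it is recomputed).
planted_design <- function(scales, spec) {
  informative <- informative_scales(scales)
  u <- t(as.matrix(scale_unit(scales_subset(scales, informative))[, AA_ORDER]))
  u[is.na(u)] <- 0.5
  vbar <- rowMeans(u)
  w <- vbar - mean(vbar)
  mean_inv_len <- expected_inv_length(spec)

  tilt <- function(t) {
    pp <- exp((t / 2) * w)
    pm <- exp(-(t / 2) * w)
    list(pos = pp / sum(pp), neg = pm / sum(pm))
  }
  std_effect <- function(t) {
    p <- tilt(t)
    mean(vapply(seq_len(ncol(u)), function(j) {
      v <- u[, j]
      gap <- sum((p$pos - p$neg) * v)
      var_p <- sum(p$pos * v^2) - sum(p$pos * v)^2
      var_m <- sum(p$neg * v^2) - sum(p$neg * v)^2
      sd_w <- sqrt(((var_p + var_m) / 2) * mean_inv_len)
      if (sd_w == 0) return(0)
      gap / sd_w
    }, numeric(1)))
  }

  if (spec$effect_size == 0 || max(abs(w)) == 0) {
    if (spec$effect_size > 0) {
      stop("informative scales have no residue contrast", call. = FALSE)
    }
    p <- tilt(0)
  } else {
    t_hi <- 1
    while (std_effect(t_hi) < spec$effect_size && t_hi < 1e4) {
      t_hi <- t_hi * 2
    }
    if (std_effect(t_hi) < spec$effect_size) {
      stop(
        "requested effect_size ", spec$effect_size, " is infeasible for ",
        "these informative scales (maximum achievable ~",
        format(std_effect(t_hi), digits = 3), ")", call. = FALSE
      )
    }
    t_star <- stats::uniroot(
      function(t) std_effect(t) - spec$effect_size,
      c(0, t_hi), tol = 1e-10
    )$root
    p <- tilt(t_star)
  }
  list(p_pos = p$pos, p_neg = p$neg, d = p$pos - p$neg)
}

# E[1/L] of the rounded, clamped normal length distribution
expected_inv_length <- function(spec) {
  lo <- spec$length_range[1]
  hi <- spec$length_range[2]
  lens <- lo:hi
  pr <- stats::pnorm(lens + 0.5, spec$length_mean, spec$length_sd) -
    stats::pnorm(lens - 0.5, spec$length_mean, spec$length_sd)
  pr[1] <- pr[1] + stats::pnorm(lo - 0.5, spec$length_mean, spec$length_sd)
  pr[length(pr)] <- pr[length(pr)] +
    stats::pnorm(hi + 0.5, spec$length_mean, spec$length_sd,
                 lower.tail = FALSE)
  sum(pr / lens) / sum(pr)
}

#' Generate a synthetic property collection
#'
#' Draws `n_scales` scales with uniform per-residue values. The first
#' `n_informative` scales are the informative ones; every other scale is
#' projected orthogonal (over the 20 residues) to the informative bias
#' direction, so peptides sampled with that bias show no expected class
#' difference on noise scales. A `missing_rate` fraction of residue cells
#' of the noise scales is set missing (informative scales stay fully
#' observed so the planted effect is exact), always leaving at least two
#' observed residues per scale.
#'
#' @param spec A [fixture_spec()].
#' @return A `prop_scales` tibble (not yet unit-scaled); informative
#'   scale ids are in attribute `"informative"` and flagged in the
#'   description.
#' @export
sim_scales <- function(spec) {
  withr::with_seed(spec$seed, {
    vals <- matrix(stats::runif(spec$n_scales * 20), nrow = spec$n_scales)
    ids <- sprintf("SYN%04d", seq_len(spec$n_scales))
    informative <- ids[seq_len(spec$n_informative)]

    if (spec$n_scales > spec$n_informative) {
      noise_rows <- seq(spec$n_informative + 1, spec$n_scales)

      if (spec$missing_rate > 0) {
        # informative scales stay fully observed so the planted effect
        # is exact; noise scales lose a missing_rate fraction of cells
        for (i in noise_rows) {
          gone <- which(stats::runif(20) < spec$missing_rate)
          gone <- utils::head(gone, 18) # keep >= 2 observed residues
          vals[i, gone] <- NA_real_
        }
      }

      if (spec$n_informative > 0) {
        # orthogonalize each noise scale to the class difference of the
        # planted residue distributions, renormalized over the scale's
        # observed residues (the encoder's exclusion rule averages over
        # exactly that distribution), so noise scales carry no expected
        # class signal; the later per-scale min-max rescale is affine
        # and preserves the constraint because the difference of two
        # renormalized distributions sums to zero
        pre <- tibble::tibble(scale_id = ids)
        pre[AA_ORDER] <- as.data.frame(vals)
        pre <- prop_scales(pre)
        attr(pre, "informative") <- informative
        des <- planted_design(pre, spec)
        for (i in noise_rows) {
          obs <- which(!is.na(vals[i, ]))
          dq <- des$p_pos[obs] / sum(des$p_pos[obs]) -
            des$p_neg[obs] / sum(des$p_neg[obs])
          dss <- sum(dq^2)
          if (dss > 0) {
            x <- vals[i, obs]
            vals[i, obs] <- x - (sum(dq * x) / dss) * dq
          }
        }
      }
    }

    out <- tibble::tibble(
      scale_id = ids,
      description = ifelse(
        ids %in% informative,
        "synthetic informative scale", "synthetic noise scale"
      ),
      origin = "aaindex"
    )
    out[AA_ORDER] <- as.data.frame(vals)
    res <- prop_scales(out)
    attr(res, "informative") <- informative
    res
  })
}

#' Informative scale ids of a synthetic collection
#'
#' @param scales A collection from [sim_scales()].
#' @return Character vector of informative scale ids.
#' @export
informative_scales <- function(scales) {
  inf <- attr(scales, "informative")
  if (is.null(inf)) {
    stop("`scales` was not produced by sim_scales()", call. = FALSE)
  }
  inf
}

sample_seqs <- function(lengths, prob) {
  vapply(lengths, function(L) {
    paste(sample(AA_ORDER, L, replace = TRUE, prob = prob), collapse = "")
  }, character(1))
}

#' Generate a labeled synthetic peptide set
#'
#' Samples peptide sequences residue by residue. Aggregating peptides
#' draw residues from the uniform distribution exponentially tilted
#' toward high values on the informative scales, non-aggregating
#' peptides with the opposite tilt; the tilt magnitude is calibrated so
#' the between-class gap of the informative-scale peptide averages
#' equals `effect_size` within-class standard deviations (a request
#' beyond what composition bias can achieve errors). Peptides are
#' assigned to `n_protein_groups` pseudo-proteins round-robin, with a
#' `de_novo_fraction` share in the reserved `"de_novo"` group. With
#' `confound_groups = TRUE` the signal sits in the protein group instead
#' (see [fixture_spec()]).
#'
#' @param spec A [fixture_spec()].
#' @param scales The collection from [sim_scales()] under the same spec.
#' @return A tibble with `sequence`, `label`, `protein_group`,
#'   `source_note`, exactly `n_peptides` rows.
#' @export
sim_peptides <- function(spec, scales) {
  withr::with_seed(spec$seed + 1L, {
    n <- spec$n_peptides
    n_pos <- round(n * spec$positive_fraction)
    lengths <- pmin(
      pmax(round(stats::rnorm(n, spec$length_mean, spec$length_sd)),
           spec$length_range[1]),
      spec$length_range[2]
    )
    label <- factor(
      c(rep("aggregating", n_pos), rep("non_aggregating", n - n_pos)),
      levels = c("non_aggregating", "aggregating")
    )

    # protein-group assignment: a de novo pool plus round-robin groups
    # over a shuffled order, so group and class are unconfounded
    ord <- sample.int(n)
    n_dn <- round(n * spec$de_novo_fraction)
    grp <- character(n)
    grp[ord[seq_len(n_dn)]] <- "de_novo"
    rest <- ord[setdiff(seq_len(n), seq_len(n_dn))]
    grp[rest] <- sprintf(
      "G%02d",
      rep_len(seq_len(spec$n_protein_groups), length(rest))
    )

    if (spec$confound_groups) {
      # group-held signal: labels constant per group, each group with its
      # own residue composition and no class-linked direction
      groups <- unique(grp)
      grp_label <- stats::setNames(
        rep_len(c("aggregating", "non_aggregating"),
                length(groups))[sample.int(length(groups))],
        groups
      )
      label <- factor(unname(grp_label[grp]),
                      levels = c("non_aggregating", "aggregating"))
      seqs <- character(n)
      for (g in groups) {
        p_g <- stats::rgamma(20, shape = 1)
        p_g <- p_g / sum(p_g)
        rows <- which(grp == g)
        seqs[rows] <- sample_seqs(lengths[rows], p_g)
      }
    } else {
      if (spec$n_informative > 0) {
        des <- planted_design(scales, spec)
        p_pos <- des$p_pos
        p_neg <- des$p_neg
      } else {
        p_pos <- p_neg <- rep(1 / 20, 20)
      }
      seqs <- character(n)
      pos <- label == "aggregating"
      seqs[pos] <- sample_seqs(lengths[pos], p_pos)
      seqs[!pos] <- sample_seqs(lengths[!pos], p_neg)
    }

    shuffle <- sample.int(n)
    tibble::tibble(
      sequence = seqs[shuffle],
      label = label[shuffle],
      protein_group = grp[shuffle],
      source_note = "synthetic"
    )
  })
}

#' Generate a complete synthetic fixture
#'
#' Convenience wrapper producing the property collection, the labeled
#' peptide set, and (optionally) on-disk copies in the formats the real
#' pipeline reads: an AAindex1-format scale file, a tab-delimited peptide
#' table, and a FASTA of the concatenated peptides for profiling tests.
#'
#' @param spec A [fixture_spec()].
#' @param dir Optional directory; when given, `scales.aaindex1`,
#'   `peptides.tsv` and `peptides.fasta` are written there.
#' @return A list with `scales`, `peptides` and (if written) `paths`.
#' @export
sim_fixture <- function(spec, dir = NULL) {
  scales <- sim_scales(spec)
  peptides <- sim_peptides(spec, scales)
  out <- list(scales = scales, peptides = peptides)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      scales = file.path(dir, "scales.aaindex1"),
      peptides = file.path(dir, "peptides.tsv"),
      fasta = file.path(dir, "peptides.fasta")
    )
    write_aaindex(scales, paths$scales)
    write_peptides(peptides, paths$peptides)
    writeLines(
      paste0(">synthetic_concatemer\n", paste(peptides$sequence, collapse = "")),
      paths$fasta
    )
    out$paths <- paths
  }
  out
}
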