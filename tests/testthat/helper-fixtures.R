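# Shared fixtures, built in code and memoized so expensive generation
# runs once per test session.

.fx_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fx_cache)) {
    assign(key, force(expr), envir = .fx_cache)
  }
  get(key, envir = .fx_cache)
}

# small planted-signal fixture used across modules
small_fixture <- function() {
  cached("small", {
    fx <- sim_fixture(fixture_spec(
      n_scales = 12, n_informative = 2, effect_size = 2,
      n_peptides = 120, n_protein_groups = 8, de_novo_fraction = 0.1,
      missing_rate = 0.05, seed = 42
    ))
    fx$unit <- scale_unit(fx$scales)
    fx$encoded <- encode_peptides(fx$peptides, fx$unit)
    fx
  })
}

# a hand-built collection whose arithmetic is easy to verify
toy_scales <- function(unit_scaled = TRUE) {
  df <- tibble::tibble(scale_id = c("P1", "P2", "P3"))
  vals <- rbind(
    c(0.2, 0.4, 0.6, 0.8, 1.0, 0.0, 0.1, 0.3, 0.5, 0.7,
      0.9, 0.2, 0.4, 0.6, 0.8, 1.0, 0.0, 0.1, 0.3, 0.5),
    c(0.6, rep(0.5, 19)), # C missing below
    rep(0.5, 20)
  )
  vals[2, 5] <- NA # residue C missing on P2
  df[aa_residues()] <- as.data.frame(vals)
  prop_scales(df, unit_scaled = unit_scaled)
}

# linearly separable encoded toy set: one feature carries the classes
separable_toy <- function(n_per_class = 15) {
  tibble::tibble(
    label = rep(c("aggregating", "non_aggregating"), each = n_per_class),
    f1 = c(seq(0.7, 0.95, length.out = n_per_class),
           seq(0.05, 0.3, length.out = n_per_class)),
    f2 = rep(seq(0.4, 0.6, length.out = n_per_class), 2)
  )
}

aaindex_record_text <- function(id = "TEST00001",
                                values = as.character(1:20),
                                desc = "Test scale") {
  c(
    paste("H", id),
    paste("D", desc),
    "R PMID:0000000",
    "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
    paste(" ", paste(values[1:10], collapse = "   ")),
    paste(" ", paste(values[11:20], collapse = "   ")),
    "//"
  )
}

# a fitted SVM on the small fixture's informative scales
small_model <- function() {
  cached("small_model", {
    fx <- small_fixture()
    train_propensity(fx$encoded, informative_scales(fx$scales),
                     method = "svm", seed = 7)
  })
}
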