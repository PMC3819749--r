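# FASTA input, sliding-window profiles, region calling, peptide mode

test_that("FASTA records read with trimmed ids and uppercased sequences", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">tau_fragment microtubule-associated", "gkvqivyk",
               ">seq2", "ACDEF", "GHIKL"), path)
  fa <- read_fasta(path)
  expect_equal(fa$id, c("tau_fragment", "seq2"))
  expect_equal(fa$sequence, c("GKVQIVYK", "ACDEFGHIKL"))
})

test_that("degenerate FASTA inputs are rejected or repaired", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), path)
  expect_error(read_fasta(path), "no sequences")
  writeLines(c(">a", "ACD", ">b"), path)
  expect_error(read_fasta(path), "no sequence")
  writeLines(c(">a", "ACD", ">a", "ACD"), path)
  expect_error(read_fasta(path), "duplicate")
  writeLines(c(">a", "AC-D*"), path)
  expect_warning(fa <- read_fasta(path), "gap/stop")
  expect_equal(fa$sequence, "ACD")
})

test_that("window-7 profiles cover positions 4 to L-3", {
  m <- small_model()
  sc <- small_fixture()$unit
  p10 <- profile_protein(strrep("ACDEFGHIKW", 1), m, sc, window = 7)
  expect_equal(p10$position, 4:7) # 10 - 7 + 1 windows
  expect_equal(p10$residue, c("E", "F", "G", "H"))
  p7 <- profile_protein("ACDEFGH", m, sc, window = 7)
  expect_equal(p7$position, 4)
  expect_true(all(p10$score >= 0 & p10$score <= 1))
})

test_that("window validation and short-sequence guidance", {
  m <- small_model()
  sc <- small_fixture()$unit
  expect_error(profile_protein("ACDEFGHIK", m, sc, window = 6), "odd")
  expect_error(profile_protein("ACDEF", m, sc, window = 7),
               "classify_peptides")
})

test_that("homopolymer profiles are constant and reversal mirrors profiles", {
  m <- small_model()
  sc <- small_fixture()$unit
  hp <- profile_protein(strrep("K", 15), m, sc)
  expect_equal(length(unique(hp$score)), 1)
  s <- "ACDEFGHIKLMNPQRSTVWY"
  fwd <- profile_protein(s, m, sc)
  rev <- profile_protein(paste(rev(strsplit(s, "")[[1]]), collapse = ""),
                         m, sc)
  # window contents are order-free, so the score series reverses exactly
  expect_equal(fwd$score, rev(rev$score))
})

fake_profile <- function(scores, positions = seq_along(scores) + 3,
                         id = "prot1") {
  structure(
    tibble::tibble(id = id, position = positions,
                   residue = "A", score = scores),
    window = 7,
    class = c("propensity_profile", class(tibble::tibble()))
  )
}

test_that("region calling finds maximal strict-threshold runs", {
  prof <- fake_profile(c(0.6, 0.7, 0.3, 0.8), positions = 4:7)
  reg <- call_regions(prof)
  expect_equal(reg$start, c(4, 7))
  expect_equal(reg$end, c(5, 7))
  expect_equal(reg$peak, c(0.7, 0.8))
  expect_equal(reg$mean, c(0.65, 0.8))
  expect_equal(nrow(call_regions(fake_profile(c(0.1, 0.5, 0.49)))), 0)
  # exact-threshold positions break runs
  reg <- call_regions(fake_profile(c(0.6, 0.5, 0.6), positions = 4:6))
  expect_equal(nrow(reg), 2)
  expect_equal(reg$start, c(4, 6))
})

test_that("region calling respects min_length and position gaps", {
  prof <- fake_profile(c(0.9, 0.9, 0.9), positions = c(4, 5, 9))
  reg <- call_regions(prof)
  expect_equal(nrow(reg), 2) # the gap at 6-8 splits the run
  expect_equal(nrow(call_regions(prof, min_length = 2)), 1)
})

test_that("regions export to BED as 0-based half-open intervals", {
  reg <- call_regions(fake_profile(c(0.6, 0.7, 0.3, 0.8), positions = 4:7))
  path <- withr::local_tempfile(fileext = ".bed")
  write_regions_bed(reg, path)
  bed <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE)
  expect_equal(bed$X2, c(3, 6))
  expect_equal(bed$X3, c(5, 7))
})

test_that("peptide classification enforces the short-peptide range", {
  m <- small_model()
  sc <- small_fixture()$unit
  expect_error(classify_peptides("AC", m, sc), "shorter than 3")
  expect_warning(classify_peptides(strrep("A", 30), m, sc), "longer than 25")
  out <- classify_peptides(c("KLVFFAE", "SSNNQQG"), m, sc)
  expect_true(all(out$score >= 0 & out$score <= 1))
  expect_equal(levels(out$predicted), c("non_aggregating", "aggregating"))
  expect_equal(as.character(out$predicted),
               ifelse(out$score > 0.5, "aggregating", "non_aggregating"))
})

test_that("profiles write to TSV and plot without error", {
  m <- small_model()
  sc <- small_fixture()$unit
  prof <- profile_protein("ACDEFGHIKLMNPQRSTVWY", m, sc)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_profile(prof, path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(nrow(back), nrow(prof))
  expect_s3_class(autoplot(prof), "ggplot")
})
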