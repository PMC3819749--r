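# SVM-RFE, RF importance-spectrum elimination, subset choice

test_that("elimination schedules are exact", {
  expect_equal(elimination_sizes(10), 10:1)
  expect_equal(elimination_sizes(560, 0.2)[1:3], c(560L, 448L, 358L))
  expect_equal(utils::tail(elimination_sizes(560, 0.2), 1), 1L)
  # one-at-a-time trace on 6 features
  fx <- small_fixture()
  tr <- svm_rfe(fx$encoded, features = feature_names(fx$encoded)[1:6],
                seed = 1)
  expect_equal(tr$n_features, 6:1)
})

test_that("traces are strictly nested and deterministic under a seed", {
  fx <- small_fixture()
  for (maker in list(
    function(s) svm_rfe(fx$encoded, drop_frac = 0.3, seed = s),
    function(s) rf_importance_selection(fx$encoded, ntree_build = 200,
                                        ntree_iter = 100, seed = s)
  )) {
    t1 <- maker(4)
    t2 <- maker(4)
    expect_identical(t1$features, t2$features)
    expect_identical(t1$error, t2$error)
    for (i in 2:nrow(t1)) {
      expect_true(all(t1$features[[i]] %in% t1$features[[i - 1]]))
      expect_lt(t1$n_features[i], t1$n_features[i - 1])
    }
  }
})

test_that("byte-identical feature columns are eliminated deterministically", {
  fx <- small_fixture()
  enc <- fx$encoded
  feats <- feature_names(enc)[1:5]
  dup <- enc
  dup$DUPLICATE <- dup[[feats[3]]]
  t1 <- svm_rfe(dup, features = c(feats, "DUPLICATE"), seed = 9)
  t2 <- svm_rfe(dup, features = c(feats, "DUPLICATE"), seed = 9)
  expect_identical(t1$features, t2$features)
  # the tied copy later in the collection order falls first
  drop_at <- function(tr, f) {
    max(which(vapply(tr$features, function(x) f %in% x, logical(1))))
  }
  expect_lte(drop_at(t1, "DUPLICATE"), drop_at(t1, feats[3]))
})

test_that("a strongly informative scale survives deep into SVM-RFE", {
  hits <- 0
  for (s in 1:5) {
    fx <- sim_fixture(fixture_spec(
      n_scales = 10, n_informative = 1, effect_size = 2.5,
      n_peptides = 60, n_protein_groups = 5, missing_rate = 0,
      seed = 100 + s
    ))
    enc <- encode_peptides(fx$peptides, scale_unit(fx$scales))
    inf <- informative_scales(fx$scales)
    # oracle: a single-feature threshold classifier singles out the
    # informative scale as the most discriminative column
    best_acc <- vapply(feature_names(enc), function(f) {
      v <- enc[[f]]
      max(vapply(sort(unique(v)), function(t) {
        max(mean((v > t) == (enc$label == "aggregating")),
            mean((v <= t) == (enc$label == "aggregating")))
      }, numeric(1)))
    }, numeric(1))
    expect_equal(names(which.max(best_acc)), inf)
    tr <- svm_rfe(enc, seed = s)
    final3 <- tr$features[[which(tr$n_features == 3)]]
    hits <- hits + (inf %in% final3)
  }
  expect_gte(hits, 4)
})

test_that("RF importance puts informative scales in the top decile", {
  fx <- sim_fixture(fixture_spec(
    n_scales = 40, n_informative = 2, effect_size = 2,
    n_peptides = 200, missing_rate = 0, seed = 31
  ))
  enc <- encode_peptides(fx$peptides, scale_unit(fx$scales))
  inf <- informative_scales(fx$scales)
  m <- train_propensity(enc, feature_names(enc), method = "rf", seed = 5)
  imp <- tidy(m)
  ranks <- rank(-imp$importance)[match(inf, imp$term)]
  expect_true(all(ranks <= 4)) # top decile of 40
  # oracle: label-permutation test finds the same scales significant
  set.seed(8)
  for (f in inf) {
    obs <- abs(diff(tapply(enc[[f]], enc$label, mean)))
    null <- replicate(200, {
      perm <- sample(enc$label)
      abs(diff(tapply(enc[[f]], perm, mean)))
    })
    expect_lt(mean(null >= obs), 0.05)
  }
})

test_that("pure-noise OOB errors stay near chance at every subset size", {
  fx <- sim_fixture(fixture_spec(
    n_scales = 15, n_informative = 0, effect_size = 0,
    n_peptides = 160, positive_fraction = 0.5, missing_rate = 0, seed = 77
  ))
  enc <- encode_peptides(fx$peptides, scale_unit(fx$scales))
  tr <- rf_importance_selection(enc, seed = 77)
  se <- sqrt(0.25 / nrow(enc))
  expect_true(all(abs(tr$error - 0.5) <= 3 * se))
})

test_that("subset choice implements the first-significant-minimum rule", {
  fake_trace <- function(sizes, errors, disp = 0) {
    aggprop:::new_elim_trace(
      tibble::tibble(
        iteration = seq_along(sizes), n_features = sizes,
        features = lapply(sizes, function(k) paste0("F", seq_len(k))),
        error = errors, dispersion = disp
      ),
      method = "svm_rfe", seed = 1
    )
  }
  # dispersion 0: smallest size attaining the minimum error
  ch <- choose_subset(fake_trace(c(10, 7, 5, 3), c(.30, .20, .20, .25)))
  expect_equal(ch$size, 5)
  # strictly decreasing error: the final size wins
  ch <- choose_subset(fake_trace(c(8, 4, 2, 1), c(.4, .3, .2, .1)))
  expect_equal(ch$size, 1)
  # a 1-dispersion band admits a smaller, slightly worse subset
  ch <- choose_subset(fake_trace(c(10, 5, 2), c(.20, .18, .21), disp = 0.05))
  expect_equal(ch$size, 2)
  expect_equal(choose_subset(fake_trace(c(10, 5, 2), c(.20, .18, .21),
                                        disp = 0.05), c_sd = 0)$size, 5)
})

test_that("traces serialize to JSON lines and back", {
  fx <- small_fixture()
  tr <- svm_rfe(fx$encoded, features = feature_names(fx$encoded)[1:4],
                seed = 2)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_trace(tr, path)
  back <- read_trace(path)
  expect_equal(back$features, tr$features)
  expect_equal(back$error, tr$error)
  expect_equal(attr(back, "method"), "svm_rfe")
  expect_equal(attr(back, "seed"), 2)
})

test_that("the published ProA subsets have the documented set structure", {
  subs <- proa_subsets()
  svm7 <- subs$scale_id[subs$method == "svm_rfe"]
  rf10 <- subs$scale_id[subs$method == "rf_is"]
  expect_length(svm7, 7)
  expect_length(rf10, 10)
  expect_length(union(svm7, rf10), 16)
  expect_equal(intersect(svm7, rf10), "ROSM880105")
})
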