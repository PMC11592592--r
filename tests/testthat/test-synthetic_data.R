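# Synthetic hairpin generator: planted-parameter contracts, negative
# mechanisms, determinism and dataset I/O.

test_that("generator configs are validated", {
  expect_s3_class(generator_config(), "generator_config")
  expect_error(generator_config(pair_fraction_range = c(0.9, 0.5)))
  expect_error(generator_config(loop_length_range = c(1, 2)))
  expect_error(generator_config(class_balance = 1.5))
  expect_error(generator_config(stem_length_range = c(99, 120)),
               "range conflict")
})

test_that("generated hairpins carry their planted parameters exactly", {
  set.seed(1)
  cfg <- generator_config(bulge_rate = 0.3)
  for (i in 1:40) {
    r <- generate_hairpin(cfg)
    f <- extract_features(r)
    pm <- planted_meta(r)
    expect_equal(f$stem_length, pm$stem)
    expect_equal(f$loop_length, pm$loop)
    expect_equal(f$pair_fraction, pm$pf, tolerance = 1e-10)
    expect_equal(f$n_bulges, pm$nb)
    expect_equal(f$max_bulge_size, pm$mb)
    expect_equal(f$max_asymmetric_bulge, pm$asym)
  }
})

test_that("boundary configurations behave as planted", {
  set.seed(2)
  # fully Watson-Crick stem, no bulges
  cfg <- generator_config(pair_fraction_range = c(1, 1), bulge_rate = 0)
  r <- generate_hairpin(cfg)
  expect_equal(extract_features(r)$pair_fraction, 1.0)
  # the smallest well-formed hairpin pattern
  cfg <- generator_config(stem_length_range = c(5, 5),
                          loop_length_range = c(4, 4),
                          pair_fraction_range = c(1, 1), bulge_rate = 0)
  r <- generate_hairpin(cfg)
  expect_identical(r$structure, "(((((....)))))")
})

test_that("identical seed and config give byte-identical datasets", {
  cfg <- generator_config(n_samples = 50, seed = 7)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1, d2)
})

test_that("class balance is exact", {
  ds <- generate_dataset(generator_config(n_samples = 200, class_balance = 0.5,
                                          seed = 3))
  expect_identical(sum(dataset_labels(ds) == 1L), 100L)
})

test_that("negative mechanisms violate pre-miRNA structure as documented", {
  set.seed(9)
  cfg <- generator_config()
  seen <- character(0)
  for (i in 1:60) {
    r <- generate_negative(cfg)
    expect_identical(r$label, 0L)
    mech <- planted_meta(r)$mech
    seen <- union(seen, mech)
    f <- extract_features(r)
    if (mech == "lowpair") expect_lte(f$pair_fraction, 0.3)
    if (mech == "short") expect_lte(f$total_length, 2 * 8 + 6)
  }
  expect_setequal(seen, c("shuffle", "lowpair", "short"))
})

test_that("dinucleotide shuffle preserves doublet composition", {
  doublets <- function(s) {
    ch <- strsplit(s, "")[[1]]
    sort(paste0(ch[-length(ch)], ch[-1]))
  }
  set.seed(5)
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "U"), 60, replace = TRUE), collapse = "")
    sh <- dinucleotide_shuffle(s)
    expect_identical(doublets(sh), doublets(s))
    expect_identical(substr(sh, 1, 1), substr(s, 1, 1))
    expect_identical(substr(sh, 60, 60), substr(s, 60, 60))
  }
})

test_that("the fallback folder returns valid nested stem-loops", {
  set.seed(6)
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "U"), 70, replace = TRUE), collapse = "")
    db <- fold_hairpin(s)
    expect_identical(nchar(db), 70L)
    expect_silent(parse_pairs(db))
    expect_true(mirdiva:::is_single_stemloop(db))
  }
  expect_identical(fold_hairpin("ACGU"), "....")
})

test_that("dataset write/read is an exact round trip", {
  dir <- withr::local_tempdir()
  ds <- small_dataset()
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_identical(length(back), length(ds))
  for (i in seq_along(ds)) {
    expect_identical(back[[i]]$id, ds[[i]]$id)
    expect_identical(back[[i]]$label, ds[[i]]$label)
    expect_same_record(back[[i]], ds[[i]])
  }
  # empty dataset round trip
  dir2 <- withr::local_tempdir()
  write_dataset(list(), dir2)
  expect_identical(read_dataset(dir2), list())
})

test_that("disjoint pair-fraction regimes are separable by one threshold", {
  # construction guarantee: with non-overlapping positive/negative pair
  # fraction ranges, the true feature classifies perfectly
  set.seed(8)
  cfg <- generator_config(n_samples = 60, pair_fraction_range = c(0.8, 1))
  pos <- replicate(30, generate_hairpin(cfg), simplify = FALSE)
  lo <- cfg; lo$pair_fraction_range <- c(0.1, 0.4)
  neg <- replicate(30, {
    r <- generate_hairpin(lo); r$label <- 0L; r
  }, simplify = FALSE)
  ft <- feature_table(c(pos, neg))
  y <- dataset_labels(c(pos, neg))
  expect_identical(as.integer(ft$pair_fraction > 0.6), y)
})

test_that("planted-rule records are labeled by the rule itself", {
  ds <- generate_planted_rule_dataset(120, seed = 13)
  ft <- feature_table(ds)
  y_rule <- as.integer(ft$pair_fraction > 0.7 & ft$total_length > 60 &
                       ft$max_asymmetric_bulge < 5)
  expect_identical(y_rule, dataset_labels(ds))
  expect_gt(mean(y_rule), 0.35)
  expect_lt(mean(y_rule), 0.65)
})
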