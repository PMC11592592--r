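# Structural feature extraction and binarization.

test_that("the minimal hairpin yields the textbook feature row", {
  f <- extract_features(structured_rna("toy", "GGGAAACCC", "(((...)))"))
  expect_identical(f$stem_length, 3L)
  expect_identical(f$loop_length, 3L)
  expect_identical(f$has_terminal_loop, 1L)
  expect_identical(f$pair_fraction, 1)
  expect_identical(f$total_length, 9L)
  expect_identical(f$n_bulges, 0L)
})

test_that("an unpaired structure yields the all-zero row", {
  f <- extract_features(structured_rna("u", "ACGUA", "....."))
  expect_identical(f$has_terminal_loop, 0L)
  expect_identical(f$stem_length, 0L)
  expect_identical(f$loop_length, 0L)
  expect_identical(f$pair_fraction, 0)
  expect_identical(f$total_length, 5L)
})

test_that("a hand-traced bulged stem is measured correctly", {
  # 4 pairs, a 4-nt 5' bulge between pairs 2 and 3, 3-nt loop:
  # GG AAAA GG AAA CC CC -> ((....((...))))  traced by hand
  r <- structured_rna("hand", "GGAAAAGGAAACCCC", "((....((...))))")
  f <- extract_features(r)
  expect_identical(f$stem_length, 4L)
  expect_identical(f$loop_length, 3L)
  expect_identical(f$n_bulges, 1L)
  expect_identical(f$max_bulge_size, 4L)
  expect_identical(f$max_asymmetric_bulge, 4L)
  expect_identical(f$total_length, 15L)
})

test_that("two-sided internal loops report asymmetry, not size", {
  # 2-nt run on the 5' side and 1-nt run on the 3' side of one junction
  r <- structured_rna("il", "GGAAGGAAACCACC", "((..((...)).))")
  f <- extract_features(r)
  expect_identical(f$n_bulges, 2L)
  expect_identical(f$max_bulge_size, 2L)
  expect_identical(f$max_asymmetric_bulge, 1L)
})

test_that("binarization matches the threshold table and is monotone", {
  tab <- data.frame(pair_fraction = c(0.8, 0.45), has_terminal_loop = c(1L, 0L))
  fb <- binarize_features(tab, list(pair_fraction = c(0.5, 0.7, 0.9)))
  expect_identical(colnames(fb),
                   c("pair_fraction>0.5", "pair_fraction>0.7",
                     "pair_fraction>0.9", "has_terminal_loop"))
  expect_identical(unname(fb[1, 1:3]), c(1L, 1L, 0L))
  expect_identical(unname(fb[2, 1:3]), c(0L, 0L, 0L))
  expect_identical(unname(fb[, 4]), c(1L, 0L))
  # monotone: raising the value never switches a column off
  lo <- binarize_features(data.frame(pair_fraction = 0.6),
                          list(pair_fraction = c(0.5, 0.7, 0.9)))
  hi <- binarize_features(data.frame(pair_fraction = 0.95),
                          list(pair_fraction = c(0.5, 0.7, 0.9)))
  expect_true(all(hi >= lo))
})

test_that("binarization validates thresholds and counts columns", {
  tab <- feature_table(small_dataset(n = 100, seed = 31))
  th <- list(loop_length = c(4, 8, 12), stem_length = c(10, 20, 30),
             pair_fraction = c(0.3, 0.6, 0.9), total_length = c(30, 60, 90),
             max_bulge_size = c(1, 2, 3))
  fb <- binarize_features(tab, th)
  expect_identical(dim(fb), c(100L, 5L * 3L + 1L))  # + has_terminal_loop
  expect_error(binarize_features(tab, list(loop_length = numeric(0))),
               "empty threshold")
  expect_error(binarize_features(tab, list(loop_length = c(8, 4))),
               "strictly increasing")
})

test_that("default thresholds are strictly increasing interior quantiles", {
  tab <- feature_table(small_dataset(n = 100, seed = 31))
  th <- default_thresholds(tab)
  for (f in names(th)) {
    expect_false(is.unsorted(th[[f]], strictly = TRUE))
    expect_true(all(th[[f]] <= max(tab[[f]])))
  }
})

test_that("feature families map names to the three rule families", {
  expect_identical(feature_family(c("pair_fraction>0.7", "total_length>60")),
                   c("pair_fraction", "total_length"))
  expect_identical(unname(FEATURE_FAMILIES[c("pair_fraction", "stem_length",
                                             "n_bulges")]),
                   c("pair", "length", "bulge"))
})
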