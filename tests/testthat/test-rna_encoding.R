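# Image codec: bond classification, arm alignment, the bar-length rule,
# exact invertibility and image validation.

test_that("bond classification follows the Watson-Crick rule", {
  expect_identical(classify_bond("G", "C"), "strong")
  expect_identical(classify_bond("A", "U"), "strong")
  expect_identical(classify_bond("U", "A"), "strong")
  expect_identical(classify_bond("G", "U"), "weak")  # wobble
  expect_identical(classify_bond("A", "C"), "weak")
  expect_identical(classify_bond("A", "GAP"), "none")
  expect_identical(classify_bond("A", "U", paired = FALSE), "none")
  expect_identical(classify_bond(NA, "U"), "none")
})

test_that("a fully complementary toy stem aligns pair-per-column", {
  aln <- align_arms(structured_rna("toy", "GGGAAACCC", "(((...)))"))
  expect_identical(aln$top[1:3], c("G", "G", "G"))
  expect_identical(aln$bottom[1:3], c("C", "C", "C"))
  expect_identical(aln$bond[1:3], rep("strong", 3))
  expect_identical(aln$role[4:5], c("loop", "loop"))
  # loop of 3: two top, one bottom, wrapped at the apex
  expect_identical(aln$top[4:5], c("A", "A"))
  expect_identical(aln$bottom[5], "A")
  expect_true(is.na(aln$bottom[4]))
})

test_that("a 5' bulge produces a nucleotide/GAP column", {
  r <- structured_rna("b", "GGAGGAAACCCC", "((.((...))))")
  aln <- align_arms(r)
  expect_identical(aln$role[3], "bulge5")
  expect_identical(aln$top[3], "A")
  expect_identical(aln$bottom[3], "GAP")
})

test_that("unpaired-only input degenerates to nucleotide/GAP columns", {
  aln <- align_arms(structured_rna("u", "ACGUA", "....."))
  expect_identical(nrow(aln), 5L)
  expect_true(all(aln$bottom == "GAP"))
  expect_true(all(aln$bond == "none"))
})

test_that("multiloops and over-long structures are rejected", {
  expect_error(align_arms(structured_rna("m", "GGAAACCGGAAACC",
                                         "((...))((...))")),
               "stem-loop")
  long <- structured_rna("long",
                         paste0(strrep("G", 90), strrep("A", 24), strrep("C", 90)),
                         paste0(strrep("(", 90), strrep(".", 24), strrep(")", 90)))
  expect_error(align_arms(long), "budget")
})

test_that("images have the contracted geometry and bar-length table", {
  r <- structured_rna("toy", "GGGAAACCC", "(((...)))")
  enc <- encode_image(r)
  expect_identical(dim(enc$image), c(100L, 25L, 5L))
  bars <- bars_from_image(enc$image)
  # strong pairs are 3 px on both rows; loop nucleotides 2 px
  expect_identical(bars$top_len[1:3], rep(3L, 3))
  expect_identical(bars$bottom_len[1:3], rep(3L, 3))
  expect_identical(bars$top_len[4:5], c(2L, 2L))
  # bond vector: 3 strong columns then zeros
  expect_identical(enc$m, c(rep(1L, 3), rep(0L, 97)))
})

test_that("gap bars are always exactly 2 px and black", {
  r <- structured_rna("b", "GGAGGAAACCCC", "((.((...))))")
  bars <- bars_from_image(encode_image(r)$image)
  gap <- bars[bars$bottom_color == "GAP" & !is.na(bars$bottom_color), ]
  expect_gt(nrow(gap), 0)
  expect_true(all(gap$bottom_len == 2L))
})

test_that("weak-bond bars are longer than strong bars and grow with runs", {
  # stem with strong, then three consecutive wobble pairs, then strong
  r <- structured_rna("w", "CGGGAAAAAUUUUG", "(((((....)))))")
  aln <- align_arms(r)
  expect_identical(aln$bond[1:5], c("strong", "weak", "weak", "weak", "strong"))
  bars <- bars_from_image(encode_image(r)$image)
  expect_identical(bars$top_len[1], 3L)
  expect_identical(bars$top_len[2:4], c(4L, 5L, 6L))  # run rule
  expect_identical(bars$top_len[5], 3L)
  expect_true(all(bars$top_len[2:4] > bars$top_len[1]))
})

test_that("no bar exceeds 12 px and a background row always remains", {
  for (r in small_dataset()) {
    bars <- bars_from_image(encode_image(r)$image)
    expect_lte(max(bars$top_len, bars$bottom_len), 12L)
    expect_true(all(bars$top_len + bars$bottom_len < 25L))
    expect_lte(max(bars$col), 100L)
  }
})

test_that("decode is the exact inverse of encode", {
  for (r in small_dataset()) {
    dec <- decode_image(encode_image(r)$image)
    expect_same_record(dec, r)
  }
})

test_that("the all-background image decodes to the empty record", {
  dec <- decode_image(array(0, dim = c(100, 25, 5)))
  expect_identical(dec$sequence, "")
  expect_identical(dec$structure, "")
})

test_that("a hand-built bulge image decodes to one bulged nucleotide", {
  # per the length table: a 4-px A bar over a 2-px black bar is a 5' bulge
  bars <- data.frame(col = 1L, top_color = "A", top_len = 4L,
                     bottom_color = "GAP", bottom_len = 2L)
  dec <- decode_image(bars_to_image(bars))
  expect_identical(dec$sequence, "A")
  expect_identical(dec$structure, ".")
})

test_that("malformed images are rejected with located errors", {
  img <- array(0, dim = c(100, 25, 5))
  img[3, 1, 1] <- 1; img[3, 1, 2] <- 1                 # multi-hot pixel
  expect_error(bars_from_image(img), "multi-hot.*\\(3,1\\)")
  img2 <- array(0, dim = c(100, 25, 5))
  img2[5, 10, 1] <- 1                                  # floating pixel
  expect_error(bars_from_image(img2), "column 5")
  img3 <- array(0, dim = c(100, 25, 5))
  img3[1, 1:25, 1] <- 1                                # full-height overlap
  expect_error(bars_from_image(img3), "overlap")
})

test_that("bond vectors match an independent per-column recomputation", {
  for (r in small_dataset()) {
    enc <- encode_image(r)
    aln <- align_arms(r)
    m2 <- integer(100)
    for (k in seq_len(nrow(aln))) {
      paired <- aln$role[k] == "pair"
      if (classify_bond(aln$top[k], aln$bottom[k], paired) == "strong") {
        m2[k] <- 1L
      }
    }
    expect_identical(enc$m, m2)
    expect_identical(bond_vector_from_image(enc$image), enc$m)
  }
})
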