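base_mutations <- function() {
  data.frame(
    sample = c("p1", "p1", "p2", "p3", "p3", "p4"),
    gene = c("TP53", "BRCA1", "TP53", "BRCA1", "KRAS", "KRAS"),
    consequence = c("non-silent", "non-silent", "non-silent", "non-silent",
                    "silent", "non-silent"),
    variant_type = c("SNV", "indel", "SNV", "SNV", "SNV", "SNV"),
    assigned_signature = c("2", NA, "3", "5", "2", "3"),
    stringsAsFactors = FALSE)
}

test_that("alteration calls apply exclusion, indel and consequence rules", {
  mut <- base_mutations()
  samples <- paste0("p", 1:4)

  # target signature 2: p1's TP53 SNV (sig 2) is excluded; indel kept
  A2 <- build_matrix(mut, target = "2C", samples = samples,
                     frequency_min = 0)
  expect_equal(unname(A2["TP53", ]), c(0L, 1L, 0L, 0L))
  expect_equal(unname(A2["BRCA1", "p1"]), 1L)   # indel kept for sig 2
  expect_false(attr(A2, "drop_indels"))

  # target signature 3: indels dropped by default, sig-3 mutations excluded
  A3 <- build_matrix(mut, target = "3D", samples = samples,
                     frequency_min = 0)
  expect_equal(unname(A3["BRCA1", ]), c(0L, 0L, 1L, 0L))  # p1 indel dropped
  expect_equal(unname(A3["TP53", ]), c(1L, 0L, 0L, 0L))   # p2 excluded
  expect_false("KRAS" %in% rownames(A3))                  # silent + excluded
  expect_true(attr(A3, "drop_indels"))

  # both contexts of the target signature are excluded regardless of C/D
  A3c <- build_matrix(mut, target = "3C", samples = samples,
                      frequency_min = 0)
  expect_equal(dim(A3c), dim(A3))
  expect_true(all(A3c == A3[rownames(A3c), colnames(A3c)]))

  expect_error(build_matrix(mut, target = ""), "unknown target")
  expect_error(build_matrix(mut[0, ], target = "2C"), "empty patient")
})

test_that("silent-only genes are never altered without biallelic annotation", {
  mut <- data.frame(sample = "p1", gene = "PTEN", consequence = "silent",
                    variant_type = "SNV", assigned_signature = "5")
  A <- build_matrix(mut, target = "2C", samples = c("p1", "p2"),
                    frequency_min = 0)
  expect_false("PTEN" %in% rownames(A))

  ba <- data.frame(sample = "p2", gene = "PTEN")
  Ab <- build_matrix(mut, target = "2C", biallelic = ba,
                     samples = c("p1", "p2"), frequency_min = 0)
  expect_equal(unname(Ab["PTEN", ]), c(0L, 1L))
})

test_that("biallelic annotations bypass signature exclusion and indel removal", {
  mut <- data.frame(sample = "p1", gene = "BRCA2", consequence = "non-silent",
                    variant_type = "indel", assigned_signature = NA)
  ba <- data.frame(sample = "p1", gene = "BRCA2")
  A <- build_matrix(mut, target = "3C", biallelic = ba, samples = c("p1", "p2"),
                    frequency_min = 0)
  expect_equal(unname(A["BRCA2", "p1"]), 1L)
})

test_that("the 1% frequency floor drops rare genes (5 of 560 rule)", {
  samples <- sprintf("s%03d", 1:560)
  mut <- data.frame(sample = samples[1:5], gene = "RARE",
                    consequence = "non-silent", variant_type = "SNV",
                    assigned_signature = "1")
  A <- build_matrix(mut, target = "2C", samples = samples)
  expect_false("RARE" %in% rownames(A))  # 5/560 < 1%

  mut6 <- data.frame(sample = samples[1:6], gene = "RARE",
                     consequence = "non-silent", variant_type = "SNV",
                     assigned_signature = "1")
  A6 <- build_matrix(mut6, target = "2C", samples = samples)
  expect_true("RARE" %in% rownames(A6))  # 6/560 >= 1%
})

test_that("signature exclusion never adds alterations (monotonicity)", {
  set.seed(60)
  sigs <- as.character(c(1, 2, 3, 5))
  mut <- data.frame(
    sample = sample(sprintf("p%02d", 1:20), 300, TRUE),
    gene = sample(sprintf("G%d", 1:15), 300, TRUE),
    consequence = sample(c("silent", "non-silent"), 300, TRUE, c(0.3, 0.7)),
    variant_type = sample(c("SNV", "indel"), 300, TRUE, c(0.9, 0.1)),
    assigned_signature = sample(sigs, 300, TRUE),
    stringsAsFactors = FALSE)
  samples <- sprintf("p%02d", 1:20)
  none <- build_matrix(mut, target = "99", samples = samples,
                       drop_indels = FALSE, frequency_min = 0)
  for (s in sigs) {
    excl <- build_matrix(mut, target = paste0(s, "C"), samples = samples,
                         drop_indels = FALSE, frequency_min = 0)
    shared <- intersect(rownames(excl), rownames(none))
    expect_true(all(excl[shared, ] <= none[shared, ]))
    expect_true(all(rownames(excl) %in% rownames(none)))
  }
})

test_that("sample subsetting re-applies the frequency filter", {
  samples <- sprintf("p%02d", 1:100)
  mut <- data.frame(sample = c("p01", "p02"), gene = "G1",
                    consequence = "non-silent", variant_type = "SNV",
                    assigned_signature = "1")
  A <- build_matrix(mut, target = "2C", samples = samples,
                    frequency_min = 0.01)
  sub_all <- subset_samples(A, samples)
  expect_equal(dim(sub_all), dim(A))
  expect_true(all(sub_all == A[rownames(sub_all), colnames(sub_all)]))

  # in a 50-sample subset without carriers, the gene disappears
  sub0 <- subset_samples(A, samples[51:100])
  expect_false("G1" %in% rownames(sub0))

  # in a subset where its frequency crosses the floor, it stays
  sub1 <- subset_samples(A, samples[1:50])
  expect_true("G1" %in% rownames(sub1))
  expect_error(subset_samples(A, "nope"), "not in matrix")
})
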