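test_that("cloud/dispersed split follows the neighbor-distance definition", {
  mut <- data.frame(sample = "s1", chrom = "1", pos = c(100, 600, 1e6))
  expect_identical(split_cloud_dispersed(mut, 1000), c("C", "C", "D"))

  expect_identical(split_cloud_dispersed(
    data.frame(sample = "s1", chrom = "1", pos = 5)), "D")

  # same positions on different chromosomes are never neighbors
  mut2 <- data.frame(sample = "s1", chrom = c("1", "2"), pos = c(100, 150))
  expect_identical(split_cloud_dispersed(mut2, 1000), c("D", "D"))

  # labels depend only on distances, not on strand/direction of traversal
  set.seed(1)
  pos <- sort(sample.int(1e6, 50))
  mut3 <- data.frame(sample = "s1", chrom = "1", pos = pos)
  fwd <- split_cloud_dispersed(mut3, 2000)
  mirrored <- data.frame(sample = "s1", chrom = "1", pos = sort(1e6 + 1 - pos))
  expect_identical(split_cloud_dispersed(mirrored, 2000), rev(fwd))

  expect_error(split_cloud_dispersed(
    data.frame(sample = "s1", chrom = "1", pos = c(10, 5))), "sorted")
})

test_that("EM attribution handles degenerate catalogs exactly", {
  ch <- sbs96_channels()
  cat1 <- synthetic_signature_catalog(1, seed = 1)
  set.seed(2)
  mut <- data.frame(sample = "p1", variant_type = "SNV",
                    channel = sample(ch, 50, TRUE, prob = cat1[1, ]))
  att <- attribute_mutations(mut, cat1, n_restarts = 3, seed = 1)
  expect_true(all(att$mutations$assigned_signature == "1"))
  expect_equal(unname(att$exposures["p1", "1"]), 1.0)

  # disjoint support: assignment equals channel membership, accuracy 100%
  cat2 <- synthetic_signature_catalog(2, seed = 2, disjoint = TRUE)
  sup1 <- ch[cat2[1, ] > 0]
  set.seed(3)
  mut2 <- data.frame(sample = "p1", variant_type = "SNV",
                     channel = c(sample(sup1, 40, TRUE,
                                        prob = cat2[1, cat2[1, ] > 0]),
                                 sample(ch[cat2[2, ] > 0], 60, TRUE,
                                        prob = cat2[2, cat2[2, ] > 0])))
  att2 <- attribute_mutations(mut2, cat2, n_restarts = 5, seed = 1)
  expect_identical(att2$mutations$assigned_signature,
                   ifelse(mut2$channel %in% sup1, "1", "2"))

  # a patient with zero SNVs yields an empty assignment, not an error
  mut3 <- data.frame(sample = "p9", variant_type = "indel", channel = NA)
  att3 <- attribute_mutations(mut3, cat1, n_restarts = 2, seed = 1)
  expect_true(is.na(att3$mutations$assigned_signature))
})

test_that("EM recovers mixture weights from a 70/30 simulation", {
  cat2 <- synthetic_signature_catalog(2, seed = 3)
  set.seed(4)
  ch <- sbs96_channels()
  mut <- data.frame(sample = "p1", variant_type = "SNV",
                    channel = c(sample(ch, 700, TRUE, prob = cat2[1, ]),
                                sample(ch, 300, TRUE, prob = cat2[2, ])))
  att <- attribute_mutations(mut, cat2, n_restarts = 11, seed = 1)
  expect_lt(abs(att$exposures["p1", "1"] - 0.7), 0.05)
  expect_lt(abs(att$exposures["p1", "2"] - 0.3), 0.05)
})

test_that("exposure tables are exact bookkeeping of attributions", {
  att <- data.frame(sample = rep("p1", 3), assigned_signature = "2",
                    context_group = "C")
  tab <- build_exposure_table(att, signatures = c("1", "2"))
  expect_equal(unname(tab["p1", "2C"]), 3L)
  expect_equal(sum(tab), 3L)

  empty <- build_exposure_table(
    data.frame(sample = character(0), assigned_signature = character(0),
               context_group = character(0)),
    patients = c("a", "b"), signatures = "1")
  expect_equal(dim(empty), c(2L, 2L))
  expect_true(all(empty == 0L))

  # generator truth as assignments: table equals planned per-label counts,
  # and column sums conserve the number of attributed mutations
  cfg <- simulation_config(n_patients = 15, seed = 5)
  mc <- generate_mutation_catalog(cfg)
  att2 <- data.frame(sample = mc$mutations$sample,
                     assigned_signature = mc$mutations$true_signature,
                     context_group = mc$mutations$true_group)
  tab2 <- build_exposure_table(att2)
  lab <- paste0(att2$assigned_signature, att2$context_group)
  labs <- sort(unique(lab))
  expect_equal(as.vector(colSums(tab2)[labs]), as.vector(table(lab)[labs]))
  expect_equal(sum(tab2), nrow(att2))
})

test_that("abundance filter keeps signatures strictly above the group share", {
  tab <- matrix(0L, 1, 6,
                dimnames = list("p1", c("1C", "2C", "5C", "1D", "2D", "5D")))
  tab[1, c("1D", "2D", "5D")] <- c(150L, 40L, 810L)
  expect_warning(kept <- filter_abundant(tab), "group C")
  expect_identical(kept, c("1D", "5D"))

  # exactly at the threshold is dropped (strict >)
  tab2 <- matrix(c(100L, 900L), 1, 2, dimnames = list("p1", c("1D", "2D")))
  expect_identical(suppressWarnings(filter_abundant(tab2)), "2D")

  # 12 equal signatures: every share is 1/12 < 0.10, nothing retained
  tab3 <- matrix(10L, 1, 12,
                 dimnames = list("p1", paste0(1:12, "D")))
  expect_length(suppressWarnings(filter_abundant(tab3)), 0)
})

test_that("phenotype transform is an exact log10 z-score", {
  tab <- matrix(c(9L, 99L, 999L), 3, 1,
                dimnames = list(c("a", "b", "c"), "2C"))
  z <- make_phenotype(tab, "2C", pseudocount = 1)
  expect_equal(as.numeric(z), c(-1, 0, 1))
  expect_equal(attr(z, "log_base"), 10)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(stats::sd(z), 1, tolerance = 1e-12)

  const <- matrix(5L, 3, 1, dimnames = list(c("a", "b", "c"), "1D"))
  expect_error(make_phenotype(const, "1D"), "zero variance")
  expect_error(make_phenotype(tab, "9C"), "unknown")

  # restricting to the samples with alteration data re-standardizes
  tab4 <- matrix(c(1L, 10L, 100L, 1000L), 4, 1,
                 dimnames = list(letters[1:4], "3D"))
  z4 <- make_phenotype(tab4, "3D", samples = c("a", "b", "c"))
  expect_equal(length(z4), 3L)
  expect_equal(mean(z4), 0, tolerance = 1e-12)
})
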