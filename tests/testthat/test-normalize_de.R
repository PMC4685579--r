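test_that("size factors recover exact library scalings", {
  m <- random_counts(40, 1, lambda = 50, seed = 2)
  two <- count_matrix(cbind(A = m[, 1], B = 2L * m[, 1]))
  sf <- size_factors(two)
  expect_equal(unname(sf["B"] / sf["A"]), 2)
  expect_equal(exp(mean(log(sf))), 1)
  # all samples identical -> all factors equal
  same <- count_matrix(cbind(a = m[, 1], b = m[, 1], c = m[, 1]))
  expect_equal(unname(size_factors(same)), rep(1, 3))
  # scaled pair: normalized column sums agree
  norm <- normalize_counts(two, sf)
  expect_equal(sum(norm[, "A"]), sum(norm[, "B"]))
})

test_that("size factors match the brute-force median-of-ratios oracle", {
  for (seed in 1:25) {
    m <- random_counts(50, 6, lambda = sample(c(5, 30, 200), 1), seed = seed)
    expect_equal(size_factors(m), bf_size_factors(m), tolerance = 1e-12)
  }
  # all-zero-touching matrix errors with the fallback hint
  z <- random_counts(10, 3, seed = 1)
  z[cbind(1:10, rep_len(1:3, 10))] <- 0L
  expect_error(size_factors(count_matrix(z)), "pseudo_reference")
  expect_silent(size_factors(count_matrix(z), pseudo_reference = TRUE))
})

test_that("size factors agree with DESeq2 up to the geometric-mean rescale", {
  m <- random_counts(81, 8, lambda = 40, seed = 7)  # odd reference count:
  # our linear-median and DESeq2 log-median conventions coincide exactly
  ours <- size_factors(m)
  theirs <- DESeq2::estimateSizeFactorsForMatrix(m)
  theirs <- theirs / exp(mean(log(theirs)))
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-10)
})

test_that("normalize_counts is the exact per-column division", {
  m <- random_counts(20, 4, seed = 3)
  expect_equal(normalize_counts(m, setNames(rep(1, 4), colnames(m))), m)
  f <- setNames(c(1, 2, 1, 1), colnames(m))
  expect_equal(normalize_counts(m, f)[, 2], m[, 2] / 2)
  expect_error(normalize_counts(m, f[-1]), "missing size factors")
})

test_that("BH adjustment matches hand evaluation and p.adjust", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.1, NA)), "finite")
  for (seed in 1:30) {
    set.seed(seed)
    p <- runif(sample(1:200, 1))^sample(1:3, 1)
    a <- bh_adjust(p)
    expect_equal(a, bf_bh(p))
    expect_equal(a, p.adjust(p, "BH"))
    expect_true(all(a >= p - 1e-12 & a <= 1))
    # invariant to input order
    o <- sample(length(p))
    expect_equal(bh_adjust(p[o]), a[o])
  }
})

test_that("nb_wald_test basics: identical groups, swaps, zero genes", {
  m <- random_counts(30, 8, lambda = 60, seed = 5)
  mm <- cbind(m[, 1:4], m[, 1:4])
  colnames(mm) <- paste0("s", 1:8)
  res <- nb_wald_test(count_matrix(mm), paste0("s", 1:4), paste0("s", 5:8))
  expect_equal(res$log2fc, rep(0, 30))
  expect_equal(res$p_value, rep(1, 30), tolerance = 1e-10)
  # swapping groups negates log2fc and preserves p exactly
  m2 <- random_counts(40, 8, lambda = 25, seed = 6)
  a <- nb_wald_test(m2, paste0("s0", 1:4), paste0("s0", 5:8))
  b <- nb_wald_test(m2, paste0("s0", 5:8), paste0("s0", 1:4))
  expect_equal(a$log2fc, -b$log2fc)
  expect_equal(a$p_value, b$p_value)
  # all-zero genes get the sentinel, not dropped
  m3 <- m2; m3[1:3, ] <- 0L
  r3 <- nb_wald_test(count_matrix(m3), paste0("s0", 1:4), paste0("s0", 5:8))
  expect_true(all(r3$all_zero[1:3]))
  expect_true(all(is.na(r3$log2fc[1:3])))
  expect_equal(r3$p_value[1:3], rep(1, 3))
  expect_equal(nrow(r3), 40)
  expect_error(nb_wald_test(m2, "s01", paste0("s0", 5:8)), ">= 2 samples")
  expect_error(nb_wald_test(m2, paste0("s0", 1:4), paste0("s0", 4:6)), "disjoint")
})

test_that("fold_change_table applies the time-0 convention and day matching", {
  w <- small_treatment_world(seed = 13, nb_dispersion = 0)
  ft <- fold_change_table(w$sim$counts, w$sim$sheet)
  expect_setequal(unique(ft$context), c("HU", "HS", "Col"))
  # day 0 forced to fold 1 / log2fc 0 regardless of counts
  expect_true(all(ft$fold[ft$timepoint_days == 0 & ft$context == "HU"] == 1))
  expect_true(all(ft$log2fc[ft$timepoint_days == 0 & ft$context == "HU"] == 0))
  # terminal flags: HU day 7, HS day 7, Col day 10
  term <- unique(ft[ft$terminal, c("context", "timepoint_days")])
  expect_equal(term$timepoint_days[match(c("HU", "HS", "Col"), term$context)],
               c(7, 7, 10))
  # noise-free: unresponsive genes sit at fold ~1, planted plasticity genes
  # recover their ramp monotonically
  un <- w$programs$gene_id[w$programs$treatment_class == "unresponsive"]
  expect_equal(ft$fold[ft$gene_id %in% un & ft$terminal],
               rep(1, 3 * length(un)), tolerance = 0.05)
  up <- w$programs$gene_id[w$programs$treatment_class == "plasticity_up"]
  hu <- ft[ft$context == "HU" & ft$gene_id %in% up, ]
  hu <- hu[order(hu$gene_id, hu$timepoint_days), ]
  expect_true(all(tapply(hu$log2fc, hu$gene_id, function(x) all(diff(x) >= 0))))
  expect_equal(ft$fold[ft$context == "HU" & ft$timepoint_days == 7 &
                         ft$gene_id %in% up],
               rep(4, length(up)), tolerance = 0.05)
  # missing matched control is a hard error naming the timepoint
  broken <- w$sim$sheet[!(w$sim$sheet$condition == "control" &
                            w$sim$sheet$timepoint_days == 10), ]
  expect_error(fold_change_table(w$sim$counts[, broken$sample_id], broken),
               "no matched control")
})

test_that("treatment_size_factors removes ablation composition bias", {
  w <- small_treatment_world(seed = 19)
  sf_plain <- size_factors(w$sim$counts)
  sf_stable <- treatment_size_factors(w$sim$counts, w$sim$sheet)
  un <- w$programs$gene_id[w$programs$treatment_class == "unresponsive"]
  bias <- function(sf) {
    ft <- fold_change_table(w$sim$counts, w$sim$sheet, factors = sf)
    mean(log(ft$fold[ft$terminal & ft$gene_id %in% un]))
  }
  expect_lt(abs(bias(sf_stable)), abs(bias(sf_plain)))
  expect_lt(abs(bias(sf_stable)), 0.1)
})
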