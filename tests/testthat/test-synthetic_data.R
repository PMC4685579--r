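noise_free <- function(...) simulation_design(nb_dispersion = 0,
                                              library_size_log_sd = 0, ...)

test_that("noise-free limits reproduce the truth templates exactly", {
  pg <- small_programs(60, 20, seed = 3)
  # spatial: counts equal rounded template means
  sp <- simulate_spatial(noise_free(), pg)
  mu <- as.matrix(sp$truth[, axial_regions()])
  for (r in axial_regions()) {
    cols <- sp$sheet$sample_id[sp$sheet$condition == r]
    expect_equal(unname(sp$counts[, cols[1]]), unname(round(mu[, r])))
  }
  # treatment: counts equal rounded base_mean x truth fold
  tr <- simulate_treatment(noise_free(), pg)
  truth <- tr$truth
  one <- tr$sheet[tr$sheet$condition == "Col", ]
  fold <- truth$true_fold[truth$condition == "Col"]
  expect_equal(unname(tr$counts[, one$sample_id[1]]),
               unname(round(pg$base_mean * fold)))
  # controls sit at baseline
  ctl <- tr$sheet$sample_id[tr$sheet$condition == "control"][1]
  expect_equal(unname(tr$counts[, ctl]), unname(round(pg$base_mean)))
  # celltype: counts equal rounded expected class means
  ct <- simulate_celltype(noise_free(), pg)
  for (fr in c("ecto", "endo", "icell", "unsorted")) {
    col <- ct$sheet$sample_id[ct$sheet$condition == fr][1]
    expect_equal(unname(ct$counts[, col]),
                 unname(round(ct$truth[[paste0("mu_", fr)]])))
  }
})

test_that("truth tables encode the stated biology", {
  pg <- small_programs(50, 10, seed = 5)
  tmpl <- spatial_templates()
  # bipolar template: both extremities above the centre
  expect_gt(tmpl["bipolar", "H"], tmpl["bipolar", "R3"])
  expect_gt(tmpl["bipolar", "F"], tmpl["bipolar", "R3"])
  tr <- simulate_treatment(noise_free(), pg)$truth
  gland <- pg$gene_id[pg$treatment_class == "gland_signature"]
  # gland genes: 5% residual after colchicine, stable or elevated in HU
  gl_col <- tr[tr$condition == "Col" & tr$gene_id %in% gland, ]
  expect_true(all(gl_col$true_fold == 0.05))
  gl_hu7 <- tr[tr$condition == "HU" & tr$timepoint_days == 7 &
                 tr$gene_id %in% gland, ]
  expect_true(all(gl_hu7$true_fold >= 1 & gl_hu7$true_fold <= 1.5))
  # plasticity genes reach their planted fold at the HU terminal timepoint,
  # monotonically
  up <- pg$gene_id[pg$treatment_class == "plasticity_up"]
  hu <- tr[tr$condition == "HU" & tr$gene_id %in% up, ]
  hu <- hu[order(hu$gene_id, hu$timepoint_days), ]
  expect_true(all(hu$true_fold[hu$timepoint_days == 7] == 4))
  by_gene <- split(hu$true_fold, hu$gene_id)
  expect_true(all(vapply(by_gene, function(x) all(diff(x) > 0), TRUE)))
  # icell genes end at the residual everywhere
  ic <- tr[tr$gene_id %in% pg$gene_id[pg$treatment_class == "icell_lost"] &
             ((tr$condition == "HU" & tr$timepoint_days == 7) |
                tr$condition %in% c("HS", "Col")), ]
  expect_true(all(ic$true_fold == 0.05))
  # every gene has exactly one label per axis
  expect_true(all(table(pg$gene_id) == 1))
  expect_false(any(is.na(pg$spatial_class) | is.na(pg$treatment_class) |
                     is.na(pg$true_celltype)))
})

test_that("celltype contamination model has exact closed-form expectations", {
  pg <- small_programs(40, 10, seed = 2)
  ct <- simulate_celltype(noise_free(), pg)
  th <- ct$truth
  gland <- th[th$true_celltype == "gland", ]
  expect_equal(gland$mu_endo, 0.08 * gland$mu_unsorted)
  expect_true(all(gland$mu_ecto == 0 & gland$mu_icell == 0))
  icell <- th[th$true_celltype == "icell", ]
  expect_true(all(icell$mu_ecto == 0 & icell$mu_endo == 0))
  both <- th[th$true_celltype == "both_epithelial", ]
  expect_equal(both$mu_ecto, both$mu_endo)
  nerve <- th[th$true_celltype == "nerve", ]
  expect_equal(nerve$mu_ecto, 0.05 * nerve$mu_unsorted)
})

test_that("generators are deterministic under a fixed seed", {
  pg <- default_gene_programs(n_unresponsive = 966, seed = 9)
  d <- simulation_design(rng_seed = 17)
  expect_identical(simulate_spatial(d, pg)$counts, simulate_spatial(d, pg)$counts)
  expect_identical(simulate_treatment(d, pg)$counts,
                   simulate_treatment(d, pg)$counts)
  expect_identical(simulate_celltype(d, pg)$counts,
                   simulate_celltype(d, pg)$counts)
  expect_identical(simulate_morphometry(5, list(a = c(1, 0.2)), seed = 3),
                   simulate_morphometry(5, list(a = c(1, 0.2)), seed = 3))
})

test_that("NB draws match their moment parameterization", {
  pg <- default_gene_programs(n_unresponsive = 9966, seed = 8)
  sim <- simulate_spatial(simulation_design(library_size_log_sd = 0,
                                            rng_seed = 21), pg)
  ub <- pg$spatial_class == "ubiquitous"
  col <- sim$counts[ub, sim$sheet$sample_id[sim$sheet$condition == "R1"][1]]
  mu <- sim$truth[ub, "R1"]
  # pooled z-scores over ~5k draws: mean ~ 0, variance ~ mu + 0.1 mu^2
  z <- (col - mu) / sqrt(mu + 0.1 * mu^2)
  expect_lt(abs(mean(z)), 0.05)
  expect_lt(abs(mean(z^2) - 1), 0.1)
})

test_that("simulate_morphometry honours group parameters", {
  flat <- simulate_morphometry(10, list(g1 = c(1.4, 0), g2 = c(2, 0)), seed = 1)
  expect_equal(basal_index(flat$rf_length, flat$diameter)[flat$group == "g1"],
               rep(1.4, 10))
  expect_true(all(flat$diameter > 0))
  # calibration: equal groups are non-significant at alpha 0.05 in >= 93% of
  # 1000 seeded replicates
  reject <- vapply(1:1000, function(s) {
    mm <- simulate_morphometry(8, list(a = c(1.5, 0.3), b = c(1.5, 0.3)), seed = s)
    compare_groups(mm, "a", "b")$welch_p <= 0.05
  }, TRUE)
  expect_gte(mean(!reject), 0.93)
})
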