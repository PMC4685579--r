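# Synthetic-data generators for the three experimental designs.
#
# Every generator draws negative-binomial counts around closed-form expected
# values ("truth") so downstream classifiers have an exact recovery surface.
# Dispersion 0 together with library_size_log_sd 0 is the noise-free limit:
# counts equal the rounded truth means exactly.

#' Default gene programs
#'
#' Builds the per-gene ground-truth table: cell type of origin, axial pattern
#' class, treatment-response class, baseline expression and (for plasticity
#' genes) the planted up-regulation fold. Defaults mirror the structure of the
#' study's candidate sets — 25 epithelial plasticity genes and 9 gland-signature
#' genes planted among i-cell-restricted and unresponsive background genes.
#'
#' @param n_unresponsive Number of background genes with no treatment response.
#' @param n_icell_lost Genes of the interstitial lineage (i-cells + neurons)
#'   that collapse under all three ablation arms.
#' @param n_gland Gland-cell genes (eliminated by colchicine only).
#' @param n_plasticity Epithelial plasticity genes, split ~40/40/20 across
#'   ecto / endo / both epithelial layers.
#' @param spatial_counts Named integer vector: genes per axial pattern class;
#'   remaining genes are ubiquitous.
#' @param up_fold_effect Planted fold for plasticity genes (>= 1).
#' @param base_mean_meanlog,base_mean_sdlog Log-normal parameters of baseline
#'   expression (expected normalized count in the gene's home context).
#' @param seed RNG seed for the base-mean draw.
#' @return data.frame: gene_id, true_celltype, spatial_class, treatment_class,
#'   base_mean, up_fold_effect.
#' @export
default_gene_programs <- function(n_unresponsive = 766, n_icell_lost = 200,
                                  n_gland = 9, n_plasticity = 25,
                                  spatial_counts = c(apical = 80, basal = 60,
                                                     foot_restricted = 40, bipolar = 80,
                                                     graded_apical_to_basal = 70,
                                                     graded_basal_to_apical = 70,
                                                     apolar = 150),
                                  up_fold_effect = 4,
                                  base_mean_meanlog = log(150),
                                  base_mean_sdlog = 0.6,
                                  seed = 1L) {
  n <- n_unresponsive + n_icell_lost + n_gland + n_plasticity
  n_ecto <- round(0.4 * n_plasticity); n_endo <- round(0.4 * n_plasticity)
  n_both <- n_plasticity - n_ecto - n_endo
  n_nerve <- round(0.3 * n_icell_lost)
  treatment_class <- c(rep("plasticity_up", n_plasticity),
                       rep("gland_signature", n_gland),
                       rep("icell_lost", n_icell_lost),
                       rep("unresponsive", n_unresponsive))
  true_celltype <- c(rep(c("ecto", "endo", "both_epithelial"), c(n_ecto, n_endo, n_both)),
                     rep("gland", n_gland),
                     rep(c("icell", "nerve"), c(n_icell_lost - n_nerve, n_nerve)),
                     rep(c("ecto", "endo", "both_epithelial", "gland"),
                         length.out = n_unresponsive))
  if (sum(spatial_counts) > n)
    stop("spatial_counts exceed total gene number", call. = FALSE)
  spatial_class <- rep("ubiquitous", n)
  idx <- seq_len(sum(spatial_counts))
  spatial_class[idx] <- rep(names(spatial_counts), spatial_counts)
  set.seed(seed)
  # interleave spatial classes across treatment classes deterministically
  spatial_class <- spatial_class[sample.int(n)]
  base_mean <- stats::rlnorm(n, base_mean_meanlog, base_mean_sdlog)
  data.frame(
    gene_id = sprintf("g%04d", seq_len(n)),
    true_celltype = true_celltype,
    spatial_class = spatial_class,
    treatment_class = treatment_class,
    base_mean = base_mean,
    up_fold_effect = ifelse(treatment_class == "plasticity_up", up_fold_effect, 1),
    stringsAsFactors = FALSE
  )
}

#' Simulation design parameters
#'
#' @param nb_dispersion Shared NB dispersion (variance = mu + a*mu^2); 0 is the
#'   deterministic noise-free limit.
#' @param library_size_log_sd SD of per-sample log-normal library factors.
#' @param spatial_replicates Replicates per axial region.
#' @param treatment_replicates Named integer vector over the 10 treatment
#'   groups; the default totals 37 samples (controls starved 3/4/6/10 d at 4
#'   replicates, HU days 0/1/3/7 at 3/3/3/4, HS day 7 and Col day 10 at 4).
#' @param celltype_replicates Replicates per FACS fraction.
#' @param unsorted_replicates Unsorted body-column samples.
#' @param contamination List of `fraction = list(source=, level=)` entries; a
#'   foreign gene appears in a sorted fraction at `level` times its expected
#'   level in unsorted tissue. Defaults: gland into endo at 0.08, nerve into
#'   ecto at 0.05.
#' @param tissue_proportions Cell-type proportions of unsorted body column;
#'   i-cells at 23% of total cells, within the 20-26% homeostatic range.
#' @param icell_trajectory_hu Multiplicative truth trajectory of i-cell-lineage
#'   genes over the HU timepoints, relative to matched controls.
#' @param icell_residual Terminal residual of i-cell genes in HS and Col.
#' @param gland_col_residual Residual of gland genes in the colchicine arm.
#' @param gland_hs_hu_range "Stable or elevated" fold range for gland genes in
#'   HU/HS, drawn once per gene.
#' @param hu_days,hs_day,col_day,control_days Sampling timepoints (days
#'   post-treatment; controls are matched starvation durations).
#' @param rng_seed Seed used by every generator unless overridden.
#' @return Named list with class `"hydraplast_design"`.
#' @export
simulation_design <- function(nb_dispersion = 0.1, library_size_log_sd = 0.15,
                              spatial_replicates = 3,
                              treatment_replicates = c(control_3 = 4, control_4 = 4,
                                                       control_6 = 4, control_10 = 4,
                                                       HU_0 = 3, HU_1 = 3, HU_3 = 3, HU_7 = 4,
                                                       HS_7 = 4, Col_10 = 4),
                              celltype_replicates = 4, unsorted_replicates = 2,
                              contamination = list(
                                endo = list(source = "gland", level = 0.08),
                                ecto = list(source = "nerve", level = 0.05)),
                              tissue_proportions = c(ecto = 0.30, endo = 0.30,
                                                     icell = 0.23, nerve = 0.07,
                                                     gland = 0.10),
                              icell_trajectory_hu = c(0.6, 0.35, 0.15, 0.05),
                              icell_residual = 0.05,
                              gland_col_residual = 0.05,
                              gland_hs_hu_range = c(1.0, 1.5),
                              hu_days = c(0, 1, 3, 7), hs_day = 7, col_day = 10,
                              control_days = c(3, 4, 6, 10),
                              rng_seed = 1L) {
  d <- as.list(environment())
  lv <- vapply(d$contamination, function(x) x$level, 0)
  if (any(lv < 0 | lv > 1)) stop("contamination levels must be in [0,1]", call. = FALSE)
  src <- vapply(d$contamination, function(x) x$source, "")
  if (any(!src %in% names(d$tissue_proportions)))
    stop("contamination source must be a known cell type", call. = FALSE)
  if (any(d$treatment_replicates < 2) || d$spatial_replicates < 2 ||
        d$celltype_replicates < 2)
    stop("replicate counts must be >= 2", call. = FALSE)
  if (length(d$icell_trajectory_hu) != length(d$hu_days))
    stop("icell_trajectory_hu must cover every HU timepoint", call. = FALSE)
  if (abs(sum(d$tissue_proportions) - 1) > 1e-8)
    stop("tissue_proportions must sum to 1", call. = FALSE)
  structure(d, class = "hydraplast_design")
}

# NB draw around mu; dispersion 0 is the documented deterministic limit.
nb_draw <- function(mu, dispersion) {
  if (dispersion == 0) return(round(mu))
  stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
}

lib_factors <- function(n, log_sd) {
  if (log_sd == 0) rep(1, n) else stats::rlnorm(n, 0, log_sd)
}

#' Axial truth templates
#'
#' Relative region means (max = 1) over (H, R1, R3, R4, F) for the eight axial
#' pattern classes. Prototypes are constructed to satisfy the default
#' classifier rules exactly (100% recovery in the noise-free limit); the two
#' graded classes are linear ramps, which keeps their central regions well
#' separated from the polar prototypes under replicate noise.
#'
#' @return 8 x 5 numeric matrix, rownames the class labels.
#' @export
spatial_templates <- function() {
  t <- rbind(
    apical                 = c(1.00, 0.15, 0.05, 0.05, 0.08),
    basal                  = c(0.08, 0.05, 0.10, 0.45, 1.00),
    foot_restricted        = c(0.05, 0.05, 0.05, 0.10, 1.00),
    bipolar                = c(1.00, 0.30, 0.10, 0.30, 1.00),
    graded_apical_to_basal = c(1.00, 0.775, 0.55, 0.325, 0.10),
    graded_basal_to_apical = c(0.10, 0.325, 0.55, 0.775, 1.00),
    apolar                 = c(0.15, 0.90, 1.00, 0.90, 0.15),
    ubiquitous             = c(0.90, 1.00, 1.00, 0.95, 0.85)
  )
  colnames(t) <- axial_regions()
  t
}

#' Simulate the axial (spatial) design
#'
#' Five regions H, R1, R3, R4, F with `spatial_replicates` biological replicates
#' each. Per gene, region means follow its class template scaled by
#' `base_mean`, multiplied by per-sample library factors, then NB-sampled.
#'
#' @param design [simulation_design()].
#' @param programs Gene-program table ([default_gene_programs()]).
#' @param seed Overrides `design$rng_seed`.
#' @return list(counts, sheet, truth) — truth holds the per-region expected
#'   (pre-library) means and the template class per gene.
#' @export
simulate_spatial <- function(design = simulation_design(),
                             programs = default_gene_programs(),
                             seed = design$rng_seed) {
  set.seed(seed)
  regions <- axial_regions()
  reps <- design$spatial_replicates
  if (reps < 1) stop("zero replicate count", call. = FALSE)
  tmpl <- spatial_templates()
  bad <- setdiff(unique(programs$spatial_class), rownames(tmpl))
  if (length(bad)) stop("unknown spatial_class: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  mu_region <- tmpl[programs$spatial_class, , drop = FALSE] * programs$base_mean
  dimnames(mu_region) <- list(programs$gene_id, regions)
  sheet <- data.frame(
    sample_id = paste0(rep(regions, each = reps), "_r", rep(seq_len(reps), length(regions))),
    experiment = "spatial",
    condition = rep(regions, each = reps),
    replicate = rep(seq_len(reps), length(regions)),
    stringsAsFactors = FALSE
  )
  lf <- lib_factors(nrow(sheet), design$library_size_log_sd)
  mu <- mu_region[, sheet$condition, drop = FALSE] %*% diag(lf)
  counts <- matrix(nb_draw(mu, design$nb_dispersion), nrow = nrow(mu),
                   dimnames = list(programs$gene_id, sheet$sample_id))
  truth <- data.frame(gene_id = programs$gene_id,
                      spatial_class = programs$spatial_class,
                      mu_region, check.names = FALSE, stringsAsFactors = FALSE)
  list(counts = count_matrix(counts), sheet = sample_sheet(sheet, counts), truth = truth)
}

# Truth fold (vs day-matched control) per gene x treatment group.
treatment_truth_folds <- function(design, programs) {
  grp <- treatment_groups(design)
  tg <- grp[grp$condition != "control", ]
  folds <- matrix(1, nrow(programs), nrow(tg),
                  dimnames = list(programs$gene_id,
                                  paste0(tg$condition, "_", tg$timepoint_days)))
  hu_cols <- paste0("HU_", design$hu_days)
  hs_col <- paste0("HS_", design$hs_day); col_col <- paste0("Col_", design$col_day)
  icell <- programs$treatment_class == "icell_lost"
  folds[icell, hu_cols] <- rep(design$icell_trajectory_hu, each = sum(icell))
  folds[icell, hs_col] <- design$icell_residual
  folds[icell, col_col] <- design$icell_residual
  gland <- programs$treatment_class == "gland_signature"
  if (any(gland)) {
    # "stable or elevated" in HU/HS: one fold per gene, uniform in the range
    gl_fold <- stats::runif(sum(gland), design$gland_hs_hu_range[1],
                            design$gland_hs_hu_range[2])
    for (cc in c(hu_cols, hs_col)) folds[gland, cc] <- gl_fold
    folds[gland, paste0("HU_", 0)] <- 1  # nothing has happened yet at day 0
    folds[gland, col_col] <- design$gland_col_residual
  }
  up <- programs$treatment_class == "plasticity_up"
  if (any(up)) {
    f <- programs$up_fold_effect[up]
    for (i in seq_along(design$hu_days))
      folds[up, hu_cols[i]] <- f ^ (design$hu_days[i] / max(design$hu_days))
    folds[up, hs_col] <- f
    folds[up, col_col] <- f
  }
  folds
}

treatment_groups <- function(design) {
  nm <- names(design$treatment_replicates)
  parts <- strsplit(nm, "_", fixed = TRUE)
  data.frame(group = nm,
             condition = vapply(parts, `[`, "", 1),
             timepoint_days = as.numeric(vapply(parts, `[`, "", 2)),
             replicates = unname(design$treatment_replicates),
             stringsAsFactors = FALSE)
}

#' Simulate the ablation (treatment) design
#'
#' Body-column samples from starved controls (3/4/6/10 d) and the HU (days
#' 0/1/3/7 post-treatment), HS (day 7) and Col (day 10) arms — 37 samples under
#' the default replicate layout. Truth folds relative to day-matched controls:
#' i-cell-lineage genes decay to a 5% residual, gland genes collapse only under
#' colchicine and stay stable-or-elevated in HU/HS, plasticity genes ramp
#' monotonically to their planted fold, background genes stay flat.
#'
#' @inheritParams simulate_spatial
#' @return list(counts, sheet, truth) — truth is long-format: gene_id,
#'   treatment_class, condition, timepoint_days, true_fold.
#' @export
simulate_treatment <- function(design = simulation_design(),
                               programs = default_gene_programs(),
                               seed = design$rng_seed) {
  set.seed(seed)
  grp <- treatment_groups(design)
  folds <- treatment_truth_folds(design, programs)
  sheet <- do.call(rbind, lapply(seq_len(nrow(grp)), function(i) {
    data.frame(sample_id = paste0(grp$group[i], "_r", seq_len(grp$replicates[i])),
               experiment = "treatment", condition = grp$condition[i],
               timepoint_days = grp$timepoint_days[i],
               replicate = seq_len(grp$replicates[i]), stringsAsFactors = FALSE)
  }))
  gkey <- paste0(sheet$condition, "_", sheet$timepoint_days)
  mu_group <- cbind(folds, matrix(1, nrow(folds), sum(grp$condition == "control"),
                                  dimnames = list(NULL, grp$group[grp$condition == "control"])))
  mu_group <- mu_group * programs$base_mean
  lf <- lib_factors(nrow(sheet), design$library_size_log_sd)
  mu <- mu_group[, gkey, drop = FALSE] %*% diag(lf)
  counts <- matrix(nb_draw(mu, design$nb_dispersion), nrow = nrow(mu),
                   dimnames = list(programs$gene_id, sheet$sample_id))
  tg <- grp[grp$condition != "control", ]
  truth <- do.call(rbind, lapply(seq_len(nrow(tg)), function(i) {
    data.frame(gene_id = programs$gene_id,
               treatment_class = programs$treatment_class,
               condition = tg$condition[i], timepoint_days = tg$timepoint_days[i],
               true_fold = folds[, paste0(tg$condition[i], "_", tg$timepoint_days[i])],
               stringsAsFactors = FALSE)
  }))
  rownames(truth) <- NULL
  list(counts = count_matrix(counts), sheet = sample_sheet(sheet, counts), truth = truth)
}

# Expected (pre-library) level of each gene in each cell-type sample class.
celltype_truth_means <- function(design, programs) {
  p <- design$tissue_proportions
  home <- list(ecto = "ecto", endo = "endo", icell = "icell")
  n <- nrow(programs)
  unsorted <- programs$base_mean * ifelse(
    programs$true_celltype == "both_epithelial", p["ecto"] + p["endo"],
    p[programs$true_celltype])
  m <- matrix(0, n, 4, dimnames = list(programs$gene_id,
                                       c("ecto", "endo", "icell", "unsorted")))
  m[, "unsorted"] <- unsorted
  for (fr in names(home)) {
    is_home <- programs$true_celltype == home[[fr]] |
      (fr %in% c("ecto", "endo") & programs$true_celltype == "both_epithelial")
    m[is_home, fr] <- programs$base_mean[is_home]
    cont <- design$contamination[[fr]]
    if (!is.null(cont)) {
      is_src <- programs$true_celltype == cont$source & !is_home
      m[is_src, fr] <- cont$level * unsorted[is_src]
    }
  }
  m
}

#' Simulate the FACS cell-type design
#'
#' Sorted ecto / endo / i-cell fractions plus unsorted body column. A gene is
#' expressed at `base_mean` in its home fraction(s); it leaks into a foreign
#' fraction only through the configured contamination, at `level` times its
#' expected level in unsorted tissue (applied to expected counts before NB
#' sampling, so the closed-form truth is exact).
#'
#' @inheritParams simulate_spatial
#' @return list(counts, sheet, truth) — truth holds expected levels per
#'   fraction and in unsorted tissue.
#' @export
simulate_celltype <- function(design = simulation_design(),
                              programs = default_gene_programs(),
                              seed = design$rng_seed) {
  set.seed(seed)
  mu_class <- celltype_truth_means(design, programs)
  reps <- c(ecto = design$celltype_replicates, endo = design$celltype_replicates,
            icell = design$celltype_replicates, unsorted = design$unsorted_replicates)
  sheet <- do.call(rbind, lapply(names(reps), function(fr) {
    data.frame(sample_id = paste0(fr, "_r", seq_len(reps[fr])),
               experiment = "celltype", condition = fr,
               replicate = seq_len(reps[fr]), stringsAsFactors = FALSE)
  }))
  lf <- lib_factors(nrow(sheet), design$library_size_log_sd)
  mu <- mu_class[, sheet$condition, drop = FALSE] %*% diag(lf)
  counts <- matrix(nb_draw(mu, design$nb_dispersion), nrow = nrow(mu),
                   dimnames = list(programs$gene_id, sheet$sample_id))
  truth <- data.frame(gene_id = programs$gene_id,
                      true_celltype = programs$true_celltype,
                      treatment_class = programs$treatment_class,
                      mu_class, check.names = FALSE, stringsAsFactors = FALSE)
  names(truth)[match(c("ecto", "endo", "icell", "unsorted"), names(truth))] <-
    c("mu_ecto", "mu_endo", "mu_icell", "mu_unsorted")
  list(counts = count_matrix(counts), sheet = sample_sheet(sheet, counts), truth = truth)
}

#' Simulate RFamide basal-index measurements
#'
#' Draws per-animal (RFamide-positive peduncle length, peduncle diameter) pairs
#' such that the index = length/diameter has the requested group mean and SD
#' exactly in distribution: index ~ Normal(mean, sd) truncated at 0 (negative
#' draws are resampled), diameter ~ Normal(1.5, 0.15) truncated positive,
#' length = index * diameter. With sd = 0 every index equals the group mean.
#'
#' @param n_per_group Animals per group (>= 2).
#' @param group_params Named list of `c(mean, sd)` per group.
#' @param seed RNG seed.
#' @return data.frame: animal_id, group, rf_length, diameter, true_index.
#' @export
simulate_morphometry <- function(n_per_group, group_params, seed = 1L) {
  set.seed(seed)
  stopifnot(n_per_group >= 2)
  draw_trunc <- function(n, mean, sd, lower) {
    if (sd == 0) return(rep(mean, n))
    x <- stats::rnorm(n, mean, sd)
    while (any(bad <- x <= lower)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
    x
  }
  out <- lapply(names(group_params), function(g) {
    p <- group_params[[g]]
    if (p[2] < 0) stop("sd must be >= 0", call. = FALSE)
    idx <- draw_trunc(n_per_group, p[1], p[2], lower = -Inf)
    idx[idx < 0] <- 0  # index is a ratio of non-negative lengths
    diam <- draw_trunc(n_per_group, 1.5, 0.15, lower = 0)
    data.frame(animal_id = paste0(g, "_a", seq_len(n_per_group)), group = g,
               rf_length = idx * diam, diameter = diam, true_index = idx,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
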