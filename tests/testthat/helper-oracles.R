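# Independent brute-force oracles. Each is a direct transcription of the
# defining formula, deliberately naive and separate from the package code
# paths it checks.

bf_size_factors <- function(m) {
  ref <- apply(m, 1, function(x) all(x > 0))
  gm <- apply(m[ref, , drop = FALSE], 1, function(x) prod(x)^(1 / length(x)))
  sf <- sapply(seq_len(ncol(m)), function(j)
    median(m[ref, j] / gm))
  sf <- sf / prod(sf)^(1 / length(sf))
  setNames(sf, colnames(m))
}

bf_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  running <- 1
  for (i in n:1) {
    running <- min(running, p[o[i]] * n / i)
    adj[o[i]] <- running
  }
  adj
}

bf_ternary <- function(norm, cols_by_frac, pc) {
  gm <- sapply(cols_by_frac, function(cols) {
    apply(norm[, cols, drop = FALSE], 1, function(x)
      max(exp(mean(log(x + pc))) - pc, 0))
  })
  tot <- rowSums(gm)
  list(fractions = gm / tot, magnitude = tot)
}

bf_venn <- function(up_hu, up_hs, up_col) {
  # plain set algebra on gene-id character vectors
  c(HU_only = length(setdiff(up_hu, union(up_hs, up_col))),
    HS_only = length(setdiff(up_hs, union(up_hu, up_col))),
    Col_only = length(setdiff(up_col, union(up_hu, up_hs))),
    HU_HS = length(setdiff(intersect(up_hu, up_hs), up_col)),
    HU_Col = length(setdiff(intersect(up_hu, up_col), up_hs)),
    HS_Col = length(setdiff(intersect(up_hs, up_col), up_hu)),
    HU_HS_Col = length(intersect(up_hu, intersect(up_hs, up_col))))
}

bf_welch <- function(x, y) {
  sx2 <- sum((x - mean(x))^2) / (length(x) - 1)
  sy2 <- sum((y - mean(y))^2) / (length(y) - 1)
  ax <- sx2 / length(x); ay <- sy2 / length(y)
  t <- (mean(x) - mean(y)) / sqrt(ax + ay)
  df <- (ax + ay)^2 / (ax^2 / (length(x) - 1) + ay^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

bf_f <- function(x, y) {
  f <- var(x) / var(y)
  pl <- pf(f, length(x) - 1, length(y) - 1)
  list(f = f, p = min(1, 2 * min(pl, 1 - pl)))
}

# two-sided permutation p of the Welch statistic (vectorized over resamples)
perm_welch_p <- function(x, y, n_perm, seed = 1) {
  set.seed(seed)
  obs <- abs(bf_welch(x, y)$t)
  z <- c(x, y); n <- length(z); nx <- length(x); ny <- length(y)
  idx <- vapply(seq_len(n_perm), function(b) sample.int(n, nx), integer(nx))
  xs <- matrix(z[idx], nx)
  sum_all <- sum(z); ss_all <- sum(z^2)
  mx <- colMeans(xs)
  vx <- (colSums(xs^2) - nx * mx^2) / (nx - 1)
  my <- (sum_all - nx * mx) / ny
  vy <- (ss_all - colSums(xs^2) - ny * my^2) / (ny - 1)
  t <- (mx - my) / sqrt(vx / nx + vy / ny)
  mean(abs(t) >= obs - 1e-12)
}

# small random count matrix with guaranteed zero-free rows
random_counts <- function(n_genes, n_samples, lambda = 30, seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_samples, lambda) + 1L, n_genes,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  count_matrix(m)
}

small_programs <- function(n_unresponsive, n_icell_lost = 20, seed = 1, ...) {
  default_gene_programs(n_unresponsive = n_unresponsive,
                        n_icell_lost = n_icell_lost, seed = seed,
                        spatial_counts = c(apical = 8, basal = 8,
                                           foot_restricted = 4, bipolar = 8,
                                           graded_apical_to_basal = 8,
                                           graded_basal_to_apical = 8,
                                           apolar = 10), ...)
}

# compact treatment world for signature tests: fast, few genes
small_treatment_world <- function(seed = 11, nb_dispersion = 0.1) {
  programs <- default_gene_programs(n_unresponsive = 120, n_icell_lost = 40,
                                    n_gland = 9, n_plasticity = 25,
                                    spatial_counts = c(apical = 10, basal = 10,
                                                       foot_restricted = 5, bipolar = 10,
                                                       graded_apical_to_basal = 10,
                                                       graded_basal_to_apical = 10,
                                                       apolar = 20),
                                    seed = seed)
  design <- simulation_design(nb_dispersion = nb_dispersion, rng_seed = seed)
  list(programs = programs, design = design,
       sim = simulate_treatment(design, programs))
}
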