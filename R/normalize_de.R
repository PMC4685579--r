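# Median-of-ratios normalization and a simplified negative-binomial Wald test
# with Benjamini-Hochberg FDR. This deliberately does not replicate the full
# DESeq2 machinery (shrinkage priors, Cook's filtering, independent filtering):
# the downstream selection rules depend on fold thresholds and an FDR cut, and
# numerical parity with DESeq2 is an explicit non-goal.

#' Median-of-ratios size factors
#'
#' Per sample: the median, over reference genes, of count / (gene's geometric
#' mean across samples). The reference set is the genes with no zero in any
#' sample; with `pseudo_reference = TRUE` the geometric means are instead taken
#' over positive counts only, which rescues matrices where every gene touches a
#' zero. Factors are rescaled to geometric mean exactly 1 so repeated
#' normalization cannot drift the global scale.
#'
#' @param counts Validated count matrix.
#' @param pseudo_reference Fall back to positive-count geometric means.
#' @return Named positive numeric vector over samples.
#' @export
size_factors <- function(counts, pseudo_reference = FALSE) {
  validate_count_matrix(counts)
  lg <- log(counts)
  if (!pseudo_reference) {
    ref <- rowSums(counts > 0) == ncol(counts)
    if (!any(ref))
      stop("no gene is nonzero in every sample; rerun with pseudo_reference = TRUE",
           call. = FALSE)
    gm <- exp(rowMeans(lg[ref, , drop = FALSE]))
    sf <- apply(counts[ref, , drop = FALSE], 2, function(x) stats::median(x / gm))
  } else {
    lgm <- apply(lg, 1, function(x) mean(x[is.finite(x)]))
    ok <- is.finite(lgm)
    if (!any(ok)) stop("count matrix is all zero", call. = FALSE)
    gm <- exp(lgm[ok])
    sf <- apply(counts[ok, , drop = FALSE], 2, function(x) {
      r <- x / gm
      stats::median(r[x > 0])
    })
  }
  sf <- sf / exp(mean(log(sf)))
  stats::setNames(sf, colnames(counts))
}

#' Treatment-design size factors on a stable reference set
#'
#' Two-pass median-of-ratios fit. When a large fraction of the transcriptome
#' collapses under ablation (the interstitial lineage alone can be a fifth of
#' all genes), a single global median-of-ratios fit is composition-biased: the
#' per-gene geometric means are dragged down by the treated arms, control
#' samples look inflated, and every treated-over-control fold inherits an
#' upward shift. The second pass therefore refits the factors on the half of
#' the zero-free genes whose group means (log scale) vary least across the
#' condition-timepoint groups — in practice the treatment-unresponsive genes.
#'
#' @param counts Treatment-design count matrix.
#' @param sheet Matching sample sheet.
#' @param stable_frac Fraction of zero-free genes kept as reference.
#' @return Named positive numeric vector over samples.
#' @export
treatment_size_factors <- function(counts, sheet, stable_frac = 0.5) {
  validate_sample_sheet(sheet, counts)
  sf0 <- size_factors(counts)
  norm <- normalize_counts(counts, sf0)
  groups <- paste0(sheet$condition, "_", sheet$timepoint_days)
  gm <- vapply(unique(groups), function(g) {
    rowMeans(log(norm[, sheet$sample_id[groups == g], drop = FALSE] + 0.5))
  }, numeric(nrow(counts)))
  spread <- apply(gm, 1, stats::var)
  zero_free <- rowSums(counts > 0) == ncol(counts)
  cand <- which(zero_free)
  keep <- cand[spread[cand] <= stats::quantile(spread[cand], stable_frac)]
  if (length(keep) < 10) return(sf0)  # too few stable genes to refit
  size_factors(counts[keep, , drop = FALSE])
}

#' Within-group size factors for compositionally disjoint sample classes
#'
#' Median-of-ratios factors computed separately inside each sample group, each
#' group rescaled to geometric mean 1. FACS-sorted fractions express largely
#' disjoint gene sets, so a single global median-of-ratios fit conflates
#' composition with sequencing depth and distorts any fraction-versus-unsorted
#' comparison; within-group fitting removes depth noise while leaving the
#' cross-group scale at the common library scale the designs share. Falls back
#' to the pseudo-reference automatically when a group has no zero-free gene.
#'
#' @param counts Count matrix.
#' @param groups Character vector over samples (e.g. the sheet's condition).
#' @return Named positive numeric vector over samples.
#' @export
size_factors_by_group <- function(counts, groups) {
  stopifnot(length(groups) == ncol(counts))
  sf <- numeric(ncol(counts))
  names(sf) <- colnames(counts)
  for (g in unique(groups)) {
    sel <- groups == g
    sub <- counts[, sel, drop = FALSE]
    f <- tryCatch(size_factors(sub), error = function(e)
      size_factors(sub, pseudo_reference = TRUE))
    sf[sel] <- f
  }
  sf
}

#' Divide counts by their size factors
#'
#' @param counts Count matrix.
#' @param factors Named factors from [size_factors()]; must cover all samples.
#' @return Matrix of non-negative reals, same dimnames.
#' @export
normalize_counts <- function(counts, factors = size_factors(counts)) {
  miss <- setdiff(colnames(counts), names(factors))
  if (length(miss)) stop("missing size factors for: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (any(!is.finite(factors) | factors <= 0))
    stop("size factors must be positive and finite", call. = FALSE)
  sweep(counts, 2, factors[colnames(counts)], "/")
}

#' Benjamini-Hochberg step-up FDR
#'
#' @param p Numeric vector of p-values in `[0,1]`; NaN/NA are errors.
#' @return Adjusted values in `[0,1]`, monotonicity enforced, input order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must be finite and in [0,1]", call. = FALSE)
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

# Gene-wise method-of-moments dispersion from normalized counts in two groups,
# optionally shrunk onto a fitted alpha(mu) = a0 + a1/mu trend ("pooled").
estimate_dispersions <- function(normA, normB, mode, floor) {
  mom_one <- function(m) {
    mu <- rowMeans(m)
    v <- apply(m, 1, stats::var)
    a <- (v - mu) / mu^2
    a[!is.finite(a)] <- NA
    a
  }
  aA <- mom_one(normA); aB <- mom_one(normB)
  a <- rowMeans(cbind(aA, aB), na.rm = TRUE)
  a[!is.finite(a)] <- floor
  a <- pmax(a, floor)
  if (mode == "moments") return(a)
  mu <- rowMeans(cbind(rowMeans(normA), rowMeans(normB)))
  pos <- a > floor & mu > 0
  if (sum(pos) >= 10) {
    fit <- try(stats::lm(a[pos] ~ I(1 / mu[pos])), silent = TRUE)
    co <- if (inherits(fit, "try-error")) c(NA, NA) else pmax(stats::coef(fit), 0)
    if (all(is.finite(co))) {
      fitted <- co[1] + ifelse(mu > 0, co[2] / mu, 0)
      return(pmax(fitted, floor))
    }
  }
  med <- stats::median(a[pos])
  pmax(rep(if (is.finite(med)) med else floor, length(a)), floor)
}

#' Negative-binomial Wald differential-expression test
#'
#' Per gene: NB group means are fitted as means of normalized counts; the
#' dispersion comes from a per-gene method of moments (floored at
#' `dispersion_floor`), in `"pooled"` mode shrunk onto a mean-dispersion trend
#' fitted across all genes (the default — stable at 3-4 replicates). The Wald
#' statistic is log2fc / se with a delta-method standard error and a two-sided
#' normal reference; BH is applied over all tested genes. Genes with all-zero
#' counts in both groups are reported with `log2fc = NA`, `p = 1` (sentinel)
#' rather than dropped, so set totals downstream are conserved.
#'
#' @param counts Count matrix containing both groups.
#' @param group_a,group_b Disjoint sample-id vectors (>= 2 each); `group_a` is
#'   the reference (control): `log2fc = log2(mean_b / mean_a)`.
#' @param dispersion_mode `"pooled"` (default) or `"moments"`.
#' @param factors Size factors; computed on `counts` when omitted.
#' @param config [run_config()] supplying `mean_floor` and `dispersion_floor`.
#' @return data.frame: gene_id, base_mean, log2fc, se_log2fc, stat, p_value,
#'   fdr, all_zero.
#' @export
nb_wald_test <- function(counts, group_a, group_b,
                         dispersion_mode = c("pooled", "moments"),
                         factors = NULL, config = run_config()) {
  dispersion_mode <- match.arg(dispersion_mode)
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each contrast group needs >= 2 samples", call. = FALSE)
  if (length(intersect(group_a, group_b)))
    stop("contrast groups must be disjoint", call. = FALSE)
  miss <- setdiff(c(group_a, group_b), colnames(counts))
  if (length(miss)) stop("samples absent from matrix: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (is.null(factors))
    factors <- size_factors(counts[, c(group_a, group_b), drop = FALSE])
  norm <- normalize_counts(counts[, c(group_a, group_b), drop = FALSE],
                           factors)
  nA <- norm[, group_a, drop = FALSE]; nB <- norm[, group_b, drop = FALSE]
  muA <- rowMeans(nA); muB <- rowMeans(nB)
  alpha <- estimate_dispersions(nA, nB, dispersion_mode, config$dispersion_floor)
  all_zero <- muA == 0 & muB == 0
  fl <- config$mean_floor
  muAf <- pmax(muA, fl); muBf <- pmax(muB, fl)
  log2fc <- log2(muBf / muAf)
  se <- sqrt((1 / muAf + alpha) / length(group_a) +
               (1 / muBf + alpha) / length(group_b)) / log(2)
  stat <- log2fc / se
  p <- 2 * stats::pnorm(-abs(stat))
  log2fc[all_zero] <- NA_real_
  stat[all_zero] <- NA_real_
  p[all_zero] <- 1
  data.frame(gene_id = rownames(counts), base_mean = (muA + muB) / 2,
             log2fc = log2fc, se_log2fc = se, stat = stat, p_value = p,
             fdr = bh_adjust(p), all_zero = all_zero,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-context fold-change table for the treatment design
#'
#' For every context (HU, HS, Col) and sampled timepoint: the linear fold,
#' treated over the day-matched starved control (the mapping lives in
#' `config$control_map`). Replicates are averaged as geometric means of
#' normalized counts (pseudo-count `config$pseudo_count` inside the log,
#' subtracted back out) — the convention used when replicate averaging feeds
#' ratio statistics, and considerably lighter-tailed than a ratio of
#' arithmetic means, so threshold rules downstream see fewer noise-driven
#' crossings. By the study's plotting convention the fold at time 0 is fixed
#' to 1 (log2 fold 0) regardless of counts. Rows at each context's terminal
#' timepoint are flagged; they feed the signature rules. Control levels of
#' zero are floored at `config$mean_floor` so retentions stay defined.
#'
#' @param counts Treatment-design count matrix.
#' @param sheet Matching sample sheet.
#' @param config [run_config()].
#' @param factors Size factors (computed over the full matrix when omitted).
#' @return data.frame: gene_id, context, timepoint_days, control_days, fold,
#'   log2fc, terminal.
#' @export
fold_change_table <- function(counts, sheet, config = run_config(),
                              factors = size_factors(counts)) {
  validate_sample_sheet(sheet, counts)
  if (!all(sheet$experiment == "treatment"))
    stop("fold_change_table requires the treatment design", call. = FALSE)
  norm <- normalize_counts(counts, factors)
  cm <- config$control_map
  out <- lapply(seq_len(nrow(cm)), function(i) {
    ctx <- cm$context[i]; tp <- cm$timepoint_days[i]; cd <- cm$control_days[i]
    tr <- sheet$sample_id[sheet$condition == ctx & sheet$timepoint_days == tp]
    cs <- sheet$sample_id[sheet$condition == "control" & sheet$timepoint_days == cd]
    if (!length(tr)) return(NULL)
    if (!length(cs))
      stop(sprintf("no matched control (starved %s d) for %s day %s", cd, ctx, tp),
           call. = FALSE)
    muT <- geom_mean_rows(norm[, tr, drop = FALSE], config$pseudo_count)
    muC <- pmax(geom_mean_rows(norm[, cs, drop = FALSE], config$pseudo_count),
                config$mean_floor)
    fold <- muT / muC
    if (tp == 0) fold <- rep(1, length(fold))  # time-0 convention
    data.frame(gene_id = rownames(counts), context = ctx, timepoint_days = tp,
               control_days = cd, fold = fold, log2fc = log2(pmax(fold, 1e-12)),
               terminal = tp == unname(config$terminal[ctx]),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, out)
  missing_ctx <- setdiff(names(config$terminal), unique(out$context))
  if (length(missing_ctx))
    stop("contexts absent from design: ", paste(missing_ctx, collapse = ", "),
         call. = FALSE)
  out
}

#' Run the terminal differential-expression contrasts
#'
#' Convenience wrapper: one [nb_wald_test()] per context at its terminal
#' timepoint against the day-matched control, sharing size factors computed on
#' the full treatment matrix.
#'
#' @inheritParams fold_change_table
#' @param dispersion_mode Passed to [nb_wald_test()].
#' @return Named list (HU, HS, Col) of DE result data.frames.
#' @export
terminal_de <- function(counts, sheet, config = run_config(),
                        dispersion_mode = "pooled",
                        factors = size_factors(counts)) {
  cm <- config$control_map
  res <- lapply(names(config$terminal), function(ctx) {
    tp <- unname(config$terminal[ctx])
    cd <- cm$control_days[cm$context == ctx & cm$timepoint_days == tp]
    tr <- sheet$sample_id[sheet$condition == ctx & sheet$timepoint_days == tp]
    cs <- sheet$sample_id[sheet$condition == "control" & sheet$timepoint_days == cd]
    nb_wald_test(counts, group_a = cs, group_b = tr,
                 dispersion_mode = dispersion_mode, factors = factors,
                 config = config)
  })
  stats::setNames(res, names(config$terminal))
}
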