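# Classification of per-gene axial expression profiles over the five body
# regions (H, R1, R3, R4, F) into the verbal pattern taxonomy: apical, basal,
# foot-restricted, bipolar, graded (either direction), apolar (central
# plateau), ubiquitous. The taxonomy is qualitative in origin; the rules here
# are an explicit, tunable encoding with every threshold in run_config().

#' Build per-gene axial profiles
#'
#' Arithmetic means of normalized counts per region (apical-to-basal order),
#' replicate coefficients of variation, and a detection flag (max region mean
#' >= `expression_floor`; below that floor a pattern call is noise).
#'
#' @param counts Spatial-design count matrix.
#' @param sheet Matching sample sheet (>= 2 replicates per region).
#' @param factors Size factors; computed on `counts` when omitted.
#' @param config [run_config()].
#' @return data.frame: gene_id, mean_H..mean_F, cv_H..cv_F, detected.
#' @export
build_profiles <- function(counts, sheet, factors = size_factors(counts),
                           config = run_config()) {
  validate_sample_sheet(sheet, counts)
  if (!all(sheet$experiment == "spatial"))
    stop("build_profiles requires the spatial design", call. = FALSE)
  regions <- axial_regions()
  miss <- setdiff(regions, unique(sheet$condition))
  if (length(miss)) stop("missing region(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  norm <- normalize_counts(counts, factors)
  means <- vapply(regions, function(r) {
    rowMeans(norm[, sheet$sample_id[sheet$condition == r], drop = FALSE])
  }, numeric(nrow(counts)))
  cvs <- vapply(regions, function(r) {
    m <- norm[, sheet$sample_id[sheet$condition == r], drop = FALSE]
    mu <- rowMeans(m)
    sd <- apply(m, 1, stats::sd)
    ifelse(mu > 0, sd / mu, 0)
  }, numeric(nrow(counts)))
  out <- data.frame(gene_id = rownames(counts), means, cvs,
                    detected = apply(means, 1, max) >= config$expression_floor,
                    stringsAsFactors = FALSE, row.names = NULL)
  names(out) <- c("gene_id", paste0("mean_", regions), paste0("cv_", regions),
                  "detected")
  out
}

# Largest absolute deviation of p from its best monotone fit in `direction`
# ("dec" = apical-to-basal decrease). Isotonic regression keeps single-step
# noise from breaking gradedness the way a pairwise step test would.
monotone_residual <- function(p, direction) {
  if (direction == "inc") {
    fit <- stats::isoreg(seq_along(p), p)$yf
  } else {
    fit <- rev(stats::isoreg(seq_along(p), rev(p))$yf)
  }
  max(abs(p - fit))
}

#' Classify one axial profile
#'
#' Deterministic rule cascade on the max-normalized profile `p` with
#' `pH = p[H]`, `pF = p[F]`, `core = max(p[R1], p[R3], p[R4])`:
#'
#' 1. foot_restricted: `pF = 1` and everything else `<= foot_max_other`.
#' 2. apical: `pH = 1`, `pF <= polar_far_max`, the adjacent region
#'    `p[R1] <= polar_near_max` and the central region `p[R3] <= polar_mid_max`
#'    (a fast drop on the near side — the joint condition separates a polar
#'    peak from a graded slope far more reliably than either alone).
#' 3. basal: mirror image of apical (conditions on `p[R4]` and `p[R3]`).
#' 4. bipolar: `min(pH, pF) >= bipolar_min` and the central trough
#'    `min(p[R1], p[R3], p[R4]) <= bipolar_trough * min(pH, pF)`.
#' 5. graded (either direction): monotone within `graded_tol` (isotonic-fit
#'    residual) and span `max(p) - min(p) >= graded_span`.
#' 6. apolar: a central region carries the maximum and both extremities are
#'    `<= apolar_extremity_max`.
#' 7. ubiquitous: both extremities at least `flat_min` — the vocabulary is
#'    about expression spreading all the way to the extremities, and the two
#'    extremity shares are far less noisy than the minimum over all five
#'    max-normalized regions.
#' 8. otherwise ambiguous.
#'
#' The score is the margin by which the winning rule clears its tightest
#' threshold, clipped to `[0,1]`; ambiguous and undetected score 0. Calls are
#' invariant to global scaling of the profile.
#'
#' @param region_means Numeric length-5 vector over (H, R1, R3, R4, F).
#' @param config [run_config()].
#' @param detected If `FALSE` the call is `undetected`.
#' @return list(pattern, score).
#' @export
classify_pattern <- function(region_means, config = run_config(), detected = TRUE) {
  if (!detected || max(region_means) <= 0)
    return(list(pattern = "undetected", score = 0))
  p <- region_means / max(region_means)
  pH <- p[1]; pF <- p[5]; core <- p[2:4]
  clip <- function(x) max(0, min(1, x))
  other_max <- function(i) max(p[-i])
  # 1. foot restricted
  if (pF == 1 && other_max(5) <= config$foot_max_other)
    return(list(pattern = "foot_restricted",
                score = clip((config$foot_max_other - other_max(5)) / config$foot_max_other)))
  # 2./3. strictly polar
  if (pH == 1 && pF <= config$polar_far_max && p[2] <= config$polar_near_max &&
        p[3] <= config$polar_mid_max)
    return(list(pattern = "apical",
                score = clip(min((config$polar_far_max - pF) / config$polar_far_max,
                                 (config$polar_near_max - p[2]) / config$polar_near_max,
                                 (config$polar_mid_max - p[3]) / config$polar_mid_max))))
  if (pF == 1 && pH <= config$polar_far_max && p[4] <= config$polar_near_max &&
        p[3] <= config$polar_mid_max)
    return(list(pattern = "basal",
                score = clip(min((config$polar_far_max - pH) / config$polar_far_max,
                                 (config$polar_near_max - p[4]) / config$polar_near_max,
                                 (config$polar_mid_max - p[3]) / config$polar_mid_max))))
  # 4. bipolar
  ext <- min(pH, pF); trough <- min(core)
  if (ext >= config$bipolar_min && trough <= config$bipolar_trough * ext)
    return(list(pattern = "bipolar",
                score = clip(min((ext - config$bipolar_min) / (1 - config$bipolar_min),
                                 (config$bipolar_trough * ext - trough) /
                                   (config$bipolar_trough * ext)))))
  # 5. graded
  span <- max(p) - min(p)
  if (span >= config$graded_span) {
    rd <- monotone_residual(p, "dec"); ri <- monotone_residual(p, "inc")
    if (min(rd, ri) <= config$graded_tol) {
      dir <- if (rd <= ri) "graded_apical_to_basal" else "graded_basal_to_apical"
      return(list(pattern = dir,
                  score = clip(1 - min(rd, ri) / config$graded_tol)))
    }
  }
  # 6. apolar
  if (max(core) == 1 && max(pH, pF) <= config$apolar_extremity_max)
    return(list(pattern = "apolar",
                score = clip((config$apolar_extremity_max - max(pH, pF)) /
                               config$apolar_extremity_max)))
  # 7. ubiquitous
  if (min(pH, pF) >= config$flat_min)
    return(list(pattern = "ubiquitous",
                score = clip((min(pH, pF) - config$flat_min) / (1 - config$flat_min))))
  list(pattern = "ambiguous", score = 0)
}

#' Classify all profiles
#'
#' @param profiles From [build_profiles()].
#' @param config [run_config()].
#' @return data.frame: gene_id, pattern, score.
#' @export
classify_patterns <- function(profiles, config = run_config()) {
  regions <- paste0("mean_", axial_regions())
  m <- as.matrix(profiles[, regions])
  calls <- lapply(seq_len(nrow(m)), function(i)
    classify_pattern(m[i, ], config, detected = profiles$detected[i]))
  data.frame(gene_id = profiles$gene_id,
             pattern = vapply(calls, `[[`, "", "pattern"),
             score = vapply(calls, function(x) as.numeric(x$score), 0),
             stringsAsFactors = FALSE)
}

#' Score pattern recovery against simulation truth
#'
#' @param calls From [classify_patterns()].
#' @param truth Truth table with gene_id and spatial_class (from
#'   [simulate_spatial()]).
#' @return list(confusion, per_class, accuracy): confusion matrix truth x call,
#'   per-class sensitivity/precision, overall accuracy over truth classes.
#' @export
score_spatial_recovery <- function(calls, truth) {
  miss <- setdiff(calls$gene_id, truth$gene_id)
  if (length(miss)) stop("genes absent from truth: ", paste(utils::head(miss, 3),
                                                            collapse = ", "), call. = FALSE)
  tc <- truth$spatial_class[match(calls$gene_id, truth$gene_id)]
  lev <- union(rownames(spatial_templates()),
               unique(c(tc, calls$pattern)))
  confusion <- table(truth = factor(tc, lev), call = factor(calls$pattern, lev))
  diagv <- diag(confusion)
  per_class <- data.frame(
    class = lev,
    n_truth = as.integer(rowSums(confusion)),
    sensitivity = ifelse(rowSums(confusion) > 0, diagv / rowSums(confusion), NA),
    precision = ifelse(colSums(confusion) > 0, diagv / colSums(confusion), NA),
    row.names = NULL
  )
  per_class <- per_class[per_class$n_truth > 0 | !is.na(per_class$precision), ]
  list(confusion = confusion, per_class = per_class,
       accuracy = sum(diagv) / sum(confusion))
}
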