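# Treatment-response signature calling across the three ablation contexts
# (HU, HS, Col), Venn partitioning of up/down gene sets, and the final
# cross-classification joining treatment signatures with cell-type and axial
# pattern calls.

#' Join fold and FDR evidence per gene per context
#'
#' One row per gene per context, carrying the terminal-timepoint linear fold
#' (treated over day-matched control), the same number named `retention` for
#' the down rule, and the FDR from that context's differential-expression
#' contrast. Genes missing from a context carry `present = FALSE` with NA
#' evidence rather than being dropped.
#'
#' @param de_results Named list (HU, HS, Col) of [nb_wald_test()] outputs for
#'   the terminal contrasts (e.g. from [terminal_de()]).
#' @param fold_table From [fold_change_table()].
#' @param config [run_config()].
#' @return data.frame: gene_id, context, final_fold, retention, fdr, present.
#' @export
context_responses <- function(de_results, fold_table, config = run_config()) {
  ctxs <- names(config$terminal)
  miss <- setdiff(ctxs, names(de_results))
  if (length(miss)) stop("missing DE results for context(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  genes <- sort(unique(unlist(c(lapply(de_results, `[[`, "gene_id"),
                                list(fold_table$gene_id)))))
  term <- fold_table[fold_table$terminal, ]
  out <- do.call(rbind, lapply(ctxs, function(ctx) {
    de <- de_results[[ctx]]
    tf <- term[term$context == ctx, ]
    if (!nrow(tf)) stop("no terminal fold rows for context ", ctx, call. = FALSE)
    fold <- tf$fold[match(genes, tf$gene_id)]
    fdr <- de$fdr[match(genes, de$gene_id)]
    data.frame(gene_id = genes, context = ctx, final_fold = fold,
               retention = fold, fdr = fdr,
               present = !is.na(fold) & !is.na(fdr),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# Wide per-gene view: fold_<ctx>, fdr_<ctx>, up_<ctx>, down_<ctx>.
responses_wide <- function(responses, config) {
  ctxs <- names(config$terminal)
  genes <- sort(unique(responses$gene_id))
  w <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  for (ctx in ctxs) {
    r <- responses[responses$context == ctx, ]
    i <- match(genes, r$gene_id)
    w[[paste0("fold_", ctx)]] <- r$final_fold[i]
    w[[paste0("fdr_", ctx)]] <- r$fdr[i]
    w[[paste0("up_", ctx)]] <- !is.na(r$final_fold[i]) & !is.na(r$fdr[i]) &
      r$final_fold[i] >= config$up_fold & r$fdr[i] <= config$fdr_alpha
    w[[paste0("down_", ctx)]] <- !is.na(r$retention[i]) &
      r$retention[i] <= config$down_retention
  }
  w
}

#' Call treatment-response signatures
#'
#' Mutually exclusive labels by precedence:
#'
#' 1. `icell_lost`: retention at most `down_retention` (>90% reduction) in all
#'    three contexts — the interstitial-lineage collapse signature.
#' 2. `gland_signature`: >90% reduction in Col (gland cells are eliminated by
#'    colchicine) while the HU and HS folds stay at or above `stable_floor`.
#' 3. `plasticity_candidate`: at least 2x up with FDR support in at least
#'    `min_contexts` of the three contexts.
#' 4. `down_other`: >90% reduction in at least one context.
#' 5. `up_other`: supported up-regulation in exactly one context.
#' 6. `unresponsive`.
#'
#' @param responses From [context_responses()]; all three contexts required
#'   per gene.
#' @param config [run_config()].
#' @return data.frame: gene_id, label, contexts_up, contexts_down90
#'   (comma-joined), n_up, max_fold, plus fold/fdr evidence columns.
#' @export
call_signatures <- function(responses, config = run_config()) {
  ctxs <- names(config$terminal)
  w <- responses_wide(responses, config)
  up <- as.matrix(w[paste0("up_", ctxs)])
  down <- as.matrix(w[paste0("down_", ctxs)])
  folds <- as.matrix(w[paste0("fold_", ctxs)])
  if (any(!stats::complete.cases(folds)))
    stop("every gene needs evidence in all three contexts", call. = FALSE)
  n_up <- rowSums(up)
  stable_hu_hs <- folds[, "fold_HU"] >= config$stable_floor &
    folds[, "fold_HS"] >= config$stable_floor
  # assigned in reverse precedence so later (higher-priority) rules overwrite
  label <- rep("unresponsive", nrow(w))
  label[n_up == 1] <- "up_other"
  label[rowSums(down) >= 1] <- "down_other"
  label[n_up >= config$min_contexts] <- "plasticity_candidate"
  label[down[, "down_Col"] & stable_hu_hs] <- "gland_signature"
  label[rowSums(down) == 3] <- "icell_lost"
  join <- function(m) apply(m, 1, function(x) paste(ctxs[x], collapse = ","))
  out <- data.frame(w["gene_id"], label = label,
                    contexts_up = join(up), contexts_down90 = join(down),
                    n_up = n_up, max_fold = apply(folds, 1, max),
                    stringsAsFactors = FALSE)
  cbind(out, w[c(paste0("fold_", ctxs), paste0("fdr_", ctxs))])
}

#' Venn partition of up- or down-regulated gene sets
#'
#' Membership per context: `up` requires fold >= `up_fold` with FDR <=
#' `fdr_alpha`; `down` requires retention <= `down_retention` (the >90%
#' reduction counting carries no FDR clause). Returns the seven disjoint cells
#' plus per-context totals; inclusion-exclusion consistency is asserted on
#' every call.
#'
#' @param responses From [context_responses()].
#' @param direction `"up"` or `"down"`.
#' @param config [run_config()].
#' @return list(direction, cells, totals): cells is a named integer vector
#'   (HU_only, HS_only, Col_only, HU_HS, HU_Col, HS_Col, HU_HS_Col).
#' @export
venn_partition <- function(responses, direction = c("up", "down"),
                           config = run_config()) {
  direction <- match.arg(direction)
  ctxs <- names(config$terminal)
  w <- responses_wide(responses, config)
  m <- as.matrix(w[paste0(direction, "_", ctxs)])
  colnames(m) <- ctxs
  key <- m %*% c(1, 2, 4)  # HU=1, HS=2, Col=4
  cells <- c(HU_only = sum(key == 1), HS_only = sum(key == 2),
             Col_only = sum(key == 4), HU_HS = sum(key == 3),
             HU_Col = sum(key == 5), HS_Col = sum(key == 6),
             HU_HS_Col = sum(key == 7))
  totals <- colSums(m)
  cover <- c(HU = sum(cells[c("HU_only", "HU_HS", "HU_Col", "HU_HS_Col")]),
             HS = sum(cells[c("HS_only", "HU_HS", "HS_Col", "HU_HS_Col")]),
             Col = sum(cells[c("Col_only", "HU_Col", "HS_Col", "HU_HS_Col")]))
  if (!all(cover == totals[names(cover)]))
    stop("internal error: Venn cells do not reconstruct per-context totals",
         call. = FALSE)
  list(direction = direction, cells = cells, totals = totals)
}

#' Cross-classify signatures with cell-type and axial pattern calls
#'
#' Plasticity candidates are joined to their cell-type label; those attributed
#' to an epithelial origin (ecto, endo, both_epithelial) form the final
#' candidate table, sorted by maximal fold (ties broken by gene id).
#' Candidates with a non-epithelial cell-type call are kept in a diagnostics
#' sheet. Gland-signature genes are reported separately. Genes missing from a
#' join are dropped from that table with their count reported.
#'
#' @param signature_calls From [call_signatures()].
#' @param celltype_calls From [call_celltype()].
#' @param pattern_calls Optional, from [classify_patterns()].
#' @param annotation Optional gene annotation (gene_id, category,
#'   family_label).
#' @return list(candidates, gland, diagnostics, n_dropped).
#' @export
cross_classify <- function(signature_calls, celltype_calls,
                           pattern_calls = NULL, annotation = NULL) {
  join <- function(tab) {
    tab$celltype <- celltype_calls$label[match(tab$gene_id, celltype_calls$gene_id)]
    if (!is.null(pattern_calls))
      tab$pattern <- pattern_calls$pattern[match(tab$gene_id, pattern_calls$gene_id)]
    if (!is.null(annotation)) {
      i <- match(tab$gene_id, annotation$gene_id)
      tab$category <- annotation$category[i]
      tab$family_label <- annotation$family_label[i]
    }
    tab
  }
  cand <- join(signature_calls[signature_calls$label == "plasticity_candidate", ])
  n_dropped <- sum(is.na(cand$celltype))
  cand <- cand[!is.na(cand$celltype), ]
  epi <- cand$celltype %in% c("ecto", "endo", "both_epithelial")
  candidates <- cand[epi, ]
  ord <- order(-candidates$max_fold, candidates$gene_id)
  candidates <- candidates[ord, ]
  rownames(candidates) <- NULL
  diagnostics <- cand[!epi, ]
  rownames(diagnostics) <- NULL
  gland <- join(signature_calls[signature_calls$label == "gland_signature", ])
  gland <- gland[order(-gland$max_fold, gland$gene_id), ]
  rownames(gland) <- NULL
  list(candidates = candidates, gland = gland, diagnostics = diagnostics,
       n_dropped = n_dropped)
}

#' Time-course profile with the time-0 convention
#'
#' Per-gene log2 folds over the HU timepoints, with the day-0 value forced to
#' 0 (the study's plotting convention: values at time 0, before treatment
#' initiation, are extrapolated to 0). Missing timepoints stay NA — never
#' interpolated. A monotonicity flag marks profiles non-decreasing within
#' `tol`.
#'
#' @param fold_table From [fold_change_table()].
#' @param gene_ids Genes to profile.
#' @param context Context with intermediate timepoints (default HU).
#' @param tol Allowed decrease between successive timepoints.
#' @return data.frame: gene_id, one `log2fc_d<t>` column per timepoint,
#'   monotone.
#' @export
kinetics_profile <- function(fold_table, gene_ids, context = "HU", tol = 0.1) {
  ft <- fold_table[fold_table$context == context, ]
  days <- sort(unique(ft$timepoint_days))
  out <- data.frame(gene_id = gene_ids, stringsAsFactors = FALSE)
  for (d in days) {
    r <- ft[ft$timepoint_days == d, ]
    v <- r$log2fc[match(gene_ids, r$gene_id)]
    if (d == 0) v <- ifelse(is.na(v), 0, 0)
    out[[paste0("log2fc_d", d)]] <- v
  }
  prof <- as.matrix(out[, -1, drop = FALSE])
  out$monotone <- apply(prof, 1, function(x) {
    x <- x[!is.na(x)]
    length(x) < 2 || all(diff(x) >= -tol)
  })
  out
}
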