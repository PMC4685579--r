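# Typed data model and flat-file I/O shared by every pipeline stage.
#
# A count matrix is a plain integer matrix (genes x samples) with unique
# dimnames, validated on construction; a sample sheet is a data.frame with a
# closed condition vocabulary per experiment. Both survive exact round-trips
# through TSV, and count matrices additionally through MatrixMarket triplets.

#' Condition vocabulary per experiment
#'
#' The three experimental designs each have a closed set of condition labels:
#' five axial regions for the spatial design (there is no R2 slice in the
#' dissection scheme), four arms for the ablation time course, and four FACS
#' fractions (plus unsorted tissue) for the cell-type design.
#'
#' @return Named list of character vectors, one per experiment.
#' @export
condition_vocabulary <- function() {
  list(
    spatial   = c("H", "R1", "R3", "R4", "F"),
    treatment = c("control", "HU", "HS", "Col"),
    celltype  = c("ecto", "endo", "icell", "unsorted")
  )
}

#' Axial regions in apical-to-basal order
#' @return Character vector `c("H","R1","R3","R4","F")`.
#' @export
axial_regions <- function() condition_vocabulary()$spatial

#' Construct and validate a count matrix
#'
#' @param counts Numeric matrix of non-negative integral read counts with
#'   unique, non-empty rownames (gene ids) and colnames (sample ids).
#'   Fractional "expected counts" are rejected, not rounded: every downstream
#'   model assumes integer support.
#' @return The validated matrix, storage mode integer-compatible numeric.
#' @export
count_matrix <- function(counts) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  validate_count_matrix(counts)
  # canonical integer storage (round-trips compare identical); keep double
  # only for counts beyond integer range
  if (!is.integer(counts) && max(counts) <= .Machine$integer.max)
    storage.mode(counts) <- "integer"
  counts
}

#' Validate count-matrix invariants
#'
#' Checks non-negativity, integrality, and uniqueness of gene and sample ids.
#' Errors name the first offending cell so malformed inputs are traceable.
#'
#' @param counts Matrix to check.
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
validate_count_matrix <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("count matrix must be a numeric matrix", call. = FALSE)
  gid <- rownames(counts); sid <- colnames(counts)
  if (is.null(gid) || is.null(sid) || any(!nzchar(gid)) || any(!nzchar(sid)))
    stop("count matrix requires non-empty gene and sample ids", call. = FALSE)
  if (anyDuplicated(gid))
    stop("duplicate gene ids: ", paste(unique(gid[duplicated(gid)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(sid))
    stop("duplicate sample ids: ", paste(unique(sid[duplicated(sid)]), collapse = ", "),
         call. = FALSE)
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts))
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(counts))
    stop(sprintf("invalid count at gene '%s', sample '%s': %s (counts must be non-negative integers)",
                 gid[i[1]], sid[i[2]], format(counts[bad[1]])), call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a count matrix from TSV or MatrixMarket triplets
#'
#' TSV layout: header row of sample ids, first column of gene ids. The
#' MatrixMarket coordinate format omits zero cells; gene and sample ids live in
#' sidecar files `<path>.genes` / `<path>.samples` (one id per line) unless
#' given explicitly. Both routes produce an identical validated matrix.
#'
#' @param path File path.
#' @param format `"tsv"` or `"mtx"`.
#' @param gene_file,sample_file Sidecar id files for `format = "mtx"`.
#' @return Validated count matrix.
#' @export
read_count_matrix <- function(path, format = c("tsv", "mtx"),
                              gene_file = paste0(path, ".genes"),
                              sample_file = paste0(path, ".samples")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "tsv") {
    tab <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                             colClasses = "character", quote = "", comment.char = "")
    if (ncol(tab) < 2) stop("malformed count TSV header in ", path, call. = FALSE)
    gid <- tab[[1]]
    m <- suppressWarnings(vapply(tab[-1], as.numeric, numeric(nrow(tab))))
    if (!is.matrix(m)) m <- matrix(m, nrow = nrow(tab), dimnames = list(NULL, names(tab)[-1]))
    rownames(m) <- gid
    count_matrix(m)
  } else {
    if (!file.exists(gene_file) || !file.exists(sample_file))
      stop("mtx format needs sidecar id files: ", gene_file, ", ", sample_file, call. = FALSE)
    mm <- Matrix::readMM(path)
    m <- as.matrix(mm)
    rownames(m) <- readLines(gene_file)
    colnames(m) <- readLines(sample_file)
    count_matrix(m)
  }
}

#' Write a count matrix
#'
#' @param counts Validated count matrix.
#' @param path Output path.
#' @param format `"tsv"` or `"mtx"` (writes sidecar id files).
#' @return Invisibly `path`.
#' @export
write_count_matrix <- function(counts, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  validate_count_matrix(counts)
  if (format == "tsv") {
    tab <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                      stringsAsFactors = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), path)
    writeLines(rownames(counts), paste0(path, ".genes"))
    writeLines(colnames(counts), paste0(path, ".samples"))
  }
  invisible(path)
}

#' Construct and validate a sample sheet
#'
#' @param sheet data.frame with columns `sample_id`, `experiment`, `condition`,
#'   `replicate`, and (treatment design) `timepoint_days`.
#' @param counts Optional count matrix to cross-check sample ids against.
#' @return Validated data.frame.
#' @export
sample_sheet <- function(sheet, counts = NULL) {
  validate_sample_sheet(sheet, counts)
  sheet
}

#' Validate sample-sheet invariants
#'
#' The condition vocabulary is closed per experiment: unknown labels are hard
#' errors rather than warnings, since a silent typo would corrupt a contrast.
#'
#' @inheritParams sample_sheet
#' @return Invisibly `TRUE`.
#' @export
validate_sample_sheet <- function(sheet, counts = NULL) {
  need <- c("sample_id", "experiment", "condition", "replicate")
  miss <- setdiff(need, names(sheet))
  if (length(miss)) stop("sample sheet missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (anyDuplicated(sheet$sample_id))
    stop("duplicate sample_id in sample sheet", call. = FALSE)
  vocab <- condition_vocabulary()
  bad_exp <- setdiff(unique(sheet$experiment), names(vocab))
  if (length(bad_exp)) stop("unknown experiment: ", paste(bad_exp, collapse = ", "),
                            call. = FALSE)
  for (e in unique(sheet$experiment)) {
    bad <- setdiff(unique(sheet$condition[sheet$experiment == e]), vocab[[e]])
    if (length(bad))
      stop(sprintf("unknown condition for experiment '%s': %s (allowed: %s)",
                   e, paste(bad, collapse = ", "), paste(vocab[[e]], collapse = ", ")),
           call. = FALSE)
  }
  if (any(sheet$experiment == "treatment")) {
    if (!"timepoint_days" %in% names(sheet))
      stop("treatment design requires a timepoint_days column", call. = FALSE)
    tp <- sheet$timepoint_days[sheet$experiment == "treatment"]
    if (any(!is.finite(tp) | tp < 0))
      stop("treatment timepoint_days must be non-negative numbers", call. = FALSE)
  }
  if (any(!is.finite(sheet$replicate) | sheet$replicate < 1 |
            sheet$replicate != round(sheet$replicate)))
    stop("replicate must be a positive integer", call. = FALSE)
  if (!is.null(counts)) {
    if (!setequal(sheet$sample_id, colnames(counts)) ||
          nrow(sheet) != ncol(counts))
      stop("sample sheet ids must match count matrix columns exactly", call. = FALSE)
  }
  invisible(TRUE)
}

#' Read / write a sample sheet TSV
#' @param path File path.
#' @return `read_sample_sheet`: validated data.frame.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  sheet <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                             stringsAsFactors = FALSE, comment.char = "")
  sample_sheet(sheet)
}

#' @rdname read_sample_sheet
#' @param sheet Validated sample sheet.
#' @export
write_sample_sheet <- function(sheet, path) {
  validate_sample_sheet(sheet)
  utils::write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene annotation table
#'
#' Optional external annotation (e.g. the curated neurogenesis/neurotransmission
#' gene lists). `category` must be one of NG, NT, other; annotation is an input,
#' never computed. Genes absent from an analysed matrix are reported by the
#' joins downstream, not errors here.
#'
#' @param path TSV with columns `gene_id`, `category`, optionally `family_label`.
#' @return data.frame.
#' @export
read_gene_annotation <- function(path) {
  ann <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           stringsAsFactors = FALSE, comment.char = "")
  if (!all(c("gene_id", "category") %in% names(ann)))
    stop("annotation needs gene_id and category columns", call. = FALSE)
  bad <- setdiff(unique(ann$category), c("NG", "NT", "other"))
  if (length(bad)) stop("annotation category must be NG/NT/other, got: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  if (!"family_label" %in% names(ann)) ann$family_label <- NA_character_
  ann
}

#' Pipeline run configuration
#'
#' All tunable thresholds in one flat list. Defaults encode the study's stated
#' selection rules (2x up-regulation, FDR <= 0.1, >90% reduction i.e. retention
#' <= 0.10, candidate support in >= 2 of the 3 ablation contexts) plus declared
#' conventions for the spatial and cell-type classifiers.
#'
#' @param ... Named overrides of any default.
#' @return Named list with class `"hydraplast_config"`.
#' @export
run_config <- function(...) {
  cfg <- list(
    # treatment-response selection rules
    up_fold        = 2.0,   # minimal linear fold for "up-regulated"
    down_retention = 0.10,  # residual fraction for ">90% reduction"
    fdr_alpha      = 0.1,
    min_contexts   = 2,     # contexts required for a plasticity candidate
    stable_floor   = 0.8,   # "stable or elevated" floor for the gland rule
    # differential expression
    dispersion_mode  = "pooled",
    dispersion_floor = 1e-8,
    mean_floor       = 0.5, # normalized-count floor inside log fold changes
    # spatial classifier (all on the max-normalized profile)
    expression_floor    = 5,    # mean normalized count in the max region
    foot_max_other      = 0.2,
    polar_far_max       = 0.3,  # opposite extremity ceiling for apical/basal
    polar_mid_max       = 0.3,  # central region ceiling for apical/basal
    polar_near_max      = 0.6,  # adjacent-region ceiling for apical/basal
    bipolar_min         = 0.6,
    bipolar_trough      = 0.5,  # central trough <= this fraction of min extremity
    graded_tol          = 0.1,  # isotonic-fit residual tolerance
    graded_span         = 0.5,  # required max-min spread for graded calls
    apolar_extremity_max = 0.5,
    flat_min            = 0.5,  # ubiquitous: min of profile
    # cell-type composition
    specific_fraction  = 0.65,
    shared_floor       = 0.15,
    epithelial_balance = 0.25,
    pseudo_count       = 0.5,
    # treatment design day matching: treated timepoint -> starved control day
    terminal = c(HU = 7, HS = 7, Col = 10),
    control_map = data.frame(
      context = c("HU", "HU", "HU", "HU", "HS", "Col"),
      timepoint_days = c(0, 1, 3, 7, 7, 10),
      control_days = c(3, 4, 6, 10, 10, 10)
    ),
    rng_seed = 1L
  )
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "),
                            call. = FALSE)
  cfg[names(ov)] <- ov
  validate_run_config(cfg)
  structure(cfg, class = "hydraplast_config")
}

#' @rdname run_config
#' @param cfg Config list to validate.
#' @export
validate_run_config <- function(cfg) {
  pos <- c("up_fold", "down_retention", "fdr_alpha", "stable_floor",
           "expression_floor", "graded_tol", "pseudo_count", "specific_fraction")
  for (k in pos) if (!is.numeric(cfg[[k]]) || cfg[[k]] <= 0)
    stop("config ", k, " must be strictly positive", call. = FALSE)
  if (cfg$down_retention >= 1) stop("down_retention must be < 1", call. = FALSE)
  if (cfg$min_contexts < 1 || cfg$min_contexts > 3)
    stop("min_contexts must be in 1..3", call. = FALSE)
  invisible(TRUE)
}

#' Read / write run configuration as a flat key=value file
#'
#' Scalar keys only; `terminal` is encoded as `terminal.HU=7` etc. and the
#' control map as `control_map.<context>.<day>=<control day>`. Unknown keys are
#' errors. Missing keys keep their defaults.
#'
#' @param path File path.
#' @return `read_run_config`: a validated config.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), "")
  cfg <- run_config()
  cm <- cfg$control_map
  for (i in seq_along(keys)) {
    k <- trimws(keys[i]); v <- trimws(vals[i])
    if (startsWith(k, "terminal.")) {
      cfg$terminal[[sub("^terminal\\.", "", k)]] <- as.numeric(v)
    } else if (startsWith(k, "control_map.")) {
      parts <- strsplit(k, ".", fixed = TRUE)[[1]]
      sel <- cm$context == parts[2] & cm$timepoint_days == as.numeric(parts[3])
      if (!any(sel)) {
        cm <- rbind(cm, data.frame(context = parts[2],
                                   timepoint_days = as.numeric(parts[3]),
                                   control_days = as.numeric(v)))
      } else cm$control_days[sel] <- as.numeric(v)
    } else if (k %in% names(cfg)) {
      cfg[[k]] <- if (k %in% c("dispersion_mode")) v else as.numeric(v)
    } else stop("unknown config key: ", k, call. = FALSE)
  }
  cfg$control_map <- cm
  validate_run_config(cfg)
  cfg
}

#' @rdname read_run_config
#' @param cfg Config from [run_config()].
#' @export
write_run_config <- function(cfg, path) {
  scal <- cfg[!names(cfg) %in% c("terminal", "control_map")]
  lines <- c(
    sprintf("%s=%s", names(scal), vapply(scal, function(x) format(x, digits = 15), "")),
    sprintf("terminal.%s=%s", names(cfg$terminal), format(cfg$terminal)),
    sprintf("control_map.%s.%s=%s", cfg$control_map$context,
            format(cfg$control_map$timepoint_days),
            format(cfg$control_map$control_days))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write a deterministic report TSV
#'
#' Output carries a comment header naming the pipeline version and the config
#' values that shaped the result; identical inputs and config produce
#' byte-identical files (numbers rendered with a fixed 15-digit format, row
#' order as given).
#'
#' @param results data.frame from a completed stage (may have zero rows).
#' @param path Output path.
#' @param config Optional [run_config()] echoed into the header.
#' @return Invisibly `path`.
#' @export
write_report <- function(results, path, config = NULL) {
  stopifnot(is.data.frame(results))
  con <- file(path, open = "wb")  # binary: fixed "\n" endings on any platform
  on.exit(close(con))
  hdr <- sprintf("# hydraplast %s", as.character(utils::packageVersion("hydraplast")))
  if (!is.null(config)) {
    scal <- config[!names(config) %in% c("terminal", "control_map")]
    hdr <- c(hdr, sprintf("# config %s=%s", names(scal),
                          vapply(scal, function(x) format(x, digits = 15), "")))
  }
  writLines <- function(x) writeLines(x, con, sep = "\n")
  writLines(hdr)
  fmt <- function(col) {
    if (is.numeric(col)) vapply(col, function(x)
      if (is.na(x)) "NA" else format(x, digits = 15, scientific = FALSE, trim = TRUE), "")
    else as.character(col)
  }
  writLines(paste(names(results), collapse = "\t"))
  if (nrow(results))
    writLines(do.call(paste, c(lapply(results, fmt), sep = "\t")))
  invisible(path)
}
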