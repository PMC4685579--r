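# RFamide basal-index statistic and maceration cell-count summaries, with the
# two group comparisons used on the index: a two-sided Welch t-test on means
# and a two-sided variance-ratio F-test.

#' RFamide basal index
#'
#' Ratio of the peduncle length containing RFamide-positive cells to the
#' peduncle diameter. Unit-agnostic (both measurements in the same arbitrary
#' units); scale-invariant by construction.
#'
#' @param rf_length Non-negative length(s).
#' @param diameter Strictly positive diameter(s).
#' @return Numeric index, vectorized.
#' @export
basal_index <- function(rf_length, diameter) {
  if (any(!is.finite(diameter) | diameter <= 0))
    stop("diameter must be strictly positive", call. = FALSE)
  if (any(!is.finite(rf_length) | rf_length < 0))
    stop("rf_length must be non-negative", call. = FALSE)
  rf_length / diameter
}

# Closed-form Welch t with Welch-Satterthwaite df, two-sided.
welch_test <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- stats::var(x); vy <- stats::var(y)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

# Variance-ratio F, two-sided by the doubling convention (equivalent to
# putting the larger variance in the numerator). f inverts under group swap;
# the p-value does not.
f_var_test <- function(x, y) {
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 || vy == 0)
    return(list(f = NA_real_, p = NA_real_, defined = FALSE))
  f <- vx / vy
  pf1 <- stats::pf(f, length(x) - 1, length(y) - 1)
  list(f = f, p = min(1, 2 * min(pf1, 1 - pf1)), defined = TRUE)
}

#' Compare the basal index between two groups
#'
#' Computes per-animal indices then a two-sided Welch unequal-variance t-test
#' (Welch-Satterthwaite degrees of freedom) on the means and a two-sided
#' variance-ratio F-test with (nA-1, nB-1) degrees of freedom. No
#' multiple-testing correction across bracket comparisons — each pair stands
#' alone. A zero-variance group leaves the F-test undefined (flagged).
#'
#' @param records data.frame with columns group, rf_length, diameter.
#' @param group_a,group_b Group labels to compare (>= 2 animals each).
#' @return list(welch_t, welch_df, welch_p, f_stat, f_p, f_defined, n_a, n_b,
#'   mean_a, mean_b).
#' @export
compare_groups <- function(records, group_a, group_b) {
  pick <- function(g) {
    r <- records[records$group == g, ]
    if (nrow(r) < 2) stop("group '", g, "' needs >= 2 records", call. = FALSE)
    basal_index(r$rf_length, r$diameter)
  }
  a <- pick(group_a); b <- pick(group_b)
  w <- welch_test(a, b)
  f <- f_var_test(a, b)
  list(welch_t = w$t, welch_df = w$df, welch_p = w$p,
       f_stat = f$f, f_p = f$p, f_defined = f$defined,
       n_a = length(a), n_b = length(b), mean_a = mean(a), mean_b = mean(b))
}

#' Cell-class ratios from a maceration count record
#'
#' Per-class ratio over epithelial cells plus each class's percentage of the
#' total counted cells (i-cells normally sit at 20-26% of total and drop below
#' 2% after ablation).
#'
#' @param counts Named non-negative integer vector of cell-class counts; must
#'   include `epithelial` with a positive count.
#' @return data.frame: class, count, ratio_over_epithelial, pct_of_total.
#' @export
cell_class_ratios <- function(counts) {
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop("counts must be a named vector", call. = FALSE)
  if (any(!is.finite(counts) | counts < 0))
    stop("cell counts must be non-negative", call. = FALSE)
  if (!"epithelial" %in% names(counts) || counts["epithelial"] <= 0)
    stop("epithelial count must be present and > 0", call. = FALSE)
  total <- sum(counts)
  if (total <= 0) stop("zero total cell count", call. = FALSE)
  data.frame(class = names(counts), count = as.numeric(counts),
             ratio_over_epithelial = as.numeric(counts / counts["epithelial"]),
             pct_of_total = as.numeric(100 * counts / total),
             stringsAsFactors = FALSE, row.names = NULL)
}
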