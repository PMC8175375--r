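#' Assemble a cohort table
#'
#' Long-format grid of per-patient, per-tissue metric values, the input to
#' group summaries and paired tests. Supported metrics: `peak_enhancement`
#' and `normalized_auc`.
#'
#' @param records `data.frame` with columns `patient_id`, `tissue_label`,
#'   `metric_name`, `value` (or a superset).
#' @return A validated `cohort_table` (a `data.frame` subclass).
#' @export
cohort_table <- function(records) {
  needed <- c("patient_id", "tissue_label", "metric_name", "value")
  if (!is.data.frame(records) || !all(needed %in% names(records))) {
    stop("cohort table needs columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  records <- records[needed]
  records <- records[!is.na(records$value), , drop = FALSE]
  if (!is.numeric(records$value) || any(!is.finite(records$value))) {
    stop("cohort values must be finite numbers", call. = FALSE)
  }
  if (any(records$metric_name == "normalized_auc" & records$value < 0)) {
    stop("normalized AUC values must be >= 0", call. = FALSE)
  }
  key <- interaction(records$patient_id, records$tissue_label,
                     records$metric_name, drop = TRUE)
  if (anyDuplicated(key)) {
    stop("at most one value per (patient, tissue, metric) is allowed",
         call. = FALSE)
  }
  class(records) <- c("cohort_table", "data.frame")
  records
}

#' Build a cohort table from per-clip summaries
#'
#' Reshapes the summary rows produced by [analyze_cine()] (or read back
#' from its CSV) into the long metric grid of [cohort_table()].
#'
#' @param summaries `data.frame` with columns `patient_id`, `roi_label`,
#'   `peak_enhancement`, `normalized_auc`.
#' @return A `cohort_table`.
#' @export
cohort_from_summaries <- function(summaries) {
  stopifnot(is.data.frame(summaries))
  long <- rbind(
    data.frame(patient_id = summaries$patient_id,
               tissue_label = summaries$roi_label,
               metric_name = "peak_enhancement",
               value = summaries$peak_enhancement),
    data.frame(patient_id = summaries$patient_id,
               tissue_label = summaries$roi_label,
               metric_name = "normalized_auc",
               value = summaries$normalized_auc)
  )
  cohort_table(long)
}

#' Group summary in count / sum / average / variance form
#'
#' Per tissue group: record count, value sum, arithmetic mean, and sample
#' variance (n - 1 denominator; `NA` for single-record groups).
#'
#' @param table A [cohort_table()].
#' @param metric `"peak_enhancement"` or `"normalized_auc"`.
#' @return `data.frame` with columns `group`, `count`, `sum`, `average`,
#'   `variance`.
#' @export
summarize_groups <- function(table, metric = "peak_enhancement") {
  table <- cohort_table(table)
  if (!metric %in% c("peak_enhancement", "normalized_auc")) {
    stop("unknown metric '", metric, "'", call. = FALSE)
  }
  sub <- table[table$metric_name == metric, , drop = FALSE]
  if (nrow(sub) == 0L) {
    stop("no records for metric '", metric, "'", call. = FALSE)
  }
  groups <- split(sub$value, sub$tissue_label)
  out <- do.call(rbind, lapply(names(groups), function(g) {
    v <- groups[[g]]
    data.frame(group = g, count = length(v), sum = sum(v),
               average = mean(v),
               variance = if (length(v) >= 2L) stats::var(v) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}

#' Paired t-test on matched per-patient values
#'
#' Two-sided paired Student t-test on the differences `x - y`. Pairs with a
#' missing side are dropped first (pairwise-complete deletion), mirroring
#' cohorts where a tissue could not be measured in every patient.
#' The test itself is [stats::t.test()] with `paired = TRUE`.
#'
#' @param x,y Numeric vectors of equal length, paired by position
#'   (i.e. by patient).
#' @param comparison Label carried on the result.
#' @return List with `comparison`, `n_pairs`, `mean_difference`,
#'   `t_statistic`, `p_value`.
#' @export
paired_t_test <- function(x, y, comparison = "x_vs_y") {
  if (length(x) != length(y)) {
    stop("paired vectors must have equal length", call. = FALSE)
  }
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2L) {
    stop("paired t-test needs at least 2 complete pairs", call. = FALSE)
  }
  d <- x - y
  if (stats::sd(d) == 0) {
    stop("degenerate variance: all paired differences are identical",
         call. = FALSE)
  }
  fit <- stats::t.test(x, y, paired = TRUE)
  list(comparison = comparison, n_pairs = length(x),
       mean_difference = mean(d),
       t_statistic = unname(fit$statistic),
       p_value = fit$p.value)
}

# "brain" in the standard comparisons means the white-matter reference ROI
.comparisons <- list(
  artery_vs_brain = c("artery", "white_matter"),
  artery_vs_tumor = c("artery", "tumor"),
  brain_vs_tumor  = c("white_matter", "tumor")
)

#' All pairwise tissue comparisons for one metric
#'
#' Runs the three paired comparisons artery-brain, artery-tumor and
#' brain-tumor ("brain" denotes the white-matter reference). For
#' `normalized_auc` the artery comparisons are reported as not applicable
#' (`NA` statistics): every clip's arterial normalized AUC is identically 1
#' by construction, so a test against it is meaningless. Each patient
#' contributes one pair per comparison; patients missing either side are
#' dropped from that comparison only. P-values are unadjusted.
#'
#' @param table A [cohort_table()] containing artery, tumor and
#'   white_matter records.
#' @param metric `"peak_enhancement"` or `"normalized_auc"`.
#' @param alpha Significance level for the `significant` flag
#'   (default 0.05).
#' @return `data.frame` with columns `comparison`, `metric`, `n_pairs`,
#'   `mean_difference`, `t_statistic`, `p_value`, `significant`,
#'   `applicable`.
#' @export
compare_all <- function(table, metric = "peak_enhancement", alpha = 0.05) {
  table <- cohort_table(table)
  sub <- table[table$metric_name == metric, , drop = FALSE]
  tissues <- c("artery", "tumor", "white_matter")
  need <- if (metric == "normalized_auc") c("tumor", "white_matter") else
    tissues
  missing <- setdiff(need, unique(sub$tissue_label))
  if (length(missing)) {
    stop("cohort table lacks ", metric, " records for: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  wide <- stats::reshape(
    sub[c("patient_id", "tissue_label", "value")],
    idvar = "patient_id", timevar = "tissue_label", direction = "wide"
  )
  col_of <- function(t) wide[[paste0("value.", t)]]

  rows <- lapply(names(.comparisons), function(cmp) {
    pair <- .comparisons[[cmp]]
    if (metric == "normalized_auc" && "artery" %in% pair) {
      return(data.frame(comparison = cmp, metric = metric,
                        n_pairs = NA_integer_, mean_difference = NA_real_,
                        t_statistic = NA_real_, p_value = NA_real_,
                        significant = NA, applicable = FALSE))
    }
    res <- paired_t_test(col_of(pair[1]), col_of(pair[2]), comparison = cmp)
    data.frame(comparison = cmp, metric = metric, n_pairs = res$n_pairs,
               mean_difference = res$mean_difference,
               t_statistic = res$t_statistic, p_value = res$p_value,
               significant = res$p_value < alpha, applicable = TRUE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
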