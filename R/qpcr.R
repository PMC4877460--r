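#' Reference-normalized Ct (delta-Ct)
#'
#' The average Ct of the technical replicates of the target minus the
#' average Ct of the reference-gene (U6) replicates from the same sample:
#' `dCt = AvgCt_target - AvgCt_reference`. Lower dCt means higher
#' expression (one cycle per doubling).
#'
#' @param ct_target,ct_reference Numeric replicate Ct values (1-3 each).
#' @return The delta-Ct value.
#' @examples
#' delta_ct(c(20, 20, 20), c(18, 18, 18))   # 2
#' @export
delta_ct <- function(ct_target, ct_reference) {
  if (length(ct_target) == 0 || length(ct_reference) == 0 ||
      anyNA(ct_target) || anyNA(ct_reference))
    abort_arg("replicate Ct sets must be non-empty and complete")
  mean(ct_target) - mean(ct_reference)
}

#' Delta-delta-Ct and fold change between two conditions
#'
#' `ddCt = dCt_case - dCt_control`; relative expression of the case versus
#' the control is `2^-ddCt`.
#'
#' @param dct_case,dct_control Delta-Ct values (vectorized).
#' @return A list with `ddct` and `fold_change`.
#' @examples
#' ddct_fold_change(-1.78, 1.89)   # ddct -3.67, fold ~12.7
#' @export
ddct_fold_change <- function(dct_case, dct_control) {
  if (any(!is.finite(dct_case)) || any(!is.finite(dct_control)))
    abort_arg("delta-Ct inputs must be finite")
  ddct <- dct_case - dct_control
  list(ddct = ddct, fold_change = 2^(-ddct))
}

#' Two-group comparison of delta-Ct values
#'
#' Two-sided t-test between two groups of per-sample delta-Ct values.
#' Welch's unequal-variance test is the default; `var_equal = TRUE` gives
#' the pooled Student test and `paired = TRUE` the paired test (samples
#' matched by position).
#'
#' @param group1,group2 Numeric vectors, each with at least two values.
#' @param paired,var_equal Test variants.
#' @return The two-sided p-value.
#' @examples
#' two_group_test(c(1, 1.2, 0.9), c(3.1, 2.8, 3.0))
#' @export
two_group_test <- function(group1, group2, paired = FALSE, var_equal = FALSE) {
  if (length(group1) < 2 || length(group2) < 2)
    abort_arg("each group needs at least two values")
  if (paired && length(group1) != length(group2))
    abort_arg("paired test needs equal group sizes")
  # degenerate zero-variance data (e.g. noise-free simulations): the t
  # statistic's limit is 0 when the means agree and +/-Inf otherwise
  if (isTRUE(all.equal(sd(group1), 0)) && isTRUE(all.equal(sd(group2), 0)) &&
      (!paired || sd(group1 - group2) == 0)) {
    return(if (isTRUE(all.equal(mean(group1), mean(group2)))) 1 else 0)
  }
  t.test(group1, group2, paired = paired, var.equal = var_equal)$p.value
}

#' Per-sample delta-Ct values of a qPCR table
#'
#' @param qpcr A `qpcr_table` (see [simulate_qpcr()] / [read_qpcr_tsv()]):
#'   long format with `sample_id`, `group`, `target_id`, `ct_rep1..3`,
#'   including reference-gene rows.
#' @param reference Reference-gene id (default `"U6"`).
#' @return Data frame `sample_id`, `group`, `target_id`, `delta_ct`.
#' @export
qpcr_delta_ct <- function(qpcr, reference = "U6") {
  need <- c("sample_id", "group", "target_id", "ct_rep1")
  if (!all(need %in% names(qpcr)))
    abort_arg("qpcr table must have columns ", paste(need, collapse = ", "))
  rep_cols <- intersect(c("ct_rep1", "ct_rep2", "ct_rep3"), names(qpcr))
  avg <- rowMeans(qpcr[, rep_cols, drop = FALSE], na.rm = TRUE)
  ref <- qpcr$target_id == reference
  if (!any(ref)) abort_arg("no rows for reference gene ", reference)
  ref_avg <- tapply(avg[ref], qpcr$sample_id[ref], mean)
  tg <- qpcr[!ref, c("sample_id", "group", "target_id")]
  if (anyNA(ref_avg[tg$sample_id]))
    abort_arg("every sample needs a reference-gene row")
  data.frame(tg, delta_ct = avg[!ref] - as.numeric(ref_avg[tg$sample_id]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Group summary, fold changes and tests for a qPCR experiment
#'
#' Computes, per target, the mean and SD of per-sample delta-Ct values in
#' each tissue group, then for each contrast (tumor vs normal, adjacent vs
#' normal, tumor vs adjacent) the delta-delta-Ct of group means, the
#' `2^-ddCt` fold change, and a two-sided t-test on the per-sample
#' delta-Ct values.
#'
#' @param qpcr A long qPCR table (see [qpcr_delta_ct()]).
#' @param reference Reference-gene id.
#' @param control_group Baseline group for the per-group ordering.
#' @param paired,var_equal Passed to [two_group_test()].
#' @return A list of class `qpcr_summary` with `groups` (target, group,
#'   `mean_dct`, `sd_dct`, `n`) and `contrasts` (target, case, control,
#'   `ddct`, `fold_change`, `p_value`).
#' @examples
#' tt <- truth_table(simulation_design(n_mirnas = 3, n_gradient_up = 1,
#'                                     gradient_step = 4))
#' qp <- simulate_qpcr(tt, n_samples = 4, noise_sd = 0.1, seed = 2)
#' qpcr_summary(qp)$contrasts
#' @export
qpcr_summary <- function(qpcr, reference = "U6", control_group = "normal",
                         paired = FALSE, var_equal = FALSE) {
  dct <- qpcr_delta_ct(qpcr, reference = reference)
  groups_present <- unique(dct$group)
  ord <- c(control_group, setdiff(c("adjacent", "tumor"), control_group))
  ord <- c(ord[ord %in% groups_present],
           setdiff(groups_present, c("normal", "adjacent", "tumor")))
  g <- do.call(rbind, lapply(split(dct, list(dct$target_id, dct$group),
                                   drop = TRUE), function(d)
    data.frame(target_id = d$target_id[1], group = d$group[1],
               mean_dct = mean(d$delta_ct), sd_dct = sd(d$delta_ct),
               n = nrow(d), stringsAsFactors = FALSE)))
  g <- g[order(g$target_id, match(g$group, ord)), ]
  rownames(g) <- NULL

  pairs <- list(c("tumor", "normal"), c("adjacent", "normal"),
                c("tumor", "adjacent"))
  pairs <- Filter(function(p) all(p %in% groups_present), pairs)
  contrasts <- do.call(rbind, unlist(lapply(unique(dct$target_id), function(t) {
    lapply(pairs, function(p) {
      case <- dct$delta_ct[dct$target_id == t & dct$group == p[1]]
      ctrl <- dct$delta_ct[dct$target_id == t & dct$group == p[2]]
      fc <- ddct_fold_change(mean(case), mean(ctrl))
      data.frame(target_id = t, case = p[1], control = p[2],
                 ddct = fc$ddct, fold_change = fc$fold_change,
                 p_value = two_group_test(case, ctrl, paired = paired,
                                          var_equal = var_equal),
                 stringsAsFactors = FALSE)
    })
  }), recursive = FALSE))
  rownames(contrasts) <- NULL
  structure(list(groups = g, contrasts = contrasts), class = "qpcr_summary")
}

#' @export
print.qpcr_summary <- function(x, ...) {
  cat("qPCR delta-Ct summary\n\nPer-group delta-Ct (mean +/- SD):\n")
  print(x$groups, row.names = FALSE)
  cat("\nContrasts (fold change = 2^-ddCt):\n")
  print(x$contrasts, row.names = FALSE)
  invisible(x)
}

#' Read and write long-format qPCR tables
#'
#' TSV with columns `sample_id`, `group`, `target_id`, `ct_rep1..3`
#' (reference-gene rows included).
#'
#' @param qpcr A qPCR data frame.
#' @param path File path.
#' @return `read_qpcr_tsv()` returns a `qpcr_table` data frame.
#' @export
write_qpcr_tsv <- function(qpcr, path) {
  tsv_write(qpcr, path)
  invisible(path)
}

#' @rdname write_qpcr_tsv
#' @export
read_qpcr_tsv <- function(path) {
  out <- tsv_read(path)
  need <- c("sample_id", "group", "target_id", "ct_rep1")
  if (!all(need %in% names(out)))
    abort_arg("qPCR TSV must have columns ", paste(need, collapse = ", "))
  class(out) <- c("qpcr_table", "data.frame")
  out
}

#' Published qPCR delta-Ct reference values
#'
#' The shipped plain-text table of published qRT-PCR validation results for
#' three miRNAs (miR-21-5p, miR-196a-5p, miR-218-5p) in paired tumor,
#' adjacent and normal lung adenocarcinoma tissue: per-group delta-Ct mean,
#' SD and sample count against a U6 reference. Used by the worked examples
#' to demonstrate delta-delta-Ct fold changes and gradient direction from
#' summary data.
#'
#' @return Data frame `target_id`, `group`, `mean_dct`, `sd_dct`, `n`.
#' @examples
#' lung_ac_qpcr_dct()
#' @export
lung_ac_qpcr_dct <- function() {
  tsv_read(system.file("extdata", "lungAC_qpcr_dct.tsv",
                       package = "miRtrend", mustWork = TRUE))
}
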