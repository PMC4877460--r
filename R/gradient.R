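#' Partition two DE sets against a common control
#'
#' Splits the miRNAs differentially expressed in tumor-vs-normal and in
#' adjacent-vs-normal into tumor-only, adjacent-only and shared sets (the
#' three regions of the two-set Venn diagram).
#'
#' @param set_t Ids DE in tumor vs normal.
#' @param set_a Ids DE in adjacent vs normal.
#' @return A list `tumor_only`, `adjacent_only`, `shared` (disjoint;
#'   `tumor_only` + `shared` recovers `set_t`).
#' @examples
#' venn_partition(c("a", "b", "c"), c("b", "c", "d"))
#' @export
venn_partition <- function(set_t, set_a) {
  set_t <- unique(as.character(set_t))
  set_a <- unique(as.character(set_a))
  list(tumor_only = setdiff(set_t, set_a),
       adjacent_only = setdiff(set_a, set_t),
       shared = intersect(set_t, set_a))
}

#' Call three-state expression gradients
#'
#' A miRNA is an `up_gradient` when it is called up in both normal-referenced
#' comparisons (tumor vs normal and adjacent vs normal, each at the FDR and
#' fold-change thresholds of the DE step) and its CPM increases strictly
#' from normal through adjacent to tumor; `down_gradient` is symmetric.
#' Ties in CPM break monotonicity ("gradually" implies change at every
#' step), giving class `none`. With `strict = TRUE` the tumor-vs-adjacent
#' step must additionally change by at least `fc_threshold`-fold (on
#' pseudocounted CPM).
#'
#' @param cpm_normal,cpm_adjacent,cpm_tumor Non-negative CPM vectors.
#' @param de_tn,de_an [de_call()] tables for tumor vs normal and adjacent vs
#'   normal; their `mirna_id` sets must match `mirna_id`.
#' @param mirna_id Ids of the CPM vectors (default taken from `de_tn`).
#' @param strict Require a `fc_threshold`-fold tumor-vs-adjacent step.
#' @param fc_threshold,pseudocount Strict-mode fold threshold and CPM
#'   pseudocount.
#' @return A `data.frame`: `mirna_id`, the three CPM columns,
#'   `de_tumor_vs_normal`, `de_adjacent_vs_normal`, `class`
#'   (`up_gradient` / `down_gradient` / `none`).
#' @examples
#' de_up <- data.frame(mirna_id = "m1", called = TRUE, direction = "up")
#' gradient_table(100, 250, 600, de_up, de_up)$class
#' @export
gradient_table <- function(cpm_normal, cpm_adjacent, cpm_tumor, de_tn, de_an,
                           mirna_id = de_tn$mirna_id, strict = FALSE,
                           fc_threshold = 2, pseudocount = 1) {
  k <- length(mirna_id)
  if (length(cpm_normal) != k || length(cpm_adjacent) != k ||
      length(cpm_tumor) != k)
    abort_arg("CPM vectors and mirna_id must have equal length")
  if (!setequal(de_tn$mirna_id, mirna_id) || !setequal(de_an$mirna_id, mirna_id))
    abort_arg("DE tables and CPM vectors must cover the same miRNA ids")
  tn <- de_tn[match(mirna_id, de_tn$mirna_id), ]
  an <- de_an[match(mirna_id, de_an$mirna_id), ]
  up <- tn$called & tn$direction == "up" & an$called & an$direction == "up" &
    cpm_normal < cpm_adjacent & cpm_adjacent < cpm_tumor
  down <- tn$called & tn$direction == "down" & an$called &
    an$direction == "down" &
    cpm_normal > cpm_adjacent & cpm_adjacent > cpm_tumor
  if (strict) {
    r <- (cpm_tumor + pseudocount) / (cpm_adjacent + pseudocount)
    big_step <- pmax(r, 1 / r) >= fc_threshold
    up <- up & big_step
    down <- down & big_step
  }
  cls <- ifelse(up, "up_gradient", ifelse(down, "down_gradient", "none"))
  data.frame(mirna_id = mirna_id,
             cpm_normal = cpm_normal, cpm_adjacent = cpm_adjacent,
             cpm_tumor = cpm_tumor,
             de_tumor_vs_normal = tn$called,
             de_adjacent_vs_normal = an$called,
             class = cls, stringsAsFactors = FALSE)
}

#' @rdname gradient_table
#' @param counts A [mir_counts()] with samples `normal`, `adjacent`,
#'   `tumor` (or a `group` assignment naming those tissues, one sample
#'   each).
#' @export
gradient_from_counts <- function(counts, de_tn, de_an, strict = FALSE,
                                 fc_threshold = 2, pseudocount = 1) {
  stopifnot(inherits(counts, "mir_counts"))
  cols <- c("normal", "adjacent", "tumor")
  if (!all(cols %in% colnames(counts$counts)) && !is.null(counts$group)) {
    idx <- vapply(cols, function(g) {
      w <- which(counts$group == g)
      if (length(w) != 1) abort_arg("need exactly one sample per tissue")
      w
    }, integer(1))
    cols <- colnames(counts$counts)[idx]
  }
  if (!all(cols %in% colnames(counts$counts)))
    abort_arg("count matrix must provide normal, adjacent and tumor samples")
  cp <- cpm(counts)
  gradient_table(cp[, cols[1]], cp[, cols[2]], cp[, cols[3]], de_tn, de_an,
                 mirna_id = rownames(cp), strict = strict,
                 fc_threshold = fc_threshold, pseudocount = pseudocount)
}

#' Log2 transform of normalized expression
#'
#' @param x Non-negative expression values (e.g. CPM).
#' @param pseudocount Added before the log (default 1).
#' @return `log2(x + pseudocount)`.
#' @export
log2_expr <- function(x, pseudocount = 1) {
  if (any(x < 0)) abort_arg("expression values must be non-negative")
  log2(x + pseudocount)
}
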