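#' miRNA count matrix with library sizes
#'
#' A light container for raw miRNA-by-sample counts. `library_size` defaults
#' to the column totals ("total copy number of each sample"), the quantity
#' the CPM normalization scales to 1,000,000; a larger externally measured
#' depth may be supplied instead (it must be at least the column total).
#'
#' @param counts Non-negative integer matrix, miRNAs in rows (rownames are
#'   miRNA ids), samples in columns (colnames are sample ids).
#' @param library_size Optional named per-sample totals.
#' @param group Optional per-sample group labels (e.g. tissue state).
#' @return An object of class `mir_counts`.
#' @export
mir_counts <- function(counts, library_size = NULL, group = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    abort_arg("counts must have miRNA rownames and sample colnames")
  if (any(counts < 0) || any(counts != round(counts)))
    abort_arg("counts must be non-negative integers")
  if (is.null(library_size)) library_size <- colSums(counts)
  library_size <- library_size[colnames(counts)]
  if (anyNA(library_size) || any(library_size < colSums(counts)))
    abort_arg("library_size must cover every sample and be >= its column sum")
  if (!is.null(group)) {
    group <- as.character(group)
    if (length(group) != ncol(counts)) abort_arg("one group label per sample")
    names(group) <- colnames(counts)
  }
  structure(list(counts = counts, library_size = library_size, group = group),
            class = "mir_counts")
}

#' @export
print.mir_counts <- function(x, ...) {
  cat("mir_counts:", nrow(x$counts), "miRNAs x", ncol(x$counts), "samples\n")
  cat("library sizes:",
      paste(colnames(x$counts), format(x$library_size), sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.mir_counts <- function(x) dim(x$counts)

#' Counts-per-million matrix of a `mir_counts` object
#'
#' @param x A [mir_counts()] object.
#' @return Matrix of the same shape with each column scaled by
#'   1e6 / library size (see [normalize_cpm()]).
#' @export
cpm <- function(x) {
  stopifnot(inherits(x, "mir_counts"))
  sweep(x$counts, 2, x$library_size / 1e6, "/")
}

#' Simulate a three-tissue miRNA count matrix with ground truth
#'
#' Raw counts are drawn independently as Poisson with the per-miRNA,
#' per-tissue expected means of [truth_table()] — the same sampling model the
#' Audic-Claverie test assumes — optionally scaled per sample to emulate
#' unequal sequencing depths. Column order is normal, adjacent, tumor
#' (`n_reps` replicate columns each); library sizes are the realized column
#' totals.
#'
#' @param design A [simulation_design()].
#' @param n_reps Replicate libraries per tissue (default 1, the pooled
#'   single-library design).
#' @param library_sizes Optional named per-sample nominal depths; expected
#'   means are scaled by `library_sizes / design$library_size`.
#' @param seed Integer seed; defaults to `design$seed`.
#' @return A list with `counts` (a [mir_counts()] with tissue groups) and
#'   `truth` (the [truth_table()]).
#' @examples
#' sim <- simulate_counts(simulation_design(n_mirnas = 20, seed = 3))
#' sim$counts
#' @export
simulate_counts <- function(design, n_reps = 1L, library_sizes = NULL,
                            seed = design$seed) {
  stopifnot(inherits(design, "simulation_design"))
  if (!is_count_scalar(n_reps) || n_reps < 1)
    abort_arg("n_reps must be a positive integer")
  truth <- truth_table(design)
  tissues <- c("normal", "adjacent", "tumor")
  samples <- if (n_reps == 1) tissues
             else as.vector(outer(tissues, seq_len(n_reps), paste, sep = "_"))
  tissue_of <- rep(tissues, times = if (n_reps == 1) 1 else n_reps)
  if (n_reps > 1) tissue_of <- sub("_\\d+$", "", samples)
  mu <- as.matrix(truth[, c("mean_normal", "mean_adjacent", "mean_tumor")])
  colnames(mu) <- tissues
  scale <- rep(1, length(samples))
  if (!is.null(library_sizes)) {
    library_sizes <- library_sizes[samples]
    if (anyNA(library_sizes)) abort_arg("library_sizes must name every sample")
    scale <- library_sizes / design$library_size
  }
  counts <- with_seed(seed, {
    m <- vapply(seq_along(samples), function(j)
      rpois(nrow(truth), mu[, tissue_of[j]] * scale[j]), numeric(nrow(truth)))
    m
  })
  dimnames(counts) <- list(truth$mirna_id, samples)
  list(counts = mir_counts(counts, group = tissue_of), truth = truth)
}

#' Simulate a triplicate qPCR plate with a U6 reference
#'
#' Emulates the validation arm of a three-tissue study: for each sample and
#' target, three technical-replicate Ct values are drawn around a true Ct
#' that decreases by one cycle per doubling of expected expression
#' (`Ct = ct_anchor - log2(mean)`), and each sample carries a triplicate U6
#' reference row with constant expected Ct. Gaussian noise of `noise_sd`
#' cycles is added per replicate.
#'
#' @param truth A [truth_table()] (expected means per tissue).
#' @param n_samples Samples per tissue group (>= 2).
#' @param noise_sd Per-replicate Ct noise in cycles (>= 0).
#' @param seed Integer seed.
#' @param targets Target miRNA ids; default the gradient miRNAs of `truth`
#'   (all miRNAs when none carry a gradient).
#' @param ct_anchor Ct of a target at unit expected expression.
#' @param ct_reference Expected Ct of the U6 reference.
#' @return A `data.frame` of class `qpcr_table`: `sample_id`, `group`,
#'   `target_id` (including `"U6"` rows), `ct_rep1`..`ct_rep3`.
#' @examples
#' tt <- truth_table(simulation_design(n_mirnas = 5, n_gradient_up = 1,
#'                                     gradient_step = 4))
#' head(simulate_qpcr(tt, n_samples = 3, noise_sd = 0, seed = 1))
#' @export
simulate_qpcr <- function(truth, n_samples = 9L, noise_sd = 0.25, seed = 1L,
                          targets = NULL, ct_anchor = 30, ct_reference = 18) {
  if (!is.data.frame(truth) || !all(c("mirna_id", "class", "mean_normal",
                                      "mean_adjacent", "mean_tumor")
                                    %in% names(truth)))
    abort_arg("truth must be a truth_table data frame")
  if (!is_count_scalar(n_samples) || n_samples < 2)
    abort_arg("n_samples must be an integer >= 2")
  if (!is.numeric(noise_sd) || noise_sd < 0)
    abort_arg("noise_sd must be >= 0")
  if (is.null(targets)) {
    targets <- truth$mirna_id[truth$class != "null"]
    if (length(targets) == 0) targets <- truth$mirna_id
  }
  if (!all(targets %in% truth$mirna_id))
    abort_arg("targets must appear in the truth table")
  tissues <- c("normal", "adjacent", "tumor")
  mu <- as.matrix(truth[match(targets, truth$mirna_id),
                        c("mean_normal", "mean_adjacent", "mean_tumor")])
  colnames(mu) <- tissues

  grid <- expand.grid(sample = seq_len(n_samples), group = tissues,
                      target_id = c(targets, "U6"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  true_ct <- ifelse(grid$target_id == "U6", ct_reference,
                    ct_anchor - log2(mu[cbind(
                      match(grid$target_id, targets), grid$group)]))
  with_seed(seed, {
    reps <- matrix(rnorm(3 * nrow(grid), mean = true_ct, sd = noise_sd),
                   ncol = 3)
    out <- data.frame(sample_id = sprintf("%s_%02d", grid$group, grid$sample),
                      group = grid$group,
                      target_id = grid$target_id,
                      ct_rep1 = reps[, 1], ct_rep2 = reps[, 2],
                      ct_rep3 = reps[, 3], stringsAsFactors = FALSE)
    out <- out[order(out$group, out$sample_id,
                     out$target_id == "U6", out$target_id), ]
    rownames(out) <- NULL
    class(out) <- c("qpcr_table", "data.frame")
    out
  })
}
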