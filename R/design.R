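#' Simulation design for synthetic small RNA data
#'
#' Bundles every tunable of the synthetic-data generator: cohort size,
#' gradient structure, sequencing depth, read-length spectrum, isomiR end
#' heterogeneity, and the per-read substitution rate. Defaults emulate a
#' pooled three-tissue lung small RNA study: a few hundred expressed miRNAs,
#' read lengths peaking at 22 nt, mostly canonical ends with rare +/-1..4 nt
#' isomiR offsets, and a small number of miRNAs carrying monotone >= 2-fold
#' expression gradients from normal through adjacent to tumor tissue.
#'
#' @param n_mirnas Number of miRNAs (one mature arm per synthetic precursor).
#' @param n_gradient_up,n_gradient_down Number of miRNAs whose expected
#'   expression rises (falls) by `gradient_step` at each tissue step
#'   normal -> adjacent -> tumor. Their sum must not exceed `n_mirnas`.
#' @param baseline_mean Expected raw count of a null miRNA in the normal
#'   library (also the normal-tissue mean of gradient miRNAs).
#' @param gradient_step Per-tissue multiplicative change of gradient miRNAs
#'   (>= 2, the study's fold-change definition of a gradient).
#' @param library_size Nominal reads per library; also the default number of
#'   reads drawn by [simulate_reads()].
#' @param read_length_weights Named probability vector over canonical read
#'   lengths 18..25 nt (names are the lengths); must sum to 1.
#' @param isomir_offset_probs End-offset distribution(s) over -4..+4
#'   (positive = extension beyond the canonical end): either one named
#'   probability vector applied independently to both ends, or a list with
#'   elements `offset5` and `offset3` giving each end its own distribution
#'   (3' end heterogeneity usually dominates in real isomiR data); each
#'   vector must sum to 1.
#' @param mismatch_rate Per-read probability of one random substitution.
#' @param seed Integer seed from which all generator randomness derives.
#'
#' @return An object of class `simulation_design` (a validated list).
#' @examples
#' d <- simulation_design(n_mirnas = 50, seed = 1)
#' d$gradient_step
#' @export
simulation_design <- function(n_mirnas = 300,
                              n_gradient_up = 2,
                              n_gradient_down = 1,
                              baseline_mean = 100,
                              gradient_step = 2,
                              library_size = 1e6,
                              read_length_weights = default_length_weights(),
                              isomir_offset_probs = default_offset_probs(),
                              mismatch_rate = 0.01,
                              seed = 1L) {
  if (!is_count_scalar(n_mirnas) || n_mirnas < 1)
    abort_arg("n_mirnas must be a positive integer")
  if (!is_count_scalar(n_gradient_up) || n_gradient_up < 0 ||
      !is_count_scalar(n_gradient_down) || n_gradient_down < 0)
    abort_arg("gradient miRNA counts must be non-negative integers")
  if (n_gradient_up + n_gradient_down > n_mirnas)
    abort_arg("n_gradient_up + n_gradient_down must not exceed n_mirnas")
  if (!is.numeric(baseline_mean) || baseline_mean <= 0)
    abort_arg("baseline_mean must be positive")
  if (!is.numeric(gradient_step) || gradient_step < 2)
    abort_arg("gradient_step must be >= 2")
  if (!is_count_scalar(library_size) || library_size < 1)
    abort_arg("library_size must be a positive integer")
  read_length_weights <- check_prob_vector(read_length_weights, 18:25,
                                           "read_length_weights")
  if (!is.list(isomir_offset_probs))
    isomir_offset_probs <- list(offset5 = isomir_offset_probs,
                                offset3 = isomir_offset_probs)
  if (!setequal(names(isomir_offset_probs), c("offset5", "offset3")))
    abort_arg("isomir_offset_probs list needs elements offset5 and offset3")
  isomir_offset_probs <- lapply(isomir_offset_probs[c("offset5", "offset3")],
                                check_prob_vector, support = -4:4,
                                what = "isomir_offset_probs")
  if (!is.numeric(mismatch_rate) || mismatch_rate < 0 || mismatch_rate > 1)
    abort_arg("mismatch_rate must be a probability")
  if (!is_count_scalar(seed)) abort_arg("seed must be an integer")

  structure(
    list(n_mirnas = as.integer(n_mirnas),
         n_gradient_up = as.integer(n_gradient_up),
         n_gradient_down = as.integer(n_gradient_down),
         baseline_mean = baseline_mean,
         gradient_step = gradient_step,
         library_size = as.integer(library_size),
         read_length_weights = read_length_weights,
         isomir_offset_probs = isomir_offset_probs,
         mismatch_rate = mismatch_rate,
         seed = as.integer(seed)),
    class = "simulation_design")
}

check_prob_vector <- function(p, support, what) {
  if (is.null(names(p)) || !setequal(names(p), as.character(support)))
    abort_arg(what, " must be named with ", paste(range(support), collapse = ".."))
  p <- p[as.character(support)]
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    abort_arg(what, " entries must be probabilities in [0, 1]")
  if (abs(sum(p) - 1) > 1e-9)
    abort_arg(what, " must sum to 1 (got ", format(sum(p)), ")")
  p
}

#' @rdname simulation_design
#' @export
default_length_weights <- function() {
  c(`18` = 0.02, `19` = 0.05, `20` = 0.15, `21` = 0.20,
    `22` = 0.35, `23` = 0.15, `24` = 0.05, `25` = 0.03)
}

#' @rdname simulation_design
#' @export
default_offset_probs <- function() {
  c(`-4` = 0.005, `-3` = 0.015, `-2` = 0.05, `-1` = 0.13, `0` = 0.60,
    `1` = 0.13, `2` = 0.05, `3` = 0.015, `4` = 0.005)
}

#' @export
print.simulation_design <- function(x, ...) {
  cat("Simulation design:", x$n_mirnas, "miRNAs (",
      x$n_gradient_up, "up-gradient,", x$n_gradient_down, "down-gradient )\n")
  cat("  baseline mean", x$baseline_mean, "| gradient step", x$gradient_step,
      "| library size", x$library_size, "\n")
  cat("  mismatch rate", x$mismatch_rate, "| seed", x$seed, "\n")
  invisible(x)
}

#' Ground-truth expression table implied by a simulation design
#'
#' Expands a [simulation_design()] into one row per miRNA with its class
#' (`up_gradient`, `down_gradient` or `null`) and the expected raw counts in
#' the normal, adjacent and tumor libraries. Up-gradients multiply the
#' baseline by `gradient_step` at each tissue step; down-gradients divide;
#' null miRNAs stay at the baseline.
#'
#' @param design A [simulation_design()].
#' @return A `data.frame` with columns `mirna_id`, `class`, `mean_normal`,
#'   `mean_adjacent`, `mean_tumor`.
#' @examples
#' truth_table(simulation_design(n_mirnas = 4, n_gradient_up = 1,
#'                               n_gradient_down = 1, gradient_step = 4))
#' @export
truth_table <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  n <- design$n_mirnas
  cls <- rep("null", n)
  if (design$n_gradient_up > 0) cls[seq_len(design$n_gradient_up)] <- "up_gradient"
  if (design$n_gradient_down > 0)
    cls[design$n_gradient_up + seq_len(design$n_gradient_down)] <- "down_gradient"
  b <- design$baseline_mean
  s <- design$gradient_step
  step <- ifelse(cls == "up_gradient", s, ifelse(cls == "down_gradient", 1 / s, 1))
  data.frame(mirna_id = sprintf("syn-mir-%04d", seq_len(n)),
             class = cls,
             mean_normal = b,
             mean_adjacent = b * step,
             mean_tumor = b * step^2,
             stringsAsFactors = FALSE)
}
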