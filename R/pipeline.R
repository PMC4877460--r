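#' Configuration for the end-to-end synthetic workflow
#'
#' Collects everything [run_all()] needs: the synthetic-data design, the
#' differential-expression thresholds, gradient strictness, qPCR options and
#' the output directory. All randomness derives from `design$seed`.
#'
#' @param out_dir Output directory (created if missing).
#' @param design A [simulation_design()].
#' @param de A [de_config()].
#' @param reads_per_sample Reads simulated per tissue library for the
#'   quantification branch (default 10000; kept modest so an end-to-end run
#'   finishes in seconds).
#' @param strict_gradient Require a 2-fold tumor-vs-adjacent step in
#'   gradient calls (see [gradient_table()]).
#' @param qpcr_n_samples,qpcr_noise_sd Validation-arm qPCR design
#'   (samples per group, per-replicate Ct noise in cycles).
#' @param qpcr_paired Use the paired t-test in the qPCR summary.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            design = simulation_design(),
                            de = de_config(),
                            reads_per_sample = 10000L,
                            strict_gradient = FALSE,
                            qpcr_n_samples = 9L,
                            qpcr_noise_sd = 0.25,
                            qpcr_paired = FALSE) {
  stopifnot(inherits(design, "simulation_design"), inherits(de, "de_config"))
  if (!is.character(out_dir) || length(out_dir) != 1 || !nzchar(out_dir))
    abort_arg("out_dir must be a directory path")
  if (!is_count_scalar(reads_per_sample) || reads_per_sample < 1)
    abort_arg("reads_per_sample must be a positive integer")
  structure(list(out_dir = out_dir, design = design, de = de,
                 reads_per_sample = as.integer(reads_per_sample),
                 strict_gradient = isTRUE(strict_gradient),
                 qpcr_n_samples = as.integer(qpcr_n_samples),
                 qpcr_noise_sd = qpcr_noise_sd,
                 qpcr_paired = isTRUE(qpcr_paired)),
            class = "pipeline_config")
}

#' Run the full synthetic three-tissue workflow
#'
#' Reproduces the study workflow on generated data with known truth:
#' simulate precursors and per-tissue read libraries, quantify them with the
#' isomiR rule, simulate the three-tissue count matrix, call differential
#' expression for tumor-vs-normal, adjacent-vs-normal and tumor-vs-adjacent
#' (filter, exact test, FDR, fold-change gate), partition the two
#' normal-referenced DE sets, call expression gradients, and run the
#' delta-delta-Ct qPCR validation arm. All tables are written as TSV (plus
#' FASTA/GFF3/FASTQ for the references and reads) under `config$out_dir`,
#' together with a machine-readable JSON run report listing every threshold
#' and the number of miRNAs surviving each stage. The report carries no
#' timestamps, so identical configurations yield byte-identical reports.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with `precursors`, `quant` (per-tissue
#'   quantification), `counts`, `truth`, `de` (three tables), `venn`,
#'   `gradient`, `qpcr`, `qpcr_summary`, `report`, `files`.
#' @examples
#' \donttest{
#' cfg <- pipeline_config(tempfile("run"),
#'                        design = simulation_design(n_mirnas = 40, seed = 42),
#'                        reads_per_sample = 2000)
#' res <- run_all(cfg, quiet = TRUE)
#' res$report$stages$tumor_vs_normal
#' }
#' @export
run_all <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  design <- config$design
  say <- function(...) if (!quiet) message(...)
  path <- function(f) file.path(config$out_dir, f)
  files <- character(0)
  add_file <- function(f) files <<- c(files, f)

  say("simulating precursors (n = ", design$n_mirnas, ")")
  precursors <- simulate_precursors(design$n_mirnas, seed = design$seed)
  write_precursor_fasta(precursors, path("precursors.fa"))
  write_mature_gff(precursors, path("mature.gff3"))
  add_file(c("precursors.fa", "mature.gff3"))

  tissues <- c("normal", "adjacent", "tumor")
  say("simulating and quantifying ", config$reads_per_sample,
      " reads per tissue")
  read_sets <- lapply(seq_along(tissues), function(i) {
    r <- simulate_reads(precursors, design, n_reads = config$reads_per_sample,
                        seed = design$seed + i)
    write_reads_fastq(r, path(paste0("reads_", tissues[i], ".fastq")))
    add_file(paste0("reads_", tissues[i], ".fastq"))
    r
  })
  names(read_sets) <- tissues
  quant <- quantify_samples(read_sets, precursors)

  say("simulating three-tissue count matrix")
  sim <- simulate_counts(design)
  counts <- sim$counts
  truth <- sim$truth
  write_counts_tsv(counts, path("counts.tsv"))
  write_table_tsv(truth, path("truth.tsv"))
  add_file(c("counts.tsv", "truth.tsv"))

  comparisons <- list(tumor_vs_normal = c("normal", "tumor"),
                      adjacent_vs_normal = c("normal", "adjacent"),
                      tumor_vs_adjacent = c("adjacent", "tumor"))
  de <- lapply(comparisons, function(p)
    de_table(counts, p[1], p[2], config = config$de))
  for (nm in names(de)) {
    write_table_tsv(de[[nm]], path(paste0("de_", nm, ".tsv")))
    add_file(paste0("de_", nm, ".tsv"))
  }
  stage_counts <- lapply(de, function(d) {
    kept <- d[d$kept, ]
    list(n_total = nrow(d),
         n_kept_filter = nrow(kept),
         n_fdr = sum(kept$q_value < config$de$q_threshold, na.rm = TRUE),
         n_called = sum(d$called))
  })

  venn <- venn_partition(de$tumor_vs_normal$mirna_id[de$tumor_vs_normal$called],
                         de$adjacent_vs_normal$mirna_id[de$adjacent_vs_normal$called])

  say("calling expression gradients")
  gradient <- gradient_from_counts(counts, de$tumor_vs_normal,
                                   de$adjacent_vs_normal,
                                   strict = config$strict_gradient,
                                   fc_threshold = config$de$fc_threshold,
                                   pseudocount = config$de$pseudocount_cpm)
  write_table_tsv(gradient, path("gradient.tsv"))
  add_file("gradient.tsv")

  say("simulating and summarizing the qPCR validation arm")
  qpcr <- simulate_qpcr(truth, n_samples = config$qpcr_n_samples,
                        noise_sd = config$qpcr_noise_sd,
                        seed = design$seed + 100L)
  write_qpcr_tsv(qpcr, path("qpcr.tsv"))
  qsum <- qpcr_summary(qpcr, paired = config$qpcr_paired)
  write_table_tsv(qsum$groups, path("qpcr_groups.tsv"))
  write_table_tsv(qsum$contrasts, path("qpcr_contrasts.tsv"))
  add_file(c("qpcr.tsv", "qpcr_groups.tsv", "qpcr_contrasts.tsv"))

  report <- list(
    schema_version = 1L,
    seed = design$seed,
    design = list(n_mirnas = design$n_mirnas,
                  n_gradient_up = design$n_gradient_up,
                  n_gradient_down = design$n_gradient_down,
                  baseline_mean = design$baseline_mean,
                  gradient_step = design$gradient_step,
                  library_size = design$library_size,
                  mismatch_rate = design$mismatch_rate,
                  reads_per_sample = config$reads_per_sample),
    thresholds = list(min_count = config$de$min_count,
                      q_threshold = config$de$q_threshold,
                      fc_threshold = config$de$fc_threshold,
                      pseudocount_cpm = config$de$pseudocount_cpm,
                      filter_mode = config$de$filter_mode,
                      strict_gradient = config$strict_gradient),
    stage_order = c("filter", "test", "fdr", "fold_change", "gradient"),
    stages = stage_counts,
    quantification = lapply(quant$quants, function(q)
      list(n_reads = q$n_reads, n_unassigned = q$n_unassigned,
           n_assigned = q$n_reads - q$n_unassigned)),
    venn = list(tumor_only = length(venn$tumor_only),
                adjacent_only = length(venn$adjacent_only),
                shared = length(venn$shared)),
    gradient = list(up_gradient = sum(gradient$class == "up_gradient"),
                    down_gradient = sum(gradient$class == "down_gradient"),
                    none = sum(gradient$class == "none")),
    qpcr = list(n_samples = config$qpcr_n_samples,
                noise_sd = config$qpcr_noise_sd,
                contrasts = qsum$contrasts),
    files = files)
  jsonlite::write_json(report, path("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  add_file("report.json")
  say("done: ", length(files), " files under ", config$out_dir)

  invisible(list(precursors = precursors, quant = quant, counts = counts,
                 truth = truth, de = de, venn = venn, gradient = gradient,
                 qpcr = qpcr, qpcr_summary = qsum, report = report,
                 files = file.path(config$out_dir, files)))
}
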