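#' Simulate small RNA reads with recorded isomiR truth
#'
#' Draws reads from the mature regions of a precursor set. For each read a
#' precursor is sampled with probability proportional to the design's
#' `read_length_weights` at its mature length (so the canonical length
#' spectrum matches the design, peaking at 22 nt by default); 5' and 3' end
#' offsets are then drawn independently from `isomir_offset_probs`
#' (positive = extension into the precursor beyond the canonical end,
#' negative = truncation), and with probability `mismatch_rate` one random
#' substitution is planted. Offset pairs that would push the read outside
#' the 15-35 nt matching domain are resampled. The generating precursor,
#' both offsets and the mismatch count are recorded per read, so
#' quantification can be scored against the truth.
#'
#' @param precursors A `precursor_set` (see [simulate_precursors()]).
#' @param design A [simulation_design()].
#' @param n_reads Number of reads; defaults to `design$library_size`.
#' @param seed Integer seed; defaults to `design$seed`.
#' @return A `data.frame` of class `read_set`: `read_id`, `sequence`,
#'   `precursor_id`, `mature_id`, `arm`, `offset5`, `offset3`,
#'   `n_mismatches`, `canonical_length` (mature length before offsets).
#' @examples
#' p <- simulate_precursors(3, seed = 1)
#' r <- simulate_reads(p, simulation_design(mismatch_rate = 0), n_reads = 50)
#' table(nchar(r$sequence))
#' @export
simulate_reads <- function(precursors, design, n_reads = design$library_size,
                           seed = design$seed) {
  stopifnot(inherits(design, "simulation_design"))
  if (!inherits(precursors, "precursor_set") || nrow(precursors) == 0)
    abort_arg("precursors must be a non-empty precursor_set")
  if (!is_count_scalar(n_reads) || n_reads < 1)
    abort_arg("n_reads must be a positive integer")

  mlen <- precursors$mature_end - precursors$mature_start + 1L
  w <- design$read_length_weights[as.character(mlen)]
  w[is.na(w)] <- 0
  # split each length's weight across the precursors carrying it, so the
  # canonical-length spectrum matches the design regardless of how many
  # precursors share a length
  tab <- table(mlen)
  w <- w / as.numeric(tab[as.character(mlen)])
  if (sum(w) == 0)
    abort_arg("no precursor has a mature length with positive weight in ",
              "read_length_weights")
  offs <- -4:4
  p5 <- design$isomir_offset_probs$offset5
  p3 <- design$isomir_offset_probs$offset3

  with_seed(seed, {
    idx <- sample.int(nrow(precursors), n_reads, replace = TRUE, prob = w)
    o5 <- sample(offs, n_reads, replace = TRUE, prob = p5)
    o3 <- sample(offs, n_reads, replace = TRUE, prob = p3)
    # keep windows inside the 15-35 nt matching domain
    repeat {
      len <- mlen[idx] + o5 + o3
      bad <- which(len < 15 | len > 35)
      if (length(bad) == 0) break
      o5[bad] <- sample(offs, length(bad), replace = TRUE, prob = p5)
      o3[bad] <- sample(offs, length(bad), replace = TRUE, prob = p3)
    }
    start <- precursors$mature_start[idx] - o5
    end <- precursors$mature_end[idx] + o3
    seqs <- substr(precursors$sequence[idx], start, end)
    mut <- runif(n_reads) < design$mismatch_rate
    if (any(mut)) {
      for (i in which(mut)) {
        pos <- sample.int(nchar(seqs[i]), 1)
        old <- substr(seqs[i], pos, pos)
        substr(seqs[i], pos, pos) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
      }
    }
    out <- data.frame(read_id = sprintf("r%07d", seq_len(n_reads)),
                      sequence = seqs,
                      precursor_id = precursors$id[idx],
                      mature_id = precursors$mature_id[idx],
                      arm = precursors$arm[idx],
                      offset5 = o5, offset3 = o3,
                      n_mismatches = as.integer(mut),
                      canonical_length = mlen[idx],
                      stringsAsFactors = FALSE)
    class(out) <- c("read_set", "data.frame")
    out
  })
}

#' Read and write simulated reads as FASTQ
#'
#' Reads are written as plain 4-line FASTQ with a constant quality string
#' (`I`); the generator truth (mature id, end offsets, mismatch count)
#' travels in the header comment so downstream scoring needs no side files.
#'
#' @param reads A `read_set` from [simulate_reads()].
#' @param path FASTQ file path.
#' @return `read_reads_fastq()` returns a `data.frame` with `read_id` and
#'   `sequence`, plus the truth columns when present in the comments;
#'   `write_reads_fastq()` returns `path` invisibly.
#' @export
write_reads_fastq <- function(reads, path) {
  stopifnot(inherits(reads, "read_set"))
  hdr <- sprintf("@%s mature_id=%s;offset5=%d;offset3=%d;mismatches=%d",
                 reads$read_id, reads$mature_id, reads$offset5,
                 reads$offset3, reads$n_mismatches)
  qual <- strrep("I", nchar(reads$sequence))
  writeLines(as.vector(rbind(hdr, reads$sequence, "+", qual)), path)
  invisible(path)
}

#' @rdname write_reads_fastq
#' @export
read_reads_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  full <- names(x)
  read_id <- sub("\\s.*$", "", full)
  out <- data.frame(read_id = read_id, sequence = as.character(x),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  comment <- ifelse(grepl("\\s", full), sub("^\\S+\\s+", "", full), "")
  if (all(grepl("mature_id=", comment))) {
    grab <- function(key, conv = identity)
      conv(sub(paste0(".*", key, "=([^;]+).*"), "\\1", comment))
    out$mature_id <- grab("mature_id")
    out$offset5 <- grab("offset5", as.integer)
    out$offset3 <- grab("offset3", as.integer)
    out$n_mismatches <- grab("mismatches", as.integer)
  }
  out
}
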