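#' Simulate pre-miRNA hairpin precursors
#'
#' Builds `n` synthetic precursors with a realistic stem-loop architecture:
#' a 4 nt single-stranded flank, a mature-bearing arm (mature 20-23 nt plus a
#' 4-6 nt stem pad), an 8-12 nt terminal loop, the opposite arm (the reverse
#' complement of the mature arm with 0-2 planted point changes, emulating the
#' bulges of natural hairpins), and a 4 nt 3' flank. Loops and flanks are
#' drawn from A/C only so they cannot base-pair with each other, keeping the
#' designed stem the unique fold. The mature miRNA is assigned to the 5p or
#' 3p arm at random; flanks and pads leave at least 4 nt of template on each
#' side of the mature region so isomiR windows up to +/-4 nt always exist.
#'
#' @param n Number of precursors (positive integer).
#' @param seed Integer seed; the output is deterministic given `seed`.
#' @return A `data.frame` of class `precursor_set` with columns `id`,
#'   `sequence` (DNA), `mature_id`, `arm` (`"5p"`/`"3p"`), `mature_start`,
#'   `mature_end` (1-based inclusive coordinates within the precursor),
#'   `mature_seq`, and the terminal-loop span `loop_start`/`loop_end`.
#' @examples
#' p <- simulate_precursors(2, seed = 7)
#' substr(p$sequence[1], p$mature_start[1], p$mature_end[1]) == p$mature_seq[1]
#' @export
simulate_precursors <- function(n, seed = 1L) {
  if (!is_count_scalar(n) || n < 1) abort_arg("n must be a positive integer")
  with_seed(seed, {
    rows <- lapply(seq_len(n), function(i) {
      m <- sample(20:23, 1)
      pad <- sample(4:6, 1)
      loop_len <- sample(8:12, 1)
      arm <- sample(c("5p", "3p"), 1)
      mature <- paste(sample(c("A", "C", "G", "T"), m, replace = TRUE),
                      collapse = "")
      pad_seq <- paste(sample(c("A", "C", "G", "T"), pad, replace = TRUE),
                       collapse = "")
      loop <- paste(sample(c("A", "C"), loop_len, replace = TRUE), collapse = "")
      flank5 <- paste(sample(c("A", "C"), 4, replace = TRUE), collapse = "")
      flank3 <- paste(sample(c("A", "C"), 4, replace = TRUE), collapse = "")
      # mature arm: pad sits loop-side of the mature sequence
      mature_arm <- if (arm == "5p") paste0(mature, pad_seq)
                    else paste0(pad_seq, mature)
      opp <- plant_changes(revcomp(mature_arm), sample(0:2, 1))
      a_len <- nchar(mature_arm)
      if (arm == "5p") {
        seqn <- paste0(flank5, mature_arm, loop, opp, flank3)
        mstart <- 5L
      } else {
        seqn <- paste0(flank5, opp, loop, mature_arm, flank3)
        mstart <- 4L + a_len + loop_len + pad + 1L
      }
      id <- sprintf("syn-mir-%04d", i)
      data.frame(id = id, sequence = seqn,
                 mature_id = paste0(id, "-", arm), arm = arm,
                 mature_start = mstart, mature_end = mstart + m - 1L,
                 mature_seq = mature,
                 loop_start = 4L + a_len + 1L,
                 loop_end = 4L + a_len + loop_len,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    class(out) <- c("precursor_set", "data.frame")
    out
  })
}

plant_changes <- function(seqn, k) {
  if (k == 0) return(seqn)
  chars <- strsplit(seqn, "")[[1]]
  pos <- sample(length(chars), k)
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  paste(chars, collapse = "")
}

#' Read and write precursor references
#'
#' Precursor sequences travel as FASTA; mature-arm coordinates travel as a
#' GFF3 annotation (`type = miRNA`, 1-based inclusive coordinates, `+`
#' strand, attributes `ID` = mature id and `arm` = 5p/3p), the layout used by
#' miRBase-style hairpin annotations.
#'
#' @param precursors A `precursor_set` data frame (see
#'   [simulate_precursors()]).
#' @param fasta,gff Paths to the precursor FASTA and the mature-arm GFF3.
#' @return `read_precursors()` returns a validated `precursor_set`;
#'   the writers return their path invisibly.
#' @examples
#' p <- simulate_precursors(2, seed = 1)
#' fa <- tempfile(fileext = ".fa"); gf <- tempfile(fileext = ".gff3")
#' write_precursor_fasta(p, fa); write_mature_gff(p, gf)
#' q <- read_precursors(fa, gf)
#' all(q$mature_seq == p$mature_seq)
#' @export
write_precursor_fasta <- function(precursors, fasta) {
  stopifnot(inherits(precursors, "precursor_set"))
  x <- Biostrings::DNAStringSet(stats::setNames(precursors$sequence,
                                                precursors$id))
  Biostrings::writeXStringSet(x, fasta)
  invisible(fasta)
}

#' @rdname write_precursor_fasta
#' @export
write_mature_gff <- function(precursors, gff) {
  stopifnot(inherits(precursors, "precursor_set"))
  lines <- c("##gff-version 3",
             sprintf("%s\tmiRtrend\tmiRNA\t%d\t%d\t.\t+\t.\tID=%s;arm=%s",
                     precursors$id, precursors$mature_start,
                     precursors$mature_end, precursors$mature_id,
                     precursors$arm))
  writeLines(lines, gff)
  invisible(gff)
}

#' @rdname write_precursor_fasta
#' @export
read_precursors <- function(fasta, gff) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  ids <- sub("\\s.*$", "", names(seqs))
  ann <- rtracklayer::import(gff)
  ann <- ann[ann$type == "miRNA"]
  seqid <- as.character(GenomicRanges::seqnames(ann))
  idx <- match(seqid, ids)
  if (anyNA(idx))
    abort_arg("annotation references precursors absent from the FASTA: ",
              paste(unique(seqid[is.na(idx)]), collapse = ", "))
  out <- data.frame(id = seqid,
                    sequence = as.character(seqs)[idx],
                    mature_id = ann$ID,
                    arm = if (!is.null(ann$arm)) ann$arm else NA_character_,
                    mature_start = GenomicRanges::start(ann),
                    mature_end = GenomicRanges::end(ann),
                    stringsAsFactors = FALSE)
  out$mature_seq <- substr(out$sequence, out$mature_start, out$mature_end)
  validate_precursors(out)
  class(out) <- c("precursor_set", "data.frame")
  out
}

validate_precursors <- function(p) {
  len <- nchar(p$sequence)
  mlen <- p$mature_end - p$mature_start + 1L
  if (any(p$mature_start < 1 | p$mature_end > len | p$mature_start > p$mature_end))
    abort_arg("mature coordinates out of precursor bounds")
  if (any(mlen < 16 | mlen > 30))
    abort_arg("mature arm lengths must be 16-30 nt")
  invisible(p)
}
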