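#' Match one read against a precursor's mature region (isomiR rule)
#'
#' A read is an isomiR of a mature miRNA when it equals the mature region of
#' the precursor shifted by at most 4 nt at each end with at most one
#' substitution. Candidate windows shift the canonical 5' end by `offset5`
#' and the 3' end by `offset3` (positive = extension into the precursor,
#' negative = truncation); only windows whose length equals the read length
#' and which lie inside the precursor are considered. Among windows within
#' the mismatch budget, ties break by fewest mismatches, then smallest
#' `|offset5| + |offset3|`, then smallest `|offset5|`.
#'
#' Reads are assumed sense-strand and adapter-trimmed (directional small RNA
#' libraries); no reverse-complement search is performed. Indels are not
#' isomiR events: only substitutions count. Reads outside 15-35 nt are
#' reported as no-match.
#'
#' @param read A single nucleotide string (ACGT/U).
#' @param precursor One row of a `precursor_set` (or any list with
#'   `sequence`, `mature_start`, `mature_end`, `mature_id` — 1-based
#'   inclusive coordinates).
#' @param arm Optional arm filter (`"5p"`/`"3p"`); when given it must equal
#'   the precursor row's arm.
#' @param max_offset Maximum end shift in nt (default 4).
#' @param max_mismatch Maximum substitutions (default 1).
#' @return A list (`mature_id`, `offset5`, `offset3`, `n_mismatches`,
#'   `is_canonical`) or `NULL` when no window matches.
#' @examples
#' p <- simulate_precursors(1, seed = 7)
#' match_read(p$mature_seq, p)            # canonical: offsets 0/0
#' match_read(substr(p$mature_seq, 1, nchar(p$mature_seq) - 2), p)
#' @export
match_read <- function(read, precursor, arm = NULL,
                       max_offset = 4L, max_mismatch = 1L) {
  if (!is.character(read) || length(read) != 1 || is.na(read) || !nzchar(read))
    abort_arg("read must be a non-empty nucleotide string")
  read <- chartr("U", "T", toupper(read))
  if (!is.null(arm) && !is.null(precursor$arm) && !identical(precursor$arm, arm))
    return(NULL)
  L <- nchar(read)
  if (L < 15 || L > 35) return(NULL)
  mstart <- precursor$mature_start
  mend <- precursor$mature_end
  mlen <- mend - mstart + 1L
  delta <- L - mlen
  if (abs(delta) > 2L * max_offset) return(NULL)
  o5s <- seq.int(max(-max_offset, delta - max_offset),
                 min(max_offset, delta + max_offset))
  best <- NULL
  plen <- nchar(precursor$sequence)
  rint <- utf8ToInt(read)
  pint <- utf8ToInt(precursor$sequence)
  for (o5 in o5s) {
    o3 <- delta - o5
    ws <- mstart - o5
    we <- mend + o3
    if (ws < 1 || we > plen) next
    mm <- sum(rint != pint[ws:we])
    if (mm > max_mismatch) next
    cand <- list(mature_id = precursor$mature_id, offset5 = as.integer(o5),
                 offset3 = as.integer(o3), n_mismatches = as.integer(mm),
                 is_canonical = (o5 == 0L && o3 == 0L && mm == 0L))
    if (is.null(best) || better_call(cand, best)) best <- cand
  }
  best
}

# TRUE when a beats b under (mismatches, |o5|+|o3|, |o5|)
better_call <- function(a, b) {
  ka <- c(a$n_mismatches, abs(a$offset5) + abs(a$offset3), abs(a$offset5))
  kb <- c(b$n_mismatches, abs(b$offset5) + abs(b$offset3), abs(b$offset5))
  d <- ka - kb
  nz <- which(d != 0)
  length(nz) > 0 && d[nz[1]] < 0
}

#' @rdname match_read
#' @export
classify_isomir <- match_read

#' Quantify one small RNA sample against a precursor reference
#'
#' Every read is matched against all mature regions with the isomiR rule of
#' [match_read()]. Across precursors a read is assigned once (single-count
#' policy): to the match with fewest mismatches, ties broken
#' lexicographically by mature id; multi-matching sequences are logged in
#' the returned `multimap` table. Reads matching nothing (or outside
#' 15-35 nt) are counted as unassigned, never dropped silently.
#'
#' For speed the canonical and offset windows of all precursors are indexed
#' once, so exact (mismatch-free) reads resolve by dictionary lookup and
#' only mismatched reads fall back to the per-precursor scan.
#'
#' @param reads Character vector of read sequences, or a `read_set` /
#'   any data frame with a `sequence` column.
#' @param precursors A `precursor_set`.
#' @param max_offset,max_mismatch As in [match_read()].
#' @return A list of class `sample_quant`: `counts` (named vector over all
#'   mature ids), `profile` (data frame `mature_id`, `offset5`, `offset3`,
#'   `n_mismatches`, `count`), `length_hist` (named vector over 15-35 nt,
#'   all reads), `n_reads`, `n_unassigned`, `multimap`.
#' @examples
#' p <- simulate_precursors(2, seed = 1)
#' q <- quantify_sample(rep(p$mature_seq[1], 5), p)
#' q$counts
#' @export
quantify_sample <- function(reads, precursors, max_offset = 4L,
                            max_mismatch = 1L) {
  if (is.data.frame(reads)) reads <- reads$sequence
  if (!inherits(precursors, "precursor_set") || nrow(precursors) == 0)
    abort_arg("precursors must be a non-empty precursor_set")
  reads <- chartr("U", "T", toupper(as.character(reads)))
  n_reads <- length(reads)
  lens <- nchar(reads)
  length_hist <- table(factor(lens[lens >= 15 & lens <= 35], levels = 15:35))
  length_hist <- stats::setNames(as.integer(length_hist), 15:35)

  mature_ids <- sort(precursors$mature_id)
  empty <- stats::setNames(integer(length(mature_ids)), mature_ids)
  if (n_reads == 0) {
    return(structure(list(counts = empty,
                          profile = data.frame(mature_id = character(),
                                               offset5 = integer(),
                                               offset3 = integer(),
                                               n_mismatches = integer(),
                                               count = integer()),
                          length_hist = length_hist, n_reads = 0L,
                          n_unassigned = 0L,
                          multimap = data.frame(sequence = character(),
                                                mature_ids = character(),
                                                count = integer())),
                     class = "sample_quant"))
  }

  win <- window_index(precursors, max_offset)
  tab <- table(reads)
  useq <- names(tab)
  umult <- as.integer(tab)

  hit <- match(useq, win$key$sequence)
  assign_id <- win$key$mature_id[hit]
  assign_o5 <- win$key$offset5[hit]
  assign_o3 <- win$key$offset3[hit]
  assign_mm <- ifelse(is.na(hit), NA_integer_, 0L)
  multi <- win$key$n_matures[hit]

  # fallback: <=1 mismatch scan for sequences without an exact window
  todo <- which(is.na(hit) & nchar(useq) >= 15 & nchar(useq) <= 35)
  for (i in todo) {
    best <- NULL
    for (r in seq_len(nrow(precursors))) {
      cand <- match_read(useq[i], precursors[r, ], max_offset = max_offset,
                         max_mismatch = max_mismatch)
      if (is.null(cand)) next
      if (is.null(best) || cand$n_mismatches < best$n_mismatches ||
          (cand$n_mismatches == best$n_mismatches &&
           cand$mature_id < best$mature_id)) best <- cand
    }
    if (!is.null(best)) {
      assign_id[i] <- best$mature_id
      assign_o5[i] <- best$offset5
      assign_o3[i] <- best$offset3
      assign_mm[i] <- best$n_mismatches
    }
  }

  ok <- !is.na(assign_id)
  counts <- empty
  if (any(ok)) {
    agg <- tapply(umult[ok], assign_id[ok], sum)
    counts[names(agg)] <- as.integer(agg)
  }
  profile <- data.frame(mature_id = assign_id[ok], offset5 = assign_o5[ok],
                        offset3 = assign_o3[ok], n_mismatches = assign_mm[ok],
                        count = umult[ok], stringsAsFactors = FALSE)
  if (nrow(profile)) {
    profile <- stats::aggregate(count ~ mature_id + offset5 + offset3 +
                                  n_mismatches, data = profile, FUN = sum)
    profile <- profile[order(profile$mature_id, -profile$count,
                             profile$offset5, profile$offset3), ]
    profile <- profile[, c("mature_id", "offset5", "offset3",
                           "n_mismatches", "count")]
    rownames(profile) <- NULL
  }
  mm_idx <- which(ok & !is.na(multi) & multi > 1)
  multimap <- data.frame(sequence = useq[mm_idx],
                         mature_ids = win$key$all_matures[hit[mm_idx]],
                         count = umult[mm_idx], stringsAsFactors = FALSE)
  structure(list(counts = counts, profile = profile,
                 length_hist = length_hist, n_reads = n_reads,
                 n_unassigned = as.integer(sum(umult[!ok])),
                 multimap = multimap),
            class = "sample_quant")
}

# Enumerate all in-bounds offset windows (length 15-35) of every precursor
# and keep, per distinct window sequence, the assignment the tie rules pick
# at zero mismatches: lexicographically smallest mature_id, then smallest
# |offset5|+|offset3|, then smallest |offset5|.
window_index <- function(precursors, max_offset = 4L) {
  offs <- seq.int(-max_offset, max_offset)
  grids <- lapply(seq_len(nrow(precursors)), function(r) {
    p <- precursors[r, ]
    g <- expand.grid(offset5 = offs, offset3 = offs, KEEP.OUT.ATTRS = FALSE)
    ws <- p$mature_start - g$offset5
    we <- p$mature_end + g$offset3
    len <- we - ws + 1L
    keep <- ws >= 1 & we <= nchar(p$sequence) & len >= 15 & len <= 35
    g <- g[keep, , drop = FALSE]
    g$sequence <- substr(rep(p$sequence, nrow(g)), ws[keep], we[keep])
    g$mature_id <- p$mature_id
    g
  })
  all <- do.call(rbind, grids)
  all <- all[order(all$mature_id, abs(all$offset5) + abs(all$offset3),
                   abs(all$offset5), all$offset5, all$offset3), ]
  per_mature <- all[!duplicated(paste(all$sequence, all$mature_id, sep = "\r")), ]
  per_mature <- per_mature[order(per_mature$mature_id), ]
  n_mat <- tapply(per_mature$mature_id, per_mature$sequence, length)
  all_mat <- tapply(per_mature$mature_id, per_mature$sequence,
                    paste, collapse = ",")
  key <- per_mature[!duplicated(per_mature$sequence), ]
  key$n_matures <- as.integer(n_mat[key$sequence])
  key$all_matures <- as.character(all_mat[key$sequence])
  list(key = key)
}

#' Dominant isomiR of a profile
#'
#' Returns the `(offset5, offset3, n_mismatches)` key with the largest
#' count. Ties break toward the canonical key `(0, 0, 0)` when it is among
#' the tied keys, then toward the smallest `|offset5| + |offset3|`, then the
#' smallest `|offset5|`.
#'
#' @param profile Data frame with columns `offset5`, `offset3`,
#'   `n_mismatches`, `count` (one miRNA's rows of a `sample_quant` profile).
#' @return Named list `offset5`, `offset3`, `n_mismatches`, `count`.
#' @examples
#' dominant_isomir(data.frame(offset5 = 0, offset3 = c(0, -1),
#'                            n_mismatches = 0, count = c(10, 50)))
#' @export
dominant_isomir <- function(profile) {
  if (!is.data.frame(profile) || nrow(profile) == 0)
    abort_arg("profile must be a non-empty data frame")
  canon <- profile$offset5 == 0 & profile$offset3 == 0 & profile$n_mismatches == 0
  ord <- order(-profile$count, !canon,
               abs(profile$offset5) + abs(profile$offset3),
               abs(profile$offset5), profile$offset5, profile$offset3)
  top <- profile[ord[1], ]
  list(offset5 = top$offset5, offset3 = top$offset3,
       n_mismatches = top$n_mismatches, count = top$count)
}

#' Quantify several samples into a count matrix
#'
#' @param read_sets Named list; each element a read vector or data frame
#'   accepted by [quantify_sample()].
#' @param precursors A `precursor_set`.
#' @param ... Passed to [quantify_sample()].
#' @return A list with `counts` (a [mir_counts()], library sizes = assigned
#'   column totals) and `quants` (per-sample `sample_quant` objects).
#' @export
quantify_samples <- function(read_sets, precursors, ...) {
  if (is.null(names(read_sets)) || any(!nzchar(names(read_sets))))
    abort_arg("read_sets must be a named list")
  quants <- lapply(read_sets, quantify_sample, precursors = precursors, ...)
  counts <- do.call(cbind, lapply(quants, `[[`, "counts"))
  colnames(counts) <- names(read_sets)
  list(counts = mir_counts(counts), quants = quants)
}
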