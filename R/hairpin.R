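#' Fold a sequence by base-pair maximization
#'
#' Computes a maximum-base-pair nested secondary structure (Nussinov-style
#' recurrence with traceback). The pairing rule: Watson-Crick pairs plus
#' G-U wobble; hairpin loops span at least `min_loop` unpaired bases;
#' pseudoknots are excluded by construction; and isolated ("lonely") pairs
#' are disallowed — every helix must contain at least two stacked pairs,
#' the standard refinement that removes the thermodynamically negligible
#' single-pair artifacts plain pair maximization produces. Base-pair
#' maximization itself is a deliberate simplification of free-energy
#' folding: it captures the qualitative stem-loop architecture that
#' distinguishes miRNA precursors without external energy-parameter tables.
#'
#' @param sequence Nucleotide string (ACGU/T, case-insensitive).
#' @param min_loop Minimal unpaired bases closed by a pair (default 3).
#' @param wobble Allow G-U wobble pairs (default `TRUE`). Note that wobble
#'   pairing breaks the reverse-complement symmetry of the pair count (a
#'   G-U pair maps to an unpairable C-A); with `wobble = FALSE` the count
#'   is invariant under reverse complement.
#' @return A list of class `hairpin_fold`: `sequence`, `pair_table`
#'   (integer vector, 1-based partner index or 0 when unpaired), `n_pairs`,
#'   `terminal_loops` (number of hairpin loops), `dot_bracket`, `min_loop`.
#' @examples
#' fold_maxpairs("GGGGAAAACCCC")$dot_bracket   # "((((....))))"
#' @export
fold_maxpairs <- function(sequence, min_loop = 3L, wobble = TRUE) {
  if (!is.character(sequence) || length(sequence) != 1 || is.na(sequence) ||
      !nzchar(sequence))
    abort_arg("sequence must be a non-empty nucleotide string")
  s <- chartr("T", "U", toupper(sequence))
  if (grepl("[^ACGU]", s))
    abort_arg("sequence contains characters outside ACGU/T")
  if (!is_count_scalar(min_loop) || min_loop < 0)
    abort_arg("min_loop must be a non-negative integer")
  n <- nchar(s)
  code <- match(strsplit(s, "")[[1]], c("A", "C", "G", "U"))
  pairable <- can_pair_matrix(wobble)
  p <- function(i, j) pairable[code[i], code[j]]

  # Two tables over spans [i, j]:
  #   W[i,j] — max pairs of a free-standing valid structure (all helices
  #            have >= 2 stacked pairs);
  #   C[i,j] — max pairs given that (i, j) is paired, its helix validity
  #            guaranteed by context (-Inf when (i, j) cannot pair).
  # A helix may start at (k, j) only if (k+1, j-1) is also paired.
  W <- matrix(0, n, n)
  C <- matrix(-Inf, n, n)
  if (n > min_loop + 1) {
    for (d in seq.int(min_loop + 1L, n - 1L)) {
      for (i in seq_len(n - d)) {
        j <- i + d
        if (p(i, j)) {
          inner <- if (d >= min_loop + 3L) max(W[i + 1L, j - 1L],
                                               C[i + 1L, j - 1L]) else 0
          C[i, j] <- 1 + max(inner, 0)
        }
        best <- W[i, j - 1L]
        ks <- i:(j - min_loop - 1L)
        ks <- ks[p(ks, j) & is.finite(C[cbind(pmin(ks + 1L, n), j - 1L)])]
        ks <- ks[ks + 1L <= j - 1L]
        if (length(ks)) {
          left <- numeric(length(ks))
          sel <- ks > i
          left[sel] <- W[i, ks[sel] - 1L]
          best <- max(best, max(left + 1 + C[cbind(ks + 1L, j - 1L)]))
        }
        W[i, j] <- best
      }
    }
  }

  pt <- integer(n)
  # traceback; at ties prefer continuing the current helix, then the
  # smallest pairing partner (canonical nesting)
  stack <- list(list("W", 1L, n))
  while (length(stack)) {
    nd <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    st <- nd[[1]]; i <- nd[[2]]; j <- nd[[3]]
    if (j - i <= min_loop) next
    if (st == "W") {
      if (W[i, j] == W[i, j - 1L]) {
        stack[[length(stack) + 1L]] <- list("W", i, j - 1L)
        next
      }
      for (k in i:(j - min_loop - 1L)) {
        if (!p(k, j) || k + 1L > j - 1L || !is.finite(C[k + 1L, j - 1L])) next
        left <- if (k > i) W[i, k - 1L] else 0
        if (left + 1 + C[k + 1L, j - 1L] == W[i, j]) {
          pt[k] <- j; pt[j] <- k
          if (k > i) stack[[length(stack) + 1L]] <- list("W", i, k - 1L)
          stack[[length(stack) + 1L]] <- list("C", k + 1L, j - 1L)
          break
        }
      }
    } else {                    # state C: (i, j) is paired
      pt[i] <- j; pt[j] <- i
      if (j - i < min_loop + 3L) next
      inner_c <- C[i + 1L, j - 1L]
      inner_w <- W[i + 1L, j - 1L]
      if (is.finite(inner_c) && 1 + inner_c == C[i, j] && inner_c >= inner_w)
        stack[[length(stack) + 1L]] <- list("C", i + 1L, j - 1L)
      else if (1 + inner_w == C[i, j] && inner_w > 0)
        stack[[length(stack) + 1L]] <- list("W", i + 1L, j - 1L)
      else if (is.finite(inner_c) && 1 + inner_c == C[i, j])
        stack[[length(stack) + 1L]] <- list("C", i + 1L, j - 1L)
    }
  }

  db <- rep(".", n)
  db[pt > seq_len(n)] <- "("
  db[pt > 0 & pt < seq_len(n)] <- ")"
  structure(list(sequence = sequence, pair_table = pt,
                 n_pairs = sum(pt > 0) %/% 2L,
                 terminal_loops = count_hairpin_loops(pt),
                 dot_bracket = paste(db, collapse = ""),
                 min_loop = as.integer(min_loop)),
            class = "hairpin_fold")
}

# symmetric lookup over A,C,G,U: Watson-Crick, optionally + G-U wobble
can_pair_matrix <- function(wobble = TRUE) {
  m <- matrix(FALSE, 4, 4, dimnames = list(c("A", "C", "G", "U"),
                                           c("A", "C", "G", "U")))
  m["A", "U"] <- m["U", "A"] <- TRUE
  m["C", "G"] <- m["G", "C"] <- TRUE
  if (wobble) m["G", "U"] <- m["U", "G"] <- TRUE
  m
}

# hairpin (terminal) loops: pairs enclosing no other paired base
count_hairpin_loops <- function(pt) {
  idx <- which(pt > seq_along(pt))
  sum(vapply(idx, function(i) all(pt[(i + 1L):(pt[i] - 1L)] == 0L),
             logical(1)))
}

#' @export
print.hairpin_fold <- function(x, ...) {
  cat(x$sequence, "\n", x$dot_bracket, "\n", sep = "")
  cat(x$n_pairs, "pairs,", x$terminal_loops, "terminal loop(s)\n")
  invisible(x)
}

#' Stem-loop plausibility check for a candidate precursor
#'
#' A fold passes when (a) it has exactly one terminal (hairpin) loop, (b)
#' the mature region does not overlap that loop, and (c) at least
#' `min_paired_frac` of the mature bases are paired — an operational
#' reading of "hairpin-shaped, with the mature miRNA far from loops and
#' bulges".
#'
#' @param fold A [fold_maxpairs()] result.
#' @param mature_start,mature_end 1-based inclusive mature coordinates.
#' @param min_paired_frac Minimal paired fraction of mature bases
#'   (default 0.6).
#' @return A list: `pass`, `n_terminal_loops`, `loop_overlap`,
#'   `mature_paired_fraction`, and per-criterion logicals `criteria`.
#' @examples
#' f <- fold_maxpairs("ACAACGGCGGCGGAAACAAACCGCCGCCGCAAC")
#' stemloop_check(f, 5, 13)
#' @export
stemloop_check <- function(fold, mature_start, mature_end,
                           min_paired_frac = 0.6) {
  stopifnot(inherits(fold, "hairpin_fold"))
  n <- length(fold$pair_table)
  if (!is_count_scalar(mature_start) || !is_count_scalar(mature_end) ||
      mature_start < 1 || mature_end > n || mature_start > mature_end)
    abort_arg("mature coordinates out of range")
  pt <- fold$pair_table
  loop_pos <- integer(0)
  for (i in which(pt > seq_along(pt))) {
    span <- (i + 1L):(pt[i] - 1L)
    if (all(pt[span] == 0L)) loop_pos <- c(loop_pos, span)
  }
  mature <- mature_start:mature_end
  one_loop <- fold$terminal_loops == 1L
  overlap <- length(intersect(mature, loop_pos)) > 0
  paired_frac <- mean(pt[mature] > 0)
  crit <- c(single_terminal_loop = one_loop,
            mature_outside_loop = !overlap,
            mature_paired = paired_frac >= min_paired_frac)
  list(pass = all(crit), n_terminal_loops = fold$terminal_loops,
       loop_overlap = overlap, mature_paired_fraction = paired_frac,
       criteria = crit)
}

#' Hairpin screening of a precursor set
#'
#' Folds every precursor and applies [stemloop_check()] to its mature
#' region.
#'
#' @param precursors A `precursor_set`.
#' @param min_loop,min_paired_frac Passed to the fold and the check.
#' @return Data frame `id`, `mature_id`, `n_pairs`, `terminal_loops`,
#'   `mature_paired_fraction`, `pass`, `dot_bracket`.
#' @export
hairpin_screen <- function(precursors, min_loop = 3L, min_paired_frac = 0.6) {
  stopifnot(inherits(precursors, "precursor_set"))
  rows <- lapply(seq_len(nrow(precursors)), function(r) {
    p <- precursors[r, ]
    f <- fold_maxpairs(p$sequence, min_loop = min_loop)
    chk <- stemloop_check(f, p$mature_start, p$mature_end,
                          min_paired_frac = min_paired_frac)
    data.frame(id = p$id, mature_id = p$mature_id, n_pairs = f$n_pairs,
               terminal_loops = f$terminal_loops,
               mature_paired_fraction = chk$mature_paired_fraction,
               pass = chk$pass, dot_bracket = f$dot_bracket,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
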