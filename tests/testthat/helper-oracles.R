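# Independent brute-force oracles. These deliberately share no code with
# the package implementations they check.

# Audic-Claverie two-sided p by direct log-gamma summation of the
# conditional pmf  P(Y = k | x) = f^k (x+k)! / (x! k! (1+f)^(x+k+1)),
# f = N_B / N_A: doubles the smaller of the two opposing upper tails,
# P(Y >= y | x) and the role-swapped P(X >= x | y).
ac_oracle <- function(x, y, n_a, n_b, cap = 5000L) {
  upper_tail <- function(obs, given, f) {   # P(count >= obs | given)
    if (obs == 0) return(1)
    ks <- obs:max(cap, 20 * (x + y + 10))
    sum(exp(ks * log(f) + lgamma(given + ks + 1) - lgamma(given + 1) -
              lgamma(ks + 1) - (given + ks + 1) * log(1 + f)))
  }
  p_up <- upper_tail(y, x, n_b / n_a)
  p_down <- upper_tail(x, y, n_a / n_b)
  min(1, 2 * min(p_up, p_down))
}

# Exhaustive enumeration of all nested pair sets (helices >= 2 stacked
# pairs, hairpin loops >= min_loop) -- maximum pair count.
brute_max_pairs <- function(s, min_loop = 3, wobble = TRUE) {
  ch <- strsplit(chartr("T", "U", toupper(s)), "")[[1]]
  n <- length(ch)
  ok <- c("A U", "U A", "C G", "G C", if (wobble) c("G U", "U G"))
  pairable <- function(a, b) paste(a, b) %in% ok
  enum <- function(i, j) {
    if (j - i <= min_loop) return(list(list()))
    res <- enum(i, j - 1)
    for (k in i:(j - min_loop - 1)) {
      if (!pairable(ch[k], ch[j])) next
      lefts <- if (k > i) enum(i, k - 1) else list(list())
      rights <- enum(k + 1, j - 1)
      for (L in lefts) for (R in rights)
        res <- c(res, list(c(L, R, list(c(k, j)))))
    }
    res
  }
  best <- 0
  for (st in enum(1, n)) {
    if (length(st) == 0) next
    m <- do.call(rbind, st)
    keys <- paste(m[, 1], m[, 2])
    lonely <- vapply(seq_len(nrow(m)), function(r)
      !(paste(m[r, 1] + 1, m[r, 2] - 1) %in% keys ||
          paste(m[r, 1] - 1, m[r, 2] + 1) %in% keys), logical(1))
    if (!any(lonely)) best <- max(best, nrow(m))
  }
  best
}

# Exhaustive 9x9 offset-window enumeration for read matching, with the
# same tie order (mismatches, |o5|+|o3|, |o5|).
match_oracle <- function(read, prec, max_offset = 4, max_mismatch = 1) {
  L <- nchar(read)
  best <- NULL
  for (o5 in -max_offset:max_offset) for (o3 in -max_offset:max_offset) {
    ws <- prec$mature_start - o5
    we <- prec$mature_end + o3
    if (we - ws + 1 != L || ws < 1 || we > nchar(prec$sequence)) next
    mm <- sum(utf8ToInt(substr(prec$sequence, ws, we)) != utf8ToInt(read))
    if (mm > max_mismatch) next
    cand <- c(mm, abs(o5) + abs(o3), abs(o5))
    if (is.null(best) || {
      d <- cand - best$key
      nz <- which(d != 0)
      length(nz) > 0 && d[nz[1]] < 0
    }) best <- list(offset5 = o5, offset3 = o3, n_mismatches = mm, key = cand)
  }
  best
}

# Hypergeometric upper tail by pmf enumeration over the support.
hyper_oracle <- function(k, K, n, N) {
  ks <- max(0, n + K - N):min(K, n)
  pmf <- exp(lchoose(K, ks) + lchoose(N - K, n - ks) - lchoose(N, n))
  sum(pmf[ks >= k])
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# minimal truth table for qPCR tests
make_truth <- function(ids, cls, mn, ma, mt) {
  data.frame(mirna_id = ids, class = cls, mean_normal = mn,
             mean_adjacent = ma, mean_tumor = mt, stringsAsFactors = FALSE)
}
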