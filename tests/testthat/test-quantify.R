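test_that("match_read resolves canonical reads, truncations and offsets", {
  p <- simulate_precursors(1, seed = 7)
  m <- p$mature_seq[1]
  cl <- match_read(m, p)
  expect_equal(cl$offset5, 0L)
  expect_equal(cl$offset3, 0L)
  expect_equal(cl$n_mismatches, 0L)
  expect_true(cl$is_canonical)

  # last two bases trimmed: pure 3' truncation
  cl2 <- match_read(substr(m, 1, nchar(m) - 2), p)
  expect_equal(cl2$offset5, 0L)
  expect_equal(cl2$offset3, -2L)
  expect_equal(cl2$n_mismatches, 0L)
  expect_false(cl2$is_canonical)

  # one interior substitution: still matched, flagged
  m1 <- m
  substr(m1, 8, 8) <- setdiff(c("A", "C", "G", "T"), substr(m, 8, 8))[1]
  cl3 <- match_read(m1, p)
  expect_equal(cl3$n_mismatches, 1L)
  expect_equal(cl3$offset5, 0L)

  # two interior substitutions: no window within one mismatch
  m2 <- m1
  substr(m2, 14, 14) <- setdiff(c("A", "C", "G", "T"), substr(m, 14, 14))[1]
  expect_null(match_read(m2, p))
  expect_null(match_oracle(m2, p))

  expect_error(match_read("", p), class = "miRtrend_error")
})

test_that("match_read agrees with the exhaustive window oracle", {
  set.seed(101)
  p <- simulate_precursors(15, seed = 31)
  for (t in 1:300) {
    prec <- p[sample(nrow(p), 1), ]
    kind <- sample(3, 1)
    read <- if (kind == 1) {
      # a true window, possibly mutated
      o5 <- sample(-4:4, 1); o3 <- sample(-4:4, 1)
      ws <- prec$mature_start - o5; we <- prec$mature_end + o3
      r <- substr(prec$sequence, ws, we)
      if (runif(1) < 0.5 && nchar(r) > 0) {
        pos <- sample(nchar(r), 1)
        substr(r, pos, pos) <- sample(c("A", "C", "G", "T"), 1)
      }
      r
    } else if (kind == 2) random_dna(sample(15:30, 1))
    else substr(prec$sequence, sample(10, 1), sample(15:35, 1) + 9)
    if (nchar(read) < 15 || nchar(read) > 35) next
    got <- match_read(read, prec)
    want <- match_oracle(read, prec)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$offset5, want$offset5)
      expect_equal(got$offset3, want$offset3)
      expect_equal(got$n_mismatches, want$n_mismatches)
    }
  }
})

test_that("quantify_sample counts, conserves and reports unassigned reads", {
  p <- simulate_precursors(3, seed = 2)
  reads <- c(rep(p$mature_seq[1], 100), strrep("A", 20), strrep("A", 40))
  q <- quantify_sample(reads, p)
  expect_equal(unname(q$counts[p$mature_id[1]]), 100L)
  expect_equal(sum(q$counts), 100L)
  expect_equal(q$n_unassigned, 2L)
  prof1 <- q$profile[q$profile$mature_id == p$mature_id[1], ]
  expect_equal(nrow(prof1), 1L)
  expect_equal(prof1$count, 100L)
  expect_equal(prof1$offset5, 0L)

  # conservation: profile totals equal matrix counts, per miRNA
  d <- simulation_design(seed = 14)
  r <- simulate_reads(p, d, n_reads = 2000)
  q2 <- quantify_sample(r, p)
  prof_tot <- tapply(q2$profile$count, q2$profile$mature_id, sum)
  expect_equal(as.vector(prof_tot[names(q2$counts)[q2$counts > 0]]),
               unname(q2$counts[q2$counts > 0]))
  expect_equal(sum(q2$counts) + q2$n_unassigned, q2$n_reads)

  # order independence
  q3 <- quantify_sample(rev(r$sequence), p)
  expect_identical(q2$counts, q3$counts)
  expect_equal(q2$profile, q3$profile)

  # empty read set: all-zero column
  q0 <- quantify_sample(character(0), p)
  expect_true(all(q0$counts == 0))
  expect_equal(nrow(q0$profile), 0L)
})

test_that("dominant_isomir follows the argmax and tie rules", {
  expect_equal(dominant_isomir(data.frame(offset5 = 0, offset3 = c(0, -1),
                                          n_mismatches = 0,
                                          count = c(10, 50)))$offset3, -1)
  tie <- dominant_isomir(data.frame(offset5 = 0, offset3 = c(0, -1),
                                    n_mismatches = 0, count = c(10, 10)))
  expect_equal(tie$offset3, 0)
  expect_error(dominant_isomir(data.frame()), class = "miRtrend_error")
})

test_that("a planted 3' offset bias dominates the isomiR profile", {
  p3 <- stats::setNames(c(0, 0, 0, 0.6, 0.4, 0, 0, 0, 0), -4:4)
  p5 <- stats::setNames(c(0, 0, 0, 0, 1, 0, 0, 0, 0), -4:4)
  d <- simulation_design(isomir_offset_probs = list(offset5 = p5,
                                                    offset3 = p3),
                         mismatch_rate = 0, seed = 4)
  p <- simulate_precursors(5, seed = 2)
  q <- quantify_sample(simulate_reads(p, d, n_reads = 10000), p)
  for (id in unique(q$profile$mature_id)) {
    dom <- dominant_isomir(q$profile[q$profile$mature_id == id, ])
    expect_equal(dom$offset5, 0L)
    expect_equal(dom$offset3, -1L)
  }
})

test_that("multi-sample quantification builds a consistent count matrix", {
  p <- simulate_precursors(4, seed = 6)
  d <- simulation_design(seed = 7)
  rs <- list(normal = simulate_reads(p, d, n_reads = 500, seed = 1),
             tumor = simulate_reads(p, d, n_reads = 500, seed = 2))
  out <- quantify_samples(rs, p)
  expect_s3_class(out$counts, "mir_counts")
  expect_equal(colnames(out$counts$counts), c("normal", "tumor"))
  expect_equal(unname(out$counts$library_size),
               unname(colSums(out$counts$counts)))
})
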