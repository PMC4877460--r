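test_that("precursor simulation is deterministic and seed-sensitive", {
  expect_identical(simulate_precursors(5, seed = 7),
                   simulate_precursors(5, seed = 7))
  a <- simulate_precursors(5, seed = 7)
  b <- simulate_precursors(5, seed = 8)
  expect_true(any(a$sequence != b$sequence))
  expect_error(simulate_precursors(0), class = "miRtrend_error")
})

test_that("simulated precursors are hairpins with complementary arms", {
  p <- simulate_precursors(20, seed = 7)
  expect_true(all(nchar(p$sequence) >= 60 & nchar(p$sequence) <= 90))
  mlen <- p$mature_end - p$mature_start + 1
  expect_true(all(mlen >= 20 & mlen <= 23))
  expect_true(all(p$mature_seq ==
                    substr(p$sequence, p$mature_start, p$mature_end)))
  # the mature-bearing arm, reverse-complemented, matches the opposite arm
  # with at most the two planted point changes
  mm <- vapply(seq_len(nrow(p)), function(i) {
    arm1 <- substr(p$sequence[i], 5, p$loop_start[i] - 1)
    arm2 <- substr(p$sequence[i], p$loop_end[i] + 1,
                   nchar(p$sequence[i]) - 4)
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(arm2)))
    sum(utf8ToInt(rc) != utf8ToInt(arm1))
  }, numeric(1))
  expect_true(all(mm <= 2))
})

test_that("precursor FASTA + GFF3 round-trip preserves every record", {
  p <- simulate_precursors(4, seed = 3)
  fa <- withr::local_tempfile(fileext = ".fa")
  gf <- withr::local_tempfile(fileext = ".gff3")
  write_precursor_fasta(p, fa)
  write_mature_gff(p, gf)
  q <- read_precursors(fa, gf)
  expect_equal(q$sequence, p$sequence)
  expect_equal(q$mature_id, p$mature_id)
  expect_equal(q$mature_start, p$mature_start)
  expect_equal(q$mature_seq, p$mature_seq)
})

test_that("degenerate read designs behave as specified", {
  p <- simulate_precursors(5, seed = 2)
  zero <- stats::setNames(c(0, 0, 0, 0, 1, 0, 0, 0, 0), -4:4)
  d <- simulation_design(isomir_offset_probs = zero, mismatch_rate = 0,
                         seed = 4)
  r <- simulate_reads(p, d, n_reads = 200)
  canon <- p$mature_seq[match(r$precursor_id, p$id)]
  expect_true(all(r$sequence == canon))
  expect_true(all(r$offset5 == 0 & r$offset3 == 0 & r$n_mismatches == 0))

  p15 <- simulate_precursors(15, seed = 2)
  expect_true(any(p15$mature_end - p15$mature_start + 1 == 22))
  only22 <- stats::setNames(c(0, 0, 0, 0, 1, 0, 0, 0), 18:25)
  d22 <- simulation_design(read_length_weights = only22, seed = 4)
  r22 <- simulate_reads(p15, d22, n_reads = 200)
  expect_true(all(r22$canonical_length == 22))

  expect_error(simulate_reads(p[0, ], d, n_reads = 10),
               class = "miRtrend_error")
})

test_that("default design yields a 22 nt modal read length", {
  p <- simulate_precursors(30, seed = 5)
  d <- simulation_design(seed = 6)
  r <- simulate_reads(p, d, n_reads = 10000)
  lens <- table(nchar(r$sequence))
  expect_equal(names(which.max(lens)), "22")
})

test_that("FASTQ output is byte-identical across runs and round-trips truth", {
  p <- simulate_precursors(3, seed = 1)
  d <- simulation_design(seed = 9)
  r <- simulate_reads(p, d, n_reads = 100)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  write_reads_fastq(r, f1)
  write_reads_fastq(simulate_reads(p, d, n_reads = 100), f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_reads_fastq(f1)
  expect_equal(back$sequence, r$sequence)
  expect_equal(back$offset5, r$offset5)
  expect_equal(back$offset3, r$offset3)
  expect_equal(back$mature_id, r$mature_id)
})

test_that("count simulation matches the design arithmetic and Poisson law", {
  d4 <- simulation_design(n_mirnas = 10, n_gradient_up = 2,
                          n_gradient_down = 1, baseline_mean = 100,
                          gradient_step = 4, seed = 1)
  tt <- truth_table(d4)
  up <- tt[tt$class == "up_gradient", ]
  expect_equal(unname(as.matrix(up[1, 3:5])[1, ]), c(100, 400, 1600))
  down <- tt[tt$class == "down_gradient", ]
  expect_equal(unname(as.matrix(down[1, 3:5])[1, ]), c(100, 25, 6.25))

  d0 <- simulation_design(n_mirnas = 8, n_gradient_up = 0,
                          n_gradient_down = 0, seed = 1)
  expect_true(all(truth_table(d0)$class == "null"))

  # law of large numbers at 1000 null miRNAs: normal-column mean near 100
  dn <- simulation_design(n_mirnas = 1000, n_gradient_up = 0,
                          n_gradient_down = 0, baseline_mean = 100, seed = 2)
  sim <- simulate_counts(dn)
  expect_lt(abs(mean(sim$counts$counts[, "normal"]) - 100), 1)
  # determinism
  expect_identical(sim$counts$counts, simulate_counts(dn)$counts$counts)
})

test_that("unequal library sizes scale counts but not CPM expectations", {
  d <- simulation_design(n_mirnas = 500, n_gradient_up = 0,
                         n_gradient_down = 0, baseline_mean = 200,
                         library_size = 1e6, seed = 3)
  ls <- c(normal = 5e5, adjacent = 1e6, tumor = 2e6)
  sim <- simulate_counts(d, library_sizes = ls)
  m <- colMeans(sim$counts$counts)
  expect_lt(abs(m[["normal"]] / m[["tumor"]] - 0.25), 0.05)
  cp <- cpm(sim$counts)
  expect_lt(abs(mean(cp[, "normal"]) / mean(cp[, "tumor"]) - 1), 0.05)
})

test_that("design validation rejects malformed inputs", {
  expect_error(simulation_design(n_mirnas = 2, n_gradient_up = 2,
                                 n_gradient_down = 1),
               class = "miRtrend_error")
  expect_error(simulation_design(gradient_step = 1.5),
               class = "miRtrend_error")
  bad <- stats::setNames(rep(0.2, 8), 18:25)
  expect_error(simulation_design(read_length_weights = bad),
               class = "miRtrend_error")
  expect_error(simulation_design(mismatch_rate = 1.2),
               class = "miRtrend_error")
})

test_that("noise-free qPCR reproduces the designed fold changes exactly", {
  tt <- make_truth(c("up4", "flat"), c("up_gradient", "null"),
                   c(100, 100), c(200, 100), c(400, 100))
  qp <- simulate_qpcr(tt, n_samples = 3, noise_sd = 0, seed = 1,
                      targets = c("up4", "flat"))
  dct <- qpcr_delta_ct(qp)
  d_up <- tapply(dct$delta_ct[dct$target_id == "up4"],
                 dct$group[dct$target_id == "up4"], mean)
  # 4-fold higher expression in tumor: delta-Ct exactly 2 cycles lower
  expect_equal(unname(d_up[["tumor"]] - d_up[["normal"]]), -2)
  d_flat <- tapply(dct$delta_ct[dct$target_id == "flat"],
                   dct$group[dct$target_id == "flat"], mean)
  expect_equal(unname(d_flat[["tumor"]] - d_flat[["normal"]]), 0)
  expect_error(simulate_qpcr(tt, n_samples = 3, noise_sd = -1),
               class = "miRtrend_error")
  expect_error(simulate_qpcr(tt, n_samples = 1, noise_sd = 0),
               class = "miRtrend_error")
})

test_that("noisy qPCR recovers a planted 8-fold change within 20%", {
  tt <- make_truth("m8", "up_gradient", 100, 283, 800)
  qp <- simulate_qpcr(tt, n_samples = 9, noise_sd = 0.1, seed = 5,
                      targets = "m8")
  ct <- qpcr_summary(qp)$contrasts
  fold <- ct$fold_change[ct$case == "tumor" & ct$control == "normal"]
  expect_lt(abs(fold - 8) / 8, 0.2)
})

test_that("mismatch-free reads always classify to their recorded offsets", {
  p <- simulate_precursors(10, seed = 21)
  d <- simulation_design(mismatch_rate = 0, seed = 22)
  r <- simulate_reads(p, d, n_reads = 300)
  for (i in seq_len(nrow(r))) {
    cl <- classify_isomir(r$sequence[i], p[p$id == r$precursor_id[i], ])
    expect_false(is.null(cl))
    expect_equal(cl$offset5, r$offset5[i])
    expect_equal(cl$offset3, r$offset3[i])
    expect_equal(cl$n_mismatches, 0L)
  }
})
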