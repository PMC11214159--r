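test_that("neutral-rate estimation is a clipped mismatch proportion", {
  rows <- c(a = strrep("A", 200), b = strrep("A", 200))
  expect_equal(estimate_neutral_rate(alignment_block(rows)), 0.01)

  set.seed(1)
  mism <- sample(200, 50)
  b2 <- strsplit(strrep("A", 200), "")[[1]]
  b2[mism] <- "C"
  rows2 <- c(a = strrep("A", 200), b = paste(b2, collapse = ""))
  expect_equal(estimate_neutral_rate(alignment_block(rows2)), 0.25)

  expect_error(estimate_neutral_rate(
    alignment_block(c(a = strrep("A", 50), b = strrep("A", 50)))),
    "100 unmasked")
})

test_that("neutral-rate estimate recovers the generator's substitution
           probability within its binomial interval", {
  set.seed(31)
  q <- 0.2
  al <- gen_alignment(n_rows = 4, length = 1000, p_neutral = q, seed = 31)
  est <- estimate_neutral_rate(al)
  ci <- q + c(-1, 1) * 1.96 * sqrt(q * (1 - q) / 1000)
  expect_gt(est, ci[1])
  expect_lt(est, ci[2])
})

test_that("column scores take the closed-form log-odds values", {
  sch <- score_scheme(p_neutral = 0.5, p_constrained = 0.25)
  expect_equal(sch$s_match, log(1.5))
  expect_equal(sch$s_mismatch, log(0.5))
  expect_error(score_scheme(0.5, 0.5))    # degenerate p_c = p_n
  expect_error(score_scheme(0.5, 0.7))

  rows <- c(a = "AAAA", b = "AACA")
  sc <- column_scores(alignment_block(rows), sch)
  expect_equal(sc, c(log(1.5), log(1.5), log(0.5), log(1.5)))

  # all-match block: total = columns x s_match
  rows2 <- c(a = strrep("G", 10), b = strrep("G", 10))
  expect_equal(sum(column_scores(alignment_block(rows2), sch)),
               10 * log(1.5))
})

test_that("Ruzzo-Tompa segments match an exhaustive oracle", {
  expect_equal(nrow(maximal_segments(c(-1, -2, -0.5))), 0L)
  seg <- maximal_segments(c(-1, 2, 1, -5, -1))
  expect_equal(seg$start, 1L)
  expect_equal(seg$end, 3L)
  expect_equal(seg$score, 3)

  set.seed(17)
  for (rep in 1:60) {
    m <- sample(3:12, 1)
    sc <- round(rnorm(m), 3) + 1e-4 * rnorm(m)   # continuous, tie-free
    got <- maximal_segments(sc)
    want <- oracle_maximal_segments(sc)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$score, want$score)
  }
  expect_error(maximal_segments(c(1, NA)), "finite")
})

test_that("lambda solves the Karlin-Altschul root equation", {
  # two-outcome scores +1 with prob 0.25, -1 with prob 0.75: lambda = ln 3
  sch <- structure(list(p_neutral = 0.75, p_constrained = 0.1,
                        s_match = 1, s_mismatch = -1),
                   class = "score_scheme")
  cal <- calibrate_karlin_altschul(sch, K = 0.3)
  expect_equal(cal$lambda, log(3), tolerance = 1e-10)

  # zero-mean score distribution has no positive root
  sch0 <- structure(list(p_neutral = 0.5, p_constrained = 0.1,
                         s_match = 1, s_mismatch = -1),
                    class = "score_scheme")
  expect_error(calibrate_karlin_altschul(sch0, K = 1), "calibration error")
})

test_that("segment P-values decrease monotonically in score and the CNS
           threshold is strict", {
  p <- sweepfoot:::segment_pvalue(c(1, 5, 10, 50), lambda = 1.1, K = 0.2,
                                  m = 300)
  expect_true(all(diff(p) < 0))
  expect_lt(sweepfoot:::segment_pvalue(1e6, 1.1, 0.2, 300), 1e-12)

  # conservation score exactly at -log10(0.05) is not a CNS (strict >)
  expect_false(-log10(0.05) > -log10(0.05))
})

test_that("CNS calls are invariant to adding masked columns", {
  set.seed(41)
  al <- gen_alignment(n_rows = 3, length = 260, p_neutral = 0.3,
                      blocks = data.frame(start = 80, end = 160,
                                          p_constrained = 0.02),
                      seed = 41)
  sch <- calibrate_karlin_altschul(score_scheme(0.3), m = 260,
                                   n_null = 2000)
  calls <- call_cns(al, sch)

  # append masked columns: same rows plus junk, masked out
  rows2 <- vapply(al$rows, function(r) paste0(r, strrep("A", 40)),
                  character(1))
  al2 <- alignment_block(rows2, mask = cbind(260, 300))
  calls2 <- call_cns(al2, sch)
  expect_equal(calls$start, calls2$start)
  expect_equal(calls$score, calls2$score)
  expect_equal(calls$p_value, calls2$p_value)
})

test_that("a planted constrained block is recovered and segment scores sum
           their columns", {
  set.seed(51)
  al <- gen_alignment(n_rows = 4, length = 300, p_neutral = 0.3,
                      blocks = data.frame(start = 100, end = 200,
                                          p_constrained = 0.02),
                      seed = 51)
  calls <- call_cns(al, n_null = 2000)
  hit <- calls[calls$is_cns & calls$start < 200 & calls$end > 100, ]
  expect_gte(nrow(hit), 1L)

  # conservation of score: reported score equals the column-score sum
  sch <- calibrate_karlin_altschul(score_scheme(estimate_neutral_rate(al)),
                                   m = 300, n_null = 500)
  sc <- column_scores(al, sch)
  seg <- maximal_segments(sc)
  for (i in seq_len(nrow(seg)))
    expect_equal(seg$score[i],
                 sum(sc[(seg$start[i] + 1):seg$end[i]]))
})
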