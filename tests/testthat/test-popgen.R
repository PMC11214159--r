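test_that("polarization against the ancestral sequence follows the
           infinite-sites rules", {
  # no variation
  w <- haplotype_window(c(a = "ACGT", b = "ACGT", c = "ACGT", d = "ACGT"),
                        "ACGT")
  expect_equal(polarize(w)$S, 0)

  # one singleton
  w <- haplotype_window(c(a = "ACGT", b = "ACGT", c = "ACGA", d = "ACGT"),
                        "ACGT")
  sfs <- polarize(w)
  expect_equal(sfs$counts, c(1, 0, 0))

  # tri-allelic site excluded
  w <- haplotype_window(c(a = "A", b = "A", c = "C", d = "G"), "A")
  expect_equal(polarize(w)$S, 0)

  # gap/N excluded listwise; fixed-derived excluded; unpolarizable excluded
  w <- haplotype_window(
    c(a = "NCTT", b = "ACTT", c = "ACTA", d = "ACTT"),
    #    ^gap/N  ^fixed C vs anc A at site2? see below
    "AATT")
  # site 1: N present -> excluded; site 2: all samples C, anc A -> fixed
  # derived -> excluded; site 4: singleton A vs anc T -> counted
  expect_equal(polarize(w)$counts, c(1, 0, 0))

  w <- haplotype_window(c(a = "C", b = "C", c = "G", d = "G"), "A")
  # ancestral absent and two sample alleles: unpolarizable
  expect_equal(polarize(w)$S, 0)

  expect_error(haplotype_window(c(a = "AC", b = "A"), "AC"), "length")
  expect_error(haplotype_window(c(a = "AC"), "AC"), "at least 2")
})

test_that("theta estimators reproduce hand-computed cases and the
           theta_pi + theta_H = 2 theta_L identity", {
  th <- theta_estimators(derived_sfs(2, 1))
  expect_equal(c(th$theta_pi, th$theta_w, th$theta_l, th$theta_h),
               rep(1, 4))

  th <- theta_estimators(derived_sfs(4, c(1, 0, 0)))
  expect_equal(th$theta_pi, 0.5)
  expect_equal(th$theta_w, 6 / 11)
  expect_equal(th$theta_l, 1 / 3)
  expect_equal(th$theta_h, 1 / 6)

  th <- theta_estimators(derived_sfs(5, c(0, 0, 0, 0)))
  expect_equal(c(th$theta_pi, th$theta_w, th$theta_l, th$theta_h),
               rep(0, 4))

  set.seed(42)
  for (rep in 1:50) {
    n <- sample(3:12, 1)
    sfs <- derived_sfs(n, rpois(n - 1, 2))
    th <- theta_estimators(sfs)
    expect_equal(th$theta_pi + th$theta_h, 2 * th$theta_l)
  }
})

test_that("theta_pi agrees with brute-force pairwise differences", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(3:8, 1)
    cnt <- rpois(n - 1, 1.5)
    expect_equal(theta_estimators(derived_sfs(n, cnt))$theta_pi,
                 oracle_pi_pairwise(n, cnt))
  }
})

test_that("Tajima's D matches an independent transcription and has the
           expected signs", {
  expect_equal(tajimas_d(derived_sfs(2, 1)), 0)
  expect_lt(tajimas_d(derived_sfs(4, c(1, 0, 0))), 0)
  expect_true(is.na(tajimas_d(derived_sfs(4, c(0, 0, 0)))))
  set.seed(11)
  for (rep in 1:40) {
    n <- sample(3:6, 1)
    cnt <- rpois(n - 1, 1)
    if (sum(cnt) == 0) next
    want <- oracle_tajima_d(n, cnt)
    if (is.nan(want)) {
      # n = 3 degeneracy: theta_pi == theta_W identically, variance 0;
      # the package reports the symmetric case as exactly 0
      expect_equal(tajimas_d(derived_sfs(n, cnt)), 0)
    } else {
      expect_equal(tajimas_d(derived_sfs(n, cnt)), want)
    }
  }
})

test_that("H and E are zero in the symmetric n = 2 case and signed by
           high-frequency derived alleles", {
  expect_equal(fay_wu_h_std(derived_sfs(2, 1)), 0)
  expect_equal(zengs_e(derived_sfs(2, 1)), 0)
  expect_lt(fay_wu_h_std(derived_sfs(4, c(0, 0, 1))), 0)
  expect_gt(zengs_e(derived_sfs(4, c(0, 0, 1))), 0)
  expect_true(is.na(fay_wu_h_std(derived_sfs(4, c(0, 0, 0)))))
  expect_true(is.na(zengs_e(derived_sfs(4, c(0, 0, 0)))))
})

test_that("D, H and E are centred at zero under the recombining neutral
           null", {
  # with tight linkage the standardized statistics carry small non-zero
  # means (the variance normalization is approximate); under the
  # recombining null used for inference they centre at zero
  set.seed(101)
  sims <- simulate_window(null_model(n = 20, theta_site = 5e-3,
                                     rho_site = 2.5e-1, L = 2000,
                                     reps = 5000))
  stats <- vapply(sims, function(s)
    c(tajimas_d(s), fay_wu_h_std(s), zengs_e(s)), numeric(3))
  for (k in 1:3) {
    v <- stats[k, ]
    v <- v[!is.na(v)]
    expect_lt(abs(mean(v)), 3 * sd(v) / sqrt(length(v)))
  }
})

test_that("sliding windows tile the locus as specified and a whole-locus
           window equals the whole-locus statistics", {
  set.seed(3)
  loc <- gen_neutral_locus(n = 8, length_bp = 4000, theta_site = 5e-3,
                           seed = 3)
  tr <- sliding_scan(loc, window_bp = 2000, step_bp = 1000)
  expect_equal(tr$start, c(0, 1000, 2000))
  expect_equal(tr$end, c(2000, 3000, 4000))

  tr1 <- sliding_scan(loc, window_bp = 4000, step_bp = 1000)
  expect_equal(nrow(tr1), 1L)
  sfs <- polarize(loc)
  expect_equal(tr1$D, tajimas_d(sfs))
  expect_equal(tr1$H, fay_wu_h_std(sfs))
  expect_equal(tr1$E, zengs_e(sfs))

  expect_error(sliding_scan(loc, window_bp = 0), "config")
  expect_error(sliding_scan(loc, window_bp = 2000, step_bp = -1), "config")
  expect_error(sliding_scan(loc, window_bp = 5000), "config")
})

test_that("peak identification maximizes E, minimizes H and D, and breaks
           ties leftward", {
  tr <- data.frame(start = c(0, 1000, 2000), end = c(2000, 3000, 4000),
                   S = c(3L, 5L, 4L),
                   D = c(-0.5, 0.2, -0.5),
                   H = c(0.1, -1.2, 0.3),
                   E = c(0.1, 2.0, 0.3))
  pk <- find_peaks(tr)
  expect_equal(pk$E$start, 1000)
  expect_equal(pk$H$start, 1000)
  expect_equal(pk$D$start, 0)      # leftmost of the two equal minima

  tr$D <- NA_real_; tr$H <- NA_real_; tr$E <- NA_real_
  expect_error(find_peaks(tr), "no-peak")

  tr2 <- data.frame(start = 0, end = 2000, S = 2L, D = 0.3, H = -0.1,
                    E = 0.5)
  pk2 <- find_peaks(tr2)
  expect_equal(pk2$E$start, 0)
  expect_equal(pk2$D$value, 0.3)
})

test_that("a sweep-skewed locus shifts median H down and median E up
           relative to neutral", {
  hs <- function(gen) {
    vapply(1:120, function(s) {
      sfs <- polarize(gen(s))
      c(H = fay_wu_h_std(sfs), E = zengs_e(sfs))
    }, numeric(2))
  }
  neu <- hs(function(s) gen_neutral_locus(n = 22, length_bp = 2000,
                                          seed = 400 + s))
  swp <- hs(function(s) gen_sweep_locus(n = 22, length_bp = 2000,
                                        sweep_pos = 1000, f = 0.9,
                                        seed = 800 + s))
  expect_lt(median(swp["H", ], na.rm = TRUE),
            median(neu["H", ], na.rm = TRUE))
  expect_gt(median(swp["E", ], na.rm = TRUE),
            median(neu["E", ], na.rm = TRUE))
})
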