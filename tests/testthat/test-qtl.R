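make_cross <- function(geno_vec, pos = seq(0, 100, length.out = length(geno_vec))) {
  # single-individual helper for genoprob checks
  g <- matrix(geno_vec, nrow = 1)
  colnames(g) <- sprintf("m%d", seq_along(geno_vec))
  cross_data(g, data.frame(marker = colnames(g), lg = 1, pos = pos),
             data.frame(y = 0))
}

test_that("markers are filtered by the 1:1 segregation chi-square", {
  ph <- data.frame(y = rnorm(132))
  g <- cbind(m1 = c(rep("b", 66), rep("h", 66)),
             m2 = c(rep("b", 90), rep("h", 42)),
             m3 = c(rep("b", 76), rep("h", 56)))
  cr <- cross_data(g, data.frame(marker = c("m1", "m2", "m3"), lg = 1,
                                 pos = c(0, 10, 20)), ph)
  # chi-square values: 0, ~17.45 (> 3.841, removed), ~3.03 (retained)
  flt <- filter_markers(cr)
  expect_equal(colnames(flt$genotypes), c("m1", "m3"))

  g2 <- cbind(m1 = c(rep("b", 120), rep("h", 12)))
  cr2 <- cross_data(g2, data.frame(marker = "m1", lg = 1, pos = 0), ph)
  expect_error(filter_markers(cr2), "empty-cross")
})

test_that("genotype probabilities are exact at typed markers and match
           enumeration between them", {
  cr <- make_cross(c("b", "h"), pos = c(0, 20))
  gp <- genotype_probabilities(cr, grid_step_cM = 10)
  # typed markers
  expect_equal(gp$prob[1, gp$grid$pos == 0], 0)
  expect_equal(gp$prob[1, gp$grid$pos == 20], 1)
  # midpoint vs exhaustive conditioning oracle
  expect_equal(gp$prob[1, gp$grid$pos == 10],
               oracle_genoprob_h("b", "h", 10, 10))

  # flanking markers at distance 0 with equal genotypes pin the state
  cr2 <- make_cross(c("h", "h"), pos = c(5, 5))
  gp2 <- genotype_probabilities(cr2, grid_step_cM = 5)
  expect_true(all(gp2$prob[1, gp2$grid$pos == 5] == 1))

  # missing genotypes fall back to the nearest typed flank
  cr3 <- make_cross(c("b", NA, "b"), pos = c(0, 10, 20))
  gp3 <- genotype_probabilities(cr3, grid_step_cM = 10)
  expect_equal(gp3$prob[1, gp3$grid$pos == 10],
               oracle_genoprob_h("b", "b", 10, 10))

  gbad <- matrix(c("b", "h"), 1, dimnames = list(NULL, c("m1", "m2")))
  expect_error(
    cross_data(gbad,
               data.frame(marker = c("m1", "m2"), lg = 1, pos = c(10, 0)),
               data.frame(y = 0)),
    "ordered")
})

test_that("the Kosambi and Haldane map functions behave at their limits", {
  expect_equal(kosambi_r(0), 0)
  expect_equal(haldane_r(0), 0)
  expect_lt(kosambi_r(1e4), 0.5 + 1e-12)
  # Kosambi implies positive interference: r smaller than Haldane at
  # moderate distance ... actually larger; just pin the 20 cM value
  expect_equal(kosambi_r(20), 0.5 * tanh(0.4))
})

test_that("the LOD scan finds a planted QTL and equals a direct regression
           at fully typed markers", {
  set.seed(9)
  cr <- gen_bc1(n_ind = 150, markers_per_lg = 12, n_lg = 3, qtl_lg = 2,
                effect = 1.2, seed = 9)
  sc <- scan_lod(cr, "head_width", "thorax_width", grid_step_cM = 2)
  pk <- sc[which.max(sc$lod), ]
  expect_equal(pk$lg, 2)
  expect_lt(abs(pk$pos - attr(cr, "qtl_cM")), 15)

  # at a fully typed marker the Haley-Knott fit is the two-group regression
  mk <- 5  # marker index within lg 1
  pos <- cr$map$pos[cr$map$lg == 1][mk]
  gvec <- as.integer(cr$genotypes[, cr$map$lg == 1][, mk] == "h")
  y <- cr$phenotypes$head_width
  cv <- cr$phenotypes$thorax_width
  rss0 <- sum(resid(lm(y ~ cv))^2)
  rss1 <- sum(resid(lm(y ~ cv + gvec))^2)
  lod_direct <- (length(y) / 2) * log10(rss0 / rss1)
  expect_equal(sc$lod[sc$lg == 1 & sc$pos == pos], lod_direct,
               tolerance = 1e-8)
})

test_that("LOD is invariant under affine rescaling of trait and covariate,
           and a constant covariate equals no covariate", {
  set.seed(19)
  cr <- gen_bc1(n_ind = 80, markers_per_lg = 6, n_lg = 2, effect = 0.8,
                qtl_lg = 1, seed = 19)
  base <- scan_lod(cr, "head_width", "thorax_width", grid_step_cM = 5)
  cr2 <- cr
  cr2$phenotypes$head_width <- 3.2 * cr$phenotypes$head_width - 7
  cr2$phenotypes$thorax_width <- -0.5 * cr$phenotypes$thorax_width + 2
  resc <- scan_lod(cr2, "head_width", "thorax_width", grid_step_cM = 5)
  expect_equal(base$lod, resc$lod, tolerance = 1e-8)

  cr3 <- cr
  cr3$phenotypes$const <- rep(2.5, nrow(cr$phenotypes))
  no_cov <- scan_lod(cr, "head_width", NULL, grid_step_cM = 5)
  const_cov <- scan_lod(cr3, "head_width", "const", grid_step_cM = 5)
  expect_equal(no_cov$lod, const_cov$lod)

  cr4 <- cr
  cr4$phenotypes$dup <- cr$phenotypes$head_width
  expect_error(scan_lod(cr4, "head_width", "dup"), "degenerate")
})

test_that("permutation thresholds are deterministic given a seed and hit
           the quantile boundaries", {
  set.seed(29)
  cr <- gen_bc1(n_ind = 60, markers_per_lg = 5, n_lg = 2, effect = 0,
                seed = 29)
  set.seed(100)
  t1 <- permutation_threshold(cr, "head_width", "thorax_width",
                              n_perm = 200, grid_step_cM = 10)
  set.seed(100)
  t2 <- permutation_threshold(cr, "head_width", "thorax_width",
                              n_perm = 200, grid_step_cM = 10)
  expect_identical(as.numeric(t1), as.numeric(t2))

  set.seed(101)
  tmin <- permutation_threshold(cr, "head_width", "thorax_width",
                                n_perm = 50, alpha = 1, grid_step_cM = 10)
  expect_equal(as.numeric(tmin), min(attr(tmin, "max_lods")))
  expect_error(permutation_threshold(cr, "head_width", n_perm = 0),
               "config")
})

test_that("the credible interval follows the normalized 10^LOD mass", {
  # delta-like peak: interval is that grid cell
  cv <- structure(data.frame(lg = 1, pos = 0:10,
                             lod = c(rep(0, 5), 10, rep(0, 5))),
                  class = c("lod_curve", "data.frame"))
  bi <- bayes_interval(cv)
  expect_equal(bi$start, 5)
  expect_equal(bi$end, 5)

  # uniform positive curve: interval spans (almost) the whole group
  cvu <- structure(data.frame(lg = 1, pos = 0:10, lod = rep(2, 11)),
                   class = c("lod_curve", "data.frame"))
  biu <- bayes_interval(cvu)
  expect_gte(biu$end - biu$start, 9)

  # triangular profile: mass agrees with direct enumeration
  lod <- c(0, 0.5, 1, 1.5, 2, 2.5, 2, 1.5, 1, 0.5, 0)
  cvt <- structure(data.frame(lg = 1, pos = 0:10, lod = lod),
                   class = c("lod_curve", "data.frame"))
  bit <- bayes_interval(cvt, prob = 0.9)
  lo <- which(0:10 == bit$start); hi <- which(0:10 == bit$end)
  expect_gte(oracle_interval_mass(lod, lo, hi), 0.9)
  # dropping the last-added endpoint must fall below the target mass
  expect_lt(min(oracle_interval_mass(lod, lo + 1, hi),
                oracle_interval_mass(lod, lo, hi - 1)), 0.9)

  # flat zero curve is undefined
  cv0 <- structure(data.frame(lg = 1, pos = 0:10, lod = rep(0, 11)),
                   class = c("lod_curve", "data.frame"))
  expect_error(bayes_interval(cv0), "undefined-interval")

  # widens monotonically in prob
  b50 <- bayes_interval(cvt, prob = 0.5)
  b95 <- bayes_interval(cvt, prob = 0.95)
  expect_lte(b50$end - b50$start, b95$end - b95$start)
})

test_that("variance explained is the LOD-implied R-squared", {
  expect_equal(variance_explained(0, 100), 0)
  expect_equal(variance_explained(50, 100), 0.9)
  # equals the regression R-squared through the LOD identity
  set.seed(39)
  g <- rbinom(82, 1, 0.5)
  y <- 0.49 * g + rnorm(82)
  rss0 <- sum(resid(lm(y ~ 1))^2)
  rss1 <- sum(resid(lm(y ~ g))^2)
  lod <- (82 / 2) * log10(rss0 / rss1)
  expect_equal(variance_explained(lod, 82), 1 - rss1 / rss0)
})
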