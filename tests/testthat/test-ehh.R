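test_that("EHH equals brute-force all-pairs shared-segment counting", {
  set.seed(42)
  for (rep in 1:60) {
    n_hap <- sample(4:32, 1L)
    n_sites <- sample(8:64, 1L)
    hm <- random_hm(n_hap, n_sites, seed = rep)
    core <- sample(2:(n_sites - 1L), 1L)
    carriers <- sample.int(n_hap, sample(2:n_hap, 1L))
    dirn <- sample(c("left", "right"), 1L)
    cv <- ehh_curve(hm, core, carriers, dirn, cutoff = 0)
    for (k in seq_along(cv$offsets)) {
      expect_equal(cv$ehh_values[k], brute_ehh(hm, core, carriers, dirn, k - 1L),
                   tolerance = 0)
    }
    expect_equal(cv$ehh_values[1L], 1)
    expect_true(all(diff(cv$ehh_values) <= 0))
  }
})

test_that("EHH hand cases: identical pairs, fully distinct carriers", {
  # 4 carriers forming two identical pairs: EHH = (1+1)/C(4,2) = 1/3
  a <- rbind(c(1, 0, 1), c(1, 0, 1), c(1, 1, 0), c(1, 1, 0))
  hm <- toy_hm(rbind(a, a))             # pad to satisfy 2-population invariant
  cv <- ehh_curve(hm, 1L, 1:4, "right", cutoff = 0)
  expect_equal(cv$ehh_values, c(1, 1/3, 1/3))

  # all carriers pairwise distinct at the first extension
  b <- rbind(c(1, 0, 0), c(1, 1, 0), c(1, 0, 1), c(1, 1, 1))
  hm2 <- toy_hm(rbind(b, b))
  cv2 <- ehh_curve(hm2, 1L, 1:2, "right", cutoff = 0.05)
  expect_equal(cv2$ehh_values[2L], 0)
  expect_false(cv2$truncated)           # stopped by the cutoff, not the end

  expect_error(ehh_curve(hm, 1L, 1L, "right"), "fewer than 2")
})

test_that("iHH trapezoid integration matches hand values and scales with bp", {
  mk <- function(offsets, ehh, trunc = FALSE)
    structure(list(offsets = offsets, ehh_values = ehh, truncated = trunc),
              class = "EhhCurve")
  pt <- mk(0, 1)
  expect_equal(integrate_ihh(pt, pt, 0.05)$ihh, 0)

  # 2-node curve per side ending exactly at the sub-cutoff node
  cv <- mk(c(0, 10000), c(1, 0.04))
  expect_equal(integrate_ihh(cv, cv, 0.05)$ihh, 2 * 10000 * (1 + 0.04) / 2)

  # doubling all offsets doubles the integral
  cv2 <- mk(c(0, 20000), c(1, 0.04))
  expect_equal(integrate_ihh(cv2, cv2, 0.05)$ihh,
               2 * integrate_ihh(cv, cv, 0.05)$ihh)

  # nodes past the first sub-cutoff point are ignored
  cv3 <- mk(c(0, 100, 200, 300), c(1, 0.02, 0.9, 0.9))
  expect_equal(integrate_ihh(cv3, mk(0, 1), 0.05)$ihh, 100 * (1 + 0.02) / 2)
})

test_that("iHH is invariant under haplotype reordering and grows as the cutoff drops", {
  hm <- random_hm(12, 40, seed = 99)
  core <- 20L
  carriers <- 1:8
  ihh <- function(cars, cutoff) {
    integrate_ihh(ehh_curve(hm, core, cars, "left", cutoff),
                  ehh_curve(hm, core, cars, "right", cutoff), cutoff)$ihh
  }
  set.seed(1)
  expect_equal(ihh(sample(carriers), 0.05), ihh(carriers, 0.05))
  for (cuts in list(c(0.5, 0.25), c(0.25, 0.05), c(0.05, 0))) {
    expect_true(ihh(carriers, cuts[2L]) >= ihh(carriers, cuts[1L]))
  }
})

test_that("iHS ln-ratio arithmetic and sweep sign behave as expected", {
  # symmetric allele classes => iHH_A = iHH_D => ihs_unstd = 0
  a <- rbind(c(0, 0, 0, 0, 0),
             c(0, 0, 0, 0, 1),
             c(1, 1, 1, 1, 0),
             c(1, 1, 1, 1, 1))
  hm <- toy_hm(rbind(a, a), positions = c(100L, 200L, 300L, 400L, 500L))
  s <- site_ihs(hm, 3L, cutoff = 0, maf_min = 0.05)
  expect_equal(s$ihh_ancestral, s$ihh_derived)
  expect_equal(s$ihs_unstd, 0)

  # consistency of the reported ratio with the reported iHH fields
  hm2 <- random_hm(16, 60, seed = 5)
  s2 <- site_ihs(hm2, 30L)
  if (is.na(s2$skip_reason))
    expect_equal(s2$ihs_unstd, log(s2$ihh_ancestral / s2$ihh_derived))

  # derived carriers identical over a long span, ancestral carriers diverse:
  # the derived class has larger iHH, so ihs_unstd < 0
  der <- matrix(rep(c(1, 0, 1, 1, 0, 1, 0, 0, 1), each = 4), nrow = 4)
  set.seed(8)
  anc <- matrix(rbinom(4 * 9, 1, 0.5), nrow = 4)
  anc[, 5] <- 0; der[, 5] <- 1          # core column: allele class split
  hm3 <- toy_hm(rbind(der, anc), positions = (1:9) * 1000L)
  s3 <- site_ihs(hm3, 5L, cutoff = 0)
  expect_lt(s3$ihs_unstd, 0)

  # maf floor and carrier-count skips
  lowmaf <- toy_hm(rbind(c(1, 0), c(0, 0), c(0, 0), c(0, 0),
                         c(0, 0), c(0, 1), c(0, 0), c(0, 0)))
  expect_equal(site_ihs(lowmaf, 1L, maf_min = 0.2)$skip_reason, "maf")
  expect_equal(site_ihs(lowmaf, 1L, maf_min = 0)$skip_reason, "carriers")
})

test_that("XP-EHH is zero for identical populations and antisymmetric", {
  set.seed(21)
  a <- matrix(rbinom(6 * 30, 1, 0.5), nrow = 6)
  hm <- toy_hm(rbind(a, a), n_pop_a = 6L)   # popB duplicates popA
  s <- site_xpehh(hm, 15L)
  expect_equal(s$xpehh_unstd, 0)

  hm2 <- random_hm(12, 40, seed = 31)
  swapped <- hm2
  swapped$pop_of_hap <- ifelse(hm2$pop_of_hap == "A", "B", "A")
  s1 <- site_xpehh(hm2, 20L)
  s2 <- site_xpehh(swapped, 20L)
  expect_equal(s1$xpehh_unstd, -s2$xpehh_unstd)
  expect_equal(s1$ihh_pop_a, s2$ihh_pop_b)
})

test_that("standardization yields exact z-scores and per-bin unit moments", {
  st <- standardize_scores(c(1, 2, 3), mode = "global")
  expect_equal(st$z, c(-1, 0, 1))

  set.seed(77)
  x <- rnorm(500)
  f <- runif(500)
  st2 <- standardize_scores(x, freq = f, mode = "freq_binned",
                            bin_width = 0.02, min_bin_n = 20L)
  bins <- findInterval(f, st2$model$bin_edges, rightmost.closed = TRUE,
                       all.inside = TRUE)
  for (b in unique(bins)) {
    expect_equal(mean(st2$z[bins == b]), 0, tolerance = 1e-9)
    expect_equal(sd(st2$z[bins == b]), 1, tolerance = 1e-9)
    expect_gte(sum(bins == b), 20L)
  }

  expect_error(standardize_scores(rep(1, 10), mode = "global"),
               "zero variance")
  expect_error(standardize_scores(c(1, 2), freq = c(0.1, 0.9),
                                  mode = "freq_binned", min_bin_n = 1L),
               "fewer than 2 scores")
})

test_that("normal-tail p-values match the quantiles and are symmetric", {
  expect_equal(score_pvalue(0), 1)
  expect_equal(score_pvalue(1.959964), 0.05, tolerance = 1e-6)
  z <- c(-2.3, -0.7, 0.4, 3.1)
  expect_equal(score_pvalue(z), score_pvalue(-z))
  expect_equal(score_pvalue(1.644854, sidedness = "one"), 0.05,
               tolerance = 1e-6)
})

test_that("scan drivers standardize their scores and flag skipped sites", {
  dir <- withr::local_tempdir()
  sim <- small_sim(dir, seed = 3L)
  hm <- sim$hm
  xp <- xpehh_scan(hm)
  ok <- !is.na(xp$xpehh)
  expect_equal(mean(xp$xpehh[ok]), 0, tolerance = 1e-9)
  expect_equal(sd(xp$xpehh[ok]), 1, tolerance = 1e-9)
  expect_true(all(xp$pvalue[ok] > 0 & xp$pvalue[ok] <= 1))

  ihs <- ihs_scan(hm, min_bin_n = 10L)
  expect_true(any(!is.na(ihs$ihs)))
  expect_identical(is.na(ihs$ihs), !is.na(ihs$skip_reason))
})
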