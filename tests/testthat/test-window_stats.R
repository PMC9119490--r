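test_that("window tiling covers the chromosome with a flagged partial tail", {
  w <- make_windows(25000, 10000)
  expect_equal(w$start, c(0L, 10000L, 20000L))
  expect_equal(w$end, c(10000L, 20000L, 25000L))
  expect_equal(w$partial, c(FALSE, FALSE, TRUE))
  expect_equal(nrow(make_windows(10000, 10000)), 1L)
  expect_error(make_windows(1000, 0), "positive")
})

test_that("a SNP at 1-based position 10000 falls in the first 10-kb window", {
  a <- matrix(c(0, 1, 0, 1, 1, 0, 1, 0), nrow = 4)
  hm <- toy_hm(a, positions = c(10000L, 10001L))
  w <- make_windows(20000, 10000)
  rec <- window_hp(hm, w)
  expect_equal(rec$n_snps, c(1L, 1L))   # 10000 -> window 1, 10001 -> window 2
})

test_that("Hp matches the closed form and its bounds", {
  # one SNP, 8 haplotypes, allele counts 6/2: Hp = 2*6*2/8^2 = 0.375
  a <- matrix(c(1, 1, 0, 0, 0, 0, 0, 0), ncol = 1)
  hm <- toy_hm(a, positions = 5000L)
  rec <- window_hp(hm, make_windows(10000, 10000))
  expect_equal(rec$hp, 0.375)
  expect_equal(rec$sum_maj, 6)
  expect_equal(rec$sum_min, 2)

  # every SNP balanced => Hp = 0.5 (its maximum)
  b <- matrix(rep(c(1, 1, 0, 0), 5), nrow = 4)
  rec2 <- window_hp(toy_hm(b), make_windows(1000, 1000))
  expect_equal(rec2$hp, 0.5)

  # all SNPs monomorphic in the subset => Hp = 0
  m <- matrix(0L, nrow = 4, ncol = 5)
  m[1, ] <- 0L
  hm3 <- toy_hm(rbind(m, matrix(1L, nrow = 4, ncol = 5)), n_pop_a = 4L)
  recA <- window_hp(subset_population(hm3, "A"), make_windows(1000, 1000))
  expect_equal(recA$hp, 0)

  # empty window: Hp undefined
  rec4 <- window_hp(hm, make_windows(30000, 10000))
  expect_true(is.na(rec4$hp[3L]))
})

test_that("single-site Hp equals expected heterozygosity 2p(1-p)", {
  set.seed(123)
  for (i in 1:200) {
    n <- sample(c(8L, 16L, 32L), 1L)
    cnt <- sample.int(n - 1L, 1L)
    a <- matrix(c(rep(1L, cnt), rep(0L, n - cnt)), ncol = 1)
    hm <- toy_hm(a, positions = 500L)
    p <- max(cnt, n - cnt) / n
    expect_equal(window_hp(hm, make_windows(1000, 1000))$hp, 2 * p * (1 - p))
  }
})

test_that("ZHp has zero mean and unit sample SD and fails on constant Hp", {
  set.seed(9)
  hp <- runif(50, 0, 0.5)
  zt <- zhp_transform(hp)
  expect_equal(mean(zt$zhp), 0, tolerance = 1e-9)
  expect_equal(sd(zt$zhp), 1, tolerance = 1e-9)
  expect_equal(zt$summary$mu_hp, mean(hp))

  # a near-zero Hp window sits below the mean
  hp2 <- c(rep(0.3, 20), 0.001)
  expect_lt(zhp_transform(hp2)$zhp[21L], 0)

  expect_error(zhp_transform(rep(0.2, 10)), "zero variance")
  # partial windows excluded from the moments but still transformed
  hp3 <- c(0.1, 0.2, 0.3, 0.9)
  zt3 <- zhp_transform(hp3, partial = c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(zt3$summary$mu_hp, 0.2)
  expect_false(is.na(zt3$zhp[4L]))
})

test_that("windowed nucleotide diversity matches hand values and brute force", {
  # 2 haplotypes differing at 1 site in a 100-bp window: pi = 0.01/bp
  a <- matrix(c(0, 1), ncol = 1)
  hm <- structure(list(chrom = "chr1", positions = 50L, alleles = a,
                       hap_labels = c("x_1", "x_2"), pop_of_hap = c("A", "A"),
                       polarized = TRUE), class = "HaplotypeSubset")
  expect_equal(window_pi(hm, make_windows(100, 100)), 0.01)

  # monomorphic window
  hm0 <- structure(list(chrom = "chr1", positions = 50L,
                        alleles = matrix(c(1, 1), ncol = 1),
                        hap_labels = c("x_1", "x_2"),
                        pop_of_hap = c("A", "A"), polarized = TRUE),
                   class = "HaplotypeSubset")
  expect_equal(window_pi(hm0, make_windows(100, 100)), 0)

  # agreement with the all-pairs oracle on random data
  set.seed(31)
  am <- matrix(rbinom(8 * 20, 1, 0.4), nrow = 8)
  hm2 <- toy_hm(am, positions = sort(sample.int(2000, 20)))
  sub <- subset_population(hm2, "A")
  expected <- sum(apply(sub$alleles, 2, brute_site_pi)) / 2000
  expect_equal(window_pi(sub, make_windows(2000, 2000)), expected)

  # duplicating every haplotype scales pi by (2n/(2n-1)) * ((n-1)/n)
  n <- nrow(sub$alleles)
  dup <- sub
  dup$alleles <- rbind(sub$alleles, sub$alleles)
  dup$pop_of_hap <- rep(sub$pop_of_hap, 2)
  dup$hap_labels <- c(sub$hap_labels, paste0(sub$hap_labels, "b"))
  ratio <- (2 * n / (2 * n - 1)) * ((n - 1) / n)
  expect_equal(window_pi(dup, make_windows(2000, 2000)),
               window_pi(sub, make_windows(2000, 2000)) * ratio)

  one <- structure(list(chrom = "chr1", positions = 50L,
                        alleles = matrix(1L, nrow = 1)), class = "HaplotypeSubset")
  expect_error(window_pi(one, make_windows(100, 100)), "at least 2")
})

test_that("score aggregation keeps the signed extreme or the mean", {
  w <- make_windows(200, 100)
  expect_equal(aggregate_scores(c(10L, 20L), c(-2.1, 1.3), w)[1L], -2.1)
  expect_equal(aggregate_scores(150L, 0.7, w)[2L], 0.7)
  expect_equal(aggregate_scores(c(10L, 20L, 30L), c(1, 2, 3), w,
                                mode = "mean")[1L], 2)
  expect_true(is.na(aggregate_scores(c(10L, 20L), c(-2.1, 1.3), w)[2L]))
  expect_error(aggregate_scores(c(20L, 10L), c(1, 2), w), "sorted")
})

test_that("window scan tiles every SNP exactly once and nests the statistics", {
  dir <- withr::local_tempdir()
  sim <- small_sim(dir, seed = 13L)
  hm <- sim$hm
  ihs <- ihs_scan(hm, min_bin_n = 10L)
  xp <- xpehh_scan(hm)
  w <- window_scan(hm, ihs_sites = ihs, xpehh_sites = xp,
                   chrom_length = sim$truth$params$chrom_length)
  expect_equal(sum(w$n_snps), ncol(hm$alleles))
  def <- !is.na(w$zhp) & !w$partial
  expect_equal(mean(w$zhp[!is.na(w$hp) & !w$partial]), 0, tolerance = 1e-9)
  expect_equal(sd(w$zhp[!is.na(w$hp) & !w$partial]), 1, tolerance = 1e-9)
  expect_true(all(w$hp >= 0 & w$hp <= 0.5, na.rm = TRUE))
  expect_true(all(w$pi_a >= 0 & w$pi_b >= 0))
})
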