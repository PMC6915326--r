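test_that("KS D and permutation p match enumeration on separated samples", {
  r <- ks_two_sample(c(1, 2, 3), c(4, 5, 6), method = "permutation")
  expect_equal(r$D, 1)
  expect_equal(r$p, 2 / 20)
  expect_equal(ks_two_sample(c(1, 2, 2, 5), c(1, 2, 2, 5))$D, 0)
  expect_error(ks_two_sample(numeric(0), 1), "non-empty")
})

test_that("KS permutation p equals an independent bitmask enumeration", {
  set.seed(43)
  for (i in 1:25) {
    n <- sample(2:6, 1); m <- sample(2:6, 1)
    x <- round(runif(n, 0, 4), 1)
    y <- round(runif(m, 0, 4), 1)
    got <- ks_two_sample(x, y, method = "permutation")
    Ds <- oracle_perm_stats(x, y, oracle_ks_D)
    expect_equal(got$p, mean(Ds >= got$D - 1e-12))
  }
})

test_that("asymptotic KS p tracks the permutation p on small samples", {
  set.seed(47)
  diffs <- replicate(100, {
    n <- 6; m <- 6   # the largest sizes the enumeration oracle covers
    x <- rnorm(n); y <- rnorm(m, sample(c(0, 1.5), 1))
    abs(ks_two_sample(x, y)$p - ks_two_sample(x, y, method = "permutation")$p)
  })
  expect_true(all(diffs < 0.05))
})

test_that("rank-sum U uses midranks and its exact p matches enumeration", {
  r <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 2 / 20)
  # tie midrank for identical singletons
  expect_equal(rank_sum_test(1, 1)$U, 0.5)
  # label swap maps U to nm - U
  set.seed(53)
  x <- runif(5); y <- runif(4)
  expect_equal(rank_sum_test(y, x)$U, 20 - rank_sum_test(x, y)$U)
  # exact p equals bitmask enumeration, including with ties
  for (i in 1:20) {
    n <- sample(2:6, 1); m <- sample(2:6, 1)
    x <- sample(1:5, n, replace = TRUE)
    y <- sample(1:5, m, replace = TRUE)
    got <- rank_sum_test(x, y, method = "exact")
    Us <- oracle_perm_stats(x, y, oracle_U)
    mu <- n * m / 2
    expect_equal(got$p, mean(abs(Us - mu) >= abs(got$U - mu) - 1e-12))
    expect_equal(got$U, oracle_U(x, y))
  }
  # no-tie exact p agrees with the base distribution-based computation
  for (i in 1:10) {
    x <- sample(1:100, 5); y <- setdiff(sample(1:100, 12), x)[1:5]
    expect_equal(rank_sum_test(x, y, method = "exact")$p,
                 wilcox.test(x, y, exact = TRUE)$p.value)
  }
})

test_that("Fisher p follows the hypergeometric enumeration and handles extremes", {
  expect_equal(fisher_exact_2x2(matrix(c(2, 0, 0, 2), 2))$p, 1 / 3)
  expect_equal(fisher_exact_2x2(matrix(c(1, 1, 1, 1), 2))$p, 1)
  expect_equal(fisher_exact_2x2(matrix(c(3, 1, 1, 3), 2))$odds_ratio, 9)
  expect_true(is.infinite(fisher_exact_2x2(matrix(c(2, 0, 0, 2), 2))$odds_ratio))
  expect_true(is.nan(fisher_exact_2x2(matrix(c(2, 0, 0, 0), 2))$odds_ratio))
  expect_error(fisher_exact_2x2(matrix(0, 2, 2)), "positive")
  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
  # invariance under simultaneous row and column swaps
  set.seed(59)
  for (i in 1:20) {
    tab <- matrix(sample(0:8, 4, replace = TRUE), 2)
    if (sum(tab) == 0) next
    swapped <- tab[2:1, 2:1]
    expect_equal(fisher_exact_2x2(swapped)$p, fisher_exact_2x2(tab)$p)
  }
})

test_that("KS D is invariant under common strictly monotone transforms", {
  set.seed(61)
  x <- rnorm(20); y <- rnorm(15, 1)
  d0 <- ks_two_sample(x, y)$D
  expect_equal(ks_two_sample(exp(x), exp(y))$D, d0)
  expect_equal(ks_two_sample(x^3, y^3)$D, d0)
  expect_equal(ks_two_sample(-x, -y)$D, d0)  # reversal also preserves sup|dF|
})

test_that("fold depletion follows its defining ratio", {
  set.seed(73)
  idx <- c(runif(12, 0.7, 0.9), runif(88, 0.1, 0.5))  # 12 high, 88 low
  names(idx) <- sprintf("rp%03d", 1:100)
  high <- names(idx)[1:12]; low <- names(idx)[13:100]
  # 10/50 high in non-abundant vs 2/50 in abundant -> 5.0
  abundant <- c(high[1:2], low[1:48])
  fd <- depletion_fold(idx, abundant)
  expect_equal(fd$fold, (10 / 50) / (2 / 50))
  # equal fractions -> 1.0
  ab2 <- c(high[1:6], low[1:44])
  expect_equal(depletion_fold(idx, ab2)$fold, 1.0)
  # no high-index proteins at all -> undefined
  alllow <- setNames(runif(10, 0, 0.5), letters[1:10])
  expect_error(depletion_fold(alllow, letters[1:5]), "undefined")
  # abundant group without any high-index protein -> infinite with flag
  ab3 <- low[1:31]
  expect_warning(fd3 <- depletion_fold(idx, ab3), "infinite")
  expect_true(fd3$infinite && is.infinite(fd3$fold))
})

test_that("abundance bias summarises group means, KS, Fisher and depletion together", {
  set.seed(67)
  g <- gen_depletion_groups(fold = 5, seed = 67)
  fpkm <- setNames(ifelse(names(g$index_by_rp) %in% g$abundant, 500, 10),
                   names(g$index_by_rp))
  b <- abundance_bias(g$index_by_rp, fpkm)
  expect_s3_class(b, "bias_result")
  expect_equal(b$n_abundant, 30L)
  expect_equal(sum(b$fisher_table), 80)
  expect_equal(colSums(b$fisher_table), c(abundant = 30, non_abundant = 50))
  expect_lt(b$group_hi_mean, b$group_lo_mean)
  expect_gt(b$fold_depletion, 1)
  # the Fisher table reproduces the depletion ratio
  expect_equal(b$fold_depletion,
               (b$fisher_table[1, 2] / 50) / (b$fisher_table[1, 1] / 30))
})

test_that("stage ratios use pseudocounts and detect a planted RP decline", {
  a <- c(t1 = 10, t2 = 20); b <- c(t1 = 10, t2 = 20)
  rp <- c(t1 = TRUE, t2 = FALSE)
  expect_error(stage_ratio_distribution(a, b, rp), "at least 2")
  set.seed(71)
  n_rp <- 60; n_non <- 600
  ids <- c(sprintf("rp%03d", 1:n_rp), sprintf("nr%03d", 1:n_non))
  is_rp <- setNames(rep(c(TRUE, FALSE), c(n_rp, n_non)), ids)
  fa <- setNames(rlnorm(n_rp + n_non, log(100), 0.5), ids)
  fb <- fa * exp(rnorm(n_rp + n_non, 0, 0.2))
  fb[1:n_rp] <- fb[1:n_rp] / 2          # planted 2-fold decline in RPs
  out <- stage_ratio_distribution(fa, fb, is_rp)
  expect_lt(out$ks_p, 0.01)
  expect_equal(out$n_rp, n_rp)
  # identical stages give identically zero log-ratios
  flat <- stage_ratio_distribution(fa, fa, is_rp)
  expect_true(all(flat$log2_ratio == 0))
  # zero FPKM with zero pseudocount is rejected
  fz <- fa; fz[1] <- 0
  expect_error(stage_ratio_distribution(fz, fb, is_rp, pseudocount = 0),
               "zero FPKM")
})

test_that("FRAP recovery is 0 at post, 1 at pre, linear between", {
  expect_equal(frap_relative_recovery(10, 10, 4), 1)
  expect_equal(frap_relative_recovery(4, 10, 4), 0)
  expect_equal(frap_relative_recovery(7, 10, 4), 0.5)
  # background subtraction applies to every reading
  expect_equal(frap_relative_recovery(c(8, 11), Ipre = 12, Ipost = 6,
                                      bg_x = 2, bg_pre = 2, bg_post = 2),
               c((6 - 4) / (10 - 4), (9 - 4) / (10 - 4)))
  expect_error(frap_relative_recovery(5, 4, 4), "Ipre must exceed")
})
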