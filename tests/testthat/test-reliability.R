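test_that("agreement statistics match hand computation and the RMSE identity", {
  id <- agreement_stats(c(1, 2, 3), c(1, 2, 3))
  expect_equal(id$mean_error, 0)
  expect_equal(id$sd, 0)
  expect_equal(id$rmse, 0)

  st <- agreement_stats(c(-1, 0, 1), c(0, 0, 0))
  expect_equal(st$mean_error, 0)
  expect_equal(st$sd, 1)
  expect_equal(st$rmse, sqrt(2 / 3))

  set.seed(12)
  for (i in 1:20) {
    n <- sample(3:40, 1)
    a <- rnorm(n, 90, 3); b <- rnorm(n, 90, 3)
    s <- agreement_stats(a, b)
    expect_equal(s$rmse^2, s$mean_error^2 + s$sd^2 * (n - 1) / n,
                 tolerance = 1e-12)
    expect_gte(s$rmse, abs(s$mean_error))
    expect_true(s$ci[1] <= s$mean_error && s$mean_error <= s$ci[2])
  }
  expect_error(agreement_stats(1, 2), "2 complete pairs")
})

test_that("ICC(A,1) matches a brute-force ANOVA oracle and penalizes bias", {
  # explicit sums-of-squares oracle
  icc_oracle <- function(m) {
    n <- nrow(m); k <- ncol(m)
    grand <- mean(m)
    msr <- k * sum((rowMeans(m) - grand)^2) / (n - 1)
    msc <- n * sum((colMeans(m) - grand)^2) / (k - 1)
    mse <- (sum((m - grand)^2) - k * sum((rowMeans(m) - grand)^2) -
              n * sum((colMeans(m) - grand)^2)) / ((n - 1) * (k - 1))
    (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  }
  m6 <- cbind(c(9, 8, 7, 10, 6, 8), c(8, 8, 6, 9, 7, 7))
  expect_equal(icc_a1(m6)$icc, icc_oracle(m6), tolerance = 1e-12)

  a <- c(85, 88, 90, 92, 95, 97)
  expect_equal(icc_a1(cbind(a, a))$icc, 1.0)

  biased <- icc_a1(cbind(a, a + 5))
  expect_lt(biased$icc, 1)           # absolute agreement penalizes bias
  expect_equal(pearson(a, a + 5)$r, 1)
  expect_lt(biased$icc, pearson(a, a + 5)$r)

  set.seed(99)
  for (i in 1:100) {
    m <- matrix(rnorm(20, 90, 3), 10, 2)
    res <- icc_a1(m)
    expect_equal(res$icc, icc_oracle(m), tolerance = 1e-10)
    expect_true(res$ci[1] <= res$icc + 1e-9 && res$icc <= res$ci[2] + 1e-9)
    # symmetry and shift invariance
    expect_equal(icc_a1(m[, 2:1])$icc, res$icc, tolerance = 1e-12)
    expect_equal(icc_a1(m + 17)$icc, res$icc, tolerance = 1e-9)
  }
  expect_error(icc_a1(cbind(c(1, 1), c(1, 1))), "zero total variance")
})

test_that("simulated two-source ratings reach the closed-form ICC of 0.9", {
  set.seed(424)
  truth <- rnorm(500, 90, 3)
  a <- truth + rnorm(500, 0, 1)
  b <- truth + rnorm(500, 0, 1)
  res <- icc_a1(cbind(a, b))
  expect_equal(res$icc, 9 / (9 + 1), tolerance = 0.02)
})

test_that("Pearson r and p match direct summation", {
  expect_equal(pearson(1:10, 2 * (1:10) + 1)$r, 1)
  a <- c(1, 2, 3, 4); b <- c(2, 1, 4, 3)
  # hand summation oracle
  r_oracle <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  res <- pearson(a, b)
  expect_equal(res$r, r_oracle, tolerance = 1e-12)
  t_stat <- res$r * sqrt((4 - 2) / (1 - res$r^2))
  expect_equal(res$p, 2 * stats::pt(-abs(t_stat), 2), tolerance = 1e-12)
  expect_error(pearson(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearson(c(1, 2), c(1, 2)), "3 complete pairs")
})

test_that("reliability reports are pairwise-complete with per-parameter n", {
  set.seed(7)
  subjects <- sprintf("s%02d", 1:30)
  mk <- function(noise) {
    d <- data.frame(subject = subjects,
                    mMPTA = rnorm(30, 87, 2), mLDFA = rnorm(30, 88, 2),
                    mFAmTA = rnorm(30, 179, 3), mLDTA = rnorm(30, 89, 2),
                    FSAmTA = rnorm(30, 173, 3))
    d
  }
  a <- mk(); b <- a
  for (p in c("mMPTA", "mLDFA", "mFAmTA", "mLDTA", "FSAmTA")) {
    b[[p]] <- a[[p]] + rnorm(30, 0, 0.5)
  }
  b$mLDTA[4] <- NA
  rep <- reliability_report(a, b)
  expect_equal(rep$n[rep$parameter == "mLDTA"], 29)
  expect_equal(rep$n[rep$parameter == "mMPTA"], 30)
  expect_true(all(rep$icc > 0.8))

  # identical sources: perfect agreement
  perfect <- reliability_report(a, a)
  expect_true(all(abs(perfect$icc - 1) < 1e-9))
  expect_true(all(abs(perfect$rmse) < 1e-9))

  # long-format input reshapes automatically
  long <- data.frame(subject = rep(subjects, 5),
                     parameter = rep(c("mMPTA", "mLDFA", "mFAmTA", "mLDTA",
                                       "FSAmTA"), each = 30),
                     value = c(a$mMPTA, a$mLDFA, a$mFAmTA, a$mLDTA, a$FSAmTA))
  expect_s3_class(rater_table(long), "rater_table")
})

test_that("printed table cells satisfy the RMSE reconstruction identity", {
  cells <- check_printed_rmse_identity()
  expect_equal(nrow(cells), 4)
  expect_true(all(cells$ok))
  expect_lt(max(abs(cells$deviation)), 0.05)
})
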