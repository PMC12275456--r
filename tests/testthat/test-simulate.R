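test_that("short-term tables have one row per chamber and correct arms", {
  d <- short_term_design(4, 50, itn_reduction = 0.6)
  dat <- simulate_short(d, seed = 1)
  expect_equal(nrow(dat), 8)  # 2 arms x 4 chambers
  expect_equal(sort(unique(dat$chamber)), 1:8)
  expect_equal(sum(dat$itn), 4)
  expect_true(all(dat$count >= 0 & dat$count == round(dat$count)))

  dc <- short_term_design(3, 50, arms = "combined")
  expect_equal(nrow(simulate_short(dc, seed = 1)), 12)  # 4 arms x 3
  # each chamber has exactly one (itn, ppf) combination
  datc <- simulate_short(dc, seed = 2)
  expect_equal(nrow(unique(datc[c("chamber", "itn", "ppf")])), 12)
})

test_that("simulation is reproducible and seed-sensitive", {
  d <- long_term_design(2, 10, sampl_freq = "monthly", itn_reduction = 0.5)
  a <- simulate_long(d, seed = 7)
  b <- simulate_long(d, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a$count, simulate_long(d, seed = 8)$count))
  s <- short_term_design(2, 50)
  expect_identical(simulate_short(s, 5), simulate_counts(s, 5))
})

test_that("conditional means follow the generative model", {
  # no chamber noise, zero effects: counts are Poisson(50)
  d0 <- short_term_design(2, 50, chamber_var = 0)
  counts <- unlist(lapply(1:500, function(i) simulate_short(d0, seed = i)$count))
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 50), 3 * se)

  # ITN arm with 80% reduction: conditional mean exactly 10
  d1 <- short_term_design(2, 50, chamber_var = 0, itn_reduction = 0.8)
  itn_counts <- unlist(lapply(1:1500, function(i) {
    dat <- simulate_short(d1, seed = i); dat$count[dat$itn == 1]
  }))
  expect_lt(abs(mean(itn_counts) - 10), 3 * sd(itn_counts) / sqrt(length(itn_counts)))
})

test_that("chamber noise mixes log-normally into the marginal mean", {
  s2 <- 0.36
  d <- short_term_design(2, 40, chamber_var = s2)
  counts <- unlist(lapply(1:3000, function(i) {
    dat <- simulate_short(d, seed = i); dat$count[dat$itn == 0]
  }))
  expected <- 40 * exp(s2 / 2)
  expect_lt(abs(mean(counts) - expected), 3 * sd(counts) / sqrt(length(counts)))
})

test_that("long-term tables are fully crossed with shared latent draws", {
  d <- long_term_design(2, 10, sampl_freq = "weekly", arms = "combined",
                        itn_reduction = 0.8)
  dat <- simulate_long(d, seed = 3)
  expect_equal(nrow(dat), 8 * 12)
  expect_equal(length(attr(dat, "latent_time")), 12)
  expect_equal(length(attr(dat, "latent_chamber")), 8)
  # every chamber is observed at every sampling time (crossed structure)
  expect_true(all(table(dat$chamber, dat$time) == 1))

  # the stored time effect is common to all chambers at that occasion:
  # control-arm log-means co-move with tau_i
  dbig <- long_term_design(4, 1000, sampl_freq = "weekly", time_var = 0.3,
                           chamber_var = 0, theta = 1e6)
  datb <- simulate_long(dbig, seed = 9)
  ctrl <- datb[datb$itn == 0, ]
  logmeans <- log(tapply(ctrl$count, ctrl$time, mean))
  tau <- attr(datb, "latent_time")
  expect_gt(cor(logmeans, tau), 0.99)
})

test_that("negative-binomial dispersion recovers the Poisson limit", {
  d <- long_term_design(4, 20, sampl_freq = "weekly", chamber_var = 0,
                        time_var = 0, theta = 1e6)
  counts <- unlist(lapply(1:60, function(i) {
    dat <- simulate_long(d, seed = i); dat$count[dat$itn == 0]
  }))
  ratio <- var(counts) / mean(counts)
  expect_lt(abs(ratio - 1), 0.1)
  # and a small theta is visibly overdispersed
  d2 <- long_term_design(4, 20, sampl_freq = "weekly", chamber_var = 0,
                         time_var = 0, theta = 2)
  counts2 <- unlist(lapply(1:60, function(i) {
    dat <- simulate_long(d2, seed = i); dat$count[dat$itn == 0]
  }))
  expect_gt(var(counts2) / mean(counts2), 5)
})

test_that("expected trajectories decay to the target remainder", {
  d <- long_term_design(4, 50, sampl_freq = "weekly", arms = "combined",
                        itn_reduction = 0.8, ppf_reduction = 0.7,
                        ixn_reduction = 0)
  tr <- expected_trajectory(d, "itn_ppf")
  expect_equal(tr$mean[12], 50 * 0.06, tolerance = 1e-10)
  d5 <- long_term_design(4, 50, sampl_freq = "weekly", arms = "combined",
                         itn_reduction = 0.8, ppf_reduction = 0.7,
                         ixn_reduction = 0.5)
  expect_equal(expected_trajectory(d5, "itn_ppf")$mean[12], 50 * 0.03,
               tolerance = 1e-10)
  # control is flat; treated arms decay monotonically
  expect_equal(expected_trajectory(d, "control")$mean, rep(50, 12))
  expect_true(all(diff(expected_trajectory(d, "itn")$mean) < 0))
  expect_error(expected_trajectory(long_term_design(2, 10), "ppf"), "no PPFa")
})

test_that("count tables round-trip through CSV", {
  d <- long_term_design(2, 10, sampl_freq = "monthly")
  dat <- simulate_long(d, seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_counts(dat, path)
  back <- read_counts(path)
  strip <- function(x) {
    x <- as.data.frame(x)
    attr(x, "latent_chamber") <- NULL
    attr(x, "latent_time") <- NULL
    x
  }
  expect_equal(strip(dat), strip(back))
  expect_error(read_counts(textConnection("a,b\n1,2")), "columns")
})
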