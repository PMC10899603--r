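boltzmann <- function(tt, tm, slope, base = 0.1, amp = 1) {
  base + amp / (1 + exp((tm - tt) / slope))
}

test_that("melt curves validate their inputs", {
  grid <- seq(25, 99, by = 0.5)
  expect_s3_class(melt_curve(grid, boltzmann(grid, 60, 1.5)), "melt_curve")
  expect_error(melt_curve(rev(grid), boltzmann(grid, 60, 1.5)),
               "increasing")
  expect_error(melt_curve(seq(10, 99, 0.5),
                          boltzmann(seq(10, 99, 0.5), 60, 1.5)),
               "within")
  expect_error(melt_curve(grid[1:5], rep(1, 5)), ">= 10")
})

test_that("noiseless sigmoid curves refit their own parameters exactly", {
  grid <- seq(25, 99, by = 0.5)
  cv <- melt_curve(grid, boltzmann(grid, 60, 1.5))
  fit <- fit_melt_sigmoid(cv)
  expect_equal(fit$tm, 60, tolerance = 1e-6)
  expect_equal(fit$slope, 1.5, tolerance = 1e-4)
  expect_equal(fit$amplitude, 1, tolerance = 1e-4)
  expect_equal(fit$baseline, 0.1, tolerance = 1e-4)
  expect_gt(fit$slope, 0)
  expect_true(fit$tm >= min(grid) && fit$tm <= max(grid))
})

test_that("derivative and sigmoid Tm agree on noiseless curves", {
  grid <- seq(25, 99, by = 0.5)
  for (tm in c(45, 60, 72)) {
    cv <- melt_curve(grid, boltzmann(grid, tm, 2))
    fs <- fit_melt_sigmoid(cv)
    fd <- tm_by_derivative(cv)
    expect_equal(fd$method, "derivative")
    expect_lt(abs(fs$tm - fd$tm), 0.5)
    expect_lte(abs(fd$tm - tm), 0.5)  # within one temperature step
  }
})

test_that("monotone curves without a transition are rejected", {
  grid <- seq(25, 99, by = 0.5)
  falling <- melt_curve(grid, 2 - 0.01 * (grid - 25))
  expect_error(fit_melt_sigmoid(falling), "no-transition")
  expect_error(tm_by_derivative(falling), "no-transition")
})

test_that("post-transition aggregation decay is excluded by truncation", {
  grid <- seq(25, 99, by = 0.5)
  f <- boltzmann(grid, 60, 1.5)
  decay <- grid > 85
  f[decay] <- f[decay] - 0.02 * (grid[decay] - 85)
  fit <- fit_melt_sigmoid(melt_curve(grid, f))
  expect_equal(fit$tm, 60, tolerance = 0.05)
  expect_lte(max(fit$curve$temperature), 85.5)
})

test_that("Tm estimates are invariant under affine fluorescence transforms", {
  g <- gen_melt_curves(91, data.frame(name = "V1", tm = 58, slope = 1.5),
                       replicates = 1)
  cv <- g$curves[[1]]
  fit0 <- fit_melt_sigmoid(cv)
  cv2 <- melt_curve(cv$temperature, 7.3 * cv$fluorescence + 42,
                    variant = "V1")
  fit2 <- fit_melt_sigmoid(cv2)
  expect_equal(fit0$tm, fit2$tm, tolerance = 1e-6)
  expect_equal(tm_by_derivative(cv)$tm, tm_by_derivative(cv2)$tm)
})

test_that("smoothing window 1 equals the raw finite-difference argmax", {
  g <- gen_melt_curves(17, data.frame(name = "V", tm = 55, slope = 2),
                       replicates = 1)
  cv <- g$curves[[1]]
  fit <- tm_by_derivative(cv, smooth_window = 1)
  tt <- cv$temperature
  ff <- cv$fluorescence
  imax <- which.max(ff)
  raw <- diff(ff[1:imax]) / diff(tt[1:imax])
  mids <- (tt[1:(imax - 1)] + tt[2:imax]) / 2
  expect_equal(fit$tm, mids[which.max(raw)])
})

test_that("melt_fit methods print, predict and expose residuals", {
  grid <- seq(25, 99, by = 0.5)
  fit <- fit_melt_sigmoid(melt_curve(grid, boltzmann(grid, 61, 1.2)))
  expect_output(print(fit), "Tm = 61.00")
  expect_named(coef(fit), c("tm", "slope", "amplitude", "baseline"))
  expect_equal(predict(fit, data.frame(temperature = 61)),
               0.1 + 0.5, tolerance = 1e-3)
  expect_lt(max(abs(residuals(fit))), 1e-6)
})

test_that("replicate aggregation produces mean, SEM and delta-Tm", {
  rec <- aggregate_variant(c(60.1, 60.2, 60.3), wildtype_mean = 50.0,
                           variant = "V1", mutations = "E75P")
  expect_equal(rec$tm_mean, 60.2)
  expect_equal(rec$tm_sem, stats::sd(c(60.1, 60.2, 60.3)) / sqrt(3))
  expect_equal(rec$tm_sem, 0.0577, tolerance = 1e-3)
  expect_equal(rec$delta_tm, 10.2)
  expect_false(rec$sem_flagged)

  single <- aggregate_variant(59.5, 50, variant = "V2")
  expect_equal(single$tm_sem, 0)
  expect_true(single$sem_flagged)

  a <- fit_melt_sigmoid(melt_curve(seq(25, 99, 0.5),
                                   boltzmann(seq(25, 99, 0.5), 60, 1.5),
                                   variant = "A"))
  b <- fit_melt_sigmoid(melt_curve(seq(25, 99, 0.5),
                                   boltzmann(seq(25, 99, 0.5), 62, 1.5),
                                   variant = "B"))
  expect_error(aggregate_variant(list(a, b), 50), "mixed variant")
})

test_that("SEM scales as one over the square root of n", {
  tms_by_n <- lapply(c(3, 12, 48), function(n) {
    g <- gen_melt_curves(300 + n, data.frame(name = "V", tm = 60,
                                             slope = 1.5),
                         replicates = n, noise_sd = 0.02,
                         grid = seq(25, 99, by = 1))
    vapply(g$curves, function(cv) fit_melt_sigmoid(cv)$tm, numeric(1))
  })
  sems <- vapply(tms_by_n, function(x) stats::sd(x) / sqrt(length(x)),
                 numeric(1))
  ## quadrupling n roughly halves the SEM
  expect_lt(sems[2], sems[1])
  expect_lt(sems[3], sems[2])
})

test_that("a wildtype/variant pair generated 13.1 C apart is recovered", {
  g <- gen_melt_curves(131, data.frame(name = c("WT", "stable"),
                                       tm = c(52.4, 65.5),
                                       slope = c(1.5, 1.5)),
                       replicates = 3, noise_sd = 0.02)
  tm <- function(v) {
    fits <- lapply(Filter(function(cv) attr(cv, "variant") == v, g$curves),
                   fit_melt_sigmoid)
    aggregate_variant(fits, wildtype_mean = 0)
  }
  wt <- tm("WT")
  st <- tm("stable")
  expect_equal(st$tm_mean - wt$tm_mean, 13.1, tolerance = 0.2)
})

test_that("combination selection unions passing single mutants by position", {
  mk <- function(v, mut, dtm, act = 1) {
    aggregate_variant(50 + dtm, 50, variant = v, mutations = mut,
                      activity = act)
  }
  recs <- list(mk("wt", character(0), 0),
               mk("m1", "E75P", 3.0), mk("m2", "Q86K", 2.2),
               mk("m3", "S110V", 0.4),          # below delta-Tm threshold
               mk("m4", "T388A", 2.0, act = 0.5),  # activity lost
               mk("m5", "G430K", 1.5))
  expect_equal(select_combination(recs), c("E75P", "Q86K", "G430K"))
  expect_equal(select_combination(list(mk("m", "E75P", 0.2))), character())
  expect_error(select_combination(list()), "empty")

  ## conflicting mutations at one position: larger delta-Tm wins
  recs2 <- list(mk("a", "G222D", 2.0), mk("b", "G222S", 3.0))
  expect_equal(select_combination(recs2), "G222S")
})

test_that("ten passing single mutants reproduce a decatuple plan", {
  sites <- stable_sites()
  muts <- paste0(sites$wt, sites$position, sites$consensus)
  recs <- lapply(seq_along(muts), function(i)
    aggregate_variant(50 + 1 + 0.3 * i, 50, variant = paste0("m", i),
                      mutations = muts[i], activity = 0.95))
  plan <- select_combination(recs)
  expect_length(plan, 10)
  expect_equal(plan, muts[order(sites$position)])
})
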