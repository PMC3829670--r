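test_that("contrast reproduces the worked score pairs", {
  expect_equal(round_tdc(contrast(4, 2)), -0.333)
  expect_equal(round_tdc(contrast(20, 3)), -0.739)
  expect_equal(contrast(7, 7), 0)
  expect_equal(contrast(5, 0), -1)
  expect_equal(contrast(0, 5), +1)
  expect_equal(contrast(0, 0), 0)  # absent sign, no change
})

test_that("contrast rejects invalid scores", {
  expect_error(contrast(-1, 2), class = "tdcontrol_error_input")
  expect_error(contrast(1, NA), class = "tdcontrol_error_input")
  expect_error(contrast(Inf, 2), class = "tdcontrol_error_input")
  expect_error(contrast(1:3, 1:2), class = "tdcontrol_error_input")
})

test_that("contrast is antisymmetric, bounded and scale invariant", {
  set.seed(101)
  a <- runif(500, 0, 100)
  b <- runif(500, 0, 100)
  expect_equal(contrast(a, b), -contrast(b, a))
  expect_true(all(abs(contrast(a, b)) <= 1))
  k <- runif(500, 0.01, 50)
  expect_equal(contrast(k * a, k * b), contrast(a, b))
})

test_that("tdc is the order-invariant mean of its components", {
  cs <- contrast(worked_patient_pairs()$s1, worked_patient_pairs()$s2)
  expect_equal(round_tdc(tdc(cs)), -0.674)
  expect_equal(round_tdc(tdc(cs[1:4])), -0.685)  # anamnestic subset
  expect_equal(tdc(cs), tdc(rev(cs)))
  expect_equal(tdc(-0.42), -0.42)  # mean of one
  expect_error(tdc(numeric()), class = "tdcontrol_error_input")
})

test_that("tdc equals the item-count-weighted mean of its subset TDCs", {
  pr <- worked_patient_pairs()
  cs <- contrast(pr$s1, pr$s2)
  anam <- pr$item_class == "anamnestic"
  weighted <- (sum(anam) * tdc(cs[anam]) + sum(!anam) * tdc(cs[!anam])) / length(cs)
  expect_equal(tdc(cs), weighted)
})

test_that("factor conversions match the printed cut-off arithmetic", {
  expect_equal(round_tdc(factor_to_contrast(0.65)), -0.212)
  expect_equal(round_tdc(factor_to_contrast(0.45)), -0.379)
  expect_equal(factor_to_contrast(1), 0)
  expect_equal(round_tdc(contrast_to_factor(-0.378)), 0.451)
  expect_equal(contrast_to_factor(0), 1)
  expect_equal(contrast_to_factor(1 / 3), 2)
  expect_error(contrast_to_factor(1), class = "tdcontrol_error_input")
  expect_error(factor_to_contrast(0), class = "tdcontrol_error_input")
})

test_that("factor round trip and reciprocal symmetry hold across the range", {
  set.seed(7)
  r <- exp(runif(500, log(0.01), log(100)))
  expect_equal(contrast_to_factor(factor_to_contrast(r)), r, tolerance = 1e-9)
  expect_equal(factor_to_contrast(r) + factor_to_contrast(1 / r),
               rep(0, length(r)), tolerance = 1e-12)
})

test_that("reversed-scale and unknown-maximum transforms match worked examples", {
  expect_equal(complement_contrast(40, 80, 100), -0.5)
  expect_equal(complement_contrast(3, 3, 4), 0)
  expect_equal(complement_contrast(0, 100, 100), -1)
  expect_error(complement_contrast(40, 120, 100), class = "tdcontrol_error_input")

  expect_equal(unknown_max_contrast(20, 30, 35), -0.5)
  expect_equal(unknown_max_contrast(20, 43, 35), -1)
  expect_equal(unknown_max_contrast(35, 35, 35), 0)
})

test_that("unknown-maximum state persists along a patient timeline", {
  # limit 35; a visit at 43 raises the effective maximum for later visits
  cs <- unknown_max_timeline(20, c(30, 43, 40), 35)
  expect_equal(cs[1], -0.5)
  expect_equal(cs[2], -1)
  # 43 persists: complements are (43-20, 43-40) = (23, 3)
  expect_equal(cs[3], contrast(23, 3))
  expect_error(unknown_max_timeline(40, c(30, 43), 35),
               class = "tdcontrol_error_input")
})

test_that("averaging methods reproduce the three demonstration blocks", {
  blocks <- list(
    equal  = data.frame(s1 = c(50, 50, 50), s2 = c(100, 50, 25)),
    middle = data.frame(s1 = c(20, 40, 60), s2 = c(40, 40, 30)),
    bottom = data.frame(s1 = c(20, 40, 60), s2 = c(10, 40, 120))
  )
  res <- lapply(blocks, compare_averaging_methods)
  expect_equal(round(res$equal$ratio_of_means, 2), 1.17)
  expect_equal(round(res$middle$ratio_of_means, 3), 0.917)
  expect_equal(round(res$bottom$ratio_of_means, 2), 1.42)
  for (r in res) {
    expect_equal(round(r$mean_of_ratios, 2), 1.17)
    expect_equal(r$mean_log_ratio, 0, tolerance = 1e-12)
    expect_equal(r$mean_contrast, 0, tolerance = 1e-12)
  }
  expect_error(compare_averaging_methods(data.frame(s1 = c(0, 1), s2 = c(1, 1))),
               class = "tdcontrol_error_input")
})

test_that("reciprocal factor pairs cancel in log and Contrast averages", {
  set.seed(3)
  k <- exp(runif(50, log(1.1), log(5)))
  s1 <- runif(100, 10, 60)
  s2 <- s1 * c(k, 1 / k)
  res <- compare_averaging_methods(data.frame(s1 = s1, s2 = s2))
  expect_equal(res$mean_log_ratio, 0, tolerance = 1e-12)
  expect_equal(res$mean_contrast, 0, tolerance = 1e-12)
  expect_gt(res$mean_of_ratios, 1)  # plain ratios lack the symmetric zero
})

test_that("log-ratio approximation stays within 15% over the stated band", {
  expect_equal(log_ratio_deviation(0), 0)
  c333 <- contrast(4, 2)
  lr <- log10((1 + c333) / (1 - c333))
  expect_equal(round(lr, 3), -0.301)  # log10(2/4)
  # grid over |log10 R| <= 0.80
  lg <- seq(-0.80, 0.80, length.out = 2001)
  cc <- factor_to_contrast(10^lg)
  expect_lt(max(log_ratio_deviation(cc)), 0.15)
})
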