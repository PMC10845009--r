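test_that("a clean slope change is located exactly and a pure line is not split", {
  x <- seq(1, 20)
  y_kink <- ifelse(x <= 12, 2 + 0.5 * x, 2 + 0.5 * 12 + 2.5 * (x - 12))
  bp <- detect_breakpoint(x, y_kink)
  expect_equal(bp$breakpoint, 12)
  expect_gt(bp$delta_bic, 0)
  expect_equal(unname(bp$slopes), c(0.5, 2.5), tolerance = 1e-8)

  y_line <- 3 - 0.7 * x
  expect_true(is.na(detect_breakpoint(x, y_line)$breakpoint))
})

test_that("noisy breakpoints agree with the exhaustive SSE scan", {
  set.seed(41)
  for (rep in 1:5) {
    x <- seq(0, 30)
    xb <- sample(8:22, 1)
    y <- ifelse(x <= xb, 1 + 0.3 * x, 1 + 0.3 * xb - 0.6 * (x - xb)) +
      rnorm(length(x), 0, 0.15)
    bp <- detect_breakpoint(x, y)
    expect_equal(bp$breakpoint, oracle_breakpoint_scan(x, y))
    expect_lt(abs(bp$breakpoint - xb), 3)
  }
})

test_that("short series and degenerate inputs return no breakpoint", {
  expect_true(is.na(detect_breakpoint(1:4, c(1, 2, 3, 4))$breakpoint))
  expect_true(is.na(detect_breakpoint(1:10, rep(2, 10))$breakpoint))
})
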