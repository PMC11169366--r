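# PSNR/SSIM/RMSE oracles, the composite objective and its gradient.

# brute-force local-statistics SSIM, written independently of the package path
ssim_bruteforce <- function(a, b, win = 11L, sigma = 1.5, C1 = 1e-4, C2 = 9e-4) {
  r <- seq_len(win) - (win + 1) / 2
  g <- exp(-r^2 / (2 * sigma^2))
  w <- outer(g, g)
  w <- w / sum(w)
  h <- nrow(a)
  half <- (win - 1) / 2
  vals <- c()
  for (i in (half + 1):(h - half))
    for (j in (half + 1):(ncol(a) - half)) {
      pa <- a[(i - half):(i + half), (j - half):(j + half)]
      pb <- b[(i - half):(i + half), (j - half):(j + half)]
      mx <- sum(w * pa); my <- sum(w * pb)
      vx <- sum(w * pa^2) - mx^2
      vy <- sum(w * pb^2) - my^2
      cxy <- sum(w * pa * pb) - mx * my
      vals <- c(vals, ((2 * mx * my + C1) * (2 * cxy + C2)) /
                        ((mx^2 + my^2 + C1) * (vx + vy + C2)))
    }
  mean(vals)
}

test_that("L1, PSNR and RMSE match elementwise brute force", {
  set.seed(11)
  for (rep in 1:5) {
    a <- matrix(runif(64), 8)
    b <- matrix(runif(64), 8)
    expect_equal(l1_loss(a, b), mean(abs(a - b)), tolerance = 1e-12)
    mse <- 0
    for (i in 1:8) for (j in 1:8) mse <- mse + (a[i, j] - b[i, j])^2
    mse <- mse / 64
    expect_lt(abs(rmse(a, b) - sqrt(mse)), 1e-9)
    expect_lt(abs(psnr(a, b) - 10 * log10(1 / mse)), 1e-9)
  }
  expect_equal(l1_loss(matrix(0.3, 4, 4), matrix(0.2, 4, 4)), 0.1)
  expect_equal(psnr(matrix(0.5, 4, 4), matrix(0.6, 4, 4)), 20)
  expect_equal(rmse(matrix(0.5, 4, 4), matrix(0.6, 4, 4)), 0.1)
  a <- matrix(runif(16), 4)
  expect_identical(psnr(a, a), Inf)
  expect_identical(rmse(a, a), 0)
  expect_error(psnr(a, matrix(0, 5, 5)), "shape")
})

test_that("SSIM matches an independent windowed-statistics implementation", {
  set.seed(12)
  a <- matrix(runif(20 * 20), 20)
  b <- pmin(pmax(a + rnorm(400, 0, 0.1), 0), 1)
  expect_lt(abs(ssim(a, b) - ssim_bruteforce(a, b)), 1e-10)
  expect_identical(ssim(a, a), 1)
  expect_equal(ssim(a, b), ssim(b, a), tolerance = 1e-12)
  expect_error(ssim(matrix(0, 8, 8), matrix(0, 8, 8)), "smaller than")
})

test_that("SSIM degrades monotonically with added noise and stays in [-1, 1]", {
  set.seed(13)
  a <- matrix(runif(32 * 32), 32)
  vals <- sapply(c(0.01, 0.05, 0.1), function(s) {
    set.seed(99)
    ssim(a, a + matrix(rnorm(1024, 0, s), 32))
  })
  expect_true(all(diff(vals) < 0))
  expect_true(all(vals >= -1 & vals <= 1))
})

test_that("composite loss is the weighted L1 + (1 - SSIM) with minimum 0", {
  set.seed(14)
  a <- matrix(runif(32 * 32), 32)
  b <- pmin(pmax(a + rnorm(1024, 0, 0.05), 0), 1)
  expect_equal(composite_loss(a, a), 0)
  expect_equal(composite_loss(a, b, loss_weights(1, 0)), l1_loss(a, b))
  w <- loss_weights()
  expect_equal(w$alpha, 1)
  expect_equal(w$lambda, 0.001)
  expect_equal(composite_loss(a, b, w),
               l1_loss(a, b) + 0.001 * (1 - ssim(a, b)), tolerance = 1e-12)
  expect_gte(composite_loss(a, b, w), 0)
  expect_error(loss_weights(-1, 0.5), "nonnegative")
  expect_error(loss_weights(0, 0), "positive")
})

test_that("the composite-loss gradient matches finite differences", {
  set.seed(15)
  x <- array(runif(24 * 24), c(24, 24, 1, 1))
  y <- array(pmin(pmax(x + rnorm(576, 0, 0.08), 0), 1), c(24, 24, 1, 1))
  w <- loss_weights(1, 0.5)  # large SSIM weight to expose that term
  r <- composite_loss(x, y, w, grad = TRUE)
  eps <- 1e-6
  for (idx in sample(576, 8)) {
    x2 <- x
    x2[idx] <- x2[idx] + eps
    num <- (composite_loss(x2, y, w) - r$value) / eps
    expect_lt(abs(num - r$grad[idx]), 1e-4 * max(1, abs(num)))
  }
})

test_that("total loss sums sources and is permutation invariant", {
  set.seed(16)
  mk <- function() {
    p <- matrix(runif(16 * 16), 16)
    list(pred = p, ref = pmin(pmax(p + rnorm(256, 0, 0.1), 0), 1))
  }
  prs <- list(mk(), mk(), mk())
  w <- loss_weights(1, 0)
  tl <- total_loss(prs, w)
  expect_equal(tl, sum(sapply(prs, function(p) composite_loss(p$pred, p$ref, w))),
               tolerance = 1e-12)
  expect_equal(total_loss(rev(prs), w), tl, tolerance = 1e-12)
  expect_equal(total_loss(prs[2], w), composite_loss(prs[[2]]$pred, prs[[2]]$ref, w))
  # identity across sources
  idp <- lapply(prs, function(p) list(pred = p$pred, ref = p$pred))
  expect_equal(total_loss(idp, w), 0)
  expect_error(total_loss(list(), w), "at least one")
  # hand-built constant offsets: 3 sources with offsets 0.1/0.2/0.3
  cst <- lapply(c(0.1, 0.2, 0.3), function(d)
    list(pred = matrix(0.5, 8, 8), ref = matrix(0.5 - d, 8, 8)))
  expect_equal(total_loss(cst, w), 0.6, tolerance = 1e-12)
})

test_that("PSNR and RMSE are consistent: PSNR = 20 log10(max/RMSE)", {
  set.seed(17)
  for (i in 1:5) {
    a <- matrix(runif(100), 10)
    b <- matrix(runif(100), 10)
    expect_equal(psnr(a, b), 20 * log10(1 / rmse(a, b)), tolerance = 1e-10)
  }
})

test_that("metrics reports aggregate as mean and sample SD per source", {
  pi_df <- data.frame(source_id = c("A", "A", "B"), psnr = c(30, 40, 35),
                      ssim = c(0.9, 0.8, 0.85), rmse = c(0.03, 0.01, 0.02))
  rep <- metrics_report(pi_df)
  a <- rep$summary[rep$summary$source_id == "A", ]
  expect_equal(a$psnr_mean, 35)
  expect_equal(a$psnr_sd, sd(c(30, 40)))  # n-1 denominator, ~7.0711
  expect_equal(a$psnr_sd, 7.0711, tolerance = 1e-4)
  expect_equal(nrow(rep$summary), 2)
  tmp <- tempfile()
  write_metrics(rep, tmp)
  expect_true(file.exists(paste0(tmp, ".tsv")))
  js <- jsonlite::read_json(paste0(tmp, ".json"))
  expect_length(js, 2)
})
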