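# Architecture contracts: residual identities, module shapes, attention,
# source coupling, ablation switches, backbone variant, parameter counts.

test_that("zero-initialised blocks collapse to the identity", {
  set.seed(31)
  x <- random_batch(8, 2, seed = 31)
  x4 <- array(rep(x, 3), c(8, 8, 3, 2))
  # residual block at equal channels
  rb0 <- residual_block_params(3, 3, zero_init = TRUE)
  expect_identical(residual_block(x4, rb0), x4)
  # FTM: trunk is zero, so gated branch is exactly zero and input passes
  f0 <- ftm_params(3, zero_init = TRUE)
  expect_identical(ftm(x4, f0), x4)
  # SEKG with theta forced to zero is the shortcut alone
  expect_identical(sekg_attention(x4, theta = array(0, c(8, 8, 27, 2))), x4)
  # zero input maps to zero through a zero-bias network
  cfg <- tiny_config(1)
  m0 <- mdftn_init(cfg, zero_init = TRUE)
  z <- array(0, c(16, 16, 1, 1))
  out <- mdftn_forward(m0, list(z))
  expect_identical(out[[1]], z)
})

test_that("residual block and FTM obey their shape and channel contracts", {
  x <- random_batch(20, 1, seed = 32)
  x64 <- array(rep(x, 4), c(20, 20, 4, 1))
  rb <- residual_block_params(4, 8, rng_seed = 1)
  y <- residual_block(x64, rb)
  expect_equal(dim(y), c(20, 20, 8, 1))
  expect_error(residual_block(x, rb), "channels")
  fp <- ftm_params(4, rng_seed = 2)
  expect_equal(dim(ftm(x64, fp)), c(20, 20, 4, 1))
  expect_error(ftm(y, fp), "channels")
})

test_that("FTM matches a step-by-step hand evaluation of its dataflow", {
  # 2-channel 2x2 toy with hand-set kernels, traced through
  # conv-PReLU-conv-PReLU, the pooled sigmoid gate, and the residual add
  fp <- ftm_params(2, zero_init = TRUE)
  fp[["ftm.conv1.W"]][2, 2, , ] <- diag(2)        # centre-tap identity conv
  fp[["ftm.conv1.b"]] <- c(0.1, -0.2)
  fp[["ftm.conv2.W"]][2, 2, , ] <- matrix(c(1, 1, 0, 1), 2)  # channel mix
  fp[["ftm.se1.W"]][1, 1, , ] <- diag(2)
  fp[["ftm.se2.W"]][1, 1, , ] <- diag(2) * 2
  x <- array(c(0.2, -0.4, 0.6, 0.1, -0.3, 0.5, 0.0, 0.25), c(2, 2, 2, 1))
  a <- 0.25
  pr <- function(v) ifelse(v > 0, v, a * v)
  h1 <- x
  h1[, , 1, 1] <- x[, , 1, 1] + 0.1
  h1[, , 2, 1] <- x[, , 2, 1] - 0.2
  h1 <- pr(h1)
  h2 <- h1
  h2[, , 1, 1] <- h1[, , 1, 1] + h1[, , 2, 1]   # mix rows of the 2x2 matrix
  h2[, , 2, 1] <- h1[, , 2, 1]
  fcp <- pr(h2)
  gate <- 1 / (1 + exp(-2 * pr(apply(fcp, 3, mean))))
  expected <- fcp
  expected[, , 1, 1] <- fcp[, , 1, 1] * gate[1]
  expected[, , 2, 1] <- fcp[, , 2, 1] * gate[2]
  expected <- expected + x
  expect_equal(ftm(x, fp), expected, tolerance = 1e-12)
})

test_that("SEKG aggregates 3x3 neighbourhoods under explicit weights", {
  set.seed(33)
  x <- array(runif(6 * 6 * 2), c(6, 6, 2, 1))
  # theta == 1 adds the full 3x3 box sum (zero padded) to the shortcut
  th1 <- array(1, c(6, 6, 18, 1))
  got <- sekg_attention(x, theta = th1)
  box <- x
  for (cc in 1:2)
    for (i in 1:6) for (j in 1:6) {
      acc <- 0
      for (di in -1:1) for (dj in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii >= 1 && ii <= 6 && jj >= 1 && jj <= 6) acc <- acc + x[ii, jj, cc, 1]
      }
      box[i, j, cc, 1] <- acc
    }
  expect_equal(got, x + box, tolerance = 1e-12)
  # generated theta preserves shape for arbitrary channel counts
  for (c in c(1, 3, 5)) {
    xc <- array(runif(8 * 8 * c), c(8, 8, c, 1))
    sp <- sekg_params(c, rng_seed = c)
    expect_equal(dim(sekg_attention(xc, sp)), c(8, 8, c, 1))
  }
})

test_that("encoder produces the contracted bottleneck and skip shapes", {
  cfg <- tiny_config(1)
  m <- mdftn_init(cfg, rng_seed = 5)
  e <- encode(m, random_batch(32, 2, seed = 35))
  expect_equal(dim(e$bottleneck), c(8, 8, cfg$bottleneck_channels, 2))
  expect_equal(dim(e$skips[[1]]), c(32, 32, cfg$base_channels, 2))
  expect_equal(dim(e$skips[[2]]), c(16, 16, 2 * cfg$base_channels, 2))
  expect_error(encode(m, array(0, c(30, 30, 1, 1))), "divisible by 4")
  expect_error(mdftn_forward(m, list(array(0, c(16, 20, 1, 1)))), "square")
})

test_that("dftm fuses sources and honours the no-FTM ablation", {
  set.seed(36)
  fs <- lapply(1:3, function(k) array(runif(5 * 5 * 4), c(5, 5, 4, 1)))
  dp <- dftm_params(3, 4, n_ftm = 2, rng_seed = 6)
  expect_equal(dim(dftm(fs, dp)), c(5, 5, 4, 1))
  # no-FTM: output is exactly the compression convolution
  dp0 <- dftm_params(3, 4, n_ftm = 2, use_ftm = FALSE, rng_seed = 6)
  manual <- mdftn:::cpp_conv2d_fw(
    array(c(fs[[1]], fs[[2]], fs[[3]]), c(5, 5, 12, 1)),
    dp0[["dftm.compress.W"]], dp0[["dftm.compress.b"]], 1L, 1L)
  expect_equal(dftm(fs, dp0), manual, tolerance = 1e-12)
  expect_error(dftm(fs[1:2], dp), "expected 3")
  fs_bad <- fs
  fs_bad[[2]] <- array(0, c(4, 4, 4, 1))
  expect_error(dftm(fs_bad, dp), "spatial size")
})

test_that("gradients couple every encoder through the shared bottleneck", {
  cfg <- tiny_config(3)
  m <- mdftn_init(cfg, rng_seed = 7, zero_head = FALSE)
  xs <- lapply(1:3, function(k) random_batch(16, 1, seed = 40 + k))
  fw <- mdftn:::model_forward_tape(m, xs)
  # loss on source 1's output only
  g1 <- array(1, dim(mdftn:::tp_value(fw$tape, fw$outputs[1])))
  m$grad <- list()
  mdftn:::tp_backward(fw$tape, fw$outputs[1], list(g1))
  for (k in 1:3) {
    gnorm <- sum(abs(m$grad[[sprintf("enc%d.stem.W", k)]]))
    expect_gt(gnorm, 0)
  }
  # decoders of other sources receive no gradient from source 1's loss
  expect_null(m$grad[["dec2.out.W"]])
  expect_null(m$grad[["dec3.out.W"]])
})

test_that("permuting sources with matching weights permutes the outputs", {
  cfg <- tiny_config(2)
  m <- mdftn_init(cfg, rng_seed = 8)
  # make branch parameters identical so the architecture is symmetric up to
  # the concatenation order inside the DFTM compression convolution
  for (nm in grep("^enc1|^dec1", names(m$par), value = TRUE)) {
    other <- sub("^(enc|dec)1", "\\12", nm)
    m$par[[other]] <- m$par[[nm]]
  }
  W <- m$par[["dftm.compress.W"]]
  cbn <- cfg$bottleneck_channels
  W[, , seq_len(cbn) + cbn, ] <- W[, , seq_len(cbn), ]  # symmetric fusion
  m$par[["dftm.compress.W"]] <- W
  xs <- list(random_batch(16, 1, seed = 51), random_batch(16, 1, seed = 52))
  o12 <- mdftn_forward(m, xs)
  o21 <- mdftn_forward(m, rev(xs))
  expect_equal(o21[[1]], o12[[2]], tolerance = 1e-10)
  expect_equal(o21[[2]], o12[[1]], tolerance = 1e-10)
})

test_that("ablation flags add or remove exactly the declared parameter blocks", {
  full <- mdftn_init(mdftn_config(n_sources = 2, base_channels = 8), rng_seed = 1)
  noftm <- mdftn_init(mdftn_config(n_sources = 2, base_channels = 8,
                                   use_ftm = FALSE), rng_seed = 1)
  nosekg <- mdftn_init(mdftn_config(n_sources = 2, base_channels = 8,
                                    use_sekg = FALSE), rng_seed = 1)
  d1 <- setdiff(names(full$par), names(noftm$par))
  expect_true(all(grepl("^dftm\\.ftm", d1)))
  expect_setequal(unique(sub("\\..*$", "", sub("^dftm\\.", "", d1))),
                  paste0("ftm", 1:4))
  expect_length(setdiff(names(noftm$par), names(full$par)), 0)
  d2 <- setdiff(names(full$par), names(nosekg$par))
  expect_true(all(grepl("^dec[12]\\.sekg[12]\\.", d2)))
  expect_length(setdiff(names(nosekg$par), names(full$par)), 0)
  expect_lt(count_parameters(noftm), count_parameters(full))
  expect_lt(count_parameters(nosekg), count_parameters(full))
})

test_that("parameter counts compose per branch and ignore input size", {
  cfg1 <- mdftn_config(n_sources = 1, base_channels = 8)
  cfg2 <- mdftn_config(n_sources = 2, base_channels = 8)
  m1 <- mdftn_init(cfg1, rng_seed = 1)
  m2 <- mdftn_init(cfg2, rng_seed = 1)
  b1 <- attr(count_parameters(m1), "by_component")
  b2 <- attr(count_parameters(m2), "by_component")
  # one more encoder + one more decoder of identical size
  expect_equal(b2[["encoders"]], 2 * b1[["encoders"]])
  expect_equal(b2[["decoders"]], 2 * b1[["decoders"]])
  # the DFTM grows only through the compression convolution input channels
  cbn <- cfg1$bottleneck_channels
  expect_equal(b2[["bottleneck"]] - b1[["bottleneck"]], 9 * cbn * cbn)
  # counts are a property of the weights, not of any input
  expect_identical(count_parameters(m1), count_parameters(m1))
})

test_that("the RED-CNN backbone swaps in under the same framework contract", {
  cfg <- mdftn_config(n_sources = 3, backbone = "red-cnn", red_channels = 16,
                      bottleneck_channels = 16, n_ftm = 2)
  m <- mdftn_init(cfg, rng_seed = 9)
  xs <- lapply(1:3, function(k) random_batch(24, 2, seed = 60 + k))
  outs <- mdftn_forward(m, xs)
  expect_length(outs, 3)
  for (o in outs) expect_equal(dim(o), c(24, 24, 1, 2))
  # distinct architecture from the default backbone
  mu <- mdftn_init(mdftn_config(n_sources = 3, base_channels = 16), rng_seed = 9)
  expect_false(count_parameters(m) == count_parameters(mu))
  # end-to-end smoke step: finite loss and populated gradients
  bt <- lapply(xs, function(x) list(ldct = x, ndct = x * 0.9))
  r <- joint_train_step(m, bt, NULL, lr = 1e-4, weights = loss_weights(1, 0))
  expect_true(is.finite(r$loss))
  expect_true(all(vapply(m$grad, function(g) all(is.finite(g)), logical(1))))
  expect_setequal(names(m$grad), names(m$par))
  expect_error(mdftn_config(backbone = "resnet"), "'arg'")
})

test_that("forward pass validates batch structure", {
  m <- mdftn_init(tiny_config(2), rng_seed = 1)
  expect_error(mdftn_forward(m, list(random_batch(16, 1))), "expected 2")
  expect_error(mdftn_forward(m, list(random_batch(16, 1), random_batch(32, 1))),
               "one shape")
})
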