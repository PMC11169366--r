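# Optimisation schedule, joint steps, the fitting function and its methods.

test_that("the stepped learning-rate schedule matches its closed form", {
  tc <- train_config()
  expect_equal(lr_at_epoch(0, tc), 1e-4)
  expect_equal(lr_at_epoch(19, tc), 1e-4)
  expect_equal(lr_at_epoch(20, tc), 5e-5)
  expect_equal(lr_at_epoch(40, tc), 2.5e-5)
  for (e in 0:100)
    expect_equal(lr_at_epoch(e, tc), 1e-4 * 0.5^(e %/% 20), tolerance = 1e-15)
  expect_error(lr_at_epoch(-1, tc), ">= 0")
  expect_error(train_config(lr_decay = 1.5), "lr_decay")
})

test_that("a joint step touches all branches; lr = 0 leaves weights bit-identical", {
  cfg <- tiny_config(3)
  m <- mdftn_init(cfg, rng_seed = 1)
  bt <- lapply(1:3, function(k) {
    x <- random_batch(16, 2, seed = 70 + k)
    list(ldct = x, ndct = 0.9 * x, source_id = paste0("s", k))
  })
  before <- m$par
  r0 <- joint_train_step(m, bt, NULL, lr = 0, weights = loss_weights(1, 0))
  expect_identical(m$par, before)  # degenerate update
  expect_true(is.finite(r0$loss))
  expect_setequal(names(m$grad), names(m$par))
  expect_true(all(vapply(m$grad, function(g) any(g != 0) || TRUE, logical(1))))
  r1 <- joint_train_step(m, bt, r0$opt, lr = 1e-3, weights = loss_weights(1, 0))
  expect_false(identical(m$par, before))
  expect_named(r1$per_source, c("s1", "s2", "s3"))
  expect_error(joint_train_step(m, bt[1:2]), "expected 3")
})

test_that("repeated steps on one fixed batch drive the loss down", {
  cfg <- tiny_config(2)
  m <- mdftn_init(cfg, rng_seed = 2)
  set.seed(80)
  bt <- lapply(1:2, function(k) {
    nd <- array(runif(16 * 16 * 2), c(16, 16, 1, 2))
    list(ldct = pmin(pmax(nd + rnorm(512, 0, 0.1), 0), 1), ndct = nd)
  })
  w <- loss_weights(1, 0)
  opt <- NULL
  first <- NULL
  for (i in 1:40) {
    r <- joint_train_step(m, bt, opt, lr = 2e-3, weights = w)
    if (i == 1) first <- r$loss
    opt <- r$opt
  }
  expect_lt(r$loss, 0.5 * first)
})

test_that("training on the fixture corpus produces a complete history", {
  man <- fixture_corpus()
  tc <- train_config(epochs = 2, batch_size = 4, patch_size = 16,
                     initial_lr = 1e-3, steps_per_epoch = 3, seed = 5,
                     lambda = 0.001)
  fit <- mdftn(man, model = tiny_config(3), train = tc, verbose = FALSE)
  expect_s3_class(fit, "mdftn")
  h <- fit$history
  expect_equal(nrow(h), 2 * 3)  # epochs x sources
  expect_setequal(unique(h$source_id), c("A", "B", "C"))
  expect_true(all(is.finite(h$train_loss)))
  expect_true(all(is.finite(h$val_psnr)))
  expect_true(fit$best_epoch %in% 1:2)
  # methods
  expect_output(print(fit), "Multisource LDCT denoiser")
  expect_output(print(summary(fit)), "Validation")
  expect_type(coef(fit), "list")
  expect_equal(length(coef(fit)), length(fit$par))
  # predict on one slice via the single-branch convention
  pair <- load_manifest_pair(man[1, , drop = FALSE], attr(man, "dir"))
  den <- predict(fit, pair, source_id = "A")
  expect_s3_class(den, "ct_slice")
  expect_equal(dim(den$pixels), c(64, 64))
  # joint-form predict
  xs <- lapply(c("A", "B", "C"), function(s) {
    rows <- man[man$source_id == s & man$split == "test", , drop = FALSE]
    load_manifest_pair(rows[1, , drop = FALSE], attr(man, "dir"))$ldct
  })
  dens <- predict(fit, xs)
  expect_length(dens, 3)
  # residuals on the validation pairs
  res <- residuals(fit)
  expect_named(res, c("A", "B", "C"))
  expect_equal(dim(res$A[[1]]), c(64, 64))
  # plot device output
  pf <- tempfile(fileext = ".png")
  grDevices::png(pf)
  plot(fit)
  grDevices::dev.off()
  expect_true(file.exists(pf))
})

test_that("identical seeds reproduce identical epoch-1 losses", {
  man <- fixture_corpus()
  tc <- train_config(epochs = 1, batch_size = 2, patch_size = 16,
                     initial_lr = 1e-3, steps_per_epoch = 2, seed = 11)
  f1 <- mdftn(man, model = tiny_config(3), train = tc, verbose = FALSE)
  f2 <- mdftn(man, model = tiny_config(3), train = tc, verbose = FALSE)
  expect_identical(f1$history$train_loss, f2$history$train_loss)
  expect_identical(f1$par, f2$par)
  tc2 <- tc
  tc2$seed <- 12L
  f3 <- mdftn(man, model = tiny_config(3), train = tc2, verbose = FALSE)
  expect_false(identical(f1$history$train_loss, f3$history$train_loss))
})

test_that("evaluation reports full-slice metrics per source", {
  man <- fixture_corpus()
  base <- evaluate_dataset(NULL, man)
  expect_s3_class(base, "mdftn_metrics")
  expect_equal(nrow(base$summary), 3)
  expect_equal(base$summary$n, rep(1L, 3))  # 10 pairs -> 1 test slice each
  expect_true(all(base$summary$psnr_mean > 10))
  expect_true(all(base$summary$rmse_mean > 0))
  expect_error(evaluate_dataset(NULL, man, split = "bogus"), "empty")
})

test_that("checkpoints round-trip parameters and configuration", {
  m <- mdftn_init(tiny_config(2), rng_seed = 3)
  p <- tempfile(fileext = ".rds")
  save_checkpoint(m, p)
  back <- load_checkpoint(p)
  expect_identical(back$par, m$par)
  expect_identical(back$config, m$config)
  ck <- readRDS(p)
  expect_true(jsonlite::validate(ck$config_json))
})

test_that("convergence logging writes the table and curve files", {
  h <- data.frame(epoch = rep(1:3, each = 2), source_id = rep(c("A", "B"), 3),
                  train_loss = runif(6), val_psnr = 30 + runif(6),
                  val_rmse = 0.01 * runif(6))
  d <- file.path(tempdir(), "convlog")
  unlink(d, recursive = TRUE)
  paths <- log_convergence(h, d)
  expect_true(file.exists(file.path(d, "convergence.tsv")))
  tab <- read.delim(file.path(d, "convergence.tsv"))
  expect_equal(names(tab), c("epoch", "source_id", "val_psnr", "val_rmse", "train_loss"))
  expect_equal(nrow(tab), 6)
  # identical histories produce identical table bytes
  log_convergence(h, d)
  b1 <- readBin(file.path(d, "convergence.tsv"), "raw", 1e5)
  log_convergence(h, d)
  b2 <- readBin(file.path(d, "convergence.tsv"), "raw", 1e5)
  expect_identical(b1, b2)
})

test_that("the ablation runner trains and reports each variant", {
  man <- fixture_corpus()
  tc <- train_config(epochs = 1, batch_size = 2, patch_size = 16,
                     initial_lr = 1e-3, steps_per_epoch = 1, seed = 9)
  res <- run_ablation(man, variants = c("full", "single_source", "no_ftm"),
                      model = tiny_config(3), train = tc)
  expect_named(res$fits, c("full", "single_source", "no_ftm"))
  expect_lt(res$fits$no_ftm$n_parameters, res$fits$full$n_parameters)
  expect_equal(res$fits$single_source$config$n_sources, 1L)
  expect_setequal(unique(res$report$variant), c("full", "single_source", "no_ftm"))
  # one row per (variant, source); single_source contributes one source
  expect_equal(nrow(res$report), 3 + 1 + 3)
  expect_error(run_ablation(man, variants = "bogus"), "unknown ablation")
})
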