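# Joint collaborative training across sources: Adam, the stepped
# learning-rate schedule, patch-based joint steps, per-epoch validation on
# full slices, checkpoint selection, convergence logging, and the ablation
# runner. The user-facing fitting function is mdftn().

#' Training configuration
#'
#' Defaults are the full-scale study protocol: Adam at 1e-4 halved every 20
#' epochs, minibatch 16 of 80 x 80 patches per source, 100 epochs,
#' L1 weight 1 and SSIM weight 0.001.
#'
#' @param epochs Number of epochs.
#' @param batch_size Patches per source per joint step.
#' @param patch_size Side length of the random training crops.
#' @param initial_lr Initial Adam learning rate.
#' @param lr_decay Multiplicative decay factor, in (0, 1].
#' @param lr_period Epochs between decays.
#' @param alpha,lambda Composite-loss weights (see [loss_weights()]).
#' @param seed Master seed covering weight init, crop positions and data
#'   order.
#' @param steps_per_epoch Joint steps per epoch; default
#'   `ceiling(pairs_per_source / batch_size)`.
#' @return Object of class `train_config`.
#' @export
train_config <- function(epochs = 100L, batch_size = 16L, patch_size = 80L,
                         initial_lr = 1e-4, lr_decay = 0.5, lr_period = 20L,
                         alpha = 1, lambda = 0.001, seed = 1L,
                         steps_per_epoch = NULL) {
  if (epochs < 1L || batch_size < 1L || patch_size < 1L)
    stop("epochs, batch_size and patch_size must be positive")
  if (initial_lr < 0) stop("initial_lr must be nonnegative")
  if (lr_decay <= 0 || lr_decay > 1) stop("lr_decay must be in (0, 1]")
  if (lr_period < 1L) stop("lr_period must be positive")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 patch_size = as.integer(patch_size), initial_lr = initial_lr,
                 lr_decay = lr_decay, lr_period = as.integer(lr_period),
                 alpha = alpha, lambda = lambda, seed = as.integer(seed),
                 steps_per_epoch = if (is.null(steps_per_epoch)) NULL
                                   else as.integer(steps_per_epoch)),
            class = "train_config")
}

#' Learning rate at a given epoch
#'
#' Stepped schedule `initial_lr * lr_decay^floor(e / lr_period)` with
#' 0-based epochs: the rate halves every `lr_period` epochs under the
#' defaults.
#'
#' @param e Epoch index (0-based).
#' @param config A [train_config()].
#' @return The learning rate.
#' @export
lr_at_epoch <- function(e, config = train_config()) {
  if (any(e < 0)) stop("epoch must be >= 0")
  config$initial_lr * config$lr_decay^(e %/% config$lr_period)
}

# predictions are reported on the clipped [0,1] intensity scale, matching
# the package-wide HU clipping convention
clip01 <- function(x) pmin(pmax(x, 0), 1)

adam_new <- function(model) {
  st <- new.env(parent = emptyenv())
  st$m <- lapply(model$par, function(p) p * 0)
  st$v <- lapply(model$par, function(p) p * 0)
  st$t <- 0L
  st
}

adam_step <- function(model, opt, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(model$par)) {
    g <- model$grad[[nm]]
    if (is.null(g)) next
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    model$par[[nm]] <- model$par[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  invisible(opt)
}

#' One joint collaborative training step
#'
#' A single forward pass through all encoders, the shared DFTM and all
#' decoders, one summed multisource loss, one backward pass, and one Adam
#' update touching every parameter simultaneously — the mechanism that
#' couples the branches through the shared bottleneck.
#'
#' @param model An `mdftn_model` (updated in place).
#' @param batches List with one element per source, each holding aligned
#'   `ldct` and `ndct` arrays `(p, p, 1, n)` on the \eqn{[0,1]} scale.
#' @param opt Adam state from a previous call, or `NULL` to create one.
#' @param lr Learning rate for this step.
#' @param weights [loss_weights()].
#' @return List `loss` (total), `per_source` (named numeric), `opt` (state).
#' @export
joint_train_step <- function(model, batches, opt = NULL, lr = 1e-4,
                             weights = loss_weights()) {
  stopifnot(inherits(model, "mdftn_model"))
  if (length(batches) != model$config$n_sources)
    stop(sprintf("expected %d source batches, got %d",
                 model$config$n_sources, length(batches)))
  if (is.null(opt)) opt <- adam_new(model)
  fw <- model_forward_tape(model, lapply(batches, `[[`, "ldct"))
  per <- numeric(length(batches))
  seeds <- vector("list", length(batches))
  for (k in seq_along(batches)) {
    cl <- composite_loss(tp_value(fw$tape, fw$outputs[k]),
                         as_batch4(batches[[k]]$ndct), weights, grad = TRUE)
    per[k] <- cl$value
    seeds[[k]] <- cl$grad
  }
  model$grad <- list()
  tp_backward(fw$tape, fw$outputs, seeds)
  if (lr > 0) adam_step(model, opt, lr)
  names(per) <- vapply(seq_along(batches), function(k) {
    sid <- batches[[k]]$source_id
    if (is.null(sid)) sprintf("source%d", k) else as.character(sid)
  }, character(1))
  list(loss = sum(per), per_source = per, opt = opt)
}

# Load the pairs of one split, normalised, grouped by source.
load_split <- function(manifest, split, dir) {
  rows <- manifest[manifest$split == split, , drop = FALSE]
  sources <- unique(manifest$source_id)
  out <- lapply(sources, function(s) {
    rs <- rows[rows$source_id == s, , drop = FALSE]
    lapply(seq_len(nrow(rs)), function(i) {
      p <- load_manifest_pair(rs[i, , drop = FALSE], dir)
      list(ldct = hu_to_normalized(p$ldct), ndct = hu_to_normalized(p$ndct))
    })
  })
  names(out) <- sources
  out
}

draw_patch_batch <- function(pairs, patch_size, batch_size) {
  lp <- array(0, c(patch_size, patch_size, 1L, batch_size))
  np <- array(0, c(patch_size, patch_size, 1L, batch_size))
  d <- dim(pairs[[1L]]$ldct)
  for (b in seq_len(batch_size)) {
    pr <- pairs[[sample.int(length(pairs), 1L)]]
    i0 <- sample.int(d[1] - patch_size + 1L, 1L) - 1L
    j0 <- sample.int(d[2] - patch_size + 1L, 1L) - 1L
    lp[, , 1L, b] <- pr$ldct[i0 + seq_len(patch_size), j0 + seq_len(patch_size)]
    np[, , 1L, b] <- pr$ndct[i0 + seq_len(patch_size), j0 + seq_len(patch_size)]
  }
  list(ldct = lp, ndct = np)
}

stack_pairs <- function(pairs, what, idx = seq_along(pairs)) {
  d <- dim(pairs[[1L]][[what]])
  a <- array(0, c(d[1], d[2], 1L, length(idx)))
  for (k in seq_along(idx)) a[, , 1L, k] <- pairs[[idx[k]]][[what]]
  a
}

validate_model <- function(model, val) {
  ns <- length(val)
  nmin <- min(vapply(val, length, integer(1)))
  preds <- vector("list", ns)
  chunk <- 4L
  for (start in seq(1L, nmin, by = chunk)) {
    idx <- start:min(start + chunk - 1L, nmin)
    xs <- lapply(val, stack_pairs, what = "ldct", idx = idx)
    outs <- mdftn_forward(model, xs)
    for (k in seq_len(ns))
      preds[[k]] <- c(preds[[k]], lapply(seq_along(idx), function(b)
        clip01(outs[[k]][, , 1L, b])))
  }
  res <- data.frame(source_id = names(val),
                    val_psnr = NA_real_, val_rmse = NA_real_)
  for (k in seq_len(ns)) {
    ps <- vapply(seq_len(nmin), function(i)
      psnr(val[[k]][[i]]$ndct, preds[[k]][[i]]), numeric(1))
    rs <- vapply(seq_len(nmin), function(i)
      rmse(val[[k]][[i]]$ndct, preds[[k]][[i]]), numeric(1))
    res$val_psnr[k] <- mean(ps)
    res$val_rmse[k] <- mean(rs)
  }
  res
}

#' Fit an MDFTN denoiser by joint collaborative training
#'
#' The main fitting function. Loads the training and validation pairs from
#' a corpus manifest, initialises the network, and runs patch-based joint
#' optimisation: every step draws one random aligned patch batch per
#' source, takes a single forward pass through all branches and the shared
#' bottleneck, and applies one Adam update to all parameters from the
#' summed multisource loss. Validation PSNR/RMSE on full slices is recorded
#' every epoch; the parameters with the best mean validation PSNR are kept
#' as the fitted coefficients.
#'
#' @param manifest A corpus manifest data frame (from [read_manifest()] or
#'   [build_multisource_corpus()]) or the path to a `manifest.tsv`.
#' @param model An [mdftn_config()]; its `n_sources` must match the
#'   manifest (it is adjusted automatically when left at the default).
#' @param train A [train_config()].
#' @param data_dir Base directory for manifest paths (defaults to the
#'   manifest's own directory).
#' @param verbose Print one line per epoch.
#' @return An object of class `mdftn`: a list with the fitted parameter set
#'   (`par`, best epoch), `last_par`, `config`, `train`, `history` (one row
#'   per epoch and source: training loss, validation PSNR/RMSE),
#'   `best_epoch`, `sources`, and the validation pairs (`val`, normalised)
#'   used for `residuals()`.
#' @seealso [predict.mdftn()], [evaluate_dataset()], [run_ablation()]
#' @export
mdftn <- function(manifest, model = mdftn_config(), train = train_config(),
                  data_dir = NULL, verbose = interactive()) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  if (is.null(data_dir)) data_dir <- attr(manifest, "dir")
  if (is.null(data_dir)) data_dir <- "."
  sources <- unique(manifest$source_id)
  if (model$n_sources != length(sources)) {
    model$n_sources <- length(sources)
  }
  tr <- load_split(manifest, "train", data_dir)
  val <- load_split(manifest, "val", data_dir)
  if (any(vapply(tr, length, integer(1)) == 0L))
    stop("every source needs at least one training pair")
  if (any(vapply(val, length, integer(1)) == 0L))
    stop("every source needs at least one validation pair")
  n_train <- min(vapply(tr, length, integer(1)))
  steps <- if (is.null(train$steps_per_epoch))
    as.integer(ceiling(n_train / train$batch_size)) else train$steps_per_epoch
  weights <- loss_weights(train$alpha, train$lambda)

  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  set.seed(train$seed)
  on.exit(restore_seed(old))
  net <- mdftn_init(model, rng_seed = train$seed + 1L)
  opt <- adam_new(net)
  history <- list()
  best <- list(psnr = -Inf, par = NULL, epoch = NA_integer_)
  for (ep in seq_len(train$epochs) - 1L) {
    lr <- lr_at_epoch(ep, train)
    ep_loss <- matrix(0, steps, length(sources))
    for (st in seq_len(steps)) {
      batches <- lapply(sources, function(s) {
        b <- draw_patch_batch(tr[[s]], train$patch_size, train$batch_size)
        b$source_id <- s
        b
      })
      r <- joint_train_step(net, batches, opt, lr, weights)
      ep_loss[st, ] <- r$per_source
    }
    vres <- validate_model(net, val)
    mean_psnr <- mean(vres$val_psnr)
    if (mean_psnr > best$psnr) {
      best$psnr <- mean_psnr
      best$par <- net$par
      best$epoch <- ep + 1L
    }
    history[[ep + 1L]] <- data.frame(
      epoch = ep + 1L, source_id = vres$source_id,
      train_loss = colMeans(ep_loss),
      val_psnr = vres$val_psnr, val_rmse = vres$val_rmse,
      stringsAsFactors = FALSE)
    if (verbose)
      message(sprintf("epoch %3d  lr %.2e  loss %.5f  val PSNR %.2f dB",
                      ep + 1L, lr, sum(colMeans(ep_loss)), mean_psnr))
  }
  history <- do.call(rbind, history)
  fit <- list(par = best$par, last_par = net$par, config = net$config,
              train = train, history = history, best_epoch = best$epoch,
              sources = sources, val = val, norm_range = hu_range(),
              n_parameters = as.integer(count_parameters(net)))
  class(fit) <- "mdftn"
  fit
}

fit_model_env <- function(object, which = c("best", "last")) {
  which <- match.arg(which)
  m <- new.env(parent = emptyenv())
  m$par <- if (which == "best") object$par else object$last_par
  m$grad <- list()
  m$config <- object$config
  class(m) <- "mdftn_model"
  m
}

#' @export
print.mdftn <- function(x, ...) {
  cat(sprintf("Multisource LDCT denoiser (MDFTN, %s backbone)\n", x$config$backbone))
  cat(sprintf("  sources: %s\n", paste(x$sources, collapse = ", ")))
  cat(sprintf("  parameters: %s  (base %d, bottleneck %d, FTMs %s, SEKG %s)\n",
              format(x$n_parameters, big.mark = ","), x$config$base_channels,
              x$config$bottleneck_channels,
              if (x$config$use_ftm) x$config$n_ftm else "off",
              if (x$config$use_sekg) "on" else "off"))
  cat(sprintf("  trained %d epoch(s); best validation at epoch %d\n",
              max(x$history$epoch), x$best_epoch))
  invisible(x)
}

#' @export
summary.mdftn <- function(object, ...) {
  h <- object$history
  last <- h[h$epoch == max(h$epoch), ]
  bst <- h[h$epoch == object$best_epoch, ]
  structure(list(fit = object, last = last, best = bst), class = "summary.mdftn")
}

#' @export
print.summary.mdftn <- function(x, ...) {
  print(x$fit)
  cat("\nValidation at the selected (best) epoch:\n")
  for (i in seq_len(nrow(x$best)))
    cat(sprintf("  %-10s PSNR %6.2f dB  RMSE %.5f\n", x$best$source_id[i],
                x$best$val_psnr[i], x$best$val_rmse[i]))
  invisible(x)
}

#' @export
coef.mdftn <- function(object, ...) object$par

#' Denoise new slices with a fitted model
#'
#' For a single slice (or one batch from one source) the image is routed
#' through every encoder branch simultaneously (the shared bottleneck then
#' sees consistent anatomy) and the requested source's decoder output is
#' returned; this is the single-branch inference convention for data from
#' one source. A list with one batch per source performs the native joint
#' forward pass instead.
#'
#' @param object A fitted `mdftn`.
#' @param newdata A `ct_slice`, an HU matrix, a `paired_slice` (its `ldct`
#'   is used), or a list with one such element per source.
#' @param source_id Source label or index selecting the encoder/decoder
#'   branch (single-input form only).
#' @param which Use the best-validation (`"best"`, default) or final
#'   (`"last"`) parameters.
#' @param ... Unused.
#' @return A denoised `ct_slice` (single input) or list of `ct_slice`
#'   (joint form).
#' @export
predict.mdftn <- function(object, newdata, source_id = 1L,
                          which = c("best", "last"), ...) {
  m <- fit_model_env(object, which)
  to_norm <- function(x) {
    if (inherits(x, "paired_slice")) x <- x$ldct
    if (inherits(x, "ct_slice")) x <- x$pixels
    hu_to_normalized(x)
  }
  if (is.list(newdata) && !inherits(newdata, c("ct_slice", "paired_slice"))) {
    xs <- lapply(newdata, to_norm)
    outs <- mdftn_forward(m, xs)
    return(lapply(seq_along(outs), function(k)
      ct_slice(normalized_to_hu(outs[[k]][, , 1L, 1L]),
               source_id = object$sources[k])))
  }
  if (is.character(source_id)) source_id <- match(source_id, object$sources)
  if (is.na(source_id) || source_id < 1L || source_id > object$config$n_sources)
    stop("unknown source_id")
  x <- to_norm(newdata)
  xs <- rep(list(x), object$config$n_sources)
  outs <- mdftn_forward(m, xs)
  ct_slice(normalized_to_hu(outs[[source_id]][, , 1L, 1L]),
           source_id = as.character(object$sources[source_id]))
}

#' @export
residuals.mdftn <- function(object, ...) {
  m <- fit_model_env(object, "best")
  lapply(stats::setNames(seq_along(object$val), names(object$val)), function(k) {
    pairs <- object$val[[k]]
    xs0 <- stack_pairs(pairs, "ldct")
    lapply(seq_along(pairs), function(i) {
      xs <- rep(list(xs0[, , , i, drop = FALSE]), object$config$n_sources)
      out <- clip01(mdftn_forward(m, xs)[[k]][, , 1L, 1L])
      out - pairs[[i]]$ndct
    })
  })
}

#' Plot training convergence
#'
#' Validation PSNR and RMSE versus epoch, one curve per source.
#'
#' @param x A fitted `mdftn`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.mdftn <- function(x, ...) {
  h <- x$history
  sources <- unique(h$source_id)
  ep <- sort(unique(h$epoch))
  pm <- sapply(sources, function(s) h$val_psnr[h$source_id == s])
  rm_ <- sapply(sources, function(s) h$val_rmse[h$source_id == s])
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::matplot(ep, pm, type = "b", pch = 1, lty = 1,
                    xlab = "epoch", ylab = "validation PSNR (dB)", ...)
  graphics::legend("bottomright", legend = sources, col = seq_along(sources),
                   lty = 1, bty = "n")
  graphics::matplot(ep, rm_, type = "b", pch = 1, lty = 1,
                    xlab = "epoch", ylab = "validation RMSE", ...)
  invisible(x)
}

#' Evaluate a fitted model (or the raw low-dose input) on a test split
#'
#' Computes per-image PSNR/SSIM/RMSE on full slices for every source and
#' aggregates them as mean and sample SD. With `object = NULL` the metrics
#' of the unprocessed low-dose input against the reference are reported
#' (the baseline the denoiser must beat).
#'
#' @param object A fitted `mdftn`, or `NULL` for the LDCT baseline.
#' @param manifest Corpus manifest (data frame or path).
#' @param split Which split to evaluate (default `"test"`).
#' @param data_dir Base directory for manifest paths.
#' @param which Parameter set to use (see [predict.mdftn()]).
#' @return An `mdftn_metrics` report.
#' @export
evaluate_dataset <- function(object, manifest, split = "test", data_dir = NULL,
                             which = "best") {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  if (is.null(data_dir)) data_dir <- attr(manifest, "dir")
  if (is.null(data_dir)) data_dir <- "."
  te <- load_split(manifest, split, data_dir)
  if (any(vapply(te, length, integer(1)) == 0L))
    stop(sprintf("empty '%s' split for at least one source", split))
  rows <- list()
  if (is.null(object)) {
    for (s in names(te))
      for (i in seq_along(te[[s]])) {
        p <- te[[s]][[i]]
        rows[[length(rows) + 1L]] <- data.frame(
          source_id = s, index = i, psnr = psnr(p$ndct, p$ldct),
          ssim = ssim(p$ndct, p$ldct), rmse = rmse(p$ndct, p$ldct),
          stringsAsFactors = FALSE)
      }
  } else {
    m <- fit_model_env(object, which)
    sources <- object$sources
    te <- te[as.character(sources)]
    nmin <- min(vapply(te, length, integer(1)))
    chunk <- 4L
    for (start in seq(1L, nmin, by = chunk)) {
      idx <- start:min(start + chunk - 1L, nmin)
      xs <- lapply(te, stack_pairs, what = "ldct", idx = idx)
      outs <- mdftn_forward(m, xs)
      for (k in seq_along(sources))
        for (b in seq_along(idx)) {
          pred <- clip01(outs[[k]][, , 1L, b])
          ref <- te[[k]][[idx[b]]]$ndct
          rows[[length(rows) + 1L]] <- data.frame(
            source_id = as.character(sources[k]), index = idx[b],
            psnr = psnr(ref, pred), ssim = ssim(ref, pred),
            rmse = rmse(ref, pred), stringsAsFactors = FALSE)
        }
    }
    # any leftover slices (unequal split sizes): single-branch convention
    for (k in seq_along(sources)) {
      nk <- length(te[[k]])
      if (nk > nmin)
        for (i in (nmin + 1L):nk) {
          x <- te[[k]][[i]]$ldct
          out <- clip01(mdftn_forward(m, rep(list(as_batch4(x)),
                                      object$config$n_sources))[[k]][, , 1L, 1L])
          rows[[length(rows) + 1L]] <- data.frame(
            source_id = as.character(sources[k]), index = i,
            psnr = psnr(te[[k]][[i]]$ndct, out),
            ssim = ssim(te[[k]][[i]]$ndct, out),
            rmse = rmse(te[[k]][[i]]$ndct, out), stringsAsFactors = FALSE)
        }
    }
  }
  metrics_report(do.call(rbind, rows))
}

#' Train and compare ablation variants
#'
#' Trains the requested variants under an identical budget and seed and
#' evaluates each on the test split: `full` (the complete network),
#' `single_source` (one encoder-bottleneck-decoder chain trained on one
#' source's data only), `no_ftm`, `no_sekg`, and `red_cnn_dftm` (RED-CNN
#' backbone inside the same collaborative framework).
#'
#' @param manifest Corpus manifest (data frame or path).
#' @param variants Character vector of variant names.
#' @param model Base [mdftn_config()].
#' @param train [train_config()] applied to every variant.
#' @param single_source Source (label or index) used by `single_source`.
#' @param data_dir Base directory for manifest paths.
#' @param verbose Passed to [mdftn()].
#' @return List with `fits` (named list of `mdftn` objects) and `report`
#'   (data frame: one row per variant x source with the metric summary).
#' @export
run_ablation <- function(manifest,
                         variants = c("full", "single_source", "no_ftm",
                                      "no_sekg", "red_cnn_dftm"),
                         model = mdftn_config(), train = train_config(),
                         single_source = 1L, data_dir = NULL,
                         verbose = FALSE) {
  known <- c("full", "single_source", "no_ftm", "no_sekg", "red_cnn_dftm")
  bad <- setdiff(variants, known)
  if (length(bad)) stop(sprintf("unknown ablation variant(s): %s",
                                paste(bad, collapse = ", ")))
  if (is.character(manifest) && length(manifest) == 1L && file.exists(manifest))
    manifest <- read_manifest(manifest)
  if (is.null(data_dir)) data_dir <- attr(manifest, "dir")
  sources <- unique(manifest$source_id)
  if (is.numeric(single_source)) single_source <- sources[single_source]
  fits <- list()
  rows <- list()
  for (v in variants) {
    cfg <- model
    mf <- manifest
    if (v == "no_ftm") cfg$use_ftm <- FALSE
    if (v == "no_sekg") cfg$use_sekg <- FALSE
    if (v == "red_cnn_dftm") cfg$backbone <- "red-cnn"
    if (v == "single_source") {
      mf <- manifest[manifest$source_id == single_source, , drop = FALSE]
      attr(mf, "dir") <- data_dir
      cfg$n_sources <- 1L
    }
    fit <- mdftn(mf, model = cfg, train = train, data_dir = data_dir,
                 verbose = verbose)
    fits[[v]] <- fit
    rep <- evaluate_dataset(fit, mf, data_dir = data_dir)
    s <- rep$summary
    s <- cbind(variant = v, s, stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- s
  }
  list(fits = fits, report = do.call(rbind, rows))
}

#' Write convergence curves and table
#'
#' Emits a tab-separated per-epoch table (`epoch`, `source_id`, `val_psnr`,
#' `val_rmse`, `train_loss`) and PSNR/RMSE-versus-epoch curve plots.
#'
#' @param history The `history` data frame of a fitted `mdftn` (or the fit
#'   itself).
#' @param out_dir Output directory.
#' @return Character vector of the written paths, invisibly.
#' @export
log_convergence <- function(history, out_dir) {
  if (inherits(history, "mdftn")) history <- history$history
  if (!nrow(history)) stop("empty training history")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tab <- history[, c("epoch", "source_id", "val_psnr", "val_rmse", "train_loss")]
  tpath <- file.path(out_dir, "convergence.tsv")
  utils::write.table(tab, tpath, sep = "\t", row.names = FALSE, quote = FALSE)
  sources <- unique(history$source_id)
  ep <- sort(unique(history$epoch))
  paths <- tpath
  for (metric in c("val_psnr", "val_rmse")) {
    ppath <- file.path(out_dir, paste0(metric, "_vs_epoch.png"))
    grDevices::png(ppath, width = 640, height = 480)
    mm <- sapply(sources, function(s) history[[metric]][history$source_id == s])
    graphics::matplot(ep, mm, type = "b", pch = 1, lty = 1, xlab = "epoch",
                      ylab = metric)
    graphics::legend("right", legend = sources, col = seq_along(sources),
                     lty = 1, bty = "n")
    grDevices::dev.off()
    paths <- c(paths, ppath)
  }
  invisible(paths)
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single RDS archive holding the parameter arrays plus
#' the full architecture configuration (also duplicated as a JSON string
#' for language-neutral inspection).
#'
#' @param object A fitted `mdftn` or an `mdftn_model`.
#' @param path Checkpoint file path.
#' @return `path` (save) / an `mdftn_model` (load).
#' @export
save_checkpoint <- function(object, path) {
  if (inherits(object, "mdftn")) {
    par <- object$par
    config <- object$config
  } else if (inherits(object, "mdftn_model")) {
    par <- object$par
    config <- object$config
  } else stop("object must be an mdftn fit or mdftn_model")
  saveRDS(list(par = par, config = config,
               config_json = jsonlite::toJSON(unclass(config), auto_unbox = TRUE)),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  m <- new.env(parent = emptyenv())
  m$par <- ck$par
  m$grad <- list()
  m$config <- ck$config
  class(m) <- "mdftn_model"
  m
}
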