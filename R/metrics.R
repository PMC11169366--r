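# Evaluation metrics (PSNR, SSIM, RMSE) and the composite L1 + SSIM training
# objective with its analytic gradient. All metrics operate on the [0, 1]
# normalised intensity scale with data_range = 1 unless stated otherwise.

as_batch4 <- function(x) {
  if (is.matrix(x)) array(x, c(nrow(x), ncol(x), 1L, 1L))
  else if (length(dim(x)) == 4L) x
  else stop("expected a matrix or a (h, w, c, n) array")
}

#' Gaussian SSIM window
#'
#' @param size Odd window side length (default 11).
#' @param sigma Gaussian standard deviation in pixels (default 1.5).
#' @return `size x size` matrix summing to 1.
#' @export
gaussian_window <- function(size = 11L, sigma = 1.5) {
  if (size %% 2L == 0L) stop("SSIM window size must be odd")
  r <- seq_len(size) - (size + 1) / 2
  g <- exp(-r^2 / (2 * sigma^2))
  w <- outer(g, g)
  w / sum(w)
}

#' SSIM parameters
#'
#' Stability constants follow the standard convention
#' \eqn{C_1 = (0.01 R)^2}, \eqn{C_2 = (0.03 R)^2} for data range \eqn{R}.
#'
#' @param window_size,sigma Gaussian window (see [gaussian_window()]).
#' @param data_range Dynamic range of the images (default 1).
#' @return List of class `ssim_params`.
#' @export
ssim_params <- function(window_size = 11L, sigma = 1.5, data_range = 1) {
  if (data_range <= 0) stop("data_range must be positive")
  structure(list(window_size = as.integer(window_size), sigma = sigma,
                 data_range = data_range,
                 C1 = (0.01 * data_range)^2, C2 = (0.03 * data_range)^2),
            class = "ssim_params")
}

conv_win <- function(x4, win, pad = 0L) {
  k <- nrow(win)
  cpp_conv2d_fw(x4, array(win, c(k, k, 1L, 1L)), 0, 1L, as.integer(pad))
}

ssim_fields <- function(x4, y4, params) {
  win <- gaussian_window(params$window_size, params$sigma)
  mux <- conv_win(x4, win)
  muy <- conv_win(y4, win)
  sxx <- conv_win(x4 * x4, win) - mux^2
  syy <- conv_win(y4 * y4, win) - muy^2
  sxy <- conv_win(x4 * y4, win) - mux * muy
  A1 <- 2 * mux * muy + params$C1
  A2 <- 2 * sxy + params$C2
  B1 <- mux^2 + muy^2 + params$C1
  B2 <- sxx + syy + params$C2
  list(S = (A1 * A2) / (B1 * B2), mux = mux, muy = muy,
       A1 = A1, A2 = A2, B1 = B1, B2 = B2, win = win)
}

#' Structural similarity index (mean SSIM)
#'
#' Mean local SSIM over a Gaussian window (11 taps, sigma 1.5 by default),
#' computed on the interior where the window fits entirely. Symmetric in its
#' arguments; equals 1 exactly for identical images.
#'
#' @param a,b Numeric matrices (or `(h, w, 1, n)` arrays) of equal shape.
#' @param params An [ssim_params()] object.
#' @return Scalar mean SSIM in \eqn{[-1, 1]}.
#' @export
ssim <- function(a, b, params = ssim_params()) {
  x4 <- as_batch4(a); y4 <- as_batch4(b)
  if (!identical(dim(x4), dim(y4))) stop("ssim: shape mismatch")
  if (min(dim(x4)[1:2]) < params$window_size)
    stop("image smaller than the SSIM window")
  mean(ssim_fields(x4, y4, params)$S)
}

# Gradient of (1 - mean local SSIM) with respect to x (the prediction).
# Derived by differentiating S = A1*A2/(B1*B2) through the windowed moments;
# the three field terms are transported back to pixel space by correlation
# with the (symmetric) window, implemented as a padded convolution.
ssim_loss_grad <- function(x4, y4, params) {
  f <- ssim_fields(x4, y4, params)
  BB <- f$B1 * f$B2
  c0 <- (2 * f$muy * f$A2 - 2 * f$A1 * f$muy) / BB -
    2 * f$S * f$mux / f$B1 + 2 * f$S * f$mux / f$B2
  cy <- 2 * f$A1 / BB
  cx <- -2 * f$S / f$B2
  k <- params$window_size
  pad <- k - 1L
  g0 <- conv_win(c0, f$win, pad)
  gy <- conv_win(cy, f$win, pad)
  gx <- conv_win(cx, f$win, pad)
  n_valid <- prod(dim(f$S))
  -(g0 + y4 * gy + x4 * gx) / n_valid
}

#' Mean absolute error (L1 loss)
#'
#' @param pred,ref Equal-shaped numeric arrays.
#' @return Mean absolute difference over all entries.
#' @export
l1_loss <- function(pred, ref) {
  if (!identical(dim(as_batch4(pred)), dim(as_batch4(ref))))
    stop("l1_loss: shape mismatch")
  mean(abs(pred - ref))
}

#' Loss weights for the composite objective
#'
#' Defaults are the study values: L1 weight `alpha = 1` and SSIM weight
#' `lambda = 0.001`.
#'
#' @param alpha Nonnegative L1 weight.
#' @param lambda Nonnegative SSIM weight.
#' @return List of class `loss_weights`.
#' @export
loss_weights <- function(alpha = 1, lambda = 0.001) {
  if (alpha < 0 || lambda < 0) stop("loss weights must be nonnegative")
  if (alpha + lambda <= 0) stop("at least one loss weight must be positive")
  structure(list(alpha = alpha, lambda = lambda), class = "loss_weights")
}

#' Composite per-source training loss
#'
#' \eqn{\alpha L_1(pred, ref) + \lambda (1 - SSIM(pred, ref))}. The SSIM
#' loss is taken as `1 - SSIM` so that the objective is nonnegative with its
#' global minimum 0 at pixelwise identity. With `lambda = 0` the SSIM term
#' (and its window-size requirement) is skipped entirely.
#'
#' @param pred,ref Prediction and reference stacks (matrices or
#'   `(h, w, 1, n)` arrays) on the \eqn{[0,1]} scale.
#' @param weights A [loss_weights()] object.
#' @param params SSIM parameters.
#' @param grad If `TRUE`, also return the gradient with respect to `pred`.
#' @return The scalar loss, or (with `grad = TRUE`) a list
#'   `list(value, grad)`.
#' @export
composite_loss <- function(pred, ref, weights = loss_weights(),
                           params = ssim_params(), grad = FALSE) {
  x4 <- as_batch4(pred); y4 <- as_batch4(ref)
  if (!identical(dim(x4), dim(y4))) stop("composite_loss: shape mismatch")
  val <- weights$alpha * mean(abs(x4 - y4))
  g <- NULL
  if (grad) g <- weights$alpha * sign(x4 - y4) / length(x4)
  if (weights$lambda > 0) {
    if (min(dim(x4)[1:2]) < params$window_size)
      stop("image smaller than the SSIM window")
    val <- val + weights$lambda * (1 - mean(ssim_fields(x4, y4, params)$S))
    if (grad) g <- g + weights$lambda * ssim_loss_grad(x4, y4, params)
  }
  if (grad) list(value = val, grad = g) else val
}

#' Joint multisource training loss
#'
#' Unweighted sum of the per-source composite losses; the collaborative
#' objective optimised by one joint backward pass.
#'
#' @param pairs List with one element per source, each a list with elements
#'   `pred` and `ref`.
#' @param weights A [loss_weights()] object.
#' @param params SSIM parameters.
#' @return Scalar total loss.
#' @export
total_loss <- function(pairs, weights = loss_weights(), params = ssim_params()) {
  if (length(pairs) < 1L) stop("total_loss requires at least one source")
  sum(vapply(pairs, function(p)
    composite_loss(p$pred, p$ref, weights, params), numeric(1)))
}

#' Root-mean-square error
#'
#' @param ref,pred Equal-shaped numeric arrays.
#' @return \eqn{\sqrt{MSE}} on the input scale.
#' @export
rmse <- function(ref, pred) {
  if (!identical(dim(as_batch4(ref)), dim(as_batch4(pred))))
    stop("rmse: shape mismatch")
  sqrt(mean((ref - pred)^2))
}

#' Peak signal-to-noise ratio
#'
#' \eqn{10 \log_{10}(max\_val^2 / MSE)} in decibels; identical inputs give
#' `Inf`.
#'
#' @param ref,pred Equal-shaped numeric arrays.
#' @param max_val Peak intensity of the scale (default 1).
#' @return PSNR in dB.
#' @export
psnr <- function(ref, pred, max_val = 1) {
  if (max_val <= 0) stop("max_val must be positive")
  if (!identical(dim(as_batch4(ref)), dim(as_batch4(pred))))
    stop("psnr: shape mismatch")
  mse <- mean((ref - pred)^2)
  if (mse == 0) Inf else 10 * log10(max_val^2 / mse)
}

#' Per-source metrics report
#'
#' Computes per-image PSNR/SSIM/RMSE for aligned prediction/reference slices
#' grouped by source and aggregates them as mean and sample standard
#' deviation (n - 1 denominator), the "mean +/- SD" convention.
#'
#' @param per_image Data frame with columns `source_id`, `psnr`, `ssim`,
#'   `rmse` (one row per image).
#' @return Object of class `mdftn_metrics`: `per_image` plus a `summary`
#'   data frame with columns `source_id`, `n`, `psnr_mean`, `psnr_sd`,
#'   `ssim_mean`, `ssim_sd`, `rmse_mean`, `rmse_sd`.
#' @export
metrics_report <- function(per_image) {
  stopifnot(all(c("source_id", "psnr", "ssim", "rmse") %in% names(per_image)))
  if (nrow(per_image) == 0L) stop("metrics_report: empty per-image table")
  sds <- function(v) if (length(v) > 1L) stats::sd(v) else NA_real_
  sp <- split(per_image, per_image$source_id)
  summary <- do.call(rbind, lapply(sp, function(d) data.frame(
    source_id = d$source_id[1], n = nrow(d),
    psnr_mean = mean(d$psnr), psnr_sd = sds(d$psnr),
    ssim_mean = mean(d$ssim), ssim_sd = sds(d$ssim),
    rmse_mean = mean(d$rmse), rmse_sd = sds(d$rmse),
    stringsAsFactors = FALSE)))
  rownames(summary) <- NULL
  structure(list(per_image = per_image, summary = summary),
            class = "mdftn_metrics")
}

#' @export
print.mdftn_metrics <- function(x, ...) {
  cat("Per-source image quality (mean +/- SD):\n")
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-10s n=%3d  PSNR %6.2f +/- %5.2f dB  SSIM %.4f +/- %.4f  RMSE %.4f +/- %.4f\n",
                s$source_id[i], s$n[i], s$psnr_mean[i], s$psnr_sd[i],
                s$ssim_mean[i], s$ssim_sd[i], s$rmse_mean[i], s$rmse_sd[i]))
  invisible(x)
}

#' Write a metrics report to disk
#'
#' Emits both a TSV table and a JSON file of the per-source summary.
#'
#' @param report An `mdftn_metrics` object.
#' @param path_prefix Output path prefix; `<prefix>.tsv` and `<prefix>.json`
#'   are written.
#' @return `path_prefix`, invisibly.
#' @export
write_metrics <- function(report, path_prefix) {
  stopifnot(inherits(report, "mdftn_metrics"))
  utils::write.table(report$summary, paste0(path_prefix, ".tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(report$summary, paste0(path_prefix, ".json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(path_prefix)
}
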