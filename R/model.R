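# The MDFTN architecture: one convolutional encoder and decoder per imaging
# source around a shared bottleneck (DFTM) that concatenates, compresses and
# refines all sources' deepest features. Includes the RED-CNN backbone
# variant and the ablation switches (no-FTM, no-SEKG, single source).

#' Architecture configuration
#'
#' @param n_sources Number of imaging sources (parallel encoder/decoder
#'   branches), >= 1.
#' @param base_channels Channel width of the first encoder stage; the
#'   progression is `base -> 2*base -> bottleneck`. Default 64 (the
#'   full-scale width); 16 gives the reduced configuration used for
#'   CPU-scale experiments.
#' @param bottleneck_channels Channels at the shared bottleneck; default
#'   `4 * base_channels` (256 at the default width).
#' @param n_ftm Number of stacked feature transformation modules in the
#'   shared bottleneck (default 4).
#' @param use_ftm If `FALSE`, the FTM chain is skipped (ablation): the
#'   shared feature is just the compression convolution output.
#' @param use_sekg If `FALSE`, decoder attention blocks are omitted
#'   (ablation); decoders become plain transposed-conv/residual stages.
#' @param backbone `"mdftn-unet"` (two avg-pool downsamplings, residual
#'   stages, skip concatenation) or `"red-cnn"` (five 5x5 convolutions and
#'   five transposed-side convolutions at full resolution with symmetric
#'   shortcuts, the DFTM kept at the deepest features).
#' @param in_channels Image channels (1 for CT slices).
#' @param sekg_kernel Attention kernel size (fixed at 3).
#' @param red_channels Filter count of the RED-CNN variant (default 96).
#' @return Object of class `mdftn_config`.
#' @export
mdftn_config <- function(n_sources = 3L, base_channels = 64L,
                         bottleneck_channels = 4L * base_channels,
                         n_ftm = 4L, use_ftm = TRUE, use_sekg = TRUE,
                         backbone = c("mdftn-unet", "red-cnn"),
                         in_channels = 1L, sekg_kernel = 3L,
                         red_channels = 96L) {
  backbone <- match.arg(backbone)
  if (n_sources < 1L) stop("n_sources must be >= 1")
  if (base_channels < 1L || bottleneck_channels < 1L) stop("channel counts must be positive")
  if (n_ftm < 0L) stop("n_ftm must be >= 0")
  if (sekg_kernel != 3L) stop("only sekg_kernel = 3 is supported")
  structure(list(n_sources = as.integer(n_sources),
                 base_channels = as.integer(base_channels),
                 bottleneck_channels = as.integer(bottleneck_channels),
                 n_ftm = as.integer(n_ftm), use_ftm = isTRUE(use_ftm),
                 use_sekg = isTRUE(use_sekg), backbone = backbone,
                 in_channels = as.integer(in_channels),
                 sekg_kernel = as.integer(sekg_kernel),
                 red_channels = as.integer(red_channels)),
            class = "mdftn_config")
}

kaiming_uniform <- function(dims, fan_in) {
  bound <- sqrt(6 / fan_in)
  array(stats::runif(prod(dims), -bound, bound), dims)
}

param_builder <- function(zero = FALSE) {
  par <- list()
  add_conv <- function(name, k, cin, cout, zero_this = FALSE) {
    par[[paste0(name, ".W")]] <<- if (zero || zero_this) array(0, c(k, k, cin, cout))
      else kaiming_uniform(c(k, k, cin, cout), k * k * cin)
    par[[paste0(name, ".b")]] <<- numeric(cout)
  }
  add_dw <- function(name, c) {
    par[[paste0(name, ".W")]] <<- if (zero) array(0, c(3, 3, c))
      else kaiming_uniform(c(3, 3, c), 9)
    par[[paste0(name, ".b")]] <<- numeric(c)
  }
  add_act <- function(name) par[[paste0(name, ".a")]] <<- 0.25
  list(add_conv = add_conv, add_dw = add_dw, add_act = add_act,
       get = function() par)
}

build_resblock_params <- function(pb, name, cin, cout) {
  pb$add_conv(paste0(name, ".fuse"), 1L, cin, cin)
  pb$add_act(paste0(name, ".act1"))
  pb$add_conv(paste0(name, ".spat"), 3L, cin, cout)
  pb$add_act(paste0(name, ".act2"))
  if (cin != cout) pb$add_conv(paste0(name, ".proj"), 1L, cin, cout)
}

build_ftm_params <- function(pb, name, c) {
  pb$add_conv(paste0(name, ".conv1"), 3L, c, c)
  pb$add_act(paste0(name, ".act1"))
  pb$add_conv(paste0(name, ".conv2"), 3L, c, c)
  pb$add_act(paste0(name, ".act2"))
  pb$add_conv(paste0(name, ".se1"), 1L, c, c)
  pb$add_act(paste0(name, ".seact"))
  pb$add_conv(paste0(name, ".se2"), 1L, c, c)
}

build_sekg_params <- function(pb, name, c) {
  pb$add_dw(paste0(name, ".dw"), c)
  pb$add_act(paste0(name, ".dwact"))
  pb$add_conv(paste0(name, ".pw"), 1L, c, 9L * c)
  pb$add_conv(paste0(name, ".ch1"), 1L, c, c)
  pb$add_act(paste0(name, ".chact"))
  pb$add_conv(paste0(name, ".ch2"), 1L, c, c)
}

build_model_params <- function(config, zero = FALSE, zero_head = TRUE) {
  pb <- param_builder(zero)
  cb <- config$base_channels
  cbn <- config$bottleneck_channels
  if (config$backbone == "mdftn-unet") {
    for (k in seq_len(config$n_sources)) {
      e <- sprintf("enc%d", k)
      pb$add_conv(paste0(e, ".stem"), 3L, config$in_channels, cb)
      pb$add_act(paste0(e, ".stemact"))
      build_resblock_params(pb, paste0(e, ".res1"), cb, cb)
      build_resblock_params(pb, paste0(e, ".res2"), cb, 2L * cb)
      build_resblock_params(pb, paste0(e, ".res3"), 2L * cb, cbn)
    }
    pb$add_conv("dftm.compress", 3L, config$n_sources * cbn, cbn)
    if (config$use_ftm)
      for (j in seq_len(config$n_ftm))
        build_ftm_params(pb, sprintf("dftm.ftm%d", j), cbn)
    for (k in seq_len(config$n_sources)) {
      d <- sprintf("dec%d", k)
      pb$add_conv(paste0(d, ".up1"), 2L, cbn, 2L * cb)
      if (config$use_sekg) build_sekg_params(pb, paste0(d, ".sekg1"), 2L * cb)
      build_resblock_params(pb, paste0(d, ".res1"), 4L * cb, 2L * cb)
      pb$add_conv(paste0(d, ".up2"), 2L, 2L * cb, cb)
      if (config$use_sekg) build_sekg_params(pb, paste0(d, ".sekg2"), cb)
      build_resblock_params(pb, paste0(d, ".res2"), 2L * cb, cb)
      # zero start: the decoder head begins as a null image, so early
      # optimisation fixes the output scale before the texture
      pb$add_conv(paste0(d, ".out"), 3L, cb, config$in_channels, zero_this = zero_head)
    }
  } else {
    cr <- config$red_channels
    for (k in seq_len(config$n_sources)) {
      e <- sprintf("enc%d", k)
      cins <- c(config$in_channels, rep(cr, 4L))
      for (j in 1:5) {
        pb$add_conv(sprintf("%s.conv%d", e, j), 5L, cins[j], cr)
        pb$add_act(sprintf("%s.act%d", e, j))
      }
    }
    pb$add_conv("dftm.compress", 3L, config$n_sources * cr, cr)
    if (config$use_ftm)
      for (j in seq_len(config$n_ftm))
        build_ftm_params(pb, sprintf("dftm.ftm%d", j), cr)
    for (k in seq_len(config$n_sources)) {
      d <- sprintf("dec%d", k)
      for (j in 1:4) {
        pb$add_conv(sprintf("%s.dconv%d", d, j), 5L, cr, cr)
        pb$add_act(sprintf("%s.dact%d", d, j))
      }
      pb$add_conv(paste0(d, ".dconv5"), 5L, cr, config$in_channels, zero_this = zero_head)
    }
  }
  pb$get()
}

#' Initialise an MDFTN model
#'
#' Builds the full parameter set (Kaiming-uniform convolution weights, zero
#' biases, PReLU slopes 0.25), deterministic given `rng_seed`.
#'
#' @param config An [mdftn_config()].
#' @param rng_seed Integer seed for weight initialisation.
#' @param zero_init If `TRUE`, all weights and biases start at zero (used to
#'   probe the residual identity structure).
#' @param zero_head If `TRUE` (default), each decoder's final output
#'   convolution starts at zero so optimisation begins from a null image
#'   (an identity image for the RED-CNN backbone, whose head sits under a
#'   global input shortcut); set `FALSE` for a fully random head, e.g. when
#'   probing gradient flow through an untrained network.
#' @return An environment of class `mdftn_model` with fields `par` (named
#'   parameter list), `grad` (gradient accumulator) and `config`.
#' @export
mdftn_init <- function(config = mdftn_config(), rng_seed = 1L, zero_init = FALSE,
                       zero_head = TRUE) {
  stopifnot(inherits(config, "mdftn_config"))
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  set.seed(rng_seed)
  on.exit(restore_seed(old))
  m <- new.env(parent = emptyenv())
  m$par <- build_model_params(config, zero = zero_init, zero_head = zero_head)
  m$grad <- list()
  m$config <- config
  class(m) <- "mdftn_model"
  m
}

#' @export
print.mdftn_model <- function(x, ...) {
  cnt <- count_parameters(x)
  cat(sprintf("<mdftn_model> backbone %s, %d source(s), base %d, bottleneck %d\n",
              x$config$backbone, x$config$n_sources, x$config$base_channels,
              x$config$bottleneck_channels))
  cat(sprintf("  FTMs: %s, SEKG: %s; %s trainable parameters\n",
              if (x$config$use_ftm) x$config$n_ftm else "off",
              if (x$config$use_sekg) "on" else "off",
              format(cnt, big.mark = ",")))
  bc <- attr(cnt, "by_component")
  cat(sprintf("  encoders %s | bottleneck %s | decoders %s\n",
              format(bc[["encoders"]], big.mark = ","),
              format(bc[["bottleneck"]], big.mark = ","),
              format(bc[["decoders"]], big.mark = ",")))
  invisible(x)
}

#' Count trainable parameters
#'
#' @param model An `mdftn_model`.
#' @return Integer total with attribute `by_component` (named vector with
#'   entries `encoders`, `bottleneck`, `decoders`).
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "mdftn_model"))
  sizes <- vapply(model$par, length, numeric(1))
  comp <- ifelse(grepl("^enc", names(sizes)), "encoders",
                 ifelse(grepl("^dftm", names(sizes)), "bottleneck", "decoders"))
  by <- vapply(c("encoders", "bottleneck", "decoders"),
               function(k) sum(sizes[comp == k]), numeric(1))
  structure(sum(sizes), by_component = by)
}

# ---- tape-level forward builders -----------------------------------------

fwd_resblock <- function(tp, m, id, name, cin, cout) {
  h <- tp_conv(tp, id, m, paste0(name, ".fuse"), 1L, 0L)
  h <- tp_prelu(tp, h, m, paste0(name, ".act1"))
  h <- tp_conv(tp, h, m, paste0(name, ".spat"), 1L, 1L)
  h <- tp_prelu(tp, h, m, paste0(name, ".act2"))
  sc <- if (cin == cout) id else tp_conv(tp, id, m, paste0(name, ".proj"), 1L, 0L)
  tp_add(tp, h, sc)
}

fwd_encoder_unet <- function(tp, m, id, name, config) {
  cb <- config$base_channels
  h <- tp_conv(tp, id, m, paste0(name, ".stem"), 1L, 1L)
  h <- tp_prelu(tp, h, m, paste0(name, ".stemact"))
  s1 <- fwd_resblock(tp, m, h, paste0(name, ".res1"), cb, cb)
  p1 <- tp_avgpool(tp, s1)
  s2 <- fwd_resblock(tp, m, p1, paste0(name, ".res2"), cb, 2L * cb)
  p2 <- tp_avgpool(tp, s2)
  bott <- fwd_resblock(tp, m, p2, paste0(name, ".res3"), 2L * cb,
                       config$bottleneck_channels)
  list(bottleneck = bott, skips = list(s1, s2))
}

fwd_ftm <- function(tp, m, id, name) {
  h <- tp_conv(tp, id, m, paste0(name, ".conv1"), 1L, 1L)
  h <- tp_prelu(tp, h, m, paste0(name, ".act1"))
  h <- tp_conv(tp, h, m, paste0(name, ".conv2"), 1L, 1L)
  h <- tp_prelu(tp, h, m, paste0(name, ".act2"))      # F_CP
  g <- tp_gap(tp, h)
  g <- tp_conv(tp, g, m, paste0(name, ".se1"), 1L, 0L)
  g <- tp_prelu(tp, g, m, paste0(name, ".seact"))
  g <- tp_conv(tp, g, m, paste0(name, ".se2"), 1L, 0L)
  g <- tp_sigmoid(tp, g)
  gated <- tp_scale_chan(tp, h, g)
  tp_add(tp, gated, id)
}

fwd_dftm <- function(tp, m, ids, config) {
  h <- if (length(ids) > 1L) tp_concat(tp, ids) else ids[[1L]]
  h <- tp_conv(tp, h, m, "dftm.compress", 1L, 1L)
  if (config$use_ftm)
    for (j in seq_len(config$n_ftm))
      h <- fwd_ftm(tp, m, h, sprintf("dftm.ftm%d", j))
  h
}

fwd_sekg <- function(tp, m, id, name) {
  sp <- tp_dwconv(tp, id, m, paste0(name, ".dw"))
  sp <- tp_prelu(tp, sp, m, paste0(name, ".dwact"))
  sp <- tp_conv(tp, sp, m, paste0(name, ".pw"), 1L, 0L)
  ch <- tp_gap(tp, id)
  ch <- tp_conv(tp, ch, m, paste0(name, ".ch1"), 1L, 0L)
  ch <- tp_prelu(tp, ch, m, paste0(name, ".chact"))
  ch <- tp_conv(tp, ch, m, paste0(name, ".ch2"), 1L, 0L)
  logits <- tp_add_chan(tp, sp, tp_rep_taps(tp, ch))
  theta <- tp_sigmoid(tp, logits)
  tp_add(tp, tp_sekg_apply(tp, id, theta), id)
}

fwd_decoder_unet <- function(tp, m, id, skips, name, config) {
  cb <- config$base_channels
  h <- tp_upconv(tp, id, m, paste0(name, ".up1"))
  if (config$use_sekg) h <- fwd_sekg(tp, m, h, paste0(name, ".sekg1"))
  h <- tp_concat(tp, c(h, skips[[2L]]))
  h <- fwd_resblock(tp, m, h, paste0(name, ".res1"), 4L * cb, 2L * cb)
  h <- tp_upconv(tp, h, m, paste0(name, ".up2"))
  if (config$use_sekg) h <- fwd_sekg(tp, m, h, paste0(name, ".sekg2"))
  h <- tp_concat(tp, c(h, skips[[1L]]))
  h <- fwd_resblock(tp, m, h, paste0(name, ".res2"), 2L * cb, cb)
  tp_conv(tp, h, m, paste0(name, ".out"), 1L, 1L)
}

fwd_encoder_red <- function(tp, m, id, name) {
  h <- id
  skips <- list()
  for (j in 1:5) {
    h <- tp_conv(tp, h, m, sprintf("%s.conv%d", name, j), 1L, 2L)
    h <- tp_prelu(tp, h, m, sprintf("%s.act%d", name, j))
    if (j %in% c(2L, 4L)) skips[[length(skips) + 1L]] <- h
  }
  list(bottleneck = h, skips = c(id, skips))  # input, conv2, conv4
}

fwd_decoder_red <- function(tp, m, id, skips, name) {
  h <- tp_conv(tp, id, m, paste0(name, ".dconv1"), 1L, 2L)
  h <- tp_prelu(tp, h, m, paste0(name, ".dact1"))
  h <- tp_conv(tp, h, m, paste0(name, ".dconv2"), 1L, 2L)
  h <- tp_add(tp, h, skips[[3L]])
  h <- tp_prelu(tp, h, m, paste0(name, ".dact2"))
  h <- tp_conv(tp, h, m, paste0(name, ".dconv3"), 1L, 2L)
  h <- tp_prelu(tp, h, m, paste0(name, ".dact3"))
  h <- tp_conv(tp, h, m, paste0(name, ".dconv4"), 1L, 2L)
  h <- tp_add(tp, h, skips[[2L]])
  h <- tp_prelu(tp, h, m, paste0(name, ".dact4"))
  h <- tp_conv(tp, h, m, paste0(name, ".dconv5"), 1L, 2L)
  tp_add(tp, h, skips[[1L]])
}

# Build the full forward tape. xs: list of (h, w, 1, n) arrays, one per
# source. Returns the tape and the output node ids.
model_forward_tape <- function(m, xs) {
  config <- m$config
  if (length(xs) != config$n_sources)
    stop(sprintf("expected %d source batches, got %d", config$n_sources, length(xs)))
  xs <- lapply(xs, as_batch4)
  d1 <- dim(xs[[1L]])
  for (x in xs) {
    d <- dim(x)
    if (!identical(d, d1)) stop("all source batches must share one shape")
  }
  if (config$backbone == "mdftn-unet") {
    if (d1[1L] != d1[2L]) stop("input images must be square")
    if (d1[1L] %% 4L != 0L) stop("input side must be divisible by 4")
  }
  tp <- tape_new()
  in_ids <- vapply(xs, function(x) tp_input(tp, x), integer(1))
  encs <- lapply(seq_len(config$n_sources), function(k) {
    if (config$backbone == "mdftn-unet")
      fwd_encoder_unet(tp, m, in_ids[k], sprintf("enc%d", k), config)
    else
      fwd_encoder_red(tp, m, in_ids[k], sprintf("enc%d", k))
  })
  shared <- fwd_dftm(tp, m, vapply(encs, `[[`, integer(1), "bottleneck"), config)
  outs <- vapply(seq_len(config$n_sources), function(k) {
    if (config$backbone == "mdftn-unet")
      fwd_decoder_unet(tp, m, shared, encs[[k]]$skips, sprintf("dec%d", k), config)
    else
      fwd_decoder_red(tp, m, shared, encs[[k]]$skips, sprintf("dec%d", k))
  }, integer(1))
  list(tape = tp, outputs = outs, inputs = in_ids)
}

#' Forward pass through the full network
#'
#' Encodes each source's batch with its own encoder, fuses all bottleneck
#' features in the shared DFTM, and decodes each source with its own
#' decoder and skip connections.
#'
#' @param model An `mdftn_model`.
#' @param xs List with one `(h, w, 1, n)` array (or single matrix) per
#'   source, equal shapes; values on the \eqn{[0,1]} scale.
#' @return List of denoised batches, one per source, same shapes as input.
#' @export
mdftn_forward <- function(model, xs) {
  stopifnot(inherits(model, "mdftn_model"))
  fw <- model_forward_tape(model, xs)
  lapply(fw$outputs, function(id) tp_value(fw$tape, id))
}

# ---- standalone module surfaces (used for unit-level probes) -------------

run_module <- function(par, fwd, xs) {
  m <- new.env(parent = emptyenv())
  m$par <- par
  m$grad <- list()
  tp <- tape_new()
  ids <- vapply(xs, function(x) tp_input(tp, as_batch4(x)), integer(1))
  tp_value(tp, fwd(tp, m, ids))
}

#' Standalone residual block
#'
#' The encoder/decoder building block: 1x1 fuse convolution, PReLU, 3x3
#' spatial convolution, PReLU, plus an identity shortcut (1x1-projected when
#' the channel counts differ). Spatial size is preserved.
#'
#' @param x `(h, w, c_in, n)` array (or matrix).
#' @param params Parameter list from [residual_block_params()].
#' @return `(h, w, c_out, n)` array.
#' @export
residual_block <- function(x, params) {
  cin <- attr(params, "cin"); cout <- attr(params, "cout")
  if (dim(as_batch4(x))[3L] != cin)
    stop(sprintf("input has %d channels, block expects %d", dim(as_batch4(x))[3L], cin))
  run_module(params, function(tp, m, ids) fwd_resblock(tp, m, ids[1L], "rb", cin, cout),
             list(x))
}

#' @rdname residual_block
#' @param c_in,c_out Input/output channel counts.
#' @param rng_seed Seed for weight initialisation.
#' @param zero_init All-zero weights (shortcut-identity probe).
#' @export
residual_block_params <- function(c_in, c_out = c_in, rng_seed = 1L, zero_init = FALSE) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  set.seed(rng_seed)
  on.exit(restore_seed(old))
  pb <- param_builder(zero_init)
  build_resblock_params(pb, "rb", c_in, c_out)
  structure(pb$get(), cin = as.integer(c_in), cout = as.integer(c_out))
}

#' Standalone feature transformation module (FTM)
#'
#' Convolutional trunk (two 3x3 convolutions with PReLU) gated by a
#' squeeze-and-excitation branch (global average pool, two 1x1 mappings,
#' sigmoid), added back onto the module input: with all-zero weights the FTM
#' is exactly the identity.
#'
#' @param x `(h, w, c, n)` feature array.
#' @param params Parameter list from [ftm_params()].
#' @return Array of the same shape.
#' @export
ftm <- function(x, params) {
  c <- attr(params, "channels")
  if (dim(as_batch4(x))[3L] != c)
    stop(sprintf("input has %d channels, FTM expects %d", dim(as_batch4(x))[3L], c))
  run_module(params, function(tp, m, ids) fwd_ftm(tp, m, ids[1L], "ftm"), list(x))
}

#' @rdname ftm
#' @param channels Feature channel count.
#' @param rng_seed Seed for weight initialisation.
#' @param zero_init All-zero weights (identity probe).
#' @export
ftm_params <- function(channels, rng_seed = 1L, zero_init = FALSE) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  set.seed(rng_seed)
  on.exit(restore_seed(old))
  pb <- param_builder(zero_init)
  build_ftm_params(pb, "ftm", channels)
  structure(pb$get(), channels = as.integer(channels))
}

#' Standalone deep feature transformation module (DFTM)
#'
#' Channel-concatenates the per-source bottleneck features, compresses them
#' back to the bottleneck width with a 3x3 convolution, and refines the
#' result with `n_ftm` stacked FTMs (skipped when `use_ftm = FALSE`).
#'
#' @param features List of `(h, w, c, n)` arrays with identical shapes.
#' @param params Parameter list from [dftm_params()].
#' @return `(h, w, c, n)` shared feature array.
#' @export
dftm <- function(features, params) {
  cfg <- attr(params, "config")
  if (length(features) != cfg$n_sources)
    stop(sprintf("expected %d feature maps, got %d", cfg$n_sources, length(features)))
  dims <- lapply(features, function(f) dim(as_batch4(f)))
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L)
    stop("feature maps must share one spatial size")
  run_module(params, function(tp, m, ids) fwd_dftm(tp, m, ids, cfg), features)
}

#' @rdname dftm
#' @param n_sources Number of incoming feature maps.
#' @param channels Bottleneck channel count.
#' @param n_ftm Number of stacked FTMs.
#' @param use_ftm Ablation switch.
#' @param rng_seed Seed.
#' @param zero_init All-zero weights.
#' @export
dftm_params <- function(n_sources, channels, n_ftm = 4L, use_ftm = TRUE,
                        rng_seed = 1L, zero_init = FALSE) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  set.seed(rng_seed)
  on.exit(restore_seed(old))
  pb <- param_builder(zero_init)
  pb$add_conv("dftm.compress", 3L, n_sources * channels, channels)
  if (use_ftm)
    for (j in seq_len(n_ftm)) build_ftm_params(pb, sprintf("dftm.ftm%d", j), channels)
  cfg <- list(n_sources = as.integer(n_sources), n_ftm = as.integer(n_ftm),
              use_ftm = isTRUE(use_ftm))
  structure(pb$get(), config = cfg)
}

#' Standalone spatially enhanced kernel generation (SEKG) attention
#'
#' Produces per-position, per-channel 3x3 kernel weights Theta by fusing a
#' spatial branch (depthwise separable 3x3 convolution expanding to
#' `9 * c` logits per position) and a channel branch (global average pool
#' and two 1x1 mappings, broadcast over positions and taps) through a
#' sigmoid. The weights are applied to the unfolded 3x3 neighbourhoods
#' (stride 1, zero padding) and the input is added back as a shortcut.
#'
#' @param x `(h, w, c, n)` feature array.
#' @param params Parameter list from [sekg_params()].
#' @param theta Optional explicit weight array `(h, w, 9*c, n)` overriding
#'   the generated Theta (e.g. all zeros makes the operator the exact
#'   identity).
#' @return Array of the same shape as `x`.
#' @export
sekg_attention <- function(x, params = NULL, theta = NULL) {
  x4 <- as_batch4(x)
  if (!is.null(theta)) return(cpp_sekg_fw(x4, theta) + x4)
  c <- attr(params, "channels")
  if (dim(x4)[3L] != c)
    stop(sprintf("input has %d channels, SEKG expects %d", dim(x4)[3L], c))
  run_module(params, function(tp, m, ids) fwd_sekg(tp, m, ids[1L], "sekg"), list(x4))
}

#' @rdname sekg_attention
#' @param channels Feature channel count.
#' @param rng_seed Seed.
#' @param zero_init All-zero weights.
#' @export
sekg_params <- function(channels, rng_seed = 1L, zero_init = FALSE) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  set.seed(rng_seed)
  on.exit(restore_seed(old))
  pb <- param_builder(zero_init)
  build_sekg_params(pb, "sekg", channels)
  structure(pb$get(), channels = as.integer(channels))
}

#' Per-source encoder (functional surface)
#'
#' Runs one source's encoder on an image batch and returns the bottleneck
#' features and the two pre-pooling skip feature maps.
#'
#' @param model An `mdftn_model`.
#' @param x `(h, w, 1, n)` array or matrix.
#' @param source Encoder index (1-based).
#' @return List with `bottleneck` and `skips` (list of two arrays).
#' @export
encode <- function(model, x, source = 1L) {
  stopifnot(inherits(model, "mdftn_model"))
  x4 <- as_batch4(x)
  if (model$config$backbone == "mdftn-unet") {
    if (dim(x4)[1L] != dim(x4)[2L]) stop("input images must be square")
    if (dim(x4)[1L] %% 4L != 0L) stop("input side must be divisible by 4")
  }
  tp <- tape_new()
  id <- tp_input(tp, x4)
  e <- if (model$config$backbone == "mdftn-unet")
    fwd_encoder_unet(tp, model, id, sprintf("enc%d", source), model$config)
  else fwd_encoder_red(tp, model, id, sprintf("enc%d", source))
  list(bottleneck = tp_value(tp, e$bottleneck),
       skips = lapply(e$skips, function(s) tp_value(tp, s)))
}
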