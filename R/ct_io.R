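# CT slice data model, Hounsfield-unit conventions, file I/O, dataset
# pairing/splitting and patch sampling.

#' Global Hounsfield-unit clip range
#'
#' All slices handled by the package live on the standard 12-bit CT scale
#' \eqn{[-1024, 3071]} HU (air = -1000 HU, water = 0 HU). Images are clipped
#' to this range on construction and normalised to \eqn{[0, 1]} against it
#' for training and metrics.
#' @return Numeric length-2 vector `c(hu_min, hu_max)`.
#' @export
hu_range <- function() c(-1024, 3071)

#' Construct a CT slice
#'
#' A `ct_slice` is one 2-D CT image in Hounsfield units together with the
#' identity of the imaging source it came from and optional acquisition
#' metadata. Pixel values are clipped to [hu_range()].
#'
#' @param pixels Numeric matrix of HU values.
#' @param source_id Character label identifying the imaging source.
#' @param meta Optional named list of acquisition metadata
#'   (e.g. `tube_current_mA`, `tube_voltage_kVp`, `slice_thickness_mm`).
#' @return An object of class `ct_slice` with elements `pixels`, `source_id`,
#'   `meta`.
#' @export
ct_slice <- function(pixels, source_id = "s1", meta = list()) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("pixels must be a numeric matrix")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("pixels must have positive dimensions")
  if (!all(is.finite(pixels)))
    stop("pixels must be finite")
  r <- hu_range()
  pixels <- pmin(pmax(pixels, r[1]), r[2])
  structure(list(pixels = pixels, source_id = as.character(source_id), meta = meta),
            class = "ct_slice")
}

#' @export
print.ct_slice <- function(x, ...) {
  cat(sprintf("<ct_slice> %d x %d, source '%s', HU range [%.1f, %.1f]\n",
              nrow(x$pixels), ncol(x$pixels), x$source_id,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Construct an aligned low-dose / normal-dose slice pair
#'
#' The supervised training unit: a low-dose slice and the normal-dose slice
#' of the same anatomy from the same source. Shapes and source identities
#' must match.
#'
#' @param ldct,ndct `ct_slice` objects of identical shape and source.
#' @return An object of class `paired_slice` with elements `ldct`, `ndct`,
#'   `source_id`.
#' @export
paired_slice <- function(ldct, ndct) {
  stopifnot(inherits(ldct, "ct_slice"), inherits(ndct, "ct_slice"))
  if (!identical(dim(ldct$pixels), dim(ndct$pixels)))
    stop("ldct and ndct must have identical dimensions")
  if (!identical(ldct$source_id, ndct$source_id))
    stop("ldct and ndct must share the same source_id")
  structure(list(ldct = ldct, ndct = ndct, source_id = ldct$source_id),
            class = "paired_slice")
}

#' Normalise a slice from HU to the unit interval
#'
#' Linear map of clipped HU onto \eqn{[0, 1]}:
#' \eqn{v = (clip(HU) - hu_{min}) / (hu_{max} - hu_{min})}. Training, the
#' loss, and all metrics operate on this scale (so RMSE is reported on a
#' unit scale).
#'
#' @param slice A `ct_slice` or numeric matrix of HU values.
#' @param norm_range HU interval used for the map; default [hu_range()].
#' @return A numeric matrix in \eqn{[0,1]} with attribute `norm_range`.
#' @export
hu_to_normalized <- function(slice, norm_range = hu_range()) {
  if (inherits(slice, "ct_slice")) slice <- slice$pixels
  if (length(norm_range) != 2L || diff(norm_range) <= 0)
    stop("norm_range must be an interval of positive width")
  v <- (pmin(pmax(slice, norm_range[1]), norm_range[2]) - norm_range[1]) / diff(norm_range)
  attr(v, "norm_range") <- norm_range
  v
}

#' Map a normalised image back to HU
#'
#' Inverse of [hu_to_normalized()]; exact (up to floating precision) on the
#' clipped range.
#'
#' @param values Numeric matrix in \eqn{[0,1]} (its `norm_range` attribute is
#'   used when `norm_range` is missing).
#' @param norm_range HU interval of the forward map.
#' @return Numeric matrix of HU values.
#' @export
normalized_to_hu <- function(values, norm_range = attr(values, "norm_range")) {
  if (is.null(norm_range)) norm_range <- hu_range()
  out <- values * diff(norm_range) + norm_range[1]
  attr(out, "norm_range") <- NULL
  out
}

#' Apply a display window for visualisation
#'
#' Maps the HU window `[lo, hi]` linearly onto 0..255 with clipping, using
#' round-half-to-even. The default window `[-160, 240]` HU is the soft-tissue
#' window used for figure rendering; windowed images are presentation-only
#' and never enter training or metrics.
#'
#' @param slice `ct_slice` or numeric HU matrix.
#' @param lo,hi Window bounds in HU, `lo < hi`.
#' @return Integer matrix with values in 0..255.
#' @export
apply_display_window <- function(slice, lo = -160, hi = 240) {
  if (inherits(slice, "ct_slice")) slice <- slice$pixels
  if (lo >= hi) stop("display window requires lo < hi")
  v <- (pmin(pmax(slice, lo), hi) - lo) / (hi - lo) * 255
  out <- round(v)
  storage.mode(out) <- "integer"
  out
}

TIFF_HU_OFFSET <- 1024
TIFF_MAXVAL <- 65535

slice_formats <- c("tiff16", "txt", "rds")

#' Write a CT slice to disk
#'
#' Supported containers:
#' \describe{
#'   \item{`tiff16`}{16-bit greyscale TIFF storing `round(HU) + 1024` as
#'     unsigned integers; lossless for integer HU.}
#'   \item{`txt`}{plain-text matrix (full double precision, lossless); first
#'     line is a header `# rows cols source_id`.}
#'   \item{`rds`}{R serialisation of the `ct_slice` (lossless, including
#'     metadata); the canonical runtime container.}
#' }
#'
#' @param slice A `ct_slice`.
#' @param path Output file path.
#' @param format One of `"tiff16"`, `"txt"`, `"rds"`; default guessed from
#'   the file extension.
#' @return `path`, invisibly.
#' @export
write_slice <- function(slice, path, format = guess_format(path)) {
  stopifnot(inherits(slice, "ct_slice"))
  format <- match.arg(format, slice_formats)
  if (format == "tiff16") {
    u <- round(slice$pixels) + TIFF_HU_OFFSET
    u <- pmin(pmax(u, 0), TIFF_MAXVAL)
    tiff::writeTIFF(u / TIFF_MAXVAL, path, bits.per.sample = 16L)
  } else if (format == "txt") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# %d %d %s", nrow(slice$pixels), ncol(slice$pixels),
                       slice$source_id), con)
    utils::write.table(format(slice$pixels, digits = 17, scientific = TRUE, trim = TRUE),
                       con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  } else {
    saveRDS(slice, path)
  }
  invisible(path)
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         tif = , tiff = "tiff16",
         txt = "txt",
         rds = "rds",
         stop(sprintf("cannot guess slice format from extension '.%s'", ext)))
}

#' Read a CT slice from disk
#'
#' Counterpart of [write_slice()]. DICOM and HDF5 containers are not
#' supported by this implementation and are rejected with a distinct error.
#'
#' @param path File path.
#' @param format Container format (see [write_slice()]); default guessed
#'   from the extension.
#' @param source_id Source label to attach (for `tiff16`, which does not
#'   carry one); ignored for formats that store it.
#' @return A `ct_slice`.
#' @export
read_slice <- function(path, format = guess_format(path), source_id = "s1") {
  if (format %in% c("dicom", "hdf5", "h5", "png16"))
    stop(sprintf("unsupported slice format '%s'", format))
  format <- match.arg(format, slice_formats)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (format == "tiff16") {
    u <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(u)) == 3L) u <- u[, , 1L]
    ct_slice(matrix(as.numeric(u), nrow(u), ncol(u)) - TIFF_HU_OFFSET,
             source_id = source_id)
  } else if (format == "txt") {
    hdr <- strsplit(sub("^#\\s*", "", readLines(path, n = 1L)), "\\s+")[[1L]]
    if (length(hdr) < 3L) stop(sprintf("malformed txt slice header in %s", path))
    m <- as.matrix(utils::read.table(path, skip = 1L))
    dimnames(m) <- NULL
    if (nrow(m) != as.integer(hdr[1L]) || ncol(m) != as.integer(hdr[2L]))
      stop(sprintf("txt slice shape %dx%d does not match header %sx%s in %s",
                   nrow(m), ncol(m), hdr[1L], hdr[2L], path))
    ct_slice(m, source_id = hdr[3L])
  } else {
    s <- readRDS(path)
    if (!inherits(s, "ct_slice")) stop(sprintf("%s does not contain a ct_slice", path))
    s
  }
}

#' Write / read an aligned slice pair
#'
#' Pairs are stored as a single RDS file holding the `paired_slice`.
#' @param pair A `paired_slice`.
#' @param path File path (`.rds`).
#' @return `path` (write) or a `paired_slice` (read).
#' @export
write_pair <- function(pair, path) {
  stopifnot(inherits(pair, "paired_slice"))
  saveRDS(pair, path)
  invisible(path)
}

#' @rdname write_pair
#' @export
read_pair <- function(path) {
  p <- readRDS(path)
  if (!inherits(p, "paired_slice")) stop(sprintf("%s does not contain a paired_slice", path))
  p
}

#' Randomly crop aligned patches from a slice pair
#'
#' Draws `n` patch positions uniformly over all valid top-left corners
#' (0-based, row-major, top-left origin) and crops the low- and normal-dose
#' images at identical coordinates. Patches are returned normalised to
#' \eqn{[0,1]}.
#'
#' @param pair A `paired_slice`.
#' @param patch_size Side length of the square crops.
#' @param n Number of patches.
#' @param rng_seed Integer seed making the crop positions deterministic.
#' @return A list of class `patch_batch`: `ldct`, `ndct` (arrays
#'   `patch_size x patch_size x 1 x n`), `indices` (n x 2 matrix of 0-based
#'   top-left row/col), `source_id`.
#' @export
extract_patches <- function(pair, patch_size, n, rng_seed = 1L) {
  stopifnot(inherits(pair, "paired_slice"))
  d <- dim(pair$ldct$pixels)
  if (patch_size > min(d)) stop("patch_size exceeds image size")
  if (n < 1L) stop("n must be >= 1")
  lx <- hu_to_normalized(pair$ldct)
  nx <- hu_to_normalized(pair$ndct)
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  set.seed(rng_seed)
  on.exit(restore_seed(old))
  i0 <- sample.int(d[1] - patch_size + 1L, n, replace = TRUE) - 1L
  j0 <- sample.int(d[2] - patch_size + 1L, n, replace = TRUE) - 1L
  lp <- array(0, c(patch_size, patch_size, 1L, n))
  np <- array(0, c(patch_size, patch_size, 1L, n))
  for (k in seq_len(n)) {
    ri <- i0[k] + seq_len(patch_size)
    cj <- j0[k] + seq_len(patch_size)
    lp[, , 1L, k] <- lx[ri, cj]
    np[, , 1L, k] <- nx[ri, cj]
  }
  structure(list(ldct = lp, ndct = np, indices = cbind(row = i0, col = j0),
                 source_id = pair$source_id),
            class = "patch_batch")
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Split pair indices into train/validation/test sets
#'
#' Deterministic, disjoint per-source split. Default proportions are 8:1:1,
#' mirroring the 1600/200/200 per-source protocol of the study corpus.
#'
#' @param n Number of available pairs.
#' @param fractions Length-3 nonnegative weights for train/val/test.
#' @param counts Optional explicit integer counts (overrides `fractions`);
#'   must sum to at most `n`.
#' @param rng_seed Seed for the random shuffle.
#' @return List with integer index vectors `train`, `val`, `test`.
#' @export
make_split <- function(n, fractions = c(8, 1, 1), counts = NULL, rng_seed = 1L) {
  if (is.null(counts)) {
    f <- fractions / sum(fractions)
    counts <- floor(f * n)
    rem <- n - sum(counts)
    if (rem > 0) {
      order_rem <- order(f * n - counts, decreasing = TRUE)
      counts[order_rem[seq_len(rem)]] <- counts[order_rem[seq_len(rem)]] + 1L
    }
  }
  counts <- as.integer(counts)
  if (length(counts) != 3L || any(counts < 0L)) stop("counts must be 3 nonnegative integers")
  if (sum(counts) > n) stop(sprintf("requested %d pairs but only %d available", sum(counts), n))
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  set.seed(rng_seed)
  on.exit(restore_seed(old))
  idx <- sample.int(n, sum(counts))
  list(train = sort(idx[seq_len(counts[1])]),
       val = sort(idx[counts[1] + seq_len(counts[2])]),
       test = sort(idx[counts[1] + counts[2] + seq_len(counts[3])]))
}

manifest_cols <- c("source_id", "ldct_path", "ndct_path", "split")

#' Read / write a dataset manifest
#'
#' The manifest is a tab-separated table with columns `source_id`,
#' `ldct_path`, `ndct_path`, `split` listing every stored pair and its
#' train/val/test assignment. Paths are interpreted relative to the
#' manifest's own directory unless absolute.
#'
#' @param manifest Data frame with the columns above.
#' @param path File path of the TSV.
#' @return The manifest data frame (with attribute `dir` when read).
#' @export
write_manifest <- function(manifest, path) {
  if (!all(manifest_cols %in% names(manifest)))
    stop("manifest must have columns source_id, ldct_path, ndct_path, split")
  utils::write.table(manifest[, manifest_cols], path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop(sprintf("manifest not found: %s", path))
  m <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  if (!all(manifest_cols %in% names(m)))
    stop("manifest must have columns source_id, ldct_path, ndct_path, split")
  attr(m, "dir") <- dirname(normalizePath(path))
  m
}

manifest_path <- function(p, dir) {
  ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(dir, p))
}

#' Load one manifest row as a slice pair
#'
#' @param row One-row data frame from [read_manifest()].
#' @param dir Base directory for relative paths (defaults to the manifest's).
#' @return A `paired_slice`.
#' @export
load_manifest_pair <- function(row, dir = attr(row, "dir")) {
  if (is.null(dir)) dir <- "."
  ld <- read_slice(manifest_path(row$ldct_path, dir), source_id = row$source_id)
  nd <- read_slice(manifest_path(row$ndct_path, dir), source_id = row$source_id)
  ld$source_id <- nd$source_id <- as.character(row$source_id)
  paired_slice(ld, nd)
}
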