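# Multisource paired LDCT/NDCT simulation: ellipse phantoms, parallel-beam
# projection, compound Poisson + Gaussian (quantum + electronic) noise in the
# count domain, and filtered back-projection with selectable apodisation.
#
# Physics conventions: pixel pitch 1 mm; attenuation from HU via
# mu = mu_water * (1 + HU/1000), mu_water = 0.0195 / mm, so line integrals p
# are dimensionless and the incident photon count I0 per detector bin acts
# as the dose surrogate.

MU_WATER <- 0.0195

mu_from_hu <- function(hu) MU_WATER * (1 + hu / 1000)
hu_from_mu <- function(mu) 1000 * (mu / MU_WATER - 1)

#' Phantom specification
#'
#' Describes a random anatomical stand-in: a circular body disk on an air
#' background, overlaid with random ellipses of varying attenuation.
#'
#' @param size Image side length in pixels (>= 32).
#' @param n_ellipses Number of random ellipses (>= 0).
#' @param hu_background Body disk attenuation in HU (0 = water).
#' @param hu_offsets HU interval the ellipse offsets are drawn from.
#' @param body_radius_fraction Body disk radius as a fraction of `size/2`.
#' @param rng_seed Integer seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(size = 256L, n_ellipses = 8L, hu_background = 0,
                         hu_offsets = c(-150, 250), body_radius_fraction = 0.85,
                         rng_seed = 1L) {
  if (size < 32L) stop("phantom size must be >= 32")
  if (n_ellipses < 0L) stop("n_ellipses must be >= 0")
  if (body_radius_fraction <= 0 || body_radius_fraction > 1)
    stop("body_radius_fraction must be in (0, 1]")
  structure(list(size = as.integer(size), n_ellipses = as.integer(n_ellipses),
                 hu_background = hu_background, hu_offsets = hu_offsets,
                 body_radius_fraction = body_radius_fraction,
                 rng_seed = as.integer(rng_seed)),
            class = "phantom_spec")
}

#' Generate a random ellipse phantom
#'
#' A body disk at `hu_background` sits on air (-1000 HU); `n_ellipses`
#' random ellipses (centres inside the body, random axes and rotations) add
#' HU offsets drawn from `hu_offsets`. Deterministic given `rng_seed`.
#'
#' @param spec A [phantom_spec()].
#' @return A `ct_slice` with `source_id = "phantom"`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  set.seed(spec$rng_seed)
  on.exit(restore_seed(old))
  s <- spec$size
  c0 <- (s - 1) / 2
  xs <- matrix(rep(seq_len(s) - 1 - c0, each = s), s)   # column coordinate
  ys <- matrix(rep(seq_len(s) - 1 - c0, times = s), s)  # row coordinate
  rbody <- spec$body_radius_fraction * s / 2
  img <- matrix(-1000, s, s)
  body <- (xs^2 + ys^2) <= rbody^2
  img[body] <- spec$hu_background
  if (spec$n_ellipses > 0L) {
    for (k in seq_len(spec$n_ellipses)) {
      rr <- sqrt(stats::runif(1)) * 0.8 * rbody
      an <- stats::runif(1, 0, 2 * pi)
      cx <- rr * cos(an); cy <- rr * sin(an)
      ax <- stats::runif(1, 0.05, 0.30) * rbody
      ay <- stats::runif(1, 0.05, 0.30) * rbody
      th <- stats::runif(1, 0, pi)
      dhu <- stats::runif(1, spec$hu_offsets[1], spec$hu_offsets[2])
      xr <- (xs - cx) * cos(th) + (ys - cy) * sin(th)
      yr <- -(xs - cx) * sin(th) + (ys - cy) * cos(th)
      inside <- ((xr / ax)^2 + (yr / ay)^2 <= 1) & body
      img[inside] <- img[inside] + dhu
    }
  }
  r <- hu_range()
  ct_slice(pmin(pmax(img, r[1]), r[2]), source_id = "phantom")
}

#' Parallel-beam acquisition geometry
#'
#' @param n_angles Number of projection angles over `[0, pi)` (>= 16).
#' @param n_detectors Number of detector bins (must be at least the image
#'   diagonal in pixels at projection time).
#' @return An object of class `ct_geometry`.
#' @export
ct_geometry <- function(n_angles = 180L, n_detectors = 367L) {
  if (n_angles < 16L) stop("n_angles must be >= 16")
  structure(list(n_angles = as.integer(n_angles),
                 n_detectors = as.integer(n_detectors),
                 model = "parallel-beam"),
            class = "ct_geometry")
}

fbp_filters <- c("ram-lak", "shepp-logan", "hann")

#' Imaging-source profile
#'
#' A simulated "manufacturer": incident photon fluence per detector bin
#' (dose surrogate), electronic noise level in photon-count units, and the
#' reconstruction filter. These three dials give each source a distinct
#' noise magnitude and texture.
#'
#' @param source_id Character label.
#' @param I0 Incident photon count per detector bin (> 0).
#' @param sigma_e Electronic noise standard deviation, in counts (>= 0).
#' @param filter Reconstruction filter, one of `"ram-lak"`,
#'   `"shepp-logan"`, `"hann"`.
#' @param geometry A [ct_geometry()].
#' @return An object of class `source_profile`.
#' @export
source_profile <- function(source_id, I0, sigma_e = 0, filter = "hann",
                           geometry = ct_geometry()) {
  if (I0 <= 0) stop("I0 must be positive")
  if (sigma_e < 0) stop("sigma_e must be nonnegative")
  filter <- match.arg(filter, fbp_filters)
  stopifnot(inherits(geometry, "ct_geometry"))
  structure(list(source_id = as.character(source_id), I0 = I0,
                 sigma_e = sigma_e, filter = filter, geometry = geometry),
            class = "source_profile")
}

#' Default three-source profiles
#'
#' Three distinct dose regimes (I0 = 2e4 / 1e5 / 5e5 photons per bin at the
#' reference 256-pixel field of view) with decreasing electronic noise and
#' different reconstruction filters, so the simulated sources differ in
#' noise magnitude and texture. The incident fluence is scaled by
#' `(size/256)^2` so that smaller phantoms (with proportionally shorter
#' attenuation paths) stay in the same photon-starved, clinically noisy
#' count regime as the reference size.
#'
#' @param size Image side length the geometry must cover.
#' @return A list of three [source_profile()] objects.
#' @export
default_source_profiles <- function(size = 256L) {
  g <- ct_geometry(n_angles = max(90L, as.integer(round(size * 0.7))),
                   n_detectors = as.integer(ceiling(sqrt(2) * size)) + 2L)
  dose <- (size / 256)^2
  list(source_profile("A", I0 = 2e4 * dose, sigma_e = 8, filter = "hann", geometry = g),
       source_profile("B", I0 = 1e5 * dose, sigma_e = 4, filter = "shepp-logan", geometry = g),
       source_profile("C", I0 = 5e5 * dose, sigma_e = 2, filter = "ram-lak", geometry = g))
}

#' Reduced-scale low-dose study profiles
#'
#' Source profiles for the 64-pixel desk-scale study (and the bundled test
#' corpus). Each simulated "manufacturer" differs in all three dials —
#' incident fluence, electronic noise, and reconstruction filter — chosen
#' jointly so that every source is photon-noise-limited at this field of
#' view (its quantum noise dominates the filtered-back-projection
#' discretisation floor) and the three reconstructed noise levels are
#' clearly separated (roughly 4 dB of spread), mirroring how reconstruction
#' choices and dose jointly shape a scanner's noise texture.
#'
#' @param size Image side length in pixels (default 64).
#' @return A list of three [source_profile()] objects.
#' @export
low_dose_study_profiles <- function(size = 64L) {
  g <- ct_geometry(n_angles = max(90L, as.integer(round(size * 0.7))),
                   n_detectors = as.integer(ceiling(sqrt(2) * size)) + 2L)
  dose <- (size / 64)^2
  list(source_profile("A", I0 = 400 * dose, sigma_e = 2, filter = "ram-lak", geometry = g),
       source_profile("B", I0 = 600 * dose, sigma_e = 4, filter = "shepp-logan", geometry = g),
       source_profile("C", I0 = 250 * dose, sigma_e = 8, filter = "hann", geometry = g))
}

#' Parallel-beam forward projection (Radon transform)
#'
#' Line integrals of a square attenuation map over `n_angles` uniformly
#' spaced angles, sampled by bilinear interpolation at half-pixel arc steps.
#' Linear in its input.
#'
#' @param image Square numeric matrix (attenuation, 1/mm) or `ct_slice`
#'   (converted from HU).
#' @param geometry A [ct_geometry()]; `n_detectors` must cover the image
#'   diagonal.
#' @return `n_angles x n_detectors` matrix of line integrals.
#' @export
forward_project <- function(image, geometry) {
  stopifnot(inherits(geometry, "ct_geometry"))
  # attenuation is physically nonnegative; reconstructed slices can ring
  # slightly below -1000 HU, which would otherwise give negative mu
  if (inherits(image, "ct_slice")) image <- pmax(mu_from_hu(image$pixels), 0)
  if (nrow(image) != ncol(image)) stop("forward_project requires a square image")
  diagonal <- sqrt(2) * nrow(image)
  if (geometry$n_detectors < diagonal)
    stop(sprintf("n_detectors = %d does not cover the image diagonal (%.1f px)",
                 geometry$n_detectors, diagonal))
  cpp_radon_fw(image, geometry$n_angles, geometry$n_detectors, 0.5)
}

#' Inject low-dose noise into a sinogram
#'
#' Count-domain compound noise model: per detector bin with line integral
#' \eqn{p}, the recorded count is
#' \eqn{N \sim Poisson(I_0 e^{-p}) + Normal(0, \sigma_e^2)} and the noisy
#' line integral is \eqn{\hat p = -\log(\max(N, 0.1) / I_0)} (the 0.1-count
#' floor guards against photon starvation). Deterministic given `rng_seed`.
#' Poisson draws with mean above 1e7 use the Gaussian limit.
#'
#' @param sinogram Nonnegative matrix of line integrals.
#' @param profile A [source_profile()] supplying `I0` and `sigma_e`.
#' @param rng_seed Integer seed.
#' @return Matrix of noisy line integrals, same shape as `sinogram`.
#' @export
inject_low_dose_noise <- function(sinogram, profile, rng_seed = 1L) {
  stopifnot(inherits(profile, "source_profile"))
  if (any(sinogram < 0)) stop("sinogram values must be nonnegative")
  if (profile$I0 <= 0) stop("I0 must be positive")
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  set.seed(rng_seed)
  on.exit(restore_seed(old))
  lam <- profile$I0 * exp(-sinogram)
  counts <- numeric(length(lam))
  big <- lam > 1e7
  if (any(!big)) counts[!big] <- stats::rpois(sum(!big), lam[!big])
  if (any(big)) counts[big] <- lam[big] + sqrt(lam[big]) * stats::rnorm(sum(big))
  if (profile$sigma_e > 0)
    counts <- counts + stats::rnorm(length(counts), 0, profile$sigma_e)
  phat <- -log(pmax(counts, 0.1) / profile$I0)
  matrix(phat, nrow(sinogram), ncol(sinogram))
}

# Discrete ramp-filter kernel (spatial domain), unit detector pitch:
# h[0] = 1/4, h[n] = -1/(pi^2 n^2) for odd n, 0 for even n != 0.
ramp_kernel_fft <- function(n_pad) {
  h <- numeric(n_pad)
  h[1] <- 0.25
  n <- seq_len(n_pad - 1)
  half <- pmin(n, n_pad - n)  # circulant distance
  odd <- half %% 2 == 1
  h[1 + n[odd]] <- -1 / (pi * half[odd])^2
  Re(stats::fft(h)) * 2
}

filter_transfer <- function(filter, n_pad) {
  ramp <- ramp_kernel_fft(n_pad)
  f <- c(seq(0, floor(n_pad / 2)), seq(-ceiling(n_pad / 2) + 1, -1)) / n_pad
  switch(filter,
         "ram-lak" = ramp,
         "shepp-logan" = {
           w <- pi * f
           s <- ifelse(w == 0, 1, sin(w) / ifelse(w == 0, 1, w))
           ramp * s
         },
         "hann" = ramp * (0.5 * (1 + cos(2 * pi * f))),
         stop(sprintf("unknown reconstruction filter '%s'", filter)))
}

#' Filtered back-projection reconstruction
#'
#' Frequency-domain ramp filtering (with optional Shepp-Logan or Hann
#' apodisation) of each projection, followed by backprojection with linear
#' detector interpolation onto the original grid.
#'
#' @param sinogram `n_angles x n_detectors` matrix of line integrals.
#' @param geometry The [ct_geometry()] used for projection.
#' @param filter One of `"ram-lak"`, `"shepp-logan"`, `"hann"`.
#' @param size Output image side length in pixels.
#' @param as_hu If `TRUE` (default) return a `ct_slice` in HU, otherwise the
#'   raw attenuation matrix.
#' @return A `ct_slice` or attenuation matrix.
#' @export
fbp_reconstruct <- function(sinogram, geometry, filter = "ram-lak", size,
                            as_hu = TRUE) {
  stopifnot(inherits(geometry, "ct_geometry"))
  filter <- match.arg(filter, fbp_filters)
  nd <- ncol(sinogram)
  n_pad <- 2^ceiling(log2(2 * nd))
  H <- filter_transfer(filter, n_pad)
  filt <- matrix(0, nrow(sinogram), nd)
  for (a in seq_len(nrow(sinogram))) {
    p <- c(sinogram[a, ], numeric(n_pad - nd))
    q <- Re(stats::fft(stats::fft(p) * H, inverse = TRUE)) / n_pad
    filt[a, ] <- q[seq_len(nd)]
  }
  mu <- cpp_radon_bp(filt, as.integer(size)) * pi / (2 * geometry$n_angles)
  if (as_hu) ct_slice(hu_from_mu(mu), source_id = "fbp") else mu
}

#' Simulate a low-dose / normal-dose pair
#'
#' Full simulation chain: the clean slice is converted to attenuation,
#' forward projected, degraded with the profile's count-domain noise, and
#' reconstructed by FBP with the profile's filter. The clean slice is kept
#' as the normal-dose reference.
#'
#' @param ndct A `ct_slice` (the clean, normal-dose image).
#' @param profile A [source_profile()].
#' @param rng_seed Integer seed for the noise draw.
#' @return A `paired_slice` carrying the profile's `source_id`.
#' @export
simulate_pair <- function(ndct, profile, rng_seed = 1L) {
  stopifnot(inherits(ndct, "ct_slice"), inherits(profile, "source_profile"))
  sino <- forward_project(ndct, profile$geometry)
  noisy <- inject_low_dose_noise(sino, profile, rng_seed = rng_seed)
  ld <- fbp_reconstruct(noisy, profile$geometry, profile$filter,
                        size = nrow(ndct$pixels))
  ld$source_id <- profile$source_id
  nd <- ndct
  nd$source_id <- profile$source_id
  paired_slice(ld, nd)
}

#' Build a multisource paired corpus on disk
#'
#' Generates `n_pairs_per_source` random phantoms per source, simulates the
#' low-dose counterpart under each source's profile, writes the slices and a
#' manifest with deterministic 8:1:1 train/val/test splits, and records all
#' profile parameters as JSON. The whole corpus is a pure function of
#' (`phantom`, `profiles`, `rng_seed`).
#'
#' @param out_dir Output directory (created if missing).
#' @param n_pairs_per_source Pairs per source.
#' @param profiles List of [source_profile()]s (one per source).
#' @param phantom A [phantom_spec()] template (its `rng_seed` is ignored;
#'   per-pair seeds derive from `rng_seed`).
#' @param rng_seed Master seed.
#' @param split_fractions Train/val/test weights, default 8:1:1.
#' @param format Slice container format (see [write_slice()]).
#' @param reference `"fbp"` (default): the normal-dose reference is the
#'   noiseless filtered-back-projection reconstruction of the phantom under
#'   the source's own geometry and filter — a band-limited, scanner-like
#'   normal-dose image, as in projection-domain low-dose synthesis from
#'   clinical normal-dose scans, so the low-dose image differs from its
#'   reference by noise alone. `"phantom"`: the mathematical phantom itself
#'   is the reference (the pair then also contains the reconstruction
#'   bias).
#' @return The manifest data frame, invisibly; files are written under
#'   `out_dir`.
#' @export
build_multisource_corpus <- function(out_dir, n_pairs_per_source = 200L,
                                     profiles = default_source_profiles(),
                                     phantom = phantom_spec(),
                                     rng_seed = 17L,
                                     split_fractions = c(8, 1, 1),
                                     format = "rds",
                                     reference = c("fbp", "phantom")) {
  reference <- match.arg(reference)
  stopifnot(length(profiles) >= 1L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ext <- switch(format, tiff16 = "tif", txt = "txt", rds = "rds",
                stop(sprintf("unsupported corpus format '%s'", format)))
  rows <- list()
  for (si in seq_along(profiles)) {
    prof <- profiles[[si]]
    sp <- make_split(n_pairs_per_source, fractions = split_fractions,
                     rng_seed = rng_seed + si)
    assign_split <- character(n_pairs_per_source)
    assign_split[sp$train] <- "train"
    assign_split[sp$val] <- "val"
    assign_split[sp$test] <- "test"
    for (k in seq_len(n_pairs_per_source)) {
      pair_seed <- (rng_seed * 1000L + si * 100000L + k) %% .Machine$integer.max
      spec_k <- phantom
      spec_k$rng_seed <- pair_seed
      nd <- generate_phantom(spec_k)
      nd$source_id <- prof$source_id
      if (reference == "fbp") {
        sino <- forward_project(nd, prof$geometry)
        nd <- fbp_reconstruct(sino, prof$geometry, prof$filter,
                              size = nrow(nd$pixels))
        nd$source_id <- prof$source_id
      }
      pair <- simulate_pair(nd, prof, rng_seed = pair_seed + 1L)
      lp <- sprintf("%s_ldct_%04d.%s", prof$source_id, k, ext)
      np <- sprintf("%s_ndct_%04d.%s", prof$source_id, k, ext)
      write_slice(pair$ldct, file.path(out_dir, lp), format = format)
      write_slice(pair$ndct, file.path(out_dir, np), format = format)
      rows[[length(rows) + 1L]] <- data.frame(
        source_id = prof$source_id, ldct_path = lp, ndct_path = np,
        split = assign_split[k], stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  write_manifest(manifest, file.path(out_dir, "manifest.tsv"))
  prof_json <- lapply(profiles, function(p)
    list(source_id = p$source_id, I0 = p$I0, sigma_e = p$sigma_e,
         filter = p$filter,
         geometry = list(n_angles = p$geometry$n_angles,
                         n_detectors = p$geometry$n_detectors,
                         model = p$geometry$model)))
  jsonlite::write_json(list(rng_seed = rng_seed, phantom = unclass(phantom),
                            profiles = prof_json),
                       file.path(out_dir, "profiles.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  attr(manifest, "dir") <- normalizePath(out_dir)
  invisible(manifest)
}
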