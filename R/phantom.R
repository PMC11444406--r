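#' Specification of a synthetic lesion phantom
#'
#' Describes a mammography-like test image: a stationary textured background
#' with one or more bright lesion blobs of irregular, fuzzy boundary, plus a
#' crisp binary ground-truth mask. Phantoms are fully determined by their
#' spec, including the seed, so identical specs generate bit-identical
#' phantoms.
#'
#' The background is Gaussian noise smoothed with a kernel of width
#' `texture_scale` and standardised to mean 0, SD 1, so `contrast` is the
#' lesion elevation in background-SD units. Lesions are ellipses whose radius
#' is modulated by low-order (2nd-4th harmonic) radial perturbations of total
#' amplitude at most 0.3 of the radius, emulating the irregular masses and
#' distortions seen in screening data. The mask records the unblurred lesion
#' support; only the image intensity is softened by `boundary_sigma`, so the
#' ground truth stays crisp while the image boundary is fuzzy.
#'
#' @param height,width Image size in pixels.
#' @param n_lesions Number of lesions (>= 0).
#' @param radius_range Length-2 numeric, min and max lesion semi-axis in
#'   pixels. The maximum must be smaller than `min(height, width) / 2`.
#' @param contrast Lesion mean elevation above background, in units of the
#'   background SD (>= 0).
#' @param boundary_sigma Gaussian blur (pixels) applied to the lesion edge in
#'   the image only.
#' @param texture_scale Correlation length (pixels) of the background texture.
#' @param seed Integer seed; fixes background, geometry and everything else.
#' @return An object of class `phantom_spec`.
#' @seealso [generate_phantom()], [generate_dataset()]
#' @export
phantom_spec <- function(height = 64, width = 64, n_lesions = 1,
                         radius_range = c(4, 10), contrast = 3,
                         boundary_sigma = 1.5, texture_scale = 12,
                         seed = 1L) {
  if (height < 1 || width < 1) stopf("invalid spec: non-positive image size")
  if (n_lesions < 0) stopf("invalid spec: n_lesions must be >= 0")
  if (length(radius_range) != 2 || radius_range[1] <= 0 ||
      radius_range[1] > radius_range[2])
    stopf("invalid spec: radius_range must be increasing and positive")
  if (radius_range[2] >= min(height, width) / 2)
    stopf("invalid spec: max radius %.1f does not fit inside a %dx%d frame",
          radius_range[2], height, width)
  if (contrast < 0) stopf("invalid spec: contrast must be >= 0")
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_lesions = as.integer(n_lesions),
                 radius_range = as.numeric(radius_range),
                 contrast = contrast, boundary_sigma = boundary_sigma,
                 texture_scale = texture_scale, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate one synthetic phantom
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `phantom`: a list with `image` (numeric matrix,
#'   background standardised to mean 0 / SD 1), `mask` (binary 0/1 matrix on
#'   the unblurred lesion support) and `spec`.
#' @examples
#' ph <- generate_phantom(phantom_spec(seed = 7))
#' mean(ph$image[ph$mask == 1]) > mean(ph$image[ph$mask == 0])
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$height; w <- spec$width
  with_seed(spec$seed, {
    bg <- matrix(stats::rnorm(h * w), h, w)
    bg <- gauss_blur(bg, spec$texture_scale)
    s <- stats::sd(as.vector(bg))
    if (s > 0) bg <- (bg - mean(bg)) / s
    mask <- matrix(0, h, w)
    if (spec$n_lesions > 0) {
      rmax <- spec$radius_range[2]
      margin <- ceiling(1.3 * rmax) + 1
      lo <- min(margin + 1, floor(min(h, w) / 2))
      rows <- matrix(rep.int(seq_len(h), w), h, w)
      cols <- matrix(rep(seq_len(w), each = h), h, w)
      for (i in seq_len(spec$n_lesions)) {
        cy <- stats::runif(1, lo, h - lo + 1)
        cx <- stats::runif(1, lo, w - lo + 1)
        a <- stats::runif(1, spec$radius_range[1], rmax)
        b <- stats::runif(1, spec$radius_range[1], rmax)
        phi <- stats::runif(1, 0, 2 * pi)
        amp <- stats::runif(3, 0, 0.1)        # harmonics m = 2..4, sum <= 0.3
        phs <- stats::runif(3, 0, 2 * pi)
        dx <- cols - cx; dy <- rows - cy
        xr <- cos(phi) * dx + sin(phi) * dy
        yr <- -sin(phi) * dx + cos(phi) * dy
        rho <- sqrt((xr / a)^2 + (yr / b)^2)
        th <- atan2(yr, xr)
        lim <- 1 + amp[1] * cos(2 * th + phs[1]) +
          amp[2] * cos(3 * th + phs[2]) + amp[3] * cos(4 * th + phs[3])
        mask[rho <= lim] <- 1
      }
    }
    edge <- gauss_blur(mask, spec$boundary_sigma)
    structure(list(image = bg + spec$contrast * edge, mask = mask,
                   spec = spec), class = "phantom")
  })
}

#' Generate a seeded phantom dataset with a manifest
#'
#' Draws `n` per-item seeds from the master `seed` (disjoint streams), builds
#' one phantom per item (geometry resampled per item) and records a manifest.
#'
#' @param spec Template [phantom_spec()]; its `seed` field is overridden per
#'   item.
#' @param n Number of phantoms (>= 1).
#' @param seed Master integer seed for deriving item seeds.
#' @return Object of class `phantom_dataset`: list with `phantoms` (list of
#'   `phantom`) and `manifest` (data frame with id, seed, n_lesions, area_px).
#' @export
generate_dataset <- function(spec, n, seed = spec$seed) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (length(n) != 1 || n < 1) stopf("invalid argument: n must be >= 1")
  n <- as.integer(n)
  item_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
  phantoms <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- spec
    sp$seed <- item_seeds[i]
    phantoms[[i]] <- generate_phantom(sp)
  }
  manifest <- data.frame(
    id = sprintf("phantom_%04d", seq_len(n)),
    seed = item_seeds,
    n_lesions = spec$n_lesions,
    area_px = vapply(phantoms, function(p) sum(p$mask), numeric(1))
  )
  structure(list(phantoms = phantoms, manifest = manifest, spec = spec),
            class = "phantom_dataset")
}

#' Write a phantom dataset to disk
#'
#' Images are written as 16-bit grayscale PNGs (min-max scaled per image, the
#' scale recorded in the manifest), masks as 8-bit 0/255 PNGs, plus a
#' `manifest.csv`.
#'
#' @param dataset A [generate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_phantom_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "phantom_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- dataset$manifest
  man$intensity_min <- NA_real_
  man$intensity_max <- NA_real_
  for (i in seq_along(dataset$phantoms)) {
    ph <- dataset$phantoms[[i]]
    rng <- range(ph$image)
    man$intensity_min[i] <- rng[1]
    man$intensity_max[i] <- rng[2]
    u <- if (diff(rng) > 0) (ph$image - rng[1]) / diff(rng) else ph$image * 0
    write_png16(u, file.path(dir, paste0(man$id[i], "_image.png")))
    write_mask(ph$mask, file.path(dir, paste0(man$id[i], "_mask.png")))
  }
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(man, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom %dx%d, %d lesion(s), mask area %d px, seed %d>\n",
              nrow(x$image), ncol(x$image), x$spec$n_lesions,
              as.integer(sum(x$mask)), x$spec$seed))
  invisible(x)
}

#' @export
print.phantom_dataset <- function(x, ...) {
  cat(sprintf("<phantom_dataset: %d phantoms, %dx%d, mean mask area %.1f px>\n",
              length(x$phantoms), x$spec$height, x$spec$width,
              mean(x$manifest$area_px)))
  invisible(x)
}
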