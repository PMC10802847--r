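# Synthetic CT phantom: a tubular bone-like structure (cortical shell in the
# 1150-1250 HU band) embedded in soft tissue and air, with fracture gaps or
# transverse displacements at known slice ranges, plus matching ground-truth
# bounding boxes. Stands in for patient series so every pipeline stage is
# testable end to end.

#' Specification of a synthetic CT phantom
#'
#' Describes one phantom case: a hollow tube of cortical-level HU along the
#' scan axis, interrupted by fracture descriptors. The seed fully determines
#' the generated volume (noise is drawn from a truncated Gaussian, clipped
#' at 3 standard deviations, so the default noise never crosses the cortical
#' HU band edges and the thresholded shell stays exact).
#'
#' @param shape integer length-3 `(rows, cols, slices)`; 512 x 512 in-plane
#'   by default, matching typical CT matrices and the detector input size.
#' @param pixel_spacing mm/pixel along X and Y (default 0.8, a typical
#'   extremity CT field of view).
#' @param slice_thickness mm (default 1).
#' @param center in-plane tube centre in 0-based pixel coordinates (default
#'   image centre).
#' @param radius_outer,radius_inner cortical shell radii in pixels
#'   (defaults 20 and 13: roughly a 16 mm outer radius with a 5.6 mm
#'   cortex at 0.8 mm/pixel, in range for a tibial shaft).
#' @param cortical_hu HU of the cortical shell (default 1200, inside the
#'   1150-1250 segmentation band).
#' @param hu_soft background soft-tissue HU inside the body cylinder
#'   (default -50).
#' @param hu_air HU outside the body (default -1000).
#' @param body_radius radius of the soft-tissue cylinder in pixels
#'   (default `4 * radius_outer`, clipped to the grid).
#' @param fractures list of fracture descriptors. Each is a list with
#'   `slices` (0-based inclusive slice range `c(from, to)`) and either
#'   `type = "gap"` with `angle` (wedge centre, degrees) and `width`
#'   (wedge angular width, degrees) — the cortical ring is interrupted over
#'   that angular sector — or `type = "displacement"` with `shift`
#'   (`c(dx, dy)` pixels) translating the whole ring transversely.
#' @param noise_sd HU noise standard deviation (default 10; truncated at
#'   3 sd). Set 0 for noiseless phantoms.
#' @param seed integer RNG seed; identical specs give bit-identical output.
#' @return a list of class `PhantomSpec`.
#' @seealso [generatePhantom()]
#' @export
phantomSpec <- function(shape = c(512L, 512L, 40L),
                        pixel_spacing = c(0.8, 0.8),
                        slice_thickness = 1.0,
                        center = NULL,
                        radius_outer = 20, radius_inner = 13,
                        cortical_hu = 1200, hu_soft = -50, hu_air = -1000,
                        body_radius = NULL,
                        fractures = list(),
                        noise_sd = 10, seed = 1L) {
  if (radius_inner >= radius_outer) {
    .stopf("radius_inner (%g) must be < radius_outer (%g)",
           radius_inner, radius_outer)
  }
  if (cortical_hu < 1150 || cortical_hu > 1250) {
    .stopf("cortical_hu %g lies outside the configured cortical band [1150, 1250]",
           cortical_hu)
  }
  if (is.null(center)) center <- c((shape[2L] - 1) / 2, (shape[1L] - 1) / 2)
  if (is.null(body_radius)) {
    body_radius <- min(4 * radius_outer,
                       min(shape[1L], shape[2L]) / 2 - 2)
  }
  for (fr in fractures) {
    if (is.null(fr$slices) || length(fr$slices) != 2L) {
      .stopf("each fracture needs a length-2 'slices' range")
    }
    if (fr$slices[1L] < 0L || fr$slices[2L] >= shape[3L] ||
        fr$slices[1L] > fr$slices[2L]) {
      .stopf("fracture slice range [%d, %d] outside grid of %d slice(s)",
             fr$slices[1L], fr$slices[2L], shape[3L])
    }
  }
  structure(list(shape = as.integer(shape), pixel_spacing = pixel_spacing,
                 slice_thickness = slice_thickness, center = center,
                 radius_outer = radius_outer, radius_inner = radius_inner,
                 cortical_hu = cortical_hu, hu_soft = hu_soft,
                 hu_air = hu_air, body_radius = body_radius,
                 fractures = fractures, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "PhantomSpec")
}

# per-slice shell pixel mask for one fracture configuration
.phantom_shell_slice <- function(base, ang, frs, k) {
  shell <- base
  for (fr in frs) {
    if (k < fr$slices[1L] || k > fr$slices[2L]) next
    type <- if (is.null(fr$type)) "gap" else fr$type
    if (type == "gap") {
      diff <- abs(((ang - fr$angle + 180) %% 360) - 180)
      shell[shell & diff <= fr$width / 2] <- FALSE
    } else if (type == "displacement") {
      shifted <- matrix(FALSE, nrow(base), ncol(base))
      src_r <- seq_len(nrow(base)) - round(fr$shift[2L])
      src_c <- seq_len(ncol(base)) - round(fr$shift[1L])
      ok_r <- src_r >= 1L & src_r <= nrow(base)
      ok_c <- src_c >= 1L & src_c <= ncol(base)
      shifted[ok_r, ok_c] <- base[src_r[ok_r], src_c[ok_c]]
      shell <- shifted
    } else {
      .stopf("unknown fracture type '%s'", type)
    }
  }
  shell
}

#' Generate a synthetic CT phantom with ground truth
#'
#' Renders the phantom described by a [phantomSpec()]: a hollow cortical
#' tube in soft tissue and air, with each fracture either removing an
#' angular wedge of the shell (a gap) or displacing the ring transversely.
#' The ground-truth box on each affected slice is the tight axis-aligned
#' bounding box of the disrupted region — the symmetric difference between
#' the fractured and unfractured shell masks — stored in the 4-tuple
#' convention.
#'
#' @param spec a `PhantomSpec`.
#' @return a list with elements `volume` (a [VolumeGrid]), `truth` (a
#'   ground-truth [BoxSet], `score = NA`), `shell` (0/1 array: the as-built,
#'   post-fracture cortical shell voxels — the oracle for HU thresholding),
#'   `disrupted` (0/1 array: voxels added or removed by the fractures) and
#'   `spec`.
#' @examples
#' ph <- generatePhantom(phantomSpec(shape = c(64, 64, 8), radius_outer = 18,
#'                                   radius_inner = 12, noise_sd = 0,
#'   fractures = list(list(slices = c(3, 5), type = "gap",
#'                         angle = 0, width = 70))))
#' boxes(ph$truth)
#' @export
generatePhantom <- function(spec) {
  stopifnot(inherits(spec, "PhantomSpec"))
  nr <- spec$shape[1L]; nc <- spec$shape[2L]; ns <- spec$shape[3L]
  X <- matrix(seq_len(nc) - 1L, nr, nc, byrow = TRUE)
  Y <- matrix(seq_len(nr) - 1L, nr, nc)
  dx <- X - spec$center[1L]; dy <- Y - spec$center[2L]
  d <- sqrt(dx^2 + dy^2)
  ang <- (atan2(dy, dx) * 180 / pi) %% 360
  base <- d >= spec$radius_inner & d <= spec$radius_outer
  body <- d <= spec$body_radius

  vox <- array(spec$hu_air, c(nr, nc, ns))
  shell <- array(0L, c(nr, nc, ns))
  disrupted <- array(0L, c(nr, nc, ns))
  truth <- list()
  for (k in seq_len(ns) - 1L) {
    sl <- .phantom_shell_slice(base, ang, spec$fractures, k)
    plane <- matrix(spec$hu_air, nr, nc)
    plane[body] <- spec$hu_soft
    plane[sl] <- spec$cortical_hu
    vox[, , k + 1L] <- plane
    shell[, , k + 1L] <- sl
    diffm <- xor(sl, base)
    if (any(diffm)) {
      disrupted[, , k + 1L] <- diffm
      idx <- which(diffm, arr.ind = TRUE)
      truth[[length(truth) + 1L]] <- c(
        slice = k,
        x_start = min(idx[, 2L]) - 1L,
        y_start = min(idx[, 1L]) - 1L,
        x_extent = max(idx[, 2L]) - min(idx[, 2L]) + 1L,
        y_extent = max(idx[, 1L]) - min(idx[, 1L]) + 1L)
    }
  }
  if (spec$noise_sd > 0) {
    vox <- vox + .with_seed(spec$seed, {
      n <- stats::rnorm(length(vox), sd = spec$noise_sd)
      pmin(pmax(n, -3 * spec$noise_sd), 3 * spec$noise_sd)
    })
  }

  tb <- if (length(truth)) {
    tm <- do.call(rbind, truth)
    boxSet(slice_index = tm[, "slice"], x_start = tm[, "x_start"],
           y_start = tm[, "y_start"], x_extent = tm[, "x_extent"],
           y_extent = tm[, "y_extent"])
  } else boxSet()

  list(volume = volumeGrid(vox, pixel_spacing = spec$pixel_spacing,
                           slice_thickness = spec$slice_thickness),
       truth = tb, shell = shell, disrupted = disrupted, spec = spec)
}

#' Split cases into train/validation/test sets
#'
#' Partitions a case list into three disjoint, exhaustive subsets using a
#' seeded shuffle and largest-remainder rounding of the requested fractions
#' (so 10 cases at 60/10/30 percent give sizes 6/1/3, and 7 cases give
#' 4/1/2).
#'
#' @param cases a list or vector of cases (length >= 1).
#' @param fractions length-3 numeric `(train, val, test)` summing to 1.
#' @param seed integer seed for the shuffle.
#' @return a list with elements `train`, `val`, `test`.
#' @export
splitDataset <- function(cases, fractions = c(0.6, 0.1, 0.3), seed = 1L) {
  n <- length(cases)
  if (n < 1L) .stopf("at least one case is required")
  if (abs(sum(fractions) - 1) > 1e-6) {
    .stopf("fractions must sum to 1 (got %g)", sum(fractions))
  }
  raw_sz <- n * fractions
  sizes <- floor(raw_sz)
  rem <- n - sum(sizes)
  if (rem > 0L) {
    extra <- order(-(raw_sz - sizes))[seq_len(rem)]  # ties: train, val, test
    sizes[extra] <- sizes[extra] + 1L
  }
  perm <- .with_seed(seed, sample.int(n))
  idx <- split(perm, rep.int(c("train", "val", "test"), sizes))
  pick <- function(i) if (is.null(i)) cases[integer()] else cases[sort(i)]
  list(train = pick(idx$train), val = pick(idx$val), test = pick(idx$test))
}
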