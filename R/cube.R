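# Whole-lens hyperspectral cubes: spatial grids of 2D spectra.

# genotype/sample presets: host library, mean amyloid fraction of the lens,
# helix/coil shoulder weight, and the sample class used for normalization
GENOTYPE_PRESETS <- list(
  wt_mouse       = list(host = "mouse", amyloid_mean = 0.010, helix_weight = 0),
  r120g_mouse    = list(host = "mouse", amyloid_mean = 0.025, helix_weight = 0),
  juvenile_human = list(host = "human", amyloid_mean = 0.005, helix_weight = 0.2),
  cataract_human = list(host = "human", amyloid_mean = 0.040, helix_weight = 0.2),
  protein_aB     = list(host = "protein_aB", amyloid_mean = 0.010,
                        helix_weight = 0.1),
  protein_R120G  = list(host = "protein_R120G", amyloid_mean = 0.030,
                        helix_weight = 0.1)
)

sample_class_for <- function(preset, environment) {
  if (preset == "protein_aB") return("protein_aB")
  if (preset == "protein_R120G") return("protein_R120G")
  switch(tolower(environment),
         ffpe = "tissue_FFPE", frozen = "tissue_frozen",
         dried = "tissue_dried")
}

#' Construct a tissue cube
#'
#' @param pump_axis,probe_axis Shared frequency axes, cm^-1.
#' @param amplitude 4D array \code{[nx, ny, n_pump, n_probe]}.
#' @param mask Logical \code{nx x ny} matrix: inside the lens and not torn.
#' @param truth Optional \code{nx x ny} matrix of true per-pixel amyloid
#'   fraction in [0, 1] (generator output only).
#' @param meta Named metadata list.
#' @return Object of class \code{TissueCube}.
#' @export
tissue_cube <- function(pump_axis, probe_axis, amplitude, mask,
                        truth = NULL, meta = list()) {
  d <- dim(amplitude)
  if (length(d) != 4L || d[3] != length(pump_axis) ||
      d[4] != length(probe_axis))
    stop("amplitude must be [nx, ny, n_pump, n_probe] matching the axes")
  if (!is.logical(mask) || !all(dim(mask) == d[1:2]))
    stop("mask must be a logical nx x ny matrix")
  if (any(mask & !apply(is.finite(amplitude), c(1, 2), all)))
    stop("masked-in pixels must have finite amplitudes")
  if (!is.null(truth)) {
    if (!all(dim(truth) == d[1:2])) stop("truth must be nx x ny")
    if (any(truth < 0 | truth > 1, na.rm = TRUE))
      stop("truth amyloid fractions must lie in [0, 1]")
  }
  structure(list(pump_axis = pump_axis, probe_axis = probe_axis,
                 amplitude = amplitude, mask = mask, truth = truth,
                 meta = meta),
            class = "TissueCube")
}

#' @export
print.TissueCube <- function(x, ...) {
  cat(sprintf("<TissueCube %dx%d pixels (%d masked-in), %dx%d spectral grid%s>\n",
              dim(x$amplitude)[1], dim(x$amplitude)[2], sum(x$mask),
              dim(x$amplitude)[3], dim(x$amplitude)[4],
              if (is.null(x$meta$preset)) "" else
                paste0(", ", x$meta$preset)))
  invisible(x)
}

# pixel-wise Spectrum2D extraction
cube_pixel <- function(cube, i, j) {
  spectrum2d(cube$pump_axis, cube$probe_axis, cube$amplitude[i, j, , ],
              meta = c(cube$meta, list(pixel = c(i, j))))
}

# low-pass-filtered white noise on an nx x ny grid, rescaled to the target
# mean/sd, clipped to [0, 1]
smooth_random_field <- function(nx, ny, mean, sd, kernel_px = 3) {
  z <- matrix(stats::rnorm(nx * ny), nx, ny)
  if (kernel_px > 0) {
    half <- ceiling(3 * kernel_px)
    k <- stats::dnorm(-half:half, sd = kernel_px)
    k <- k / sum(k)
    # separable Gaussian blur with replicated edges
    pad_blur <- function(m) {
      idx <- pmin(pmax(seq_len(nrow(m) + 2 * half) - half, 1), nrow(m))
      mp <- m[idx, , drop = FALSE]
      out <- matrix(0, nrow(m), ncol(m))
      for (s in seq_along(k))
        out <- out + k[s] * mp[seq_len(nrow(m)) + s - 1L, , drop = FALSE]
      out
    }
    z <- pad_blur(z)
    z <- t(pad_blur(t(z)))
    z <- z / stats::sd(as.numeric(z))
  }
  pmin(pmax(mean + sd * (z - base::mean(z)), 0), 1)
}

# contiguous torn regions grown by random walk until 'n_target' pixels
grow_tears <- function(mask, n_target, n_tears = 2L) {
  torn <- matrix(FALSE, nrow(mask), ncol(mask))
  inside <- which(mask, arr.ind = TRUE)
  if (n_target <= 0 || nrow(inside) == 0) return(torn)
  seeds <- inside[sample.int(nrow(inside), min(n_tears, nrow(inside))), ,
                  drop = FALSE]
  frontier <- lapply(seq_len(nrow(seeds)), function(i) seeds[i, ])
  count <- 0L
  while (count < n_target && length(frontier) > 0) {
    pick <- sample.int(length(frontier), 1L)
    p <- frontier[[pick]]
    frontier[[pick]] <- NULL
    if (p[1] < 1 || p[2] < 1 || p[1] > nrow(mask) || p[2] > ncol(mask)) next
    if (!mask[p[1], p[2]] || torn[p[1], p[2]]) next
    torn[p[1], p[2]] <- TRUE
    count <- count + 1L
    nb <- list(p + c(1, 0), p - c(1, 0), p + c(0, 1), p - c(0, 1))
    frontier <- c(frontier, nb[sample.int(4)])
  }
  torn
}

#' Simulate a whole-lens 2DIR image cube
#'
#' Generates an elliptical lens-shaped tissue slice on an \code{nx x ny}
#' pixel grid. Each pixel's amide-I spectrum is a mixture of the host's
#' component bands: the amyloid-like beta-sheet fraction varies smoothly
#' across the lens around the genotype preset's mean, the helix/coil
#' shoulder weight is fixed per host (present for human lenses, absent for
#' mouse), and the native beta-sheet band takes the remaining weight.
#' Optional torn-tissue regions zero out the signal (noise only remains)
#' and are excluded from the stored mask; the true per-pixel amyloid
#' fraction is kept in \code{truth}.
#'
#' @param preset Genotype/sample preset name: one of
#'   \code{"wt_mouse"}, \code{"r120g_mouse"}, \code{"juvenile_human"},
#'   \code{"cataract_human"}, \code{"protein_aB"}, \code{"protein_R120G"}.
#' @param nx,ny Spatial grid size, both >= 8.
#' @param environment Preservation environment preset
#'   (\code{"frozen"}, \code{"dried"}, \code{"ffpe"}).
#' @param amyloid_field_params List: \code{mean} (defaults to the preset
#'   mean), \code{sd} (default \code{mean / 2}), \code{kernel_px} smoothing
#'   width (default 3).
#' @param tear_params List: \code{fraction} of lens pixels torn (default 0),
#'   \code{n_tears} contiguous regions (default 2).
#' @param noise_sd Additive Gaussian noise SD per spectral point.
#' @param seed Integer seed; identical seeds give bit-identical cubes.
#' @param axes Frequency axes (default \code{\link{default_axes}()}).
#' @param oversample Probe-pixel box-averaging factor for rendering.
#' @return A \code{TissueCube} with \code{truth} filled in.
#' @export
simulate_cube <- function(preset, nx = 16L, ny = 16L, environment = "ffpe",
                          amyloid_field_params = list(),
                          tear_params = list(fraction = 0),
                          noise_sd = 0.005, seed = 1L,
                          axes = default_axes(), oversample = 5L) {
  if (!preset %in% names(GENOTYPE_PRESETS))
    stop("unknown preset '", preset, "'; valid presets: ",
         paste(names(GENOTYPE_PRESETS), collapse = ", "))
  if (nx < 8L || ny < 8L) stop("nx and ny must be >= 8")
  gp <- GENOTYPE_PRESETS[[preset]]
  f_mean <- amyloid_field_params$mean %||% gp$amyloid_mean
  f_sd <- amyloid_field_params$sd %||% (f_mean / 2)
  kernel_px <- amyloid_field_params$kernel_px %||% 3
  if (f_mean < 0 || f_mean > 1)
    stop("amyloid field mean must lie in [0, 1]")
  tear_frac <- tear_params$fraction %||% 0
  n_tears <- tear_params$n_tears %||% 2L

  set.seed(as.integer(seed))
  lib <- component_library(environment, gp$host)

  # elliptical lens silhouette filling ~80% of the grid extent
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  rx <- 0.42 * nx; ry <- 0.42 * ny
  ell <- outer(seq_len(nx), seq_len(ny),
               function(i, j) ((i - cx) / rx)^2 + ((j - cy) / ry)^2 <= 1)

  truth <- smooth_random_field(nx, ny, f_mean, f_sd, kernel_px)
  truth[!ell] <- NA_real_

  torn <- if (tear_frac > 0)
    grow_tears(ell, round(tear_frac * sum(ell)), n_tears)
  else matrix(FALSE, nx, ny)

  # component basis rendered once; pixels are linear combinations
  basis <- lapply(lib, function(cmp)
    render_component(cmp, axes$pump, axes$probe,
                     oversample = oversample)$amplitude)
  np <- length(axes$pump); nr <- length(axes$probe)
  # per-pixel weights; pixels are linear combinations of the basis
  live <- as.numeric(ell & !torn)
  w_h <- gp$helix_weight * live
  w_a <- pmin(as.numeric(ifelse(is.na(truth), 0, truth)),
              1 - gp$helix_weight) * live
  w_n <- live - w_h - w_a
  W <- cbind(w_n, w_a, w_h)
  B <- rbind(as.numeric(basis$native_beta), as.numeric(basis$amyloid_beta),
             as.numeric(basis$helix_coil))
  amp <- array(W %*% B, dim = c(nx, ny, np, nr))
  if (noise_sd > 0)
    amp <- amp + array(stats::rnorm(length(amp), sd = noise_sd), dim(amp))

  tissue_cube(axes$pump, axes$probe, amp, mask = ell & !torn, truth = truth,
              meta = list(preset = preset, host = gp$host,
                          environment = tolower(environment),
                          sample_class = sample_class_for(preset, environment),
                          helix_weight = gp$helix_weight,
                          noise_sd = noise_sd, seed = as.integer(seed),
                          tear_fraction = tear_frac))
}
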