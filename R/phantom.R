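#' Specification of a digital tumor phantom
#'
#' Describes one heterogeneous-uptake tumor embedded in a uniform
#' background, the image model the generator emulates: an eccentric
#' ellipsoid with a smooth random radial boundary perturbation, uniform
#' base uptake plus Gaussian "lumps" (focal hot spots), blurred with the
#' reconstruction point-spread function and degraded with additive
#' Gaussian noise truncated at 0.
#'
#' @param grid_shape voxels per axis (default 40^3).
#' @param spacing mm per axis (default 2 mm isotropic).
#' @param base_radius mean tumor radius in mm.
#' @param eccentricity per-axis unitless scale of the ellipsoid radii.
#' @param n_lumps,lump_amplitude count and SUV amplitude of Gaussian hot
#'   spots planted inside the tumor (lump sigma ~ base_radius / 3).
#' @param boundary_perturbation amplitude (mm) of the smooth random radial
#'   field added to the ellipsoid radius.
#' @param background_suv,tumor_base_suv background and tumor plateau SUV;
#'   `tumor_base_suv > background_suv >= 0`.
#' @param psf_fwhm full width at half maximum (mm) of the Gaussian
#'   post-filter (default 5 mm).
#' @param noise_sd SUV standard deviation of the additive noise.
#' @param seed integer; the phantom is a pure function of spec + seed.
#' @return a `phantom_spec` object.
#' @export
phantom_spec <- function(grid_shape = c(40L, 40L, 40L), spacing = c(2, 2, 2),
                         base_radius = 12, eccentricity = c(1, 1, 1),
                         n_lumps = 3L, lump_amplitude = 4,
                         boundary_perturbation = 2,
                         background_suv = 1, tumor_base_suv = 6,
                         psf_fwhm = 5, noise_sd = 0.2, seed = 1L) {
  stopifnot(tumor_base_suv > background_suv, background_suv >= 0,
            psf_fwhm >= 0, noise_sd >= 0, base_radius > 0,
            all(eccentricity > 0), n_lumps >= 0, lump_amplitude >= 0,
            boundary_perturbation >= 0)
  structure(list(grid_shape = as.integer(grid_shape),
                 spacing = as.numeric(spacing),
                 base_radius = base_radius, eccentricity = eccentricity,
                 n_lumps = as.integer(n_lumps),
                 lump_amplitude = lump_amplitude,
                 boundary_perturbation = boundary_perturbation,
                 background_suv = background_suv,
                 tumor_base_suv = tumor_base_suv,
                 psf_fwhm = psf_fwhm, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

## Smooth random directional field: sum of a few random plane-wave
## harmonics evaluated on unit directions; amplitude-normalized.
.radial_field <- function(units, amplitude, rng_n = 6L) {
  if (amplitude <= 0) return(rep(0, nrow(units)))
  w <- matrix(stats::rnorm(rng_n * 3), rng_n, 3) * 2.2
  ph <- stats::runif(rng_n, 0, 2 * pi)
  a <- stats::rnorm(rng_n)
  f <- as.vector(cos(units %*% t(w) + matrix(ph, nrow(units), rng_n,
                                             byrow = TRUE)) %*% a)
  f * amplitude / max(abs(f))
}

#' Generate a tumor phantom
#'
#' Builds the ground-truth tumor support (perturbed ellipsoid), paints
#' background and tumor uptake plus interior lumps, applies the Gaussian
#' PSF and adds truncated Gaussian noise. The returned mask is the
#' pre-blur tumor support. Deterministic given `spec` (the seed is part of
#' the spec).
#'
#' @param spec a [phantom_spec()].
#' @return list with `volume` (a [pet_volume()], SUV) and `mask` (a
#'   [tumor_mask()] tagged `"ground_truth"`).
#' @export
make_tumor_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  d <- spec$grid_shape
  sp <- spec$spacing
  ctr <- (d + 1) / 2 * sp
  g <- expand.grid(i = seq_len(d[1]), j = seq_len(d[2]), k = seq_len(d[3]))
  pos <- cbind(g$i * sp[1], g$j * sp[2], g$k * sp[3])
  rel <- sweep(pos, 2, ctr)
  rho <- sqrt(rowSums(sweep(rel, 2, spec$eccentricity, `/`)^2))
  r_eucl <- sqrt(rowSums(rel^2))
  units <- rel / pmax(r_eucl, 1e-9)
  delta <- .radial_field(units, spec$boundary_perturbation)
  inside <- rho <= spec$base_radius + delta
  mask <- array(inside, d)
  if (!any(mask)) stop("phantom spec produced an empty tumor")
  if (touches_edge(mask)) {
    stop("tumor touches the grid boundary; enlarge grid_shape or shrink the tumor")
  }
  uptake <- array(spec$background_suv, d)
  uptake[mask] <- spec$tumor_base_suv
  if (spec$n_lumps > 0 && spec$lump_amplitude > 0) {
    in_idx <- which(inside)
    centers <- pos[sample(in_idx, spec$n_lumps, replace = TRUE), , drop = FALSE]
    amp <- stats::runif(spec$n_lumps, 0.5, 1) * spec$lump_amplitude
    lsig <- spec$base_radius / 3
    lump <- numeric(nrow(pos))
    for (l in seq_len(spec$n_lumps)) {
      d2 <- rowSums(sweep(pos, 2, centers[l, ])^2)
      lump <- lump + amp[l] * exp(-d2 / (2 * lsig^2))
    }
    lump[!inside] <- 0  # lumps live inside the tumor support
    uptake <- uptake + array(lump, d)
  }
  if (spec$psf_fwhm > 0) {
    sigma_vox <- spec$psf_fwhm / (2 * sqrt(2 * log(2))) / sp
    uptake <- gaussian_smooth_3d(uptake, sigma_vox)
  }
  if (spec$noise_sd > 0) {
    uptake <- uptake + array(stats::rnorm(prod(d), 0, spec$noise_sd), d)
  }
  uptake <- pmax(uptake, 0)
  pid <- sprintf("P%04d", spec$seed)
  list(volume = pet_volume(uptake, sp, "SUV", pid),
       mask = tumor_mask(mask, sp, "ground_truth", pid))
}

#' Generate a phantom cohort
#'
#' Draws per-patient phantom specs reproducibly from stated ranges
#' (uniform over each range) and generates the phantoms. Defaults emulate a
#' 45-patient cohort of irregular, heterogeneous-uptake tumors spanning a
#' wide MATV range.
#'
#' @param n_patients number of patients (>= 2), default 45.
#' @param seed integer master seed.
#' @param base_radius_range,lump_amplitude_range,boundary_perturbation_range,tumor_base_suv_range
#'   uniform sampling ranges for the per-patient spec fields.
#' @param n_lumps_range integer range for the lump count.
#' @param ... fixed fields passed through to [phantom_spec()].
#' @return list of `list(volume, mask)` pairs, one per patient.
#' @export
make_cohort <- function(n_patients = 45L, seed = 1L,
                        base_radius_range = c(8, 18),
                        lump_amplitude_range = c(2, 6),
                        boundary_perturbation_range = c(1, 4),
                        tumor_base_suv_range = c(4, 9),
                        n_lumps_range = c(1L, 5L), ...) {
  stopifnot(n_patients >= 2)
  set.seed(seed)
  draws <- data.frame(
    base_radius = stats::runif(n_patients, base_radius_range[1], base_radius_range[2]),
    lump_amplitude = stats::runif(n_patients, lump_amplitude_range[1], lump_amplitude_range[2]),
    boundary_perturbation = stats::runif(n_patients, boundary_perturbation_range[1],
                                         boundary_perturbation_range[2]),
    tumor_base_suv = stats::runif(n_patients, tumor_base_suv_range[1],
                                  tumor_base_suv_range[2]),
    n_lumps = sample(n_lumps_range[1]:n_lumps_range[2], n_patients, replace = TRUE),
    ecc2 = stats::runif(n_patients, 0.7, 1.3),
    ecc3 = stats::runif(n_patients, 0.7, 1.3),
    seed = seed * 10000L + seq_len(n_patients))
  lapply(seq_len(n_patients), function(p) {
    spec <- phantom_spec(base_radius = draws$base_radius[p],
                         n_lumps = draws$n_lumps[p],
                         lump_amplitude = draws$lump_amplitude[p],
                         boundary_perturbation = draws$boundary_perturbation[p],
                         tumor_base_suv = draws$tumor_base_suv[p],
                         eccentricity = c(1, draws$ecc2[p], draws$ecc3[p]),
                         seed = draws$seed[p], ...)
    ph <- make_tumor_phantom(spec)
    ph$volume$patient_id <- sprintf("P%02d", p)
    ph$mask$patient_id <- sprintf("P%02d", p)
    ph
  })
}
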