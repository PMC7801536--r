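#' Hounsfield units to mass density
#'
#' Piecewise-linear CT-number-to-density correlation in the spirit of the
#' stoichiometric (Schneider-type) calibrations used for voxel phantoms:
#' a linear air-to-water segment below 0 HU, a soft-tissue/bone ramp above
#' it, and a flatter high-mineral segment, continuous and monotone
#' throughout. Inputs outside \[-1024, 3000\] are clamped and counted in
#' the `n_clamped` attribute.
#'
#' @param hu Hounsfield units (vector or array).
#' @return density in g/cm^3, same shape, with attribute `n_clamped`.
#' @export
hu_to_density <- function(hu) {
  n_clamped <- sum(hu < -1024 | hu > 3000)
  h <- pmin(pmax(hu, -1024), 3000)
  h <- pmax(h, -1000)
  rho <- ifelse(h <= 0,
                1.0 + h * (1.0 - 0.00121) / 1000,
                ifelse(h <= 1600,
                       1.0 + 6.25e-4 * h,
                       2.0 + 1.0e-4 * (h - 1600)))
  if (!is.null(dim(hu))) dim(rho) <- dim(hu)
  attr(rho, "n_clamped") <- n_clamped
  rho
}

#' Default HU material bin table
#'
#' @return data.frame with columns `material` and `hu_min` (lower edge of
#'   each class; the first class is open below).
#' @export
default_material_table <- function() {
  data.frame(material = c("air", "lung", "soft_tissue", "bone"),
             hu_min = c(-Inf, -950, -200, 120))
}

#' Hounsfield units to material class
#'
#' Bins HU into coarse material classes (default: air, lung, soft tissue,
#' bone). The bin table is configurable; finer schemes can be supplied the
#' same way.
#'
#' @param hu Hounsfield units.
#' @param table bin table as from [default_material_table()].
#' @return integer array of class indices with a `materials` attribute
#'   naming the classes.
#' @export
hu_to_material <- function(hu, table = default_material_table()) {
  idx <- findInterval(hu, table$hu_min)
  idx[idx < 1L] <- 1L
  if (!is.null(dim(hu))) dim(idx) <- dim(hu)
  attr(idx, "materials") <- table$material
  idx
}

#' Build a voxel phantom from a CT volume
#'
#' @param hu 3-D array of Hounsfield units.
#' @param spacing_mm voxel spacing in mm, length 3 (or scalar, isotropic).
#' @param material_table bin table for [hu_to_material()].
#' @return object of class `voxel_phantom`: arrays `density` (g/cm^3),
#'   `material`, `mass_kg`; scalars `voxel_volume_cm3`, `spacing_mm`;
#'   clamp counter `n_clamped`. Mass is exactly density x voxel volume.
#' @export
build_phantom <- function(hu, spacing_mm,
                          material_table = default_material_table()) {
  if (length(dim(hu)) != 3) stop("hu must be a 3-D array", call. = FALSE)
  if (length(spacing_mm) == 1) spacing_mm <- rep(spacing_mm, 3)
  if (any(spacing_mm <= 0)) stop("spacing must be > 0", call. = FALSE)
  rho <- hu_to_density(hu)
  vol_cm3 <- prod(spacing_mm / 10)
  mass <- rho * vol_cm3 / 1000  # g -> kg
  structure(list(density = rho,
                 material = hu_to_material(hu, material_table),
                 mass_kg = mass,
                 voxel_volume_cm3 = vol_cm3,
                 spacing_mm = spacing_mm,
                 dim = dim(hu),
                 n_clamped = attr(rho, "n_clamped")),
            class = "voxel_phantom")
}

#' Mass of a masked region
#' @param phantom a [build_phantom()] result.
#' @param mask logical array of the same shape.
#' @return total mass in kg.
#' @export
region_mass <- function(phantom, mask) {
  stopifnot(inherits(phantom, "voxel_phantom"),
            identical(dim(mask), phantom$dim))
  sum(phantom$mass_kg[mask])
}

#' @export
print.voxel_phantom <- function(x, ...) {
  cat(sprintf(
    "<voxel_phantom>  %s voxels at %s mm, total mass %.3f kg (%d HU clamped)\n",
    paste(x$dim, collapse = "x"), paste(x$spacing_mm, collapse = "x"),
    sum(x$mass_kg), x$n_clamped))
  invisible(x)
}
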