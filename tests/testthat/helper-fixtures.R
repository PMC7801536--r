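# Shared fixtures: tiny phantoms and fictitious single-line sources.

tiny_water_phantom <- function(d = c(8, 8, 8), spacing_mm = 4) {
  build_phantom(array(0, d), spacing_mm)
}

# monoenergetic source helper
mono_nuclide <- function(kind, energy_mev, yield = 1, half_life_h = 1,
                         name = sprintf("%s-%g", kind, energy_mev)) {
  nuclide(name, half_life_h,
          data.frame(kind = kind, energy_mev = energy_mev, yield = yield))
}

# small synthetic study spec that keeps pipeline tests fast
small_spec <- function(seed = 1, sensitivity = 0.2, psf_fwhm_mm = 4) {
  org <- data.frame(
    name = c("body", "kidney", "bladder"),
    cx = c(16.5, 11, 22), cy = c(16.5, 16.5, 16.5), cz = c(10.5, 10.5, 10.5),
    ax = c(58, 16, 12), ay = c(52, 13, 12), az = c(36, 14, 10),
    hu = c(20, 30, 15),
    a0_bq_ml = c(5e3, 2.5e4, 1.5e4),
    lambda_bio = c(0.10, 0.35, -0.15))
  phantom_spec(dim = c(32, 32, 20), spacing_mm = 4, organs = org,
               seed = seed, sensitivity = sensitivity,
               psf_fwhm_mm = psf_fwhm_mm)
}

hsg_params <- function() {
  # fixed z_star_ref keeps most MKM tests independent of the spectrum
  # sampler; chain tests build their own params with the sampled default
  mkm_params(z_star_ref = 1.0)
}
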