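#' Embedded nuclear decay data
#'
#' Per-decay emission inventories and physical decay constants for the
#' nuclides relevant to targeted radionuclide therapy with this toolkit:
#' F-18, At-211 (with its short-lived alpha-emitting daughter Po-211),
#' I-131 and Lu-177. The data are compiled, compact summaries of published
#' ICRP-107-style decay tables shipped as human-readable JSON under
#' `inst/extdata/decay_data.json`. Continuous beta spectra are carried as
#' their mean energy (for dose bookkeeping) plus the spectrum endpoint
#' (for microdosimetric sampling).
#'
#' Tally convention: alpha lines feed the alpha dose component; every other
#' kind (beta particles, discrete electrons, photons via their secondary
#' electrons) feeds the beta dose component.
#'
#' @name decay_data
NULL

.decay_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "decay_data.json", package = "tatdose")
      cache <<- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    }
    cache
  }
})

.supported_kinds <- c("alpha", "beta_plus", "beta_minus",
                      "discrete_electron", "photon")
# kinds whose energy is tallied with the beta dose component
BETA_KINDS <- c("beta_plus", "beta_minus", "discrete_electron", "photon")

#' Construct a nuclide object
#'
#' Low-level constructor used both by [load_nuclide()] and for fictitious
#' single-line sources in tests and reference-radiation definitions.
#'
#' @param name nuclide label.
#' @param half_life_h physical half-life in hours (> 0).
#' @param emissions data frame with columns `kind` (one of `alpha`,
#'   `beta_plus`, `beta_minus`, `discrete_electron`, `photon`),
#'   `energy_mev` (> 0; mean energy for continuous beta spectra),
#'   `yield` (> 0, per parent decay) and optionally `endpoint_mev`.
#' @param daughters list of `list(nuclide = <nuclide>, branching = <frac>)`.
#' @return an object of class `nuclide`.
#' @export
nuclide <- function(name, half_life_h, emissions, daughters = list()) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(half_life_h) || half_life_h <= 0) {
    stop("half_life_h must be > 0", call. = FALSE)
  }
  emissions <- as.data.frame(emissions)
  req <- c("kind", "energy_mev", "yield")
  if (!all(req %in% names(emissions))) {
    stop("emissions needs columns kind, energy_mev, yield", call. = FALSE)
  }
  if (!all(emissions$kind %in% .supported_kinds)) {
    stop("unknown emission kind", call. = FALSE)
  }
  if (any(emissions$energy_mev <= 0) || any(emissions$yield <= 0)) {
    stop("emission energies and yields must be positive", call. = FALSE)
  }
  if (is.null(emissions$endpoint_mev)) emissions$endpoint_mev <- NA_real_
  br <- vapply(daughters, function(d) d$branching, numeric(1))
  if (length(br) && (any(br <= 0 | br > 1) || sum(br) > 1 + 1e-9)) {
    stop("daughter branching fractions must be in (0,1] and sum to <= 1",
         call. = FALSE)
  }
  structure(
    list(name = name, half_life_h = half_life_h,
         emissions = emissions[, c("kind", "energy_mev", "yield",
                                   "endpoint_mev")],
         daughters = daughters),
    class = "nuclide")
}

#' Load a supported nuclide from the embedded decay table
#'
#' @param name one of `"F-18"`, `"At-211"`, `"I-131"`, `"Lu-177"` (daughter
#'   nuclides appearing in their chains can also be loaded directly).
#' @return a [nuclide()] object with the daughter chain resolved recursively.
#' @examples
#' at <- load_nuclide("At-211")
#' physical_lambda(at)
#' @export
load_nuclide <- function(name) {
  tab <- .decay_table()$nuclides
  if (!name %in% names(tab)) {
    stop(sprintf("unsupported nuclide '%s'; available: %s", name,
                 paste(names(tab), collapse = ", ")), call. = FALSE)
  }
  rec <- tab[[name]]
  daughters <- list()
  if (length(rec$daughters) && NROW(rec$daughters) > 0) {
    dd <- as.data.frame(rec$daughters)
    daughters <- lapply(seq_len(nrow(dd)), function(i) {
      list(nuclide = load_nuclide(dd$name[i]), branching = dd$branching[i])
    })
  }
  nuclide(name, rec$half_life_h, as.data.frame(rec$emissions), daughters)
}

#' Physical decay constant
#'
#' @param nuc a [nuclide()] object.
#' @return `ln(2) / half_life` in 1/h.
#' @export
physical_lambda <- function(nuc) {
  stopifnot(inherits(nuc, "nuclide"))
  log(2) / nuc$half_life_h
}

#' Flatten a decay chain into per-parent-decay emissions
#'
#' Daughters with half-life not exceeding `truncation_h` are assumed to be
#' in transient equilibrium with the parent (instantaneous decay) and their
#' emissions are folded in, scaled by the branching fraction, recursively.
#' Longer-lived daughters contribute nothing and are reported in the
#' `dropped` attribute (name, branching, half-life) so the truncation is
#' auditable.
#'
#' @param nuc a [nuclide()] object, or an already flattened inventory data
#'   frame (returned unchanged, making the operation idempotent).
#' @param truncation_h daughter half-life cutoff in hours (default 24).
#' @return data frame of emission lines (`kind`, `energy_mev`, `yield`,
#'   `endpoint_mev`) per parent decay, class `chain_inventory`, with a
#'   `dropped` attribute.
#' @export
chain_inventory <- function(nuc, truncation_h = 24) {
  if (inherits(nuc, "chain_inventory")) return(nuc)
  stopifnot(inherits(nuc, "nuclide"))
  if (!is.numeric(truncation_h) || truncation_h <= 0) {
    stop("truncation_h must be > 0", call. = FALSE)
  }
  dropped <- data.frame(name = character(), branching = numeric(),
                        half_life_h = numeric())
  collect <- function(n, weight) {
    em <- n$emissions
    em$yield <- em$yield * weight
    out <- list(em)
    for (d in n$daughters) {
      if (d$nuclide$half_life_h <= truncation_h) {
        out <- c(out, collect(d$nuclide, weight * d$branching))
      } else {
        dropped <<- rbind(dropped, data.frame(
          name = d$nuclide$name, branching = weight * d$branching,
          half_life_h = d$nuclide$half_life_h))
      }
    }
    out
  }
  inv <- do.call(rbind, collect(nuc, 1))
  rownames(inv) <- NULL
  structure(inv, dropped = dropped, nuclide = nuc$name,
            class = c("chain_inventory", class(inv)))
}

#' Per-decay emitted energy by dose component
#'
#' Sums yield times energy over the flattened inventory, split into the
#' alpha component (alpha lines) and the beta component (beta particles,
#' discrete electrons and photons, per the tally convention).
#'
#' @param inv a [nuclide()] or flattened [chain_inventory()].
#' @param truncation_h passed to [chain_inventory()] when `inv` is a nuclide.
#' @return named numeric vector `c(alpha = MeV, beta = MeV)`.
#' @export
per_decay_energy <- function(inv, truncation_h = 24) {
  inv <- chain_inventory(inv, truncation_h)
  e <- inv$yield * inv$energy_mev
  c(alpha = sum(e[inv$kind == "alpha"]),
    beta = sum(e[inv$kind %in% BETA_KINDS]))
}

#' @export
print.nuclide <- function(x, ...) {
  cat(sprintf("<nuclide %s>  half-life %.4g h  (lambda_phy %.4g /h)\n",
              x$name, x$half_life_h, physical_lambda(x)))
  print(x$emissions)
  for (d in x$daughters) {
    cat(sprintf("  daughter %s (branching %.3f, half-life %.3g h)\n",
                d$nuclide$name, d$branching, d$nuclide$half_life_h))
  }
  invisible(x)
}
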