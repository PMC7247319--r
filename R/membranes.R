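# Lipid species and bilayer compositions, and the geometric/charge quantities
# derived from them. Cross-sectional areas are data, not constants: the
# shipped species table carries literature approximations (POPC/POPG 70 A^2,
# TOCL 130 A^2, MLCL 110 A^2) and every field is overridable per species.
# Charges assume full ionization at pH 7.5: cardiolipins dianionic, PG
# monoanionic.

#' Define a lipid species
#'
#' @param name Species identifier (e.g. `"POPC"`).
#' @param formal_charge Formal headgroup charge in elementary charges; must be
#'   0, -1 or -2 (zwitterionic, monoanionic, dianionic).
#' @param cross_sectional_area Lipid cross-sectional area in Angstrom^2;
#'   must be positive.
#' @return An object of class `lipid_species`.
#' @export
#' @examples
#' lipid_species("TOCL", -2, 130)
lipid_species <- function(name, formal_charge, cross_sectional_area) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!formal_charge %in% c(0, -1, -2))
    stop("formal_charge must be 0, -1 or -2 (got ", formal_charge, ")")
  if (!is.finite(cross_sectional_area) || cross_sectional_area <= 0)
    stop("cross_sectional_area must be positive")
  structure(list(name = name,
                 formal_charge = as.integer(formal_charge),
                 cross_sectional_area = as.numeric(cross_sectional_area)),
            class = "lipid_species")
}

#' @export
print.lipid_species <- function(x, ...) {
  cat(sprintf("<lipid_species> %s: charge %+d e, area %.0f A^2\n",
              x$name, x$formal_charge, x$cross_sectional_area))
  invisible(x)
}

#' Built-in lipid species library
#'
#' Reads the plain-text species table shipped with the package (name, formal
#' charge, cross-sectional area in Angstrom^2).
#'
#' @return Named list of [lipid_species] objects.
#' @export
#' @examples
#' names(lipid_library())
lipid_library <- function() {
  path <- system.file("extdata", "lipid_species.tsv", package = "membind",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(tab)), function(i)
    lipid_species(tab$name[i], tab$formal_charge[i],
                  tab$cross_sectional_area_A2[i]))
  names(out) <- tab$name
  out
}

#' Specify a bilayer composition
#'
#' A membrane is an ordered set of lipid species with mole fractions summing
#' to one, plus a temperature. Species may be named (resolved from
#' [lipid_library()]) or passed as [lipid_species] objects to override the
#' default charge/area.
#'
#' @param fractions Named numeric vector of mole fractions (names are species
#'   identifiers), e.g. `c(TOCL = 0.2, POPC = 0.8)`.
#' @param species Optional list of [lipid_species] objects overriding or
#'   extending the built-in library.
#' @param temperature Absolute temperature in K (default 298.15).
#' @return An object of class `membrane_spec` with a `components` data frame
#'   (name, mole_fraction, formal_charge, cross_sectional_area).
#' @export
#' @examples
#' membrane_spec(c(TOCL = 0.2, POPC = 0.8))
membrane_spec <- function(fractions, species = NULL, temperature = 298.15) {
  if (length(fractions) == 0L) stop("empty composition")
  if (is.null(names(fractions)) || any(!nzchar(names(fractions))))
    stop("fractions must be a named vector of mole fractions")
  if (any(fractions < 0)) stop("mole fractions must be >= 0")
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("mole fractions must sum to 1 (got ", format(sum(fractions)), ")")
  if (!is.finite(temperature) || temperature <= 0)
    stop("temperature must be positive (K)")

  lib <- lipid_library()
  if (!is.null(species)) {
    for (sp in species) {
      stopifnot(inherits(sp, "lipid_species"))
      lib[[sp$name]] <- sp
    }
  }
  missing <- setdiff(names(fractions), names(lib))
  if (length(missing))
    stop("unknown lipid species: ", paste(missing, collapse = ", "))

  comp <- data.frame(
    name = names(fractions),
    mole_fraction = as.numeric(fractions),
    formal_charge = vapply(names(fractions),
                           function(n) lib[[n]]$formal_charge, integer(1)),
    cross_sectional_area = vapply(names(fractions),
                                  function(n) lib[[n]]$cross_sectional_area,
                                  numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(components = comp, temperature = temperature),
            class = "membrane_spec")
}

#' @export
print.membrane_spec <- function(x, ...) {
  cat("<membrane_spec> T =", x$temperature, "K\n")
  print(x$components, row.names = FALSE)
  cat(sprintf("mean area %.1f A^2; sigma_max %.4f C/m^2\n",
              mean_lipid_area(x), intrinsic_surface_charge_density(x)))
  invisible(x)
}

#' Effective (outer-leaflet) lipid concentration
#'
#' Only the outer leaflet of a unilamellar vesicle is accessible to an
#' externally added peptide, so the effective lipid concentration is taken as
#' half of the total.
#'
#' @param total_lipid Total lipid concentration (M); must be non-negative.
#' @return `total_lipid / 2`, same units.
#' @export
#' @examples
#' effective_lipid_concentration(200e-6)  # 100 uM
effective_lipid_concentration <- function(total_lipid) {
  if (any(!is.finite(total_lipid)) || any(total_lipid < 0))
    stop("total_lipid must be non-negative")
  total_lipid / 2
}

#' Mole-fraction-weighted mean lipid cross-sectional area
#'
#' Assumes ideal mixing of the component lipids.
#'
#' @param spec A [membrane_spec].
#' @return Mean area per lipid in Angstrom^2.
#' @export
#' @examples
#' mean_lipid_area(membrane_spec(c(TOCL = 0.2, POPC = 0.8)))  # 82
mean_lipid_area <- function(spec) {
  stopifnot(inherits(spec, "membrane_spec"))
  with(spec$components, sum(mole_fraction * cross_sectional_area))
}

#' Intrinsic (maximal) surface charge density
#'
#' The fully ionized surface charge density sigma_max of a bilayer:
#' the mole-fraction-weighted mean headgroup charge divided by the mean
#' cross-sectional area, in C/m^2. Negative for anionic membranes.
#'
#' @param spec A [membrane_spec].
#' @return sigma_max in C/m^2.
#' @export
#' @examples
#' intrinsic_surface_charge_density(membrane_spec(c(TOCL = 0.2, POPC = 0.8)))
intrinsic_surface_charge_density <- function(spec) {
  stopifnot(inherits(spec, "membrane_spec"))
  area <- mean_lipid_area(spec)
  if (area <= 0) stop("mean lipid area must be positive")
  qbar <- with(spec$components, sum(mole_fraction * formal_charge))
  qbar * .const$e / (area * .A2_TO_M2)
}

#' Area of the peptide binding site
#'
#' With a fitted stoichiometry of `n` lipids per bound peptide, the binding
#' site footprint is `n` times the mean lipid area.
#'
#' @param n Lipids per bound peptide (> 0).
#' @param spec A [membrane_spec].
#' @return Binding-site area in Angstrom^2.
#' @export
#' @examples
#' binding_site_area(6.9, membrane_spec(c(TOCL = 0.2, POPC = 0.8)))
binding_site_area <- function(n, spec) {
  if (any(!is.finite(n)) || any(n <= 0)) stop("n must be positive")
  n * mean_lipid_area(spec)
}

#' Anionic lipids per bound peptide
#'
#' @param n Lipids per bound peptide (> 0).
#' @param spec A [membrane_spec].
#' @return `n` times the total anionic mole fraction (dimensionless count).
#' @export
#' @examples
#' anionic_lipids_per_peptide(6.9, membrane_spec(c(TOCL = 0.2, POPC = 0.8)))
anionic_lipids_per_peptide <- function(n, spec) {
  if (any(!is.finite(n)) || any(n <= 0)) stop("n must be positive")
  stopifnot(inherits(spec, "membrane_spec"))
  frac_anionic <- with(spec$components, sum(mole_fraction[formal_charge < 0]))
  n * frac_anionic
}
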