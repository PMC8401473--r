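#' Shear and bulk modulus from Young's modulus and Poisson's ratio
#'
#' For an isotropic material, `mu = E / (2 (1 + nu))` and
#' `K = E / (3 (1 - 2 nu))`. These are the initial (small-strain) moduli used
#' by the nearly incompressible neo-Hookean law.
#'
#' @param E Young's modulus, kPa (> 0).
#' @param nu Poisson's ratio, in (0, 0.5); at 0.5 the bulk modulus diverges.
#' @return list with `mu` and `K` in kPa.
#' @export
derive_moduli <- function(E, nu) {
  if (any(E <= 0)) stop("Young's modulus must be positive")
  if (any(nu <= 0) || any(nu >= 0.5)) stop("Poisson's ratio must lie in (0, 0.5)")
  list(mu = E / (2 * (1 + nu)), K = E / (3 * (1 - 2 * nu)))
}

#' Per-tissue material parameters
#'
#' Defaults are the standard initial properties for breast tissue: adipose
#' E = 250 kPa, fibro-glandular E = 1875 kPa (stiffness ratio 7.5), skin
#' E = 1000 kPa, all at Poisson's ratio 0.49 (near incompressibility), with
#' mass densities 950 / 1020 / 1000 kg/m^3. Shear and bulk moduli are derived
#' via [derive_moduli()].
#'
#' @param E_adipose,E_gland,E_skin Young's moduli in kPa. When `E_gland` is
#'   `NULL` it is slaved to `stiffness_ratio * E_adipose`.
#' @param nu Poisson's ratio shared by all tissues.
#' @param rho_adipose,rho_gland,rho_skin mass densities in kg/m^3.
#' @param stiffness_ratio fibro-glandular / adipose modulus ratio (default 7.5).
#' @return object of class `breastfem_materials`: a list with one entry per
#'   tissue (`adipose`, `gland`, `skin`), each holding `E`, `nu`, `rho`, `mu`,
#'   `K`, plus the `stiffness_ratio`.
#' @export
material_params <- function(E_adipose = 250, E_gland = NULL, E_skin = 1000,
                            nu = 0.49, rho_adipose = 950, rho_gland = 1020,
                            rho_skin = 1000, stiffness_ratio = 7.5) {
  if (is.null(E_gland)) E_gland <- stiffness_ratio * E_adipose
  mk <- function(E, rho) {
    m <- derive_moduli(E, nu)
    list(E = E, nu = nu, rho = rho, mu = m$mu, K = m$K)
  }
  structure(
    list(adipose = mk(E_adipose, rho_adipose),
         gland = mk(E_gland, rho_gland),
         skin = mk(E_skin, rho_skin),
         stiffness_ratio = E_gland / E_adipose),
    class = "breastfem_materials"
  )
}

#' @export
print.breastfem_materials <- function(x, ...) {
  cat("<Materials> (kPa, kg/m^3)\n")
  for (t in c("adipose", "gland", "skin")) {
    p <- x[[t]]
    cat(sprintf("  %-8s E=%-8.4g nu=%.3g rho=%-5g mu=%.4g K=%.4g\n",
                t, p$E, p$nu, p$rho, p$mu, p$K))
  }
  cat(sprintf("  gland/adipose stiffness ratio: %.4g\n", x$stiffness_ratio))
  invisible(x)
}

# Per-element material vectors for the assembly kernels, in the internal
# mm-mN-kPa-kg-s unit system (density kg/m^3 -> kg/mm^3 via 1e-9).
element_materials <- function(mesh, materials) {
  tiss <- mesh$element_tissue
  key <- c(adipose = "adipose", gland = "gland", `fibro-glandular` = "gland",
           skin = "skin")
  tn <- key[tiss]
  if (any(is.na(tn))) stop("unknown element tissue tag(s): ",
                           paste(unique(tiss[is.na(tn)]), collapse = ", "))
  list(mu = vapply(tn, function(t) materials[[t]]$mu, 0),
       K = vapply(tn, function(t) materials[[t]]$K, 0),
       rho = vapply(tn, function(t) materials[[t]]$rho, 0) * 1e-9)
}
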