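# Kinetic parameters and the compound capture quantities derived from them.
#
# Internal unit system: lengths in cm, times in hours. Inputs are accepted in
# the units the experimental literature quotes them in (kon in M^-1 min^-1,
# ke/koff in min^-1, DL in cm^2/s) and converted on ingestion.

#' Avogadro constant (mol^-1)
#' @keywords internal
AVOGADRO <- 6.02214076e23

#' Kinetic parameters of SASP ligand emission, capture and senescence induction
#'
#' Bundles the raw physical constants of the monolayer signalling model in the
#' units they are usually quoted in. All downstream computation converts to a
#' consistent cm/hour system via [derive_compound_params()].
#'
#' @param NE Ligands emitted per senescent cell per hour (count h^-1). The
#'   default 2887 is an estimate for the combined IL-6, IL-8 and Activin A
#'   output of a senescent fibroblast.
#' @param ND Ligands that must be bound per hour to induce senescence
#'   (count h^-1).
#' @param DL Ligand diffusion coefficient (cm^2 s^-1).
#' @param sigma Cell area fraction of the monolayer (dimensionless, in (0,1)).
#' @param rcell Cell radius (cm).
#' @param Rtot Receptors per cell (count).
#' @param ke Endocytosis (internalisation) rate of bound complexes (min^-1).
#' @param koff Ligand-receptor dissociation rate (min^-1).
#' @param kon Forward binding rate constant (M^-1 min^-1).
#' @param bound_forever Set `TRUE` to declare the no-unbinding/no-endocytosis
#'   regime explicitly when `ke = koff = 0`; ligands then stay where they first
#'   bind and the internalisation probability is taken as 1.
#'
#' @return An object of class `kinetic_params` (a named list).
#' @examples
#' p <- kinetic_params(ND = 20)
#' derive_compound_params(p)
#' @export
kinetic_params <- function(NE = 2887, ND = 10, DL = 1e-6, sigma = 0.35,
                           rcell = 10e-4, Rtot = 1e5, ke = 0.2, koff = 0.2,
                           kon = 1e8, bound_forever = FALSE) {
  p <- list(NE = NE, ND = ND, DL = DL, sigma = sigma, rcell = rcell,
            Rtot = Rtot, ke = ke, koff = koff, kon = kon,
            bound_forever = isTRUE(bound_forever))
  validate_kinetic_params(p)
  class(p) <- "kinetic_params"
  p
}

validate_kinetic_params <- function(p) {
  num <- c("NE", "ND", "DL", "sigma", "rcell", "Rtot", "ke", "koff", "kon")
  for (f in num) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("kinetic parameter '", f, "' must be a single finite number")
    if (v < 0) stop("kinetic parameter '", f, "' must be >= 0")
  }
  if (p$sigma <= 0 || p$sigma >= 1)
    stop("sigma must lie strictly between 0 and 1")
  if (p$rcell <= 0) stop("rcell must be > 0")
  if (p$DL <= 0) stop("DL must be > 0")
  if (p$ke + p$koff <= 0 && !isTRUE(p$bound_forever))
    stop("undefined internalisation probability: ke = koff = 0; set ",
         "bound_forever = TRUE to declare the no-unbinding regime")
  invisible(p)
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Kinetic parameters (monolayer SASP signalling)\n")
  cat(sprintf("  NE    = %g ligands/h        ND  = %g ligands/h\n", x$NE, x$ND))
  cat(sprintf("  DL    = %g cm^2/s           sigma = %g\n", x$DL, x$sigma))
  cat(sprintf("  rcell = %g cm               Rtot  = %g receptors\n",
              x$rcell, x$Rtot))
  cat(sprintf("  ke    = %g /min  koff = %g /min  kon = %g /M/min\n",
              x$ke, x$koff, x$kon))
  if (x$bound_forever) cat("  regime: no unbinding / no endocytosis (nu = 1)\n")
  invisible(x)
}

#' Derive compound capture parameters from kinetic constants
#'
#' Converts the raw kinetic constants to a consistent cm/hour system and
#' evaluates the homogenised-capture quantities of ligand trapping on a
#' cell-covered plane:
#' \itemize{
#'   \item internalisation probability `nu = ke / (ke + koff)`;
#'   \item per-cell trapping rate constant
#'     `kappa = kon * Rtot / (pi * rcell^2 * NA)` (cm/h);
#'   \item Damkohler number `Da = rcell * kappa / DL`;
#'   \item effective trapping rate of the homogeneous surface
#'     `keff = kappa * sigma / (1 + pi * Da / 4)` (cm/h);
#'   \item capture length `a = 1.1 * DL / (nu * keff)` (cm), the half-distance
#'     of the cumulative binding-distance law;
#'   \item autocrine probabilities `Pau = Da / (Da + 4/pi)` (first binding) and
#'     `Pau_in = nu * Da / (nu * Da + 4/pi)` (internalisation).
#' }
#'
#' @param p A [kinetic_params()] object.
#' @return An object of class `derived_params` with fields `nu`, `kappa`
#'   (cm/h), `Da`, `keff` (cm/h), `a` (cm), `Pau`, `Pau_in`, plus the unit
#'   conversions `DL_cmh` (cm^2/h) and `kappa_cms` (cm/s) used by the
#'   Brownian simulator.
#' @export
derive_compound_params <- function(p) {
  stopifnot(inherits(p, "kinetic_params"))
  validate_kinetic_params(p)
  nu <- if (p$ke + p$koff > 0) p$ke / (p$ke + p$koff) else 1
  DL_cmh <- p$DL * 3600                      # cm^2/s -> cm^2/h
  kon_cm3h <- p$kon * 1000 * 60              # M^-1 min^-1 -> cm^3 mol^-1 h^-1
  kappa <- kon_cm3h * p$Rtot / (pi * p$rcell^2 * AVOGADRO)   # cm/h
  Da <- p$rcell * kappa / DL_cmh
  keff <- kappa * p$sigma / (1 + pi * Da / 4)                # cm/h
  if (nu <= 0 || keff <= 0)
    stop("capture length undefined: nu * keff must be > 0")
  a <- 1.1 * DL_cmh / (nu * keff)                            # cm
  d <- list(nu = nu, kappa = kappa, Da = Da, keff = keff, a = a,
            Pau = Da / (Da + 4 / pi),
            Pau_in = nu * Da / (nu * Da + 4 / pi),
            DL_cmh = DL_cmh, kappa_cms = kappa / 3600)
  class(d) <- "derived_params"
  d
}

#' @export
print.derived_params <- function(x, ...) {
  cat("Derived capture parameters (cm / hour system)\n")
  cat(sprintf("  nu = %.4g   kappa = %.4g cm/h   Da = %.4g\n",
              x$nu, x$kappa, x$Da))
  cat(sprintf("  keff = %.4g cm/h   capture length a = %.4g cm\n",
              x$keff, x$a))
  cat(sprintf("  Pau (first binding) = %.4g   Pau (internalised) = %.4g\n",
              x$Pau, x$Pau_in))
  invisible(x)
}

#' Read kinetic parameters from a flat YAML/JSON configuration section
#'
#' Keys mirror the literature symbol names (`NE`, `ND`, `DL`, `sigma`,
#' `rcell`, `Rtot`, `ke`, `koff`, `kon`, `bound_forever`). Unknown keys are
#' rejected so that unit mistakes (for instance supplying `kon_s`) fail loudly.
#'
#' @param x A named list, e.g. one section of a parsed YAML config.
#' @return A [kinetic_params()] object.
#' @export
kinetic_params_from_list <- function(x) {
  allowed <- names(formals(kinetic_params))
  unknown <- setdiff(names(x), allowed)
  if (length(unknown))
    stop("unknown kinetic parameter key(s): ", paste(unknown, collapse = ", "))
  do.call(kinetic_params, x)
}
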