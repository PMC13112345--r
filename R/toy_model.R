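#' Titratable-particle membrane surrogate
#'
#' A one-dimensional model of a single titratable site moving along the
#' membrane normal `z` (nm; the phosphate plane sits near `z = 0`, water is
#' on the positive side).  Each protonation state `s` in
#' (`"protonated"`, `"deprotonated"`) feels its own potential `U_s(z)`, a sum
#' of analytic terms (Gaussian wells/barriers and sigmoid steps), anchored so
#' that `U_s(z_water_ref) = 0` for both states.  Together with the aqueous
#' reference pKa this fixes the full semi-grand-canonical thermodynamics in
#' closed form: `pKa(z)`, titration curves, state-resolved densities and the
#' potential of mean force are all analytic, which is what makes the model a
#' ground-truth oracle for the sampling schemes and estimators in this
#' package.
#'
#' @section Potential terms:
#' Each term is a list with fields `shape` (`"gaussian"` or
#' `"sigmoid-step"`), `amplitude` (kJ/mol), `center` (nm) and `width` (nm,
#' positive).  A gaussian term is `A * exp(-(z - c)^2 / (2 w^2))`; a
#' sigmoid-step term is `A / (1 + exp((z - c)/w))`, tending to `A` on the
#' membrane side (`z -> -Inf`) and 0 in water.
#'
#' @param residue_class `"acid"` (ionized when deprotonated, e.g. Asp) or
#'   `"base"` (ionized when protonated, e.g. His).
#' @param pka_w Aqueous reference pKa (dimensionless).
#' @param terms_protonated,terms_deprotonated Lists of potential terms (see
#'   above) for each protonation state; may be empty (flat potential).
#' @param temperature Kelvin.
#' @param z_water_ref Position (nm) in the water phase where both state
#'   potentials vanish by convention.  Default 2.0 nm (= +20 Angstrom, the
#'   outermost water window of the umbrella ladders used here).
#' @return An object of class `toy_model`.
#' @examples
#' m <- toy_model("acid", pka_w = 3.94,
#'                terms_deprotonated = list(gaussian_term(12, 0, 0.5)))
#' analytic_pka(0, m)     # shifted up: ionized state penalised in membrane
#' analytic_pka(2, m)     # == 3.94 at the water reference
#' @seealso [analytic_pka()], [analytic_density()], [analytic_pmf()]
#' @export
toy_model <- function(residue_class = c("acid", "base"),
                      pka_w,
                      terms_protonated = list(),
                      terms_deprotonated = list(),
                      temperature = 300,
                      z_water_ref = 2.0) {
  residue_class <- match.arg(residue_class)
  stopifnot(is.numeric(pka_w), length(pka_w) == 1L, is.finite(pka_w),
            is.numeric(z_water_ref), length(z_water_ref) == 1L,
            is.finite(z_water_ref))
  th <- thermo(temperature)
  model <- structure(
    list(residue_class = residue_class,
         pka_w = pka_w,
         terms = list(protonated = lapply(terms_protonated, validate_term),
                      deprotonated = lapply(terms_deprotonated, validate_term)),
         temperature = temperature,
         thermo = th,
         z_water_ref = z_water_ref),
    class = "toy_model")
  model
}

#' @rdname toy_model
#' @param amplitude,center,width Term parameters (kJ/mol, nm, nm).
#' @export
gaussian_term <- function(amplitude, center, width) {
  validate_term(list(shape = "gaussian", amplitude = amplitude,
                     center = center, width = width))
}

#' @rdname toy_model
#' @export
sigmoid_term <- function(amplitude, center, width) {
  validate_term(list(shape = "sigmoid-step", amplitude = amplitude,
                     center = center, width = width))
}

validate_term <- function(term) {
  stopifnot(is.list(term),
            all(c("shape", "amplitude", "center", "width") %in% names(term)))
  if (!term$shape %in% c("gaussian", "sigmoid-step"))
    stop("unknown potential term shape: ", term$shape)
  stopifnot(is.finite(term$amplitude), is.finite(term$center),
            is.finite(term$width), term$width > 0)
  term[c("shape", "amplitude", "center", "width")]
}

#' @export
print.toy_model <- function(x, ...) {
  nterm <- vapply(x$terms, length, integer(1))
  cat(sprintf(
    "toy_model: %s, pKa_w = %g, T = %g K, z_water_ref = %g nm\n",
    x$residue_class, x$pka_w, x$temperature, x$z_water_ref))
  cat(sprintf("  terms: %d protonated, %d deprotonated\n",
              nterm[["protonated"]], nterm[["deprotonated"]]))
  invisible(x)
}

#' Which protonation state is the ionized one
#'
#' Acids ionize by deprotonation, bases by protonation.  This single mapping
#' is used everywhere downstream (ionized-population profiles, pKa gates).
#'
#' @param model A [toy_model()].
#' @return `"deprotonated"` or `"protonated"`.
#' @export
ionized_state <- function(model) {
  if (model$residue_class == "acid") "deprotonated" else "protonated"
}

raw_terms_energy <- function(z, terms) {
  u <- numeric(length(z))
  for (term in terms) {
    u <- u + switch(term$shape,
      "gaussian" =
        term$amplitude * exp(-(z - term$center)^2 / (2 * term$width^2)),
      "sigmoid-step" =
        term$amplitude / (1 + exp((z - term$center) / term$width)))
  }
  u
}

raw_terms_gradient <- function(z, terms) {
  g <- numeric(length(z))
  for (term in terms) {
    g <- g + switch(term$shape,
      "gaussian" = {
        term$amplitude * exp(-(z - term$center)^2 / (2 * term$width^2)) *
          (-(z - term$center) / term$width^2)
      },
      "sigmoid-step" = {
        e <- exp((z - term$center) / term$width)
        -term$amplitude * e / (term$width * (1 + e)^2)
      })
  }
  g
}

check_state <- function(s) {
  if (!all(s %in% c("protonated", "deprotonated")))
    stop("unknown protonation state label: ",
         paste(setdiff(unique(s), c("protonated", "deprotonated")),
               collapse = ", "))
  s
}

#' State-dependent potential energy of the surrogate
#'
#' `U_s(z)` is the sum of the model's analytic terms for state `s` minus the
#' same sum at `z_water_ref`, so both state potentials vanish in water by
#' construction.  Vectorised over `z`.
#'
#' @param z Position(s) along the membrane normal, nm.
#' @param s Protonation state, `"protonated"` or `"deprotonated"`.
#' @param model A [toy_model()].
#' @return Energy in kJ/mol, same length as `z`.
#' @export
potential_energy <- function(z, s, model) {
  check_state(s)
  stopifnot(length(s) == 1L)
  terms <- model$terms[[s]]
  raw_terms_energy(z, terms) - raw_terms_energy(model$z_water_ref, terms)
}

#' Gradient dU_s/dz of the state potential (kJ/mol/nm)
#'
#' @inheritParams potential_energy
#' @return `dU_s/dz` at `z`, kJ/mol/nm.
#' @export
potential_gradient <- function(z, s, model) {
  check_state(s)
  stopifnot(length(s) == 1L)
  raw_terms_gradient(z, model$terms[[s]])
}

#' Analytic pKa profile of the surrogate
#'
#' `pKa(z) = pKa_w + beta * (U_deprot(z) - U_prot(z)) / ln(10)`: penalising
#' the deprotonated state raises the local pKa, so an acid whose ionized
#' (deprotonated) form is excluded from the membrane core has its pKa shifted
#' up inside the membrane, and a base shifted down — the neutral form is
#' favoured in apolar media.  Equals `pKa_w` at `z_water_ref`.
#'
#' @inheritParams potential_energy
#' @return pKa value(s), same length as `z`.
#' @export
analytic_pka <- function(z, model) {
  du <- potential_energy(z, "deprotonated", model) -
    potential_energy(z, "protonated", model)
  model$pka_w + model$thermo$beta * du / log(10)
}

#' Closed-form deprotonated fraction (Henderson-Hasselbalch)
#'
#' `f_deprot(z, pH) = 1 / (1 + 10^(pKa(z) - pH))`.
#'
#' @inheritParams potential_energy
#' @param pH External pH (scalar or same length as `z`).
#' @return Fraction in `[0, 1]`.
#' @export
analytic_deprot_fraction <- function(z, pH, model) {
  1 / (1 + 10^(analytic_pka(z, model) - pH))
}

#' Closed-form mean protonation at fixed position
#'
#' Complement of [analytic_deprot_fraction()]; this is the quantity the
#' Henderson-Hasselbalch fit consumes.
#'
#' @inheritParams analytic_deprot_fraction
#' @return Mean number of protons bound (0..1).
#' @export
analytic_protonation <- function(z, pH, model) {
  1 - analytic_deprot_fraction(z, pH, model)
}

state_log_weights <- function(z, pH, model) {
  # log semi-grand weights per state, up to a common constant:
  # w_deprot / w_prot = 10^(pH - pKa_w) * exp(-beta (U_dep - U_prot));
  # the chemical-potential part is identical for acids and bases, the
  # residue class only decides which state counts as ionized.
  b <- model$thermo$beta
  cbind(
    protonated   = -b * potential_energy(z, "protonated", model),
    deprotonated = -b * potential_energy(z, "deprotonated", model) +
      log(10) * (pH - model$pka_w))
}

#' Analytic position density marginalised over protonation
#'
#' `rho(z) propto sum_s w_s(pH) exp(-beta U_s(z))` with the semi-grand state
#' weights `w_deprot / w_prot = 10^(pH - pKa_w)`, normalised to sum to 1 on
#' the supplied grid.  Optionally includes a harmonic umbrella bias, giving
#' the exact stationary density of a biased constant-pH run.
#'
#' @param pH External pH.
#' @param model A [toy_model()].
#' @param grid Numeric vector of positions (nm) where the density is wanted;
#'   must be non-empty and cover the region of non-negligible density.
#' @param window Optional umbrella [window()]; its harmonic bias is added to
#'   both state potentials.
#' @return Numeric vector summing to 1 over `grid`.
#' @export
analytic_density <- function(pH, model, grid, window = NULL) {
  if (length(grid) == 0) stop("empty grid")
  lw <- state_log_weights(grid, pH, model)
  if (!is.null(window))
    lw <- lw - model$thermo$beta * harmonic_bias(grid, window)
  m <- max(lw)
  rho <- exp(lw[, 1] - m) + exp(lw[, 2] - m)
  rho / sum(rho)
}

#' Analytic potential of mean force at fixed pH
#'
#' `PMF(z) = -kT ln sum_s w_s(pH) exp(-beta U_s(z))`, anchored to a minimum
#' of 0 over the supplied grid.  This is the exact profile that WHAM applied
#' to umbrella runs of the surrogate should recover.
#'
#' @inheritParams analytic_density
#' @param grid Positions (nm).
#' @return Energy profile in kJ/mol, min 0 over `grid`.
#' @export
analytic_pmf <- function(pH, model, grid) {
  lw <- state_log_weights(grid, pH, model)
  m <- apply(lw, 1, max)
  lse <- m + log(exp(lw[, 1] - m) + exp(lw[, 2] - m))
  pmf <- -lse / model$thermo$beta
  pmf - min(pmf)
}
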