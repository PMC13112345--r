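#' Reference titratable residues and their simulation pH grids
#'
#' The aqueous reference pKa of each titratable amino-acid pentapeptide and
#' the four external pH values its constant-pH simulations use, as a
#' lookup table for configuring surrogate models and worked examples.
#'
#' @return Data.frame with columns `residue`, `class` (`acid`/`base`),
#'   `pka_w`, and `ph1`..`ph4` (the simulation pH ladder).
#' @examples
#' reference_residues()
#' @export
reference_residues <- function() {
  data.frame(
    residue = c("Asp", "Glu", "C-ter", "Cys", "Tyr", "His", "Lys", "N-ter"),
    class = c("acid", "acid", "acid", "acid", "acid",
              "base", "base", "base"),
    pka_w = c(3.94, 4.25, 3.67, 8.55, 9.84, 6.54, 10.40, 8.00),
    ph1 = c(3, 3, 3, 8, 9, 4.5, 8, 5),
    ph2 = c(4, 4, 4, 9, 10, 5.5, 9, 6),
    ph3 = c(5, 5, 5, 10, 11, 6.5, 10, 7),
    ph4 = c(6, 6, 6, 11, 12, 7.5, 11, 8),
    stringsAsFactors = FALSE)
}

#' @rdname reference_residues
#' @param residue Residue name as in `reference_residues()$residue`.
#' @return `ph_ladder_of`: the four simulation pH values of a residue.
#' @export
ph_ladder_of <- function(residue) {
  tab <- reference_residues()
  row <- tab[tab$residue == residue, ]
  if (nrow(row) != 1) stop("unknown residue: ", residue)
  as.numeric(row[, c("ph1", "ph2", "ph3", "ph4")])
}

#' Shipped surrogate models
#'
#' Ready-made [toy_model()]s: `asp_like_model()` is an acid (aqueous pKa
#' 3.94) whose ionized (deprotonated) state pays a sigmoid desolvation
#' penalty inside the membrane while the neutral form feels a shallow
#' interface well — so the pKa shifts up on insertion; `his_like_model()`
#' is the basic counterpart (aqueous pKa 6.54, ionized = protonated state
#' penalised, pKa shifts down).  Amplitudes are modest (a few kT to ~4 pKa
#' units at full insertion), typical of the shifts seen for titratable
#' residues at lipid interfaces.
#'
#' @param pka_w Override the aqueous reference pKa.
#' @return A [toy_model()].
#' @export
asp_like_model <- function(pka_w = 3.94) {
  toy_model("acid", pka_w = pka_w,
            terms_protonated = list(
              gaussian_term(-4, center = 0.2, width = 0.45)),
            terms_deprotonated = list(
              sigmoid_term(18, center = 0.1, width = 0.3)))
}

#' @rdname asp_like_model
#' @export
his_like_model <- function(pka_w = 6.54) {
  toy_model("base", pka_w = pka_w,
            terms_protonated = list(
              sigmoid_term(18, center = 0.1, width = 0.3)),
            terms_deprotonated = list(
              gaussian_term(-4, center = 0.2, width = 0.45)))
}

#' Draw i.i.d. positions from the analytic (optionally biased) density
#'
#' Samples bin centres of `grid` with the exact probabilities of
#' [analytic_density()] — the discretised stationary distribution of a
#' (possibly umbrella-biased) constant-pH run.  Used to feed estimators
#' with exactly distributed input, isolating estimator error from sampler
#' error.
#'
#' @param n Number of draws.
#' @param pH External pH.
#' @param model A [toy_model()].
#' @param grid Bin centres, nm.
#' @param window Optional umbrella [window()].
#' @return Numeric vector of positions (values of `grid`).
#' @export
sample_analytic_positions <- function(n, pH, model, grid, window = NULL) {
  p <- analytic_density(pH, model, grid, window = window)
  grid[sample.int(length(grid), n, replace = TRUE, prob = p)]
}

#' Synthetic titration records from the exact conditional
#'
#' Generates a record table whose positions are drawn from a supplied
#' sampler (default: uniform over `insertion_range`, giving every sliding
#' pKa bin comparable coverage) and whose protonation states come from the
#' model's exact conditional `P(deprotonated | z, pH)`.  This is the
#' ground-truth input of the pKa-profile pipeline: fitted bins should
#' recover [analytic_pka()].
#'
#' @param model A [toy_model()].
#' @param ph_values External pH ladder.
#' @param replicates Number of replicates.
#' @param n_per_ph Frames per (replicate, pH).
#' @param insertion_range `c(lo, hi)` in Angstrom for the default uniform
#'   position sampler.
#' @param position_sampler Optional function `n -> z positions (nm)`.
#' @return Record table in the [run_segment()] schema (no equilibration
#'   frames; `time` is the frame index).
#' @export
synth_titration_records <- function(model, ph_values, replicates = 3,
                                    n_per_ph = 2000,
                                    insertion_range = c(-13, 23),
                                    position_sampler = NULL) {
  if (is.null(position_sampler))
    position_sampler <- function(n)
      stats::runif(n, insertion_range[1] / 10, insertion_range[2] / 10)
  out <- vector("list", replicates * length(ph_values))
  i <- 0L
  for (r in seq_len(replicates)) {
    for (ph in ph_values) {
      z <- position_sampler(n_per_ph)
      p_deprot <- analytic_deprot_fraction(z, ph, model)
      s <- ifelse(stats::runif(n_per_ph) < p_deprot,
                  "deprotonated", "protonated")
      i <- i + 1L
      out[[i]] <- data.frame(
        time = seq_len(n_per_ph), replica_id = sprintf("r%d_pH%g", r, ph),
        replicate_index = r, pH = ph, window_id = NA_character_,
        z_nm = z, state = s, bias_kJmol = 0, equilibration_flag = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
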