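#' Umbrella window
#'
#' A harmonic restraint `V_m(xi) = (k_m/2) (xi - xi_m)^2` along the membrane
#' normal, defined by its reference coordinate `xi_ref` (nm) and force
#' constant `k` (kJ mol^-1 nm^-2).
#'
#' @param window_id Label (coerced to character).
#' @param xi_ref Reference reaction-coordinate value, nm.
#' @param k Force constant, kJ mol^-1 nm^-2; must be > 0.
#' @return An object of class `umbrella_window`.
#' @export
window <- function(window_id, xi_ref, k) {
  stopifnot(is.numeric(xi_ref), length(xi_ref) == 1L, is.finite(xi_ref),
            is.numeric(k), length(k) == 1L, is.finite(k), k > 0)
  structure(list(window_id = as.character(window_id),
                 xi_ref = xi_ref, k = k),
            class = "umbrella_window")
}

#' @export
print.umbrella_window <- function(x, ...) {
  cat(sprintf("umbrella_window %s: xi_ref = %g nm, k = %g kJ/mol/nm^2\n",
              x$window_id, x$xi_ref, x$k))
  invisible(x)
}

#' Harmonic umbrella bias energy and force
#'
#' `harmonic_bias` returns `(k/2)(xi - xi_ref)^2` (kJ/mol);
#' `harmonic_force` the matching restraint force `-k (xi - xi_ref)`
#' (kJ/mol/nm) used by the dynamics engine.  Vectorised over `xi`.
#'
#' @param xi Reaction-coordinate value(s), nm.
#' @param window An umbrella [window()] (or `NULL`, meaning no bias: energy
#'   and force are 0).
#' @return Numeric vector, same length as `xi`.
#' @export
harmonic_bias <- function(xi, window) {
  if (is.null(window)) return(numeric(length(xi)))
  0.5 * window$k * (xi - window$xi_ref)^2
}

#' @rdname harmonic_bias
#' @export
harmonic_force <- function(xi, window) {
  if (is.null(window)) return(numeric(length(xi)))
  -window$k * (xi - window$xi_ref)
}

#' REUS exchange exponent
#'
#' For configurations `i` (currently restrained by window `m`, at `xi_i`)
#' and `j` (window `n`, at `xi_j`) the Metropolis exponent for swapping the
#' two windows is
#' `Delta = beta * (V_m(xi_j) - V_m(xi_i) - V_n(xi_j) + V_n(xi_i))`,
#' antisymmetric under exchanging `(i, m) <-> (j, n)`.
#'
#' @param xi_i,xi_j Coordinates of the two configurations, nm.
#' @param win_m,win_n Their current umbrella [window()]s.
#' @param thermo A [thermo()] context.
#' @return Dimensionless exponent `Delta`.
#' @export
reus_delta <- function(xi_i, xi_j, win_m, win_n, thermo) {
  thermo$beta * (harmonic_bias(xi_j, win_m) - harmonic_bias(xi_i, win_m) -
                 harmonic_bias(xi_j, win_n) + harmonic_bias(xi_i, win_n))
}

#' pH-replica-exchange exponent
#'
#' Discrete-protonation pH-RE criterion for swapping the pH labels of two
#' replicas carrying `N_i`, `N_j` bound protons.  The semi-grand weight of
#' one site is `P(N | pH) propto 10^((pKa - pH) N)`, so the joint-weight
#' ratio of the swapped to the current assignment is
#' `10^((pH_i - pH_j)(N_i - N_j))`, giving the Metropolis exponent
#' `Delta = ln(10) * (pH_j - pH_i) * (N_i - N_j)`.  Moving the more
#' protonated configuration to the lower pH is favourable (`Delta < 0`);
#' the exponent is antisymmetric in the pair and the kernel satisfies
#' detailed balance with respect to the product of the per-replica
#' titration laws.
#'
#' @param n_i,n_j Proton counts of the two replicas (0 or 1 for a single
#'   site).
#' @param ph_i,ph_j Their current pH values.
#' @return Dimensionless exponent `Delta`.
#' @export
phre_delta <- function(n_i, n_j, ph_i, ph_j) {
  log(10) * (ph_j - ph_i) * (n_i - n_j)
}

#' Metropolis acceptance of an exchange
#'
#' Accept with probability `min(1, exp(-Delta))`; the uniform draw used for
#' the decision is recorded so every attempt is auditable.
#'
#' @param delta Exchange exponent (from [reus_delta()] or [phre_delta()]).
#' @param pair Optional length-2 label vector identifying the pair.
#' @return A list of class `exchange_decision` with fields `pair`, `delta`,
#'   `accepted`, `uniform_draw`.
#' @export
metropolis_accept <- function(delta, pair = c(NA, NA)) {
  u <- stats::runif(1)
  structure(list(pair = pair, delta = delta,
                 accepted = (delta <= 0) || (u < exp(-delta)),
                 uniform_draw = u),
            class = "exchange_decision")
}

#' Build an umbrella-window ladder
#'
#' Inclusive ladder of windows from `start` to `stop` (Angstrom, converted
#' to nm internally) at the given spacing, each assigned a force constant by
#' `k_rule`.  The published ladders are e.g. +20..-12 A at 2 A (17 windows,
#' k = 1000 kJ/mol/nm^2 throughout for plain umbrella sampling) and the
#' split-force variant with k = 500 over 20..8 A and k = 1000 over 6..-12 A.
#'
#' @param start,stop Ladder end points, Angstrom.  `start != stop`.
#' @param spacing Window spacing, Angstrom (> 0); must divide
#'   `|start - stop|` exactly (no silent truncation).
#' @param k_rule Either a single force constant (kJ mol^-1 nm^-2) applied to
#'   all windows, or a function `xi_ref_angstrom -> k` evaluated per window.
#' @return List of [window()]s ordered from `start` to `stop`, with ids
#'   `"W01"`, `"W02"`, ...
#' @examples
#' length(build_window_ladder(20, -12, 2, 1000))  # 17
#' # split force constants of the replica-exchange variant:
#' wl <- build_window_ladder(20, -12, 2, reus_k_rule())
#' @export
build_window_ladder <- function(start, stop, spacing, k_rule = 1000) {
  stopifnot(spacing > 0)
  if (start == stop) stop("start and stop must differ")
  span <- abs(start - stop)
  n_int <- span / spacing
  if (abs(n_int - round(n_int)) > 1e-9)
    stop(sprintf("spacing %g A does not divide the range |%g - %g| = %g A",
                 spacing, start, stop, span))
  xi_A <- seq(start, stop, by = if (stop > start) spacing else -spacing)
  kfun <- if (is.function(k_rule)) k_rule else function(xi) k_rule
  lapply(seq_along(xi_A), function(i)
    window(sprintf("W%02d", i), xi_ref = xi_A[i] / 10, k = kfun(xi_A[i])))
}

#' @rdname build_window_ladder
#' @param k_outer,k_inner Force constants for the water-phase and inserted
#'   regions (kJ mol^-1 nm^-2).
#' @param boundary Windows at or above this xi_ref (Angstrom) get `k_outer`;
#'   below it `k_inner`.  Default 7 A splits 20..8 from 6..-12.
#' @export
reus_k_rule <- function(k_outer = 500, k_inner = 1000, boundary = 7) {
  function(xi_A) if (xi_A >= boundary) k_outer else k_inner
}

#' Extend a pH ladder on the ionized side
#'
#' Appends two additional pH values continuing the ladder spacing on the
#' side that promotes ionization: higher pH for acids (anionic when
#' ionized), lower pH for bases (cationic).  This is the "extended" pH set
#' used to improve sampling of ionized species in umbrella runs.
#'
#' @param ladder Uniformly spaced numeric pH ladder, length >= 2.
#' @param residue_class `"acid"` or `"base"`.
#' @return Sorted extended ladder (length + 2).
#' @examples
#' extend_ph_ladder(c(3, 4, 5, 6), "acid")   # 3 4 5 6 7 8
#' extend_ph_ladder(c(8, 9, 10, 11), "base") # 6 7 8 9 10 11
#' @export
extend_ph_ladder <- function(ladder, residue_class = c("acid", "base")) {
  residue_class <- match.arg(residue_class)
  if (length(ladder) < 2) stop("ladder spacing undefined for fewer than 2 values")
  ladder <- sort(ladder)
  d <- diff(ladder)
  if (diff(range(d)) > 1e-9) stop("ladder is not uniformly spaced")
  h <- d[1]
  if (residue_class == "acid")
    c(ladder, max(ladder) + h, max(ladder) + 2 * h)
  else
    c(min(ladder) - 2 * h, min(ladder) - h, ladder)
}

#' One replica-exchange sweep over adjacent pairs
#'
#' Attempts Metropolis swaps on the disjoint adjacent pairs of the given
#' parity (even parity: pairs (1,2), (3,4), ...; odd: (2,3), (4,5), ...).
#' `ladder_values[i]` is the ladder label (pH, or window index) currently
#' held by replica `i`, in ladder order; `delta_fun(i, j)` must return the
#' exchange exponent for the adjacent pair.  On acceptance the ladder
#' labels are swapped via the returned permutation.
#'
#' @param n_replicas Number of replicas on the ladder.
#' @param parity `"even"` or `"odd"`.
#' @param delta_fun Function of the two ladder positions `(i, j = i + 1)`
#'   returning the Metropolis exponent.
#' @param time Attempt time stamp recorded in the decision log.
#' @return List with `decisions` (data.frame: time, i, j, delta, accepted,
#'   uniform_draw) and `swap` (permutation of `1:n_replicas`: entry `i`
#'   gives the ladder slot whose occupant moves to slot `i`).
#' @export
exchange_sweep <- function(n_replicas, parity = c("even", "odd"),
                           delta_fun, time = NA_real_) {
  parity <- match.arg(parity)
  swap <- seq_len(n_replicas)
  if (n_replicas < 2) {
    return(list(decisions = data.frame(
      time = numeric(0), i = integer(0), j = integer(0), delta = numeric(0),
      accepted = logical(0), uniform_draw = numeric(0)), swap = swap))
  }
  first <- if (parity == "even") 1L else 2L
  if (first > n_replicas - 1L) {
    return(list(decisions = data.frame(
      time = numeric(0), i = integer(0), j = integer(0), delta = numeric(0),
      accepted = logical(0), uniform_draw = numeric(0)), swap = swap))
  }
  is <- seq.int(first, n_replicas - 1L, by = 2L)
  dec <- vector("list", length(is))
  for (idx in seq_along(is)) {
    i <- is[idx]; j <- i + 1L
    d <- metropolis_accept(delta_fun(i, j), pair = c(i, j))
    if (d$accepted) { tmp <- swap[i]; swap[i] <- swap[j]; swap[j] <- tmp }
    dec[[idx]] <- data.frame(time = time, i = i, j = j, delta = d$delta,
                             accepted = d$accepted,
                             uniform_draw = d$uniform_draw)
  }
  list(decisions = do.call(rbind, dec), swap = swap)
}
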