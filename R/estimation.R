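#' Build umbrella histograms on a shared grid
#'
#' Bins the reaction coordinate of every non-equilibration frame of each
#' window onto one common grid (half-open bins `[lo, hi)`), the input WHAM
#' expects.
#'
#' @param records Record table (see [run_segment()]) containing `z_nm`,
#'   `window_id` and `equilibration_flag` columns.
#' @param windows List of [window()]s; every `window_id` present in
#'   `records` must appear here.
#' @param bin_width Bin width in nm (default 0.02 nm = 0.2 Angstrom, the
#'   same grid as the ionized-population profiles).
#' @param range Grid range in nm; defaults to the span of the window ladder
#'   padded by 3 bias standard deviations.
#' @param drop_equilibration Ignore frames flagged as equilibration
#'   (default TRUE).
#' @return Object of class `histogram_set`: `breaks`, `mids` (nm), `counts`
#'   (bins x windows matrix), `N` (frames per window), `windows`.
#' @export
make_histograms <- function(records, windows, bin_width = 0.02,
                            range = NULL, drop_equilibration = TRUE) {
  stopifnot(bin_width > 0, length(windows) >= 1)
  ids <- vapply(windows, function(w) w$window_id, "")
  if (anyDuplicated(ids)) stop("duplicate window ids")
  if (drop_equilibration) records <- records[!records$equilibration_flag, ]
  miss <- setdiff(unique(records$window_id), ids)
  if (length(miss))
    stop("records contain unknown window ids: ", paste(miss, collapse = ", "))
  if (is.null(range)) {
    xi <- vapply(windows, function(w) w$xi_ref, 0)
    pad <- 3 * sqrt(1 / (min(vapply(windows, function(w) w$k, 0)) * 0.4))
    range <- c(min(xi) - pad, max(xi) + pad)
  }
  lo <- floor(range[1] / bin_width) * bin_width
  hi <- ceiling(range[2] / bin_width) * bin_width
  breaks <- seq(lo, hi, by = bin_width)
  nb <- length(breaks) - 1L
  counts <- matrix(0L, nrow = nb, ncol = length(windows),
                   dimnames = list(NULL, ids))
  for (j in seq_along(windows)) {
    z <- records$z_nm[records$window_id == ids[j]]
    z <- z[z >= lo & z < hi]
    if (length(z))
      counts[, j] <- tabulate(findInterval(z, breaks,
                                           rightmost.closed = FALSE),
                              nbins = nb)
  }
  structure(list(breaks = breaks, mids = breaks[-1] - bin_width / 2,
                 bin_width = bin_width, counts = counts,
                 N = colSums(counts), windows = windows),
            class = "histogram_set")
}

#' Inject known counts into a histogram set
#'
#' Builds a `histogram_set` directly from a counts matrix — used to feed
#' WHAM exact (expected) or externally generated counts.
#'
#' @param mids Bin centres, nm (uniform spacing).
#' @param counts Bins x windows matrix.
#' @param windows List of [window()]s matching the columns.
#' @return A `histogram_set`.
#' @export
histogram_set <- function(mids, counts, windows) {
  counts <- as.matrix(counts)
  stopifnot(length(mids) == nrow(counts),
            length(windows) == ncol(counts))
  bw <- if (length(mids) > 1) mids[2] - mids[1] else 1
  colnames(counts) <- vapply(windows, function(w) w$window_id, "")
  structure(list(breaks = c(mids - bw / 2, mids[length(mids)] + bw / 2),
                 mids = mids, bin_width = bw, counts = counts,
                 N = colSums(counts), windows = windows),
            class = "histogram_set")
}

check_overlap <- function(hs) {
  if (length(hs$windows) < 2) return(invisible(TRUE))
  xi <- vapply(hs$windows, function(w) w$xi_ref, 0)
  ord <- order(xi)
  for (k in seq_len(length(ord) - 1L)) {
    a <- ord[k]; b <- ord[k + 1L]
    if (!any(hs$counts[, a] > 0 & hs$counts[, b] > 0))
      stop(sprintf(
        "no histogram overlap between windows %s (xi_ref %g nm) and %s (xi_ref %g nm)",
        colnames(hs$counts)[a], xi[a], colnames(hs$counts)[b], xi[b]))
  }
  invisible(TRUE)
}

#' Weighted histogram analysis method (WHAM)
#'
#' Self-consistent unbiasing of umbrella histograms into a potential of
#' mean force: iterate
#' `P(x) = n(x) / sum_j N_j exp(beta (f_j - V_j(x)))` and
#' `f_j = -kT ln sum_x P(x) exp(-beta V_j(x))` until the largest change in
#' any window free energy is below `tol` (in kT).  The PMF is
#' `-kT ln P(x)`, anchored so its minimum over covered bins is zero.
#'
#' @param hs A `histogram_set` (see [make_histograms()]); adjacent windows
#'   must have overlapping counts.
#' @param thermo A [thermo()] context.
#' @param tol Convergence tolerance on the window free energies, kT
#'   (default 1e-7).
#' @param max_iter Maximum iterations (default 1e5); exceeding it is an
#'   error reporting the residual.
#' @return Object of class `pmf_profile`: data.frame `profile` with
#'   `xi_A` (Angstrom), `pmf_kJmol`, `pmf_kcalmol`, `counts` (bins with no
#'   counts carry `NA`), plus `f_kJmol` (window free energies, first window
#'   0), `iterations`, `residual_kT`, `thermo`.
#' @export
wham <- function(hs, thermo = memtitr::thermo(), tol = 1e-7,
                 max_iter = 1e5) {
  stopifnot(inherits(hs, "histogram_set"), tol > 0)
  check_overlap(hs)
  b <- thermo$beta
  n_tot <- rowSums(hs$counts)
  covered <- n_tot > 0
  # beta * V_j(x_i): bins x windows
  bV <- vapply(hs$windows,
               function(w) b * harmonic_bias(hs$mids, w),
               numeric(length(hs$mids)))
  bf <- numeric(length(hs$windows))  # beta * f_j
  lognj <- log(hs$N)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    # log denominator per bin: logsumexp_j [log N_j + beta f_j - beta V_j]
    m <- sweep(-bV, 2, lognj + bf, "+")
    mmax <- apply(m, 1, max)
    logden <- mmax + log(rowSums(exp(m - mmax)))
    logP <- ifelse(covered, log(n_tot) - logden, -Inf)
    logP <- logP - max(logP[covered])
    # beta f_j = -logsumexp_i [logP_i - beta V_j(i)]
    mm <- logP - bV
    mmax2 <- apply(mm, 2, max)
    bf_new <- -(mmax2 + log(colSums(exp(sweep(mm, 2, mmax2, "-")))))
    bf_new <- bf_new - bf_new[1]
    resid <- max(abs(bf_new - bf))
    bf <- bf_new
    if (resid < tol) break
    if (iter >= max_iter)
      stop(sprintf("WHAM did not converge in %d iterations (residual %.3g kT)",
                   max_iter, resid))
  }
  pmf <- -logP / b
  pmf <- pmf - min(pmf[covered])
  pmf[!covered] <- NA_real_
  structure(list(
    profile = data.frame(xi_A = hs$mids * 10,
                         pmf_kJmol = pmf,
                         pmf_kcalmol = pmf / KJ_PER_KCAL,
                         counts = n_tot),
    f_kJmol = bf / b, iterations = iter, residual_kT = resid,
    thermo = thermo), class = "pmf_profile")
}

#' @export
print.pmf_profile <- function(x, ...) {
  cov <- !is.na(x$profile$pmf_kJmol)
  cat(sprintf(
    "pmf_profile: %d/%d covered bins over [%.1f, %.1f] A; converged in %d iterations (residual %.2g kT)\n",
    sum(cov), nrow(x$profile), min(x$profile$xi_A[cov]),
    max(x$profile$xi_A[cov]), x$iterations, x$residual_kT))
  invisible(x)
}

#' Leave-one-out jackknife error of a PMF
#'
#' Given `n >= 2` leave-one-out PMFs (each computed by WHAM from the pooled
#' histograms of the remaining replicates), re-anchors all of them at a
#' common reference bin and returns
#' `error(x) = sqrt((n-1)/n * sum_i (PMF_i(x) - mean(x))^2)` per bin —
#' the standard jackknife variance inflation.  Anchoring at a common bin
#' makes the error invariant to each profile's arbitrary offset.
#'
#' @param loo_pmfs List of `pmf_profile`s on a common grid.
#' @param anchor_xi_A Reference position (Angstrom) used to anchor all
#'   profiles; default: the covered bin closest to the water-side end of
#'   the common coverage.
#' @return Data.frame `xi_A`, `error_kJmol`, `error_kcalmol` (`NA` where
#'   any leave-one-out profile is uncovered).
#' @export
jackknife_pmf_error <- function(loo_pmfs, anchor_xi_A = NULL) {
  n <- length(loo_pmfs)
  if (n < 2) stop("jackknife needs at least 2 leave-one-out profiles")
  grids <- lapply(loo_pmfs, function(p) p$profile$xi_A)
  if (!all(vapply(grids[-1], function(g) isTRUE(all.equal(g, grids[[1]])),
                  FALSE)))
    stop("leave-one-out PMFs are not on a common grid")
  vals <- vapply(loo_pmfs, function(p) p$profile$pmf_kJmol,
                 numeric(length(grids[[1]])))
  covered <- rowSums(is.na(vals)) == 0
  if (!any(covered)) stop("no commonly covered bins")
  xi <- grids[[1]]
  if (is.null(anchor_xi_A)) anchor_xi_A <- max(xi[covered])
  ai <- which.min(abs(xi - anchor_xi_A))
  if (!covered[ai]) stop("anchor bin not covered by all profiles")
  vals <- sweep(vals, 2, vals[ai, ], "-")
  mu <- rowMeans(vals)
  err <- sqrt((n - 1) / n * rowSums((vals - mu)^2))
  err[!covered] <- NA_real_
  data.frame(xi_A = xi, error_kJmol = err,
             error_kcalmol = err / KJ_PER_KCAL)
}

#' Jackknife PMF errors from per-replicate records
#'
#' Convenience wrapper: for each replicate, pools the histograms of the
#' remaining replicates, runs [wham()], and feeds the leave-one-out
#' profiles to [jackknife_pmf_error()].
#'
#' @param records Record table with `replicate_index`.
#' @param windows List of [window()]s.
#' @param thermo A [thermo()].
#' @param ... Passed to [make_histograms()] (`bin_width`, `range`) — the
#'   range defaults to the full ladder so all profiles share one grid.
#' @param anchor_xi_A See [jackknife_pmf_error()].
#' @return As [jackknife_pmf_error()], with the list of leave-one-out
#'   profiles attached as attribute `loo_pmfs`.
#' @export
jackknife_pmf <- function(records, windows, thermo = memtitr::thermo(),
                          ..., anchor_xi_A = NULL) {
  reps <- sort(unique(records$replicate_index))
  if (length(reps) < 2) stop("jackknife needs at least 2 replicates")
  loo <- lapply(reps, function(r) {
    wham(make_histograms(records[records$replicate_index != r, ],
                         windows, ...), thermo)
  })
  out <- jackknife_pmf_error(loo, anchor_xi_A = anchor_xi_A)
  attr(out, "loo_pmfs") <- loo
  out
}

#' Umbrella reweighting of biased frames
#'
#' WHAM-consistent per-frame weights for estimating unbiased averages from
#' a set of umbrella runs:
#' `w(xi) propto 1 / sum_j N_j exp(beta (f_j - V_j(xi)))`, normalised to
#' mean 1 over the supplied frames.  `N_j` is the number of
#' non-equilibration frames per window in `records`.
#'
#' @param records Record table with `z_nm`, `window_id`,
#'   `equilibration_flag`.
#' @param windows List of [window()]s.
#' @param f_kJmol Window free energies from [wham()], same order as
#'   `windows`.
#' @param thermo A [thermo()].
#' @param support_range Optional `c(lo, hi)` in nm; frames outside it get a
#'   tail warning (the weight formula itself is global and is still
#'   applied).
#' @return Numeric weight per row of `records` (equilibration rows get
#'   `NA`); strictly positive elsewhere.
#' @export
reweight_frames <- function(records, windows, f_kJmol,
                            thermo = memtitr::thermo(),
                            support_range = NULL) {
  stopifnot(length(windows) == length(f_kJmol))
  b <- thermo$beta
  keep <- !records$equilibration_flag
  z <- records$z_nm[keep]
  ids <- vapply(windows, function(w) w$window_id, "")
  Nj <- vapply(ids, function(id) sum(records$window_id[keep] == id), 0)
  if (!is.null(support_range) &&
      any(z < support_range[1] | z > support_range[2]))
    warning("some frames lie outside the histogram support; ",
            "their weights come from the global formula tail")
  m <- vapply(seq_along(windows), function(j)
    log(Nj[j]) + b * (f_kJmol[j] - harmonic_bias(z, windows[[j]])),
    numeric(length(z)))
  mmax <- apply(m, 1, max)
  logw <- -(mmax + log(rowSums(exp(m - mmax))))
  w <- exp(logw - mean(logw))
  w <- w / mean(w)
  out <- rep(NA_real_, nrow(records))
  out[keep] <- w
  out
}

insertion_of <- function(records) {
  if ("insertion_A" %in% names(records)) records$insertion_A
  else records$z_nm * 10
}

ionized_flags <- function(records, residue_class) {
  ion_state <- if (residue_class == "acid") "deprotonated" else "protonated"
  records$state == ion_state
}

#' Ionized-population profile along the insertion axis
#'
#' Slices the insertion range into half-open 0.2 Angstrom bins from -15 to
#' 25 Angstrom and counts ionized configurations across all replicates and
#' pH values (equilibration frames excluded).  Two views are emitted: the
#' per-bin ionized fraction (`ionized / total`) and the normalised density
#' of ionized frames (`ionized / sum(ionized)`); published "probability of
#' the ionized species" panels are compatible with either reading.
#'
#' @param records Record table; insertion is taken from an `insertion_A`
#'   column when present, else from `z_nm * 10`.
#' @param residue_class `"acid"` or `"base"` (maps state to ionized).
#' @param weights Optional per-frame weights (e.g. [reweight_frames()]);
#'   `NA` weights drop the frame.
#' @param breaks Bin edges, Angstrom (default `seq(-15, 25, 0.2)`: 200
#'   bins).
#' @return Data.frame of class `ionized_profile`: `bin_lo`, `bin_hi`,
#'   `mid_A`, `ionized`, `total`, `fraction`, `density`.
#' @export
ionized_population_profile <- function(records,
                                       residue_class = c("acid", "base"),
                                       weights = NULL,
                                       breaks = seq(-15, 25, by = 0.2)) {
  residue_class <- match.arg(residue_class)
  keep <- !records$equilibration_flag
  if (!is.null(weights)) {
    stopifnot(length(weights) == nrow(records))
    keep <- keep & !is.na(weights)
  }
  x <- insertion_of(records)[keep]
  ion <- ionized_flags(records[keep, , drop = FALSE], residue_class)
  w <- if (is.null(weights)) rep(1, sum(keep)) else weights[keep]
  nb <- length(breaks) - 1L
  inrange <- x >= breaks[1] & x < breaks[nb + 1L]
  if (!any(inrange)) warning("no frames inside the profile range")
  idx <- findInterval(x[inrange], breaks, rightmost.closed = FALSE)
  total <- as.numeric(tapply(w[inrange], factor(idx, levels = seq_len(nb)),
                             sum, default = 0))
  ionized <- as.numeric(tapply(w[inrange] * ion[inrange],
                               factor(idx, levels = seq_len(nb)),
                               sum, default = 0))
  out <- data.frame(bin_lo = breaks[-(nb + 1L)], bin_hi = breaks[-1],
                    mid_A = (breaks[-(nb + 1L)] + breaks[-1]) / 2,
                    ionized = ionized, total = total,
                    fraction = ifelse(total > 0, ionized / total, NA_real_),
                    density = if (sum(ionized) > 0) ionized / sum(ionized)
                              else 0)
  class(out) <- c("ionized_profile", "data.frame")
  out
}

#' Henderson-Hasselbalch pKa fit
#'
#' Least-squares fit of the single-site titration curve
#' `<protonation>(pH) = 1 / (1 + 10^(pH - pKa))` with the pKa as the only
#' free parameter (Hill slope fixed at 1), optionally weighting each pH by
#' its frame count.  Deterministic given its inputs.
#'
#' @param ph Numeric pH values (>= 2 distinct).
#' @param mean_prot Mean protonation per pH, in `[0, 1]`.
#' @param counts Optional per-pH frame counts (weights).
#' @return Fitted pKa (numeric scalar).
#' @export
hh_fit <- function(ph, mean_prot, counts = NULL) {
  stopifnot(length(ph) == length(mean_prot))
  if (any(!is.finite(ph)) || any(!is.finite(mean_prot)))
    stop("non-finite inputs to hh_fit")
  if (length(unique(ph)) < 2)
    stop("hh_fit needs at least 2 distinct pH values")
  if (all(mean_prot <= 0) || all(mean_prot >= 1))
    stop("titration data are flat (all 0 or all 1); no pKa is identifiable")
  w <- if (is.null(counts)) rep(1, length(ph)) else counts
  obj <- function(pka) sum(w * (mean_prot - 1 / (1 + 10^(ph - pka)))^2)
  lo <- min(ph) - 10
  hi <- max(ph) + 10
  stats::optimize(obj, c(lo, hi), tol = 1e-9)$minimum
}

#' Bayesian-bootstrap error of a bin's pKa
#'
#' For each of `n_boot` bootstraps, draws flat-Dirichlet weights over the
#' frames within each pH group, recomputes the weighted per-pH mean
#' protonations and refits the Henderson-Hasselbalch curve; the reported
#' error is the standard deviation of the bootstrap pKa distribution.
#' Refits that fail (flat resampled data) are counted, not silently
#' dropped into the sd.
#'
#' @param ph Per-frame pH values.
#' @param prot Per-frame protonation (0/1 or logical).
#' @param n_boot Number of bootstraps (default 1000).
#' @param level `"frame"` (Dirichlet over frames within each pH group) or
#'   `"replicate"` (Dirichlet over replicate means within each pH group;
#'   requires `replicate`).
#' @param replicate Per-frame replicate index (for
#'   `level = "replicate"`).
#' @return List: `sd` (bootstrap error; `NA` and `degenerate = TRUE` when
#'   `n_boot < 2`), `n_failed`, `estimates`.
#' @export
bayesian_bootstrap_pka <- function(ph, prot, n_boot = 1000,
                                   level = c("frame", "replicate"),
                                   replicate = NULL) {
  level <- match.arg(level)
  prot <- as.numeric(prot)
  groups <- split(seq_along(ph), ph)
  ph_vals <- as.numeric(names(groups))
  if (level == "replicate") {
    stopifnot(!is.null(replicate))
    # collapse to replicate means within each pH group first
    groups <- lapply(groups, function(ix) {
      tapply(prot[ix], replicate[ix], mean)
    })
  }
  est <- rep(NA_real_, n_boot)
  n_failed <- 0L
  for (bidx in seq_len(n_boot)) {
    means <- vapply(groups, function(g) {
      x <- if (level == "frame") prot[g] else as.numeric(g)
      w <- stats::rexp(length(x))
      sum(w * x) / sum(w)
    }, 0)
    fit <- tryCatch(hh_fit(ph_vals, means), error = function(e) NA_real_)
    if (is.na(fit)) n_failed <- n_failed + 1L
    est[bidx] <- fit
  }
  ok <- !is.na(est)
  list(sd = if (n_boot >= 2 && sum(ok) >= 2) stats::sd(est[ok]) else NA_real_,
       degenerate = n_boot < 2,
       n_failed = n_failed,
       estimates = est)
}

#' Sliding-bin pKa profile with fitting gates
#'
#' Scans the insertion range (default -12 to 22 Angstrom) with a 1 Angstrom
#' bin sliding in 0.25 Angstrom steps.  In each half-open bin
#' `[lo, lo + 1)` the non-equilibration frames of all replicates and pH
#' values are pooled, protonation states are averaged per pH, and a
#' Henderson-Hasselbalch curve is fitted — but only when every gate holds:
#' \itemize{
#'   \item each protonation state has at least `min_points` frames
#'     (`insufficient-points`),
#'   \item each state is observed at >= 2 pH values
#'     (`insufficient-pH`) and >= 2 replicates
#'     (`insufficient-replicas`),
#'   \item the per-pH mean protonation is non-increasing with pH within an
#'     absolute slack (`non-monotonic`).
#' }
#' Gated-out bins carry their status instead of an estimate.  Bootstrap
#' errors come from [bayesian_bootstrap_pka()].
#'
#' @param records Record table (`insertion_A` column or `z_nm`, plus
#'   `state`, `pH`, `replicate_index`, `equilibration_flag`).
#' @param residue_class `"acid"` or `"base"`.
#' @param scan_from,scan_to Scan limits, Angstrom (left edges
#'   `scan_from, scan_from + stride, ..., scan_to - bin_width`).
#' @param bin_width Bin width, Angstrom (default 1).
#' @param stride Sliding step, Angstrom (default 0.25).
#' @param min_points Minimum frames per protonation state (default 50).
#' @param mono_slack Absolute tolerance on the monotonicity gate
#'   (default 0.02).
#' @param n_boot Bootstraps per fitted bin (default 1000; 0 skips errors).
#' @param boot_level Passed to [bayesian_bootstrap_pka()].
#' @return Data.frame of class `pka_profile`: `bin_lo`, `bin_center`,
#'   `pka`, `boot_err`, `n_prot`, `n_deprot`, `n_ph`, `n_replicas`,
#'   `status` (`"fitted"` or the failed gate).
#' @export
pka_profile <- function(records, residue_class = c("acid", "base"),
                        scan_from = -12, scan_to = 22, bin_width = 1,
                        stride = 0.25, min_points = 50, mono_slack = 0.02,
                        n_boot = 1000, boot_level = "frame") {
  residue_class <- match.arg(residue_class)
  keep <- !records$equilibration_flag
  x <- insertion_of(records)[keep]
  st <- records$state[keep]
  ph <- records$pH[keep]
  rep_ix <- records$replicate_index[keep]
  prot <- as.numeric(st == "protonated")

  edges <- seq(scan_from, scan_to - bin_width, by = stride)
  ord <- order(x)
  x <- x[ord]; ph <- ph[ord]; rep_ix <- rep_ix[ord]; prot <- prot[ord]

  res <- vector("list", length(edges))
  for (i in seq_along(edges)) {
    lo <- edges[i]
    # half-open [lo, lo + bin_width): x is sorted, pick the index range
    a <- findInterval(lo, x, left.open = TRUE) + 1L
    b <- findInterval(lo + bin_width, x, left.open = TRUE)
    sel <- if (b >= a) a:b else integer(0)
    p <- prot[sel]; f_ph <- ph[sel]; f_rep <- rep_ix[sel]
    is_p <- p == 1
    n_prot <- sum(is_p); n_deprot <- sum(!is_p)
    n_ph_state <- c(length(unique(f_ph[is_p])), length(unique(f_ph[!is_p])))
    n_rep_state <- c(length(unique(f_rep[is_p])),
                     length(unique(f_rep[!is_p])))
    status <- "fitted"
    pka <- NA_real_; berr <- NA_real_
    if (n_prot < min_points || n_deprot < min_points) {
      status <- "insufficient-points"
    } else if (any(n_ph_state < 2)) {
      status <- "insufficient-pH"
    } else if (any(n_rep_state < 2)) {
      status <- "insufficient-replicas"
    } else {
      mp <- tapply(p, f_ph, mean)
      ph_sorted <- sort(as.numeric(names(mp)))
      mp <- mp[as.character(ph_sorted)]
      if (any(diff(mp) > mono_slack)) {
        status <- "non-monotonic"
      } else {
        pka <- tryCatch(hh_fit(ph_sorted, as.numeric(mp),
                               counts = as.numeric(table(f_ph)[
                                 as.character(ph_sorted)])),
                        error = function(e) NA_real_)
        if (is.na(pka)) {
          status <- "insufficient-points"
        } else if (n_boot > 0) {
          berr <- bayesian_bootstrap_pka(f_ph, p, n_boot = n_boot,
                                         level = boot_level,
                                         replicate = f_rep)$sd
        }
      }
    }
    res[[i]] <- data.frame(
      bin_lo = lo, bin_center = lo + bin_width / 2, pka = pka,
      boot_err = berr, n_prot = n_prot, n_deprot = n_deprot,
      n_ph = length(unique(f_ph)), n_replicas = length(unique(f_rep)),
      status = status, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  class(out) <- c("pka_profile", "data.frame")
  out
}

#' Align a PMF to a reference over a coordinate region
#'
#' Adds to `profile` the constant that minimises the mean squared
#' difference to `reference` over the given region (e.g. aligning a
#' 1 Angstrom-ladder profile to a 2 Angstrom-ladder profile in the water
#' region, where both are flat and well converged).
#'
#' @param profile,reference `pmf_profile` objects (or data.frames with
#'   `xi_A` and `pmf_kJmol`).
#' @param region `c(lo, hi)` in Angstrom.
#' @return `profile` with shifted values; the applied shift (kJ/mol) is in
#'   attribute `shift_kJmol`.
#' @export
align_pmf <- function(profile, reference, region) {
  pr <- if (inherits(profile, "pmf_profile")) profile$profile else profile
  rf <- if (inherits(reference, "pmf_profile")) reference$profile
        else reference
  sel_p <- pr$xi_A >= region[1] & pr$xi_A <= region[2] & !is.na(pr$pmf_kJmol)
  if (!any(sel_p)) stop("profile has no covered bins in the region")
  ref_interp <- stats::approx(rf$xi_A[!is.na(rf$pmf_kJmol)],
                              rf$pmf_kJmol[!is.na(rf$pmf_kJmol)],
                              xout = pr$xi_A[sel_p], rule = 1)$y
  ok <- !is.na(ref_interp)
  if (!any(ok)) stop("alignment region does not overlap the reference")
  shift <- mean(ref_interp[ok] - pr$pmf_kJmol[sel_p][ok])
  pr$pmf_kJmol <- pr$pmf_kJmol + shift
  pr$pmf_kcalmol <- pr$pmf_kJmol / KJ_PER_KCAL
  if (inherits(profile, "pmf_profile")) {
    profile$profile <- pr
    attr(profile, "shift_kJmol") <- shift
    profile
  } else {
    attr(pr, "shift_kJmol") <- shift
    pr
  }
}
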