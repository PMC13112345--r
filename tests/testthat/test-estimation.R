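test_that("degenerate WHAM on one near-unbiased window returns -kT ln rho", {
  m <- double_well_model()
  th <- m$thermo
  grid <- seq(-1.19, 2.19, by = 0.02)
  w0 <- window("u", 0, 1e-9)     # numerically unbiased umbrella
  rho <- analytic_density(5, m, grid)
  counts <- matrix(round(rho * 5e6), ncol = 1)
  hs <- histogram_set(grid, counts, list(w0))
  fit <- wham(hs, th)
  covered <- fit$profile$counts > 0
  truth <- -th$kT * log(rho[covered])
  truth <- truth - min(truth)
  est <- fit$profile$pmf_kJmol[covered]
  est <- est - min(est)
  # rounding of counts dominates; everything well under 0.05 kT
  expect_lt(max(abs(est - truth)[counts[covered] > 100]), 0.05 * th$kT)
})

test_that("WHAM recovers a flat PMF from exact Gaussian window counts", {
  m <- flat_model()
  th <- m$thermo
  wl <- build_window_ladder(8, 0, 2, 500)
  grid <- seq(-0.4 + 0.01, 1.2 - 0.01, by = 0.02)
  # exact expected counts: discretised Gaussian per window
  counts <- vapply(wl, function(w) {
    p <- analytic_density(7, m, grid, window = w)
    p * 1e6
  }, numeric(length(grid)))
  hs <- histogram_set(grid, counts, wl)
  fit <- wham(hs, th, tol = 1e-10)
  sel <- fit$profile$counts > 50
  vals <- fit$profile$pmf_kJmol[sel]
  expect_lt(max(vals) - min(vals), 0.02 * th$kT)
  expect_gt(fit$iterations, 1L)
})

test_that("WHAM errors on non-overlapping windows and iteration exhaustion", {
  m <- flat_model()
  wl <- list(window("a", 0, 500), window("b", 1.0, 500))
  grid <- seq(-0.3, 1.3, by = 0.02)
  counts <- vapply(wl, function(w)
    round(analytic_density(7, m, grid, window = w) * 1e4),
    numeric(length(grid)))
  hs <- histogram_set(grid, counts, wl)
  expect_error(wham(hs, m$thermo), "no histogram overlap")
  wl2 <- build_window_ladder(8, 0, 2, 500)
  counts2 <- vapply(wl2, function(w)
    analytic_density(7, m, grid, window = w) * 1e6,
    numeric(length(grid)))
  hs2 <- histogram_set(grid, counts2, wl2)
  expect_error(wham(hs2, m$thermo, tol = 1e-12, max_iter = 3),
               "did not converge")
})

test_that("jackknife error is zero for identical replicates and matches the hand formula", {
  mk_prof <- function(vals) {
    structure(list(profile = data.frame(
      xi_A = c(0, 1, 2), pmf_kJmol = vals,
      pmf_kcalmol = vals / KJ_PER_KCAL, counts = 1000)),
      class = "pmf_profile")
  }
  same <- lapply(1:3, function(i) mk_prof(c(0, 1, 2)))
  err <- jackknife_pmf_error(same)
  expect_equal(err$error_kJmol, rep(0, 3))
  # one shifted middle value: hand-computed jackknife at the middle bin
  loo <- list(mk_prof(c(0, 1.0, 2)), mk_prof(c(0, 1.3, 2)),
              mk_prof(c(0, 0.7, 2)))
  err <- jackknife_pmf_error(loo, anchor_xi_A = 0)
  v <- c(1.0, 1.3, 0.7)
  hand <- sqrt(2 / 3 * sum((v - mean(v))^2))
  expect_equal(err$error_kJmol[2], hand)
  expect_equal(err$error_kJmol[c(1, 3)], c(0, 0))
  # invariance to each profile's global offset after common anchoring
  loo_off <- list(mk_prof(c(0, 1.0, 2) + 5), mk_prof(c(0, 1.3, 2) - 2),
                  mk_prof(c(0, 0.7, 2) + 0.3))
  expect_equal(jackknife_pmf_error(loo_off, anchor_xi_A = 0)$error_kJmol,
               err$error_kJmol)
  expect_error(jackknife_pmf_error(same[1]), "at least 2")
})

test_that("reweighting is uniform for a single unbiased window and inverts the bias", {
  m <- double_well_model()
  th <- m$thermo
  set.seed(12)
  # single near-unbiased window: all weights equal
  w0 <- window("u", 0.4, 1e-9)
  rec0 <- data.frame(time = 1:500, replica_id = "r", replicate_index = 1L,
                     pH = 5, window_id = "u",
                     z_nm = runif(500, -1, 2), state = "protonated",
                     bias_kJmol = 0, equilibration_flag = FALSE)
  w <- reweight_frames(rec0, list(w0), f_kJmol = 0, thermo = th)
  expect_equal(w, rep(1, 500))
  expect_true(all(w > 0))
  # umbrella runs: reweighted state populations match the unbiased law
  wl <- build_window_ladder(16, -8, 2, 300)
  grid <- seq(-1.0 + 0.01, 1.8 - 0.01, by = 0.02)
  ph <- 5
  n_per <- 20000
  recs <- lapply(seq_along(wl), function(j) {
    z <- sample_analytic_positions(n_per, ph, m, grid, wl[[j]])
    s <- ifelse(runif(n_per) < analytic_deprot_fraction(z, ph, m),
                "deprotonated", "protonated")
    data.frame(time = seq_len(n_per), replica_id = "r",
               replicate_index = 1L, pH = ph,
               window_id = wl[[j]]$window_id, z_nm = z, state = s,
               bias_kJmol = harmonic_bias(z, wl[[j]]),
               equilibration_flag = FALSE)
  })
  rec <- do.call(rbind, recs)
  hs <- make_histograms(rec, wl, range = range(grid) + c(-0.01, 0.01))
  fit <- wham(hs, th)
  wts <- reweight_frames(rec, wl, fit$f_kJmol, th)
  # reweighting identity: weighted histogram equals the WHAM estimate
  bin <- findInterval(rec$z_nm, hs$breaks, rightmost.closed = FALSE)
  wh <- tapply(wts, factor(bin, levels = seq_along(hs$mids)), sum,
               default = 0)
  wh <- as.numeric(wh) / sum(wh)
  pmf <- fit$profile$pmf_kJmol
  p_wham <- exp(-th$beta * ifelse(is.na(pmf), Inf, pmf))
  p_wham <- p_wham / sum(p_wham)
  keep <- fit$profile$counts > 200
  expect_lt(max(abs(wh[keep] - p_wham[keep]) / p_wham[keep]), 0.02)
  # reweighted ionized fraction approaches the analytic mean over the
  # unbiased density
  ion <- rec$state == "deprotonated"
  rho_u <- analytic_density(ph, m, grid)
  f_true <- sum(rho_u * analytic_deprot_fraction(grid, ph, m))
  f_rw <- sum(wts * ion) / sum(wts)
  expect_lt(abs(f_rw - f_true), 0.02)
})

test_that("ionized population profile counts by half-open 0.2 A bins", {
  rec <- data.frame(
    time = 1:10, replica_id = "r", replicate_index = 1L, pH = 4,
    window_id = NA_character_,
    z_nm = rep(0.01, 10),    # insertion 0.1 A -> bin [0, 0.2)
    state = c(rep("deprotonated", 4), rep("protonated", 6)),
    bias_kJmol = 0, equilibration_flag = FALSE)
  prof <- ionized_population_profile(rec, "acid")
  expect_equal(nrow(prof), 200L)
  row <- prof[prof$bin_lo == 0, ]
  expect_equal(row$total, 10)
  expect_equal(row$fraction, 0.4)
  expect_equal(sum(prof$total), 10)
  # a frame exactly on an edge belongs to the upper bin (half-open [lo, hi));
  # 0.5 A edges are exactly representable so the convention is unambiguous
  rec$z_nm <- 0.05
  prof2 <- ionized_population_profile(rec, "acid",
                                      breaks = seq(-2, 2, by = 0.5))
  expect_equal(prof2$total[prof2$bin_lo == 0.5], 10)
  expect_equal(prof2$total[prof2$bin_lo == 0.0], 0)
  # all-neutral records give zero ionized everywhere
  rec$state <- "protonated"
  prof3 <- ionized_population_profile(rec, "acid")
  expect_true(all(prof3$ionized == 0))
  # base mapping: ionized = protonated
  prof4 <- ionized_population_profile(rec, "base")
  expect_equal(sum(prof4$ionized), 10)
})

test_that("hh_fit recovers generating pKa values exactly and under noise", {
  for (resid in c("Asp", "Glu", "Tyr", "His")) {
    row <- reference_residues()[reference_residues()$residue == resid, ]
    ph <- as.numeric(row[, c("ph1", "ph2", "ph3", "ph4")])
    mp <- 1 / (1 + 10^(ph - row$pka_w))
    expect_equal(hh_fit(ph, mp), row$pka_w, tolerance = 1e-6)
  }
  # noisy titration means stay close to truth across seeds: 95% of fits
  # within 0.1, none far out
  set.seed(77)
  devs <- replicate(100, {
    ph <- c(3, 4, 5, 6)
    mp <- 1 / (1 + 10^(ph - 3.94)) + rnorm(4, 0, 0.02)
    hh_fit(ph, pmin(pmax(mp, 0), 1)) - 3.94
  })
  expect_lt(stats::quantile(abs(devs), 0.95), 0.1)
  expect_lt(max(abs(devs)), 0.2)
  expect_error(hh_fit(c(4, 4), c(0.4, 0.6)), "distinct pH")
  expect_error(hh_fit(c(3, 4), c(1, 1)), "flat")
  expect_error(hh_fit(c(3, 4), c(0.5, NA)), "non-finite")
})

test_that("pKa profile gates emit exactly the documented statuses", {
  mk <- function(n_prot, n_deprot, ph_prot, ph_deprot, rep_prot, rep_deprot,
                 z = 0.05) {
    data.frame(
      time = 1, replica_id = "x",
      replicate_index = c(rep(rep_prot, length.out = n_prot),
                          rep(rep_deprot, length.out = n_deprot)),
      pH = c(rep(ph_prot, length.out = n_prot),
             rep(ph_deprot, length.out = n_deprot)),
      window_id = NA_character_, z_nm = z,
      state = c(rep("protonated", n_prot), rep("deprotonated", n_deprot)),
      bias_kJmol = 0, equilibration_flag = FALSE)
  }
  scan1 <- function(rec) {
    pka_profile(rec, "acid", scan_from = 0, scan_to = 1, stride = 1,
                n_boot = 0)
  }
  # 49 ionized frames: insufficient points; 50 passes that gate
  r49 <- scan1(mk(200, 49, c(4, 5), c(4, 5), c(1, 2), c(1, 2)))
  expect_equal(r49$status, "insufficient-points")
  expect_true(is.na(r49$pka))
  r50 <- scan1(mk(200, 50, c(4, 5), c(4, 5), c(1, 2), c(1, 2)))
  expect_false(r50$status == "insufficient-points")
  # one state seen at a single pH
  r_ph <- scan1(mk(200, 60, c(4, 5), 5, c(1, 2), c(1, 2)))
  expect_equal(r_ph$status, "insufficient-pH")
  # one state seen in a single replicate
  r_rep <- scan1(mk(200, 60, c(4, 5), c(4, 5), c(1, 2), 1))
  expect_equal(r_rep$status, "insufficient-replicas")
  # protonation increasing with pH beyond the slack
  bad <- rbind(mk(40, 160, 4, 4, c(1, 2), c(1, 2)),
               mk(160, 40, 5, 5, c(1, 2), c(1, 2)))
  r_mono <- scan1(bad)
  expect_equal(r_mono$status, "non-monotonic")
  # a clean bin fits
  good <- rbind(mk(160, 40, 4, 4, c(1, 2), c(1, 2)),
                mk(40, 160, 5, 5, c(1, 2), c(1, 2)))
  r_ok <- scan1(good)
  expect_equal(r_ok$status, "fitted")
  expect_false(is.na(r_ok$pka))
  # statuses and estimates are invariant to row order
  perm <- good[sample.int(nrow(good)), ]
  expect_equal(scan1(perm), r_ok)
})

test_that("pKa profile scan bins follow the published sliding grid", {
  rec <- synth_titration_records(flat_model(4), c(3, 5), replicates = 2,
                                 n_per_ph = 10)
  prof <- pka_profile(rec, "acid", n_boot = 0)
  expect_equal(prof$bin_lo[1], -12)
  expect_equal(diff(prof$bin_lo)[1], 0.25)
  expect_equal(prof$bin_lo[nrow(prof)], 21)
  expect_equal(nrow(prof), 133L)
})

test_that("flat models yield a flat pKa profile at pKa_w and ignore equilibration frames", {
  m <- flat_model(pka_w = 7)
  set.seed(5)
  rec <- synth_titration_records(m, c(6, 6.5, 7, 7.5, 8), replicates = 3,
                                 n_per_ph = 3000)
  # poison some frames and flag them as equilibration: must not matter
  poison <- rec[1:2000, ]
  poison$state <- "protonated"
  poison$equilibration_flag <- TRUE
  prof <- pka_profile(rbind(poison, rec), "acid", n_boot = 0)
  fitted <- prof[prof$status == "fitted", ]
  expect_gt(nrow(fitted), 100)
  expect_lt(max(abs(fitted$pka - 7)), 0.15)
  prof_clean <- pka_profile(rec, "acid", n_boot = 0)
  expect_equal(prof, prof_clean)
})

test_that("Bayesian bootstrap error shrinks with sample size and is seed-stable", {
  ph <- c(4.5, 5.5, 6.5, 7.5)
  sds <- vapply(c(50, 500, 5000), function(n) {
    f <- 1 / (1 + 10^(ph - 6.54))
    ph_v <- rep(ph, each = n)
    prot <- unlist(lapply(f, function(p) {
      rep(c(1, 0), times = c(round(n * p), n - round(n * p)))
    }))
    set.seed(1)
    bayesian_bootstrap_pka(ph_v, prot, n_boot = 300)$sd
  }, 0)
  expect_true(all(diff(sds) < 0))
  # determinism under a fixed seed
  ph_v <- rep(ph, each = 100)
  prot <- rep(rep(c(1, 0), times = c(50, 50)), 4)
  set.seed(3); a <- bayesian_bootstrap_pka(ph_v, prot, n_boot = 100)
  set.seed(3); b <- bayesian_bootstrap_pka(ph_v, prot, n_boot = 100)
  expect_identical(a, b)
  # single bootstrap is degenerate by definition
  set.seed(4)
  expect_true(bayesian_bootstrap_pka(ph_v, prot, n_boot = 1)$degenerate)
})

test_that("align_pmf shifts by the mean difference over the region", {
  prof <- data.frame(xi_A = seq(0, 20, 2), pmf_kJmol = seq(0, 20, 2) * 0.3)
  prof$pmf_kcalmol <- prof$pmf_kJmol / KJ_PER_KCAL
  self <- align_pmf(prof, prof, region = c(10, 20))
  expect_equal(attr(self, "shift_kJmol"), 0)
  shifted <- prof
  shifted$pmf_kJmol <- prof$pmf_kJmol + 3 * KJ_PER_KCAL
  out <- align_pmf(shifted, prof, region = c(10, 20))
  expect_equal(attr(out, "shift_kJmol"), -3 * KJ_PER_KCAL)
  expect_equal(out$pmf_kJmol, prof$pmf_kJmol)
  expect_error(align_pmf(prof, prof, region = c(100, 120)), "no covered bins")
})
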