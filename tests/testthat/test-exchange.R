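test_that("harmonic bias reproduces the published force constants in closed form", {
  w1000 <- window("a", 0, 1000)
  expect_equal(harmonic_bias(0, w1000), 0)
  expect_equal(harmonic_bias(0.1, w1000), 5)          # (1000/2)(0.1)^2
  expect_equal(harmonic_bias(0.1, window("b", 0, 500)), 2.5)
  expect_equal(harmonic_force(0.1, w1000), -100)
  expect_equal(harmonic_bias(0.3, NULL), 0)
  expect_error(window("w", 0, -1))
})

test_that("REUS exchange exponent matches the hand-evaluated oracle and is antisymmetric", {
  th <- thermo(300)
  wm <- window("m", 0, 1000)
  wn <- window("n", 0.2, 1000)
  # hand evaluation: Vm(j)=11.25, Vm(i)=1.25, Vn(j)=1.25, Vn(i)=11.25 kJ/mol
  d <- reus_delta(0.05, 0.15, wm, wn, th)
  expect_equal(d, (11.25 - 1.25 - 1.25 + 11.25) / th$kT)
  expect_equal(d, 8.018, tolerance = 1e-3)
  expect_equal(exp(-d), 3.3e-4, tolerance = 0.01)
  # identical configurations or identical windows: no cost
  expect_equal(reus_delta(0.1, 0.1, wm, wn, th), 0)
  expect_equal(reus_delta(0.05, 0.15, wm, wm, th), 0)
  # antisymmetry under exchanging the configurations at fixed windows
  # (the reverse move from the post-swap state)
  expect_equal(reus_delta(0.15, 0.05, wm, wn, th), -d)
})

test_that("pHRE exchange exponent follows the discrete-protonation criterion", {
  expect_equal(phre_delta(1, 1, 4, 5), 0)
  # protonated replica at pH 4, deprotonated at pH 5: the current
  # assignment is the favourable one, so the swap costs +ln10
  expect_equal(phre_delta(1, 0, 4, 5), log(10))
  # the mirrored assignment gains ln10 and is always accepted
  expect_equal(phre_delta(0, 1, 4, 5), -log(10))
  # antisymmetry when the pair is relabeled
  expect_equal(phre_delta(0, 1, 5, 4), -phre_delta(1, 0, 5, 4))
})

test_that("Metropolis acceptance is exact at the boundary and in expectation", {
  set.seed(5)
  for (d in c(-5, 0)) {
    dec <- replicate(200, metropolis_accept(d)$accepted)
    expect_true(all(dec))
  }
  n <- 1e5
  acc <- replicate(n, metropolis_accept(2)$accepted)
  p <- exp(-2)
  expect_lt(abs(mean(acc) - p), 3 * sqrt(p * (1 - p) / n))
  dec <- metropolis_accept(1.5)
  expect_identical(dec$accepted,
                   (dec$delta <= 0) || (dec$uniform_draw < exp(-dec$delta)))
})

test_that("exchange_sweep pairs by parity and swaps on forced acceptance", {
  set.seed(1)
  sw <- exchange_sweep(4, "even", function(i, j) -1)
  expect_equal(sw$decisions$i, c(1, 3))
  expect_equal(sw$decisions$j, c(2, 4))
  expect_true(all(sw$decisions$accepted))
  expect_equal(sw$swap, c(2, 1, 4, 3))
  sw_odd <- exchange_sweep(4, "odd", function(i, j) -1)
  expect_equal(sw_odd$decisions$i, 2)
  expect_equal(sw_odd$swap, c(1, 3, 2, 4))
  # rejection leaves the identity permutation
  sw_rej <- exchange_sweep(4, "even", function(i, j) 1e9)
  expect_equal(sw_rej$swap, 1:4)
  expect_equal(nrow(exchange_sweep(1, "even", function(i, j) 0)$decisions), 0L)
})

test_that("window ladders reproduce the published counts and force rules", {
  expect_length(build_window_ladder(20, -12, 2, 1000), 17L)
  expect_length(build_window_ladder(12, -10, 1, 1000), 23L)
  wl <- build_window_ladder(20, -12, 2, reus_k_rule())
  xi_A <- vapply(wl, function(w) w$xi_ref * 10, 0)
  k <- vapply(wl, function(w) w$k, 0)
  expect_equal(xi_A, seq(20, -12, by = -2))
  expect_equal(k[xi_A >= 8], rep(500, 7))
  expect_equal(k[xi_A <= 6], rep(1000, 10))
  expect_error(build_window_ladder(20, -12, 3, 1000), "does not divide")
  expect_error(build_window_ladder(5, 5, 1, 1000))
})

test_that("pH ladders extend by two values on the ionized side", {
  expect_equal(extend_ph_ladder(c(3, 4, 5, 6), "acid"), 3:8)
  expect_equal(extend_ph_ladder(c(8, 9, 10, 11), "base"), 6:11)
  expect_equal(extend_ph_ladder(c(4.5, 5.5, 6.5, 7.5), "base"),
               c(2.5, 3.5, 4.5, 5.5, 6.5, 7.5))
  expect_error(extend_ph_ladder(5, "acid"), "fewer than 2")
  expect_error(extend_ph_ladder(c(3, 4, 6), "acid"), "uniformly spaced")
})

test_that("pHRE exchange kernel satisfies detailed balance on a discrete two-replica system", {
  # two replicas, pH a and b; states: which replica holds pH a (perm) and
  # each replica's protonation. Stationary law: product of HH conditionals
  # at the held pH (position fixed), uniform over the two permutations.
  m <- flat_model(pka_w = 7)
  phs <- c(6.5, 7.5)
  p_prot <- function(ph) 1 - analytic_deprot_fraction(m$z_water_ref, ph, m)
  states <- expand.grid(perm = 1:2, s1 = 0:1, s2 = 0:1)  # s: protons bound
  pi_s <- apply(states, 1, function(st) {
    ph1 <- phs[if (st["perm"] == 1) 1 else 2]
    ph2 <- phs[if (st["perm"] == 1) 2 else 1]
    0.5 * (p_prot(ph1)^st["s1"] * (1 - p_prot(ph1))^(1 - st["s1"])) *
      (p_prot(ph2)^st["s2"] * (1 - p_prot(ph2))^(1 - st["s2"]))
  })
  # exchange move: flip perm, protonations ride along with their replicas
  for (i in seq_len(nrow(states))) {
    st <- states[i, ]
    ph1 <- phs[if (st$perm == 1) 1 else 2]
    ph2 <- phs[if (st$perm == 1) 2 else 1]
    delta <- phre_delta(st$s1, st$s2, ph1, ph2)
    j <- which(states$perm == 3 - st$perm & states$s1 == st$s1 &
                 states$s2 == st$s2)
    # detailed balance flux: pi(i) A(i->j) == pi(j) A(j->i)
    expect_equal(pi_s[i] * min(1, exp(-delta)),
                 pi_s[j] * min(1, exp(delta)), tolerance = 1e-12)
  }
})

test_that("empirical REUS acceptance matches the brute-force two-sampler oracle", {
  m <- flat_model()
  wl <- build_window_ladder(6, 0, 2, 500)  # 4 windows
  cfg <- campaign_config(m, schedule(dt = 0.1, n_steps = 200000,
                                     record_period = 100,
                                     exchange_period = 20,
                                     exchange_offset = 10,
                                     equilibration_cutoff = 0),
                         method = "reus", ph_ladder = 7, windows = wl,
                         replicates = 1, seeds = 3)
  rec <- run_campaign(cfg)
  xl <- attr(rec, "exchange_log")
  th <- m$thermo
  set.seed(99)
  for (pair_i in 1:3) {
    emp <- xl$accepted[xl$i == pair_i]
    bf <- brute_force_reus_acceptance(wl[[pair_i]], wl[[pair_i + 1]], th,
                                      n = 1e5)
    # binomial SE at the oracle rate plus the oracle's own MC error
    se <- sqrt(bf$mean * (1 - bf$mean) / length(emp) + bf$se^2)
    expect_lt(abs(mean(emp) - bf$mean), 3 * se)
  }
  # multiset invariance: every window id present exactly once per time slice
  expect_true(all(table(rec$time, rec$window_id) == 1))
})

test_that("softer umbrellas exchange more often at fixed spacing", {
  m <- flat_model()
  th <- m$thermo
  set.seed(17)
  acc <- vapply(c(250, 500, 1000), function(k) {
    wl <- build_window_ladder(2, 0, 2, k)
    brute_force_reus_acceptance(wl[[1]], wl[[2]], th, n = 40000)$mean
  }, 0)
  expect_true(all(diff(acc) < 0))
})
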