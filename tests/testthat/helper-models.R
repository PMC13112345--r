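# shared fixtures, built in code

# flat model: both state potentials identically zero -> pKa(z) = pKa_w
flat_model <- function(pka_w = 7, class = "acid") {
  toy_model(class, pka_w = pka_w)
}

# double-well surrogate used by the WHAM oracle studies: interface well and
# a deeper pre-core well for the neutral form; the ionized form pays a
# sigmoid desolvation step into the membrane
double_well_model <- function() {
  toy_model("acid", pka_w = 3.94,
            terms_protonated = list(gaussian_term(-5, 0.3, 0.25),
                                    gaussian_term(-7, -0.6, 0.3)),
            terms_deprotonated = list(sigmoid_term(15, 0.1, 0.3),
                                      gaussian_term(-3, 0.3, 0.25)))
}

# vectorised heat-bath titration at fixed position: n draws from the same
# conditional titration_resample() uses
heat_bath_mean_protonation <- function(model, z, ph, n) {
  p_deprot <- analytic_deprot_fraction(z, ph, model)
  mean(stats::runif(n) >= p_deprot)
}

# exact multinomial counts from the discretised biased density, per window
analytic_window_counts <- function(model, ph, windows, grid, n_per_window) {
  vapply(windows, function(w) {
    p <- analytic_density(ph, model, grid, window = w)
    as.numeric(stats::rmultinom(1, n_per_window, p))
  }, numeric(length(grid)))
}

# brute-force REUS acceptance between two harmonic windows on a flat
# potential: xi_m ~ N(xi_ref, sqrt(kT/k)) i.i.d. in each window
brute_force_reus_acceptance <- function(win_m, win_n, th, n = 20000) {
  xi_i <- stats::rnorm(n, win_m$xi_ref, sqrt(th$kT / win_m$k))
  xi_j <- stats::rnorm(n, win_n$xi_ref, sqrt(th$kT / win_n$k))
  acc <- pmin(1, exp(-reus_delta(xi_i, xi_j, win_m, win_n, th)))
  list(mean = mean(acc), se = stats::sd(acc) / sqrt(n))
}

# minimal GRO writer for reader round-trip tests
write_gro_fixture <- function(path, atoms, box = c(5, 5, 10),
                              velocities = FALSE, title = "fixture") {
  lines <- c(title, sprintf("%5d", nrow(atoms)))
  for (i in seq_len(nrow(atoms))) {
    l <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", i, atoms$resname[i],
                 atoms$atom[i], i, atoms$x[i], atoms$y[i], atoms$z[i])
    if (velocities) l <- paste0(l, sprintf("%8.4f%8.4f%8.4f", 0, 0, 0))
    lines <- c(lines, l)
  }
  lines <- c(lines, sprintf("%10.5f%10.5f%10.5f", box[1], box[2], box[3]))
  writeLines(lines, path)
  path
}

# simple two-leaflet atom table: phosphate lattice plus one site atom
gro_atom_table <- function(site_z = 7.2, upper_z = 6.75, lower_z = 3.25,
                           nx = 5, ny = 5, spacing = 1.0) {
  g <- expand.grid(x = seq(0.5, by = spacing, length.out = nx),
                   y = seq(0.5, by = spacing, length.out = ny))
  phos <- rbind(
    data.frame(resname = "DMPC", atom = "P", x = g$x, y = g$y, z = upper_z),
    data.frame(resname = "DMPC", atom = "P", x = g$x, y = g$y, z = lower_z))
  rbind(data.frame(resname = "ASP", atom = "SITE",
                   x = mean(g$x), y = mean(g$y), z = site_z), phos)
}
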