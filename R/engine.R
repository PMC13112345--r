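#' Simulation schedule
#'
#' Time bookkeeping of a stochastic-titration constant-pH run, in "toy
#' picoseconds".  Defaults mirror the published cadence: protonation-state
#' resampling every 20 time units starting at t = 0, replica-exchange
#' attempts every 20 units starting at t = 10 (offset to misalign from the
#' titration attempts), and the first 25 units of each replicate flagged as
#' equilibration for the analysis layer to discard.
#'
#' @param dt Integration time step (> 0).
#' @param n_steps Number of Brownian steps per segment (>= 0).
#' @param titration_period Time between protonation resampling attempts.
#' @param record_period Time between stored frames.
#' @param exchange_period Time between exchange attempts (`NA` disables
#'   exchange).
#' @param exchange_offset Time of the first exchange attempt; must be
#'   < `exchange_period` when exchange is enabled.
#' @param equilibration_cutoff Frames with `time < equilibration_cutoff` are
#'   flagged (not deleted).
#' @return An object of class `schedule`.
#' @export
schedule <- function(dt = 0.1, n_steps = 1000,
                     titration_period = 20, record_period = 20,
                     exchange_period = NA, exchange_offset = 10,
                     equilibration_cutoff = 25) {
  stopifnot(dt > 0, n_steps >= 0, titration_period > 0, record_period > 0,
            equilibration_cutoff >= 0)
  as_steps <- function(period, name) {
    k <- period / dt
    if (abs(k - round(k)) > 1e-9)
      stop(name, " must be an integer multiple of dt")
    as.integer(round(k))
  }
  exchange_enabled <- !is.na(exchange_period)
  if (exchange_enabled) {
    stopifnot(exchange_period > 0, exchange_offset >= 0,
              exchange_offset < exchange_period)
  }
  structure(
    list(dt = dt, n_steps = as.integer(n_steps),
         titration_period = titration_period,
         record_period = record_period,
         exchange_period = exchange_period,
         exchange_offset = exchange_offset,
         equilibration_cutoff = equilibration_cutoff,
         titration_every = as_steps(titration_period, "titration_period"),
         record_every = as_steps(record_period, "record_period"),
         exchange_every = if (exchange_enabled)
           as_steps(exchange_period, "exchange_period") else NA_integer_,
         exchange_offset_steps = if (exchange_enabled)
           as_steps(max(exchange_offset, dt), "exchange_offset") else NA_integer_),
    class = "schedule")
}

#' A single simulation frame
#'
#' One time point of one replica: position, protonation state, pH, window
#' and bias energy.  Mostly used at API boundaries; the engine keeps frames
#' in plain data.frame record tables (see [run_segment()]).
#'
#' @param time Simulation time.
#' @param replica_id Replica label.
#' @param replicate_index 1-based replicate number.
#' @param pH External pH.
#' @param window_id Umbrella window label or `NA` (unbiased).
#' @param z Position along the membrane normal, nm.
#' @param s Protonation state (`"protonated"` / `"deprotonated"`).
#' @param bias_energy Harmonic bias energy, kJ/mol (0 when unbiased).
#' @return One-row data.frame in the record-table schema.
#' @export
frame <- function(time = 0, replica_id = "r1", replicate_index = 1L,
                  pH = 7, window_id = NA_character_, z = 0,
                  s = "protonated", bias_energy = 0) {
  check_state(s)
  stopifnot(replicate_index >= 1, bias_energy >= 0)
  data.frame(time = time, replica_id = replica_id,
             replicate_index = as.integer(replicate_index), pH = pH,
             window_id = window_id, z_nm = z, state = s,
             bias_kJmol = bias_energy, equilibration_flag = FALSE,
             stringsAsFactors = FALSE)
}

# flattened per-state term tables for the fast inner loop
model_term_tables <- function(model) {
  lapply(model$terms, function(terms) {
    list(shape = vapply(terms, function(t) t$shape, ""),
         A = vapply(terms, function(t) t$amplitude, 0),
         C = vapply(terms, function(t) t$center, 0),
         W = vapply(terms, function(t) t$width, 0))
  })
}

grad_from_table <- function(z, tab) {
  g <- 0
  for (i in seq_along(tab$A)) {
    if (tab$shape[i] == "gaussian") {
      g <- g + tab$A[i] * exp(-(z - tab$C[i])^2 / (2 * tab$W[i]^2)) *
        (-(z - tab$C[i]) / tab$W[i]^2)
    } else {
      e <- exp((z - tab$C[i]) / tab$W[i])
      g <- g - tab$A[i] * e / (tab$W[i] * (1 + e)^2)
    }
  }
  g
}

#' One overdamped Brownian step
#'
#' `z' = z - beta * D * d/dz [U_s(z) + V_bias(z)] * dt + sqrt(2 D dt) * eta`
#' with `eta` standard normal; the protonation state is untouched and time
#' advances by `dt`.  This is the surrogate for the molecular-dynamics
#' segments of stochastic-titration constant-pH MD.
#'
#' @param fr A [frame()] (one-row record table).
#' @param model A [toy_model()].
#' @param window Umbrella [window()] or `NULL`.
#' @param dt Time step (> 0).
#' @param D Diffusion coefficient, nm^2 per time unit (> 0).
#' @param eta Optional standard-normal deviate (drawn from the RNG when
#'   missing); exposed so deterministic tests can force the noise.
#' @return The updated frame.
#' @export
brownian_step <- function(fr, model, window = NULL, dt = 0.1, D = 0.1,
                          eta = NULL) {
  stopifnot(dt > 0, D > 0)
  if (is.null(eta)) eta <- stats::rnorm(1)
  f <- -potential_gradient(fr$z_nm, fr$state, model) +
    harmonic_force(fr$z_nm, window)
  if (!is.finite(f)) stop("non-finite force at z = ", fr$z_nm,
                          " (potential misconfiguration)")
  fr$z_nm <- fr$z_nm + model$thermo$beta * D * f * dt + sqrt(2 * D * dt) * eta
  fr$time <- fr$time + dt
  fr$bias_kJmol <- harmonic_bias(fr$z_nm, window)
  fr
}

#' Heat-bath protonation resampling
#'
#' Draws the protonation state from its exact conditional at fixed position,
#' `P(deprotonated | z, pH) = 1 / (1 + 10^(pKa(z) - pH))` — the surrogate
#' for a full Poisson-Boltzmann/Monte-Carlo re-equilibration of protonation
#' at fixed conformation.  Being an exact heat-bath kernel it satisfies
#' detailed balance by construction.
#'
#' @inheritParams brownian_step
#' @param pH External pH.
#' @param u Optional uniform(0,1) draw (from the RNG when missing).
#' @return The frame with state resampled; position and time unchanged.
#' @export
titration_resample <- function(fr, pH, model, u = NULL) {
  if (is.null(u)) u <- stats::runif(1)
  p_deprot <- analytic_deprot_fraction(fr$z_nm, pH, model)
  fr$state <- if (u < p_deprot) "deprotonated" else "protonated"
  fr
}

# inner loop shared by run_segment and the exchange-coupled chunks.
# step_offset is the absolute step index of `z0` so titration/record
# cadence stays aligned across exchange chunks.
segment_core <- function(z0, s0, t0, n_steps, step_offset, model, window,
                         pH, dt, D, sched, record_initial = TRUE) {
  tabs <- model_term_tables(model)
  b <- model$thermo$beta
  ln10 <- log(10)
  pka_w <- model$pka_w
  zref <- model$z_water_ref
  uref_p <- raw_terms_energy(zref, model$terms$protonated)
  uref_d <- raw_terms_energy(zref, model$terms$deprotonated)
  wk <- if (is.null(window)) 0 else window$k
  wxi <- if (is.null(window)) 0 else window$xi_ref
  amp <- sqrt(2 * D * dt)
  drift <- b * D * dt
  # splitting integrator for biased runs: the harmonic bias is integrated
  # exactly as an Ornstein-Uhlenbeck step (stable for any k * dt), the soft
  # model force explicitly.  a = exp(-beta D k dt) is the OU decay factor.
  if (wk > 0) {
    a_ou <- exp(-b * D * wk * dt)
    drift_ou <- (1 - a_ou) / wk          # multiplies the model force
    amp_ou <- sqrt((1 - a_ou^2) / (b * wk))
  }

  n_rec_max <- n_steps %/% sched$record_every + 2L
  rec_t <- numeric(n_rec_max); rec_z <- numeric(n_rec_max)
  rec_s <- character(n_rec_max); rec_b <- numeric(n_rec_max)
  nr <- 0L
  titration_attempts <- 0L

  z <- z0
  s <- s0  # "protonated"/"deprotonated"
  if (record_initial) {
    nr <- nr + 1L
    rec_t[nr] <- t0; rec_z[nr] <- z; rec_s[nr] <- s
    rec_b[nr] <- 0.5 * wk * (z - wxi)^2
  }
  if (n_steps > 0) {
    eta <- stats::rnorm(n_steps)
    for (k in seq_len(n_steps)) {
      abs_step <- step_offset + k - 1L
      if (abs_step %% sched$titration_every == 0L) {
        du <- (raw_terms_energy(z, model$terms$deprotonated) - uref_d) -
          (raw_terms_energy(z, model$terms$protonated) - uref_p)
        pka <- pka_w + b * du / ln10
        p_deprot <- 1 / (1 + 10^(pka - pH))
        s <- if (stats::runif(1) < p_deprot) "deprotonated" else "protonated"
        titration_attempts <- titration_attempts + 1L
      }
      g <- grad_from_table(z, tabs[[s]])
      if (!is.finite(g))
        stop("non-finite force at z = ", z, " (potential misconfiguration)")
      if (wk > 0) {
        z <- wxi + (z - wxi) * a_ou - g * drift_ou + amp_ou * eta[k]
      } else {
        z <- z - drift * g + amp * eta[k]
      }
      if ((abs_step + 1L) %% sched$record_every == 0L) {
        nr <- nr + 1L
        rec_t[nr] <- t0 + k * dt; rec_z[nr] <- z; rec_s[nr] <- s
        rec_b[nr] <- 0.5 * wk * (z - wxi)^2
      }
    }
  }
  list(time = rec_t[seq_len(nr)], z = rec_z[seq_len(nr)],
       state = rec_s[seq_len(nr)], bias = rec_b[seq_len(nr)],
       z_final = z, s_final = s, t_final = t0 + n_steps * dt,
       titration_attempts = titration_attempts)
}

#' Run one constant-pH segment
#'
#' Alternates Brownian dynamics with heat-bath titration per the schedule
#' (titration attempts at t = 0, then every `titration_period`), recording
#' a frame every `record_period` plus the initial frame.  Reproducible
#' given the RNG state: call `set.seed()` beforehand.
#'
#' @param initial A [frame()] giving the starting state.
#' @param model A [toy_model()].
#' @param window Umbrella [window()] or `NULL` for an unbiased run.
#' @param sched A [schedule()].
#' @param D Diffusion coefficient, nm^2 per time unit.
#' @return Record table (data.frame) in the schema of [frame()], with
#'   `equilibration_flag = time < equilibration_cutoff` and an attribute
#'   `titration_attempts`.
#' @export
run_segment <- function(initial, model, window = NULL, sched, D = 0.1) {
  res <- segment_core(initial$z_nm, initial$state, initial$time,
                      sched$n_steps, step_offset = 0L, model, window,
                      initial$pH, sched$dt, D, sched)
  out <- data.frame(
    time = res$time, replica_id = initial$replica_id,
    replicate_index = initial$replicate_index, pH = initial$pH,
    window_id = if (is.null(window)) NA_character_ else window$window_id,
    z_nm = res$z, state = res$state, bias_kJmol = res$bias,
    equilibration_flag = res$time < sched$equilibration_cutoff,
    stringsAsFactors = FALSE)
  attr(out, "titration_attempts") <- res$titration_attempts
  out
}

#' Run a full sampling campaign
#'
#' Orchestrates replicates over a pH ladder and/or an umbrella-window
#' ladder with one of four methods:
#' \describe{
#'   \item{`cphmd`}{independent unbiased constant-pH runs, one per
#'     (replicate, pH);}
#'   \item{`phre`}{per replicate, one replica per pH value running
#'     synchronously with Metropolis pH-label swaps between adjacent pH
#'     values every `exchange_period` (first attempt at `exchange_offset`);}
#'   \item{`us`}{independent umbrella runs, one per (replicate, pH,
#'     window);}
#'   \item{`reus`}{per (replicate, pH), one replica per umbrella window
#'     with Metropolis window swaps between adjacent windows.}
#' }
#' Exchange sweeps alternate even/odd adjacent pairs deterministically;
#' accepted swaps exchange the ladder labels (pH value or window
#' reference), not the coordinates.  A ladder with a single rung disables
#' exchange with a warning.
#'
#' @param config A `campaign_config` (see [campaign_config()] /
#'   [load_config()]).
#' @return Record table covering replicates x (pH ladder | windows), with
#'   attributes `exchange_log` (data.frame of every attempt: time, pair,
#'   delta, accepted, uniform draw), `titration_attempts` and `manifest`
#'   (method, seeds, ladders).
#' @export
run_campaign <- function(config) {
  config <- validate_campaign_config(config)
  model <- config$model
  sched <- config$schedule
  method <- config$method
  D <- config$diffusion

  records <- list()
  xlog <- list()
  tit_total <- 0L
  z0 <- if (is.null(config$z_init)) model$z_water_ref else config$z_init

  for (r in seq_len(config$replicates)) {
    set.seed(config$seeds[r])
    if (method == "cphmd") {
      for (ph in config$ph_ladder) {
        fr <- frame(replica_id = sprintf("r%d_pH%g", r, ph),
                    replicate_index = r, pH = ph, z = z0,
                    s = initial_state(model, z0, ph))
        seg <- run_segment(fr, model, NULL, sched, D)
        tit_total <- tit_total + attr(seg, "titration_attempts")
        records[[length(records) + 1L]] <- seg
      }
    } else if (method == "us") {
      for (ph in config$ph_ladder) for (w in config$windows) {
        fr <- frame(replica_id = sprintf("r%d_pH%g_%s", r, ph, w$window_id),
                    replicate_index = r, pH = ph, z = w$xi_ref,
                    s = initial_state(model, w$xi_ref, ph))
        seg <- run_segment(fr, model, w, sched, D)
        tit_total <- tit_total + attr(seg, "titration_attempts")
        records[[length(records) + 1L]] <- seg
      }
    } else if (method == "phre") {
      out <- run_exchange_coupled(
        ladder = config$ph_ladder, mode = "phre", model = model,
        sched = sched, D = D, replicate_index = r, z0 = z0,
        windows = NULL, pH_fixed = NA)
      records[[length(records) + 1L]] <- out$records
      xlog[[length(xlog) + 1L]] <- out$exchange_log
      tit_total <- tit_total + out$titration_attempts
    } else { # reus
      for (ph in config$ph_ladder) {
        out <- run_exchange_coupled(
          ladder = config$windows, mode = "reus", model = model,
          sched = sched, D = D, replicate_index = r, z0 = NA,
          windows = config$windows, pH_fixed = ph)
        records[[length(records) + 1L]] <- out$records
        xlog[[length(xlog) + 1L]] <- out$exchange_log
        tit_total <- tit_total + out$titration_attempts
      }
    }
  }
  records <- do.call(rbind, records)
  rownames(records) <- NULL
  attr(records, "exchange_log") <-
    if (length(xlog)) do.call(rbind, xlog) else empty_exchange_log()
  attr(records, "titration_attempts") <- tit_total
  attr(records, "manifest") <- list(
    method = method, replicates = config$replicates, seeds = config$seeds,
    ph_ladder = config$ph_ladder,
    windows = if (is.null(config$windows)) NULL else
      vapply(config$windows, function(w) w$xi_ref, 0),
    schedule = sched[c("dt", "n_steps", "titration_period", "record_period",
                       "exchange_period", "exchange_offset",
                       "equilibration_cutoff")])
  records
}

initial_state <- function(model, z, pH) {
  if (analytic_deprot_fraction(z, pH, model) >= 0.5) "deprotonated"
  else "protonated"
}

empty_exchange_log <- function() {
  data.frame(time = numeric(0), replicate_index = integer(0),
             pH = numeric(0), i = integer(0), j = integer(0),
             label_i = character(0), label_j = character(0),
             delta = numeric(0), accepted = logical(0),
             uniform_draw = numeric(0), stringsAsFactors = FALSE)
}

# synchronous multi-replica run with exchange; ladder slots hold either pH
# values (phre) or windows (reus).  Replica k keeps its own continuous
# trajectory; accepted swaps exchange the ladder labels between replicas.
run_exchange_coupled <- function(ladder, mode, model, sched, D,
                                 replicate_index, z0, windows, pH_fixed) {
  n <- length(ladder)
  if (n < 2) warning("ladder has fewer than 2 rungs; exchange disabled")
  exchange_on <- n >= 2 && !is.na(sched$exchange_every)

  # slot[k]: ladder slot currently held by replica k
  slot <- seq_len(n)
  if (mode == "phre") {
    z <- rep(z0, n)
    s <- vapply(seq_len(n), function(k)
      initial_state(model, z[k], ladder[[k]]), "")
  } else {
    z <- vapply(ladder, function(w) w$xi_ref, 0)
    s <- vapply(seq_len(n), function(k)
      initial_state(model, z[k], pH_fixed), "")
  }
  tcur <- 0
  step_abs <- 0L
  parity <- "even"
  chunks <- list()
  xlog <- list()
  tit <- 0L

  # absolute step indices at which exchange is attempted
  next_x_step <- if (exchange_on) sched$exchange_offset_steps else NA_integer_
  total_steps <- sched$n_steps

  repeat {
    n_chunk <- if (!exchange_on || is.na(next_x_step))
      total_steps - step_abs
    else min(next_x_step, total_steps) - step_abs
    if (n_chunk > 0 || step_abs == 0L) {
      for (k in seq_len(n)) {
        ph_k <- if (mode == "phre") ladder[[slot[k]]] else pH_fixed
        win_k <- if (mode == "reus") windows[[slot[k]]] else NULL
        res <- segment_core(z[k], s[k], tcur, n_chunk, step_abs, model,
                            win_k, ph_k, sched$dt, D, sched,
                            record_initial = (step_abs == 0L))
        tit <- tit + res$titration_attempts
        z[k] <- res$z_final; s[k] <- res$s_final
        nrec <- length(res$time)
        if (nrec > 0) {
          chunks[[length(chunks) + 1L]] <- data.frame(
            time = res$time,
            replica_id = sprintf("r%d_k%02d", replicate_index, k),
            replicate_index = replicate_index,
            pH = ph_k,
            window_id = if (mode == "reus") win_k$window_id
                        else NA_character_,
            z_nm = res$z, state = res$state, bias_kJmol = res$bias,
            equilibration_flag = res$time < sched$equilibration_cutoff,
            stringsAsFactors = FALSE)
        }
      }
      tcur <- tcur + n_chunk * sched$dt
      step_abs <- step_abs + n_chunk
    }
    if (step_abs >= total_steps) break
    # exchange attempt between adjacent ladder slots
    holder <- order(slot)  # holder[m]: replica currently holding slot m
    if (mode == "phre") {
      dfun <- function(m1, m2) {
        k1 <- holder[m1]; k2 <- holder[m2]
        phre_delta(as.integer(s[k1] == "protonated"),
                   as.integer(s[k2] == "protonated"),
                   ladder[[m1]], ladder[[m2]])
      }
    } else {
      dfun <- function(m1, m2) {
        k1 <- holder[m1]; k2 <- holder[m2]
        reus_delta(z[k1], z[k2], windows[[m1]], windows[[m2]],
                   model$thermo)
      }
    }
    sw <- exchange_sweep(n, parity, dfun, time = tcur)
    if (nrow(sw$decisions) > 0) {
      d <- sw$decisions
      d$replicate_index <- replicate_index
      d$pH <- if (mode == "reus") pH_fixed else NA_real_
      d$label_i <- ladder_label(ladder, d$i, mode)
      d$label_j <- ladder_label(ladder, d$j, mode)
      xlog[[length(xlog) + 1L]] <-
        d[, c("time", "replicate_index", "pH", "i", "j", "label_i",
              "label_j", "delta", "accepted", "uniform_draw")]
    }
    # apply accepted swaps: slots m1,m2 exchange their holders' labels
    for (m in seq_len(n)) {
      if (sw$swap[m] != m && sw$swap[m] > m) {
        m2 <- sw$swap[m]
        k1 <- holder[m]; k2 <- holder[m2]
        slot[k1] <- m2; slot[k2] <- m
      }
    }
    parity <- if (parity == "even") "odd" else "even"
    next_x_step <- next_x_step + sched$exchange_every
  }
  list(records = do.call(rbind, chunks),
       exchange_log = if (length(xlog)) do.call(rbind, xlog)
                      else empty_exchange_log(),
       titration_attempts = tit)
}

ladder_label <- function(ladder, idx, mode) {
  if (mode == "phre") as.character(unlist(ladder)[idx])
  else vapply(idx, function(i) ladder[[i]]$window_id, "")
}
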