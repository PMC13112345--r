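#' Build a campaign configuration
#'
#' Aggregates everything a sampling campaign needs: the surrogate model,
#' the schedule, the method, the pH and/or window ladders, replicates and
#' their seeds.  `run_campaign()` validates before running.
#'
#' @param model A [toy_model()].
#' @param schedule A [schedule()].
#' @param method One of `"cphmd"`, `"phre"`, `"us"`, `"reus"`.
#' @param ph_ladder Numeric pH values (for `us`/`reus` this may include
#'   the two extended values on the ionized side, see
#'   [extend_ph_ladder()]).
#' @param windows List of [window()]s (required for `us` / `reus`).
#' @param replicates Number of replicates.
#' @param seeds One RNG seed per replicate.
#' @param diffusion Diffusion coefficient, nm^2 per time unit.
#' @param z_init Initial position (nm); default the model's water
#'   reference.
#' @param analysis Named list of analysis settings (bins, gates,
#'   bootstrap counts, equilibration cutoff) carried along to reporting.
#' @return Object of class `campaign_config`.
#' @export
campaign_config <- function(model, schedule, method, ph_ladder,
                            windows = NULL, replicates = 1,
                            seeds = seq_len(replicates),
                            diffusion = 0.1, z_init = NULL,
                            analysis = list()) {
  structure(list(model = model, schedule = schedule, method = method,
                 ph_ladder = ph_ladder, windows = windows,
                 replicates = replicates, seeds = seeds,
                 diffusion = diffusion, z_init = z_init,
                 analysis = analysis),
            class = "campaign_config")
}

validate_campaign_config <- function(config) {
  if (!inherits(config, "campaign_config"))
    stop("config must be a campaign_config (see campaign_config() / load_config())")
  if (!config$method %in% c("cphmd", "phre", "us", "reus"))
    stop("method must be one of cphmd, phre, us, reus; got '",
         config$method, "'")
  if (!inherits(config$model, "toy_model")) stop("config$model must be a toy_model")
  if (!inherits(config$schedule, "schedule"))
    stop("config$schedule must be a schedule")
  if (length(config$ph_ladder) < 1 || any(!is.finite(config$ph_ladder)))
    stop("ph_ladder must contain at least one finite pH value")
  if (config$method %in% c("us", "reus")) {
    if (is.null(config$windows) || length(config$windows) == 0)
      stop("method '", config$method, "' requires a window ladder ",
           "(config block 'window_ladder')")
    ok <- vapply(config$windows, inherits, TRUE, what = "umbrella_window")
    if (!all(ok)) stop("windows must be umbrella_window objects")
  }
  if (config$replicates < 1) stop("replicates must be >= 1")
  if (length(config$seeds) != config$replicates)
    stop(sprintf("need one seed per replicate: %d replicates but %d seeds",
                 config$replicates, length(config$seeds)))
  if (config$diffusion <= 0) stop("diffusion must be > 0")
  config
}

known_keys <- list(
  top = c("model", "schedule", "method", "replicates", "seeds",
          "diffusion", "z_init", "ph_ladder", "window_ladder", "analysis"),
  model = c("residue_class", "pka_w", "temperature", "z_water_ref",
            "terms"),
  schedule = c("dt", "n_steps", "titration_period", "record_period",
               "exchange_period", "exchange_offset",
               "equilibration_cutoff"),
  ph_ladder = c("values", "extend"),
  window_ladder = c("start", "stop", "spacing", "k", "k_outer", "k_inner",
                    "k_boundary"),
  analysis = c("bin_width_A", "scan_from", "scan_to", "stride",
               "min_points", "mono_slack", "n_boot",
               "equilibration_cutoff"),
  term = c("shape", "amplitude", "center", "width"))

reject_unknown <- function(block, where) {
  unknown <- setdiff(names(block), known_keys[[where]])
  if (length(unknown))
    stop("unknown key(s) in '", where, "' block: ",
         paste(unknown, collapse = ", "))
  block
}

#' Load a campaign configuration from a YAML file
#'
#' Parses and fully validates a declarative campaign description,
#' rejecting unknown keys and filling defaults; see the shipped examples
#' under `system.file("extdata", package = "memtitr")`.
#'
#' @param path Path to a YAML config file.
#' @return A validated [campaign_config()].
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  reject_unknown(raw, "top")
  for (req in c("model", "method"))
    if (is.null(raw[[req]])) stop("config block '", req, "' is required")
  mb <- reject_unknown(raw$model, "model")
  if (is.null(mb$residue_class) || is.null(mb$pka_w))
    stop("'model' block requires residue_class and pka_w")
  if (!is.null(mb$terms)) {
    bad <- setdiff(names(mb$terms), c("protonated", "deprotonated"))
    if (length(bad))
      stop("unknown key(s) in 'model.terms' block: ",
           paste(bad, collapse = ", "))
  }
  parse_terms <- function(lst) {
    lapply(lst, function(t) {
      reject_unknown(t, "term")
      validate_term(t)
    })
  }
  model <- toy_model(
    residue_class = mb$residue_class, pka_w = mb$pka_w,
    terms_protonated = parse_terms(mb$terms$protonated),
    terms_deprotonated = parse_terms(mb$terms$deprotonated),
    temperature = mb$temperature %||% 300,
    z_water_ref = mb$z_water_ref %||% 2.0)

  sb <- reject_unknown(raw$schedule %||% list(), "schedule")
  sched <- schedule(
    dt = sb$dt %||% 0.1, n_steps = sb$n_steps %||% 1000,
    titration_period = sb$titration_period %||% 20,
    record_period = sb$record_period %||% 20,
    exchange_period = sb$exchange_period %||% NA,
    exchange_offset = sb$exchange_offset %||% 10,
    equilibration_cutoff = sb$equilibration_cutoff %||% 25)

  pb <- raw$ph_ladder
  ph <- if (is.null(pb)) 7 else if (is.list(pb)) {
    reject_unknown(pb, "ph_ladder")
    v <- as.numeric(pb$values)
    if (isTRUE(pb$extend)) extend_ph_ladder(v, model$residue_class) else v
  } else as.numeric(pb)

  windows <- NULL
  wb <- raw$window_ladder
  if (!is.null(wb)) {
    reject_unknown(wb, "window_ladder")
    for (req in c("start", "stop", "spacing"))
      if (is.null(wb[[req]]))
        stop("'window_ladder' block requires start, stop, spacing")
    k_rule <- if (!is.null(wb$k_outer)) {
      reus_k_rule(wb$k_outer, wb$k_inner %||% 1000, wb$k_boundary %||% 7)
    } else wb$k %||% 1000
    windows <- build_window_ladder(wb$start, wb$stop, wb$spacing, k_rule)
  }

  replicates <- raw$replicates %||% 1
  cfg <- campaign_config(
    model = model, schedule = sched, method = raw$method,
    ph_ladder = ph, windows = windows, replicates = replicates,
    seeds = as.integer(raw$seeds %||% seq_len(replicates)),
    diffusion = raw$diffusion %||% 0.1, z_init = raw$z_init,
    analysis = reject_unknown(raw$analysis %||% list(), "analysis"))
  validate_campaign_config(cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
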