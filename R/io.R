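# Experiment configuration, orchestration and plain-text serialization.

#' Load and validate an experiment configuration
#'
#' Reads a YAML experiment description and resolves it into validated
#' components.  Required fields: `model` (a built-in name, `"hh"` or
#' `"ca1"`, or an inline definition with `channels`, `leaks`, `c_m`),
#' `seed` (explicit; no implicit entropy), and `experiment` (one of
#' `"simulate"`, `"rate-vs-area"`, `"noise-report"`, `"ou-rates"`, `"sta"`).
#' Optional fields get documented defaults: `dt` 0.005 ms, `duration`
#' 5000 ms, `threshold` -20 mV, `refractory` 2 ms, `areas` 100,
#' `voltage` -65, `sigma_v` 8, `taus` 10^(-2..4), `modes` (per-population
#' gating mode overrides), `window` 10 ms.
#'
#' Inline channel definitions give, per channel: `name`, `density`,
#' `gamma`, `e_rev` and a list of `subunits`, each with `name`,
#' `multiplicity` and `alpha`/`beta` rate descriptors
#' (`form`: `linexp`, `expo` or `logistic`; parameters `a`, `vh`, `k`).
#'
#' @param path YAML file path.
#' @return List of class `cn_config` with the validated fields and a
#'   `model_fn(area)` factory.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) stop("config must set an explicit 'seed'")
  if (is.null(cfg$model)) stop("config must set 'model'")
  if (is.null(cfg$experiment)) stop("config must set 'experiment'")
  cfg$experiment <- match.arg(cfg$experiment,
    c("simulate", "rate-vs-area", "noise-report", "ou-rates", "sta"))
  defaults <- list(dt = 0.005, duration = 5000, threshold = -20,
                   refractory = 2, areas = 100, voltage = -65,
                   sigma_v = 8, taus = 10 ^ seq(-2, 4), window = 10,
                   burn_in = 200)
  cfg <- modifyList(defaults, cfg)
  if (cfg$dt <= 0) stop("non-positive dt in config")

  modes <- cfg$modes
  cfg$model_fn <- .resolve_model_fn(cfg$model, modes)
  # fail early on unresolvable schemes
  invisible(cfg$model_fn(cfg$areas[[1]]))
  structure(cfg, class = "cn_config")
}

.resolve_model_fn <- function(model, modes = NULL) {
  apply_modes <- function(m) {
    if (is.null(modes)) return(m)
    for (nm in names(modes)) {
      if (!nm %in% names(m$populations))
        stop("mode given for unknown population: ", nm)
      stopifnot(modes[[nm]] %in% c("stochastic", "deterministic"))
      m$populations[[nm]]$mode <- modes[[nm]]
    }
    m
  }
  if (is.character(model)) {
    fn <- switch(model,
      hh = hh_model, hh_table1 = hh_model, ca1 = ca1_model,
      stop("unknown model name: ", model))
    return(function(area) apply_modes(fn(area)))
  }
  # inline definition
  if (is.null(model$channels)) stop("inline model needs a 'channels' list")
  pops <- lapply(model$channels, function(ch) {
    for (fld in c("name", "density", "gamma", "e_rev", "subunits"))
      if (is.null(ch[[fld]])) stop("inline channel missing field: ", fld)
    subs <- lapply(ch$subunits, function(su) {
      if (is.logical(su$name))
        stop("subunit name was parsed as a YAML boolean; quote ",
             "single-letter names like \"n\" or \"y\" in the config")
      subunit_spec(su$name, su$multiplicity,
                   rate_pair(.rate_from_desc(su$alpha),
                             .rate_from_desc(su$beta)))
    })
    sch <- channel_scheme(ch$name, subs, gamma = ch$gamma, e_rev = ch$e_rev)
    register_scheme(ch$name, sch)
    population(sch, ch$density, ch$mode %||% "stochastic")
  })
  leaks <- if (is.null(model$leaks)) data.frame(g = 3, e = -55) else
    do.call(rbind, lapply(model$leaks, as.data.frame))
  c_m <- model$c_m %||% 1
  function(area) apply_modes(
    membrane_model(area, pops, leaks = leaks, c_m = c_m))
}

.rate_from_desc <- function(d) {
  if (is.null(d$form)) stop("rate descriptor missing 'form'")
  ctor <- switch(d$form, linexp = rate_linexp, expo = rate_expo,
                 logistic = rate_logistic,
                 stop("unknown rate form: ", d$form))
  ctor(d$a, d$vh, d$k)
}

#' Write / read a trace as delimited text
#'
#' Tab-separated values with `#`-commented header lines recording dt and
#' column meanings: time (ms), voltage (mV), one current column per
#' population (pA, outward positive), injected current (pA).
#'
#' @param trace a `cn_trace`.
#' @param path output file.
#' @return `write_trace()` the path, invisibly; `read_trace()` a `cn_trace`
#'   (without gating columns).
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "cn_trace"))
  inj <- trace$injected
  if (length(inj) == 1) inj <- rep(inj, length(trace$t))
  df <- data.frame(t = trace$t, v = trace$v, trace$currents,
                   injected = inj, check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# dt_ms: %.17g", trace$dt),
               sprintf("# area_um2: %.17g", trace$area %||% NA_real_),
               paste0("# columns: ", paste(names(df), collapse = "\t"))),
             con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  hdr <- readLines(path, n = 3)
  dt <- as.numeric(sub("# dt_ms: ", "", hdr[1]))
  area <- as.numeric(sub("# area_um2: ", "", hdr[2]))
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE)
  cur_cols <- setdiff(names(df), c("t", "v", "injected"))
  structure(list(dt = dt, t = df$t, v = df$v,
                 currents = as.matrix(df[cur_cols]),
                 injected = df$injected, gating = NULL,
                 spikes = numeric(0), area = area), class = "cn_trace")
}

#' Run a configured experiment and write its artifacts
#'
#' Dispatches on `config$experiment`, writes all outputs as delimited text
#' into `out_dir`, plus a `manifest.txt` recording the config hash, seed,
#' package version and the defaults actually used, so reruns are
#' reproducible bit for bit.
#'
#' @param config a `cn_config` from [load_config()] (or a path to one).
#' @param out_dir output directory (created if needed).
#' @return The output directory, invisibly.
#' @export
run_experiment <- function(config, out_dir) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "cn_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- config

  w <- function(df, name) {
    p <- file.path(out_dir, name)
    con <- file(p, "w")
    writeLines(paste0("# columns: ", paste(names(df), collapse = "\t")), con)
    utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
    close(con)
    p
  }

  outputs <- character(0)
  if (cfg$experiment == "simulate") {
    for (a in cfg$areas) {
      tr <- simulate_stochastic(cfg$model_fn(a), dt = cfg$dt,
                                t_max = cfg$duration, seed = cfg$seed,
                                threshold = cfg$threshold,
                                refractory = cfg$refractory)
      outputs <- c(outputs,
                   write_trace(tr, file.path(out_dir,
                                             sprintf("trace_area%g.tsv", a))),
                   w(data.frame(spike_ms = tr$spikes),
                     sprintf("spikes_area%g.tsv", a)))
    }
  } else if (cfg$experiment == "rate-vs-area") {
    res <- rate_vs_area(cfg$model_fn, cfg$areas, t_total = cfg$duration,
                        seed = cfg$seed, dt = cfg$dt,
                        threshold = cfg$threshold,
                        refractory = cfg$refractory, burn_in = cfg$burn_in)
    outputs <- c(outputs, w(res, "rate_vs_area.tsv"))
  } else if (cfg$experiment == "noise-report") {
    rep <- noise_report(cfg$model_fn(cfg$areas[[1]]), cfg$voltage)
    outputs <- c(outputs, w(rep, "noise_report.tsv"))
  } else if (cfg$experiment == "ou-rates") {
    res <- rate_vs_tau(cfg$model_fn(cfg$areas[[1]]), sigma_v = cfg$sigma_v,
                       taus = unlist(cfg$taus), t_total = cfg$duration,
                       seed = cfg$seed, dt = cfg$dt,
                       threshold = cfg$threshold,
                       refractory = cfg$refractory)
    outputs <- c(outputs, w(res, "ou_rates.tsv"))
  } else if (cfg$experiment == "sta") {
    tr <- simulate_stochastic(cfg$model_fn(cfg$areas[[1]]), dt = cfg$dt,
                              t_max = cfg$duration, seed = cfg$seed,
                              threshold = cfg$threshold,
                              refractory = cfg$refractory)
    sta <- sta_currents(tr, tr$spikes, window = cfg$window)
    df <- data.frame(lag_ms = sta$lags, sta$mean, check.names = FALSE)
    outputs <- c(outputs, w(df, "sta_currents.tsv"))
  }

  # manifest: config hash (via a canonical YAML dump), seed, version
  cfg_plain <- unclass(cfg)
  cfg_plain$model_fn <- NULL
  tmp <- file.path(out_dir, ".config_echo.yaml")
  yaml::write_yaml(cfg_plain, tmp)
  writeLines(c(
    sprintf("config_md5: %s", unname(tools::md5sum(tmp))),
    sprintf("seed: %s", cfg$seed),
    sprintf("dt_ms: %g", cfg$dt),
    sprintf("threshold_mv: %g", cfg$threshold),
    sprintf("refractory_ms: %g", cfg$refractory),
    sprintf("package_version: %s",
            as.character(utils::packageVersion("channelnoise"))),
    paste0("outputs: ", paste(basename(outputs), collapse = ", "))),
    file.path(out_dir, "manifest.txt"))
  invisible(out_dir)
}

#' Generate deterministic small test fixtures
#'
#' Produces the small plain-text fixtures used by the test suite, regenerated
#' on demand: a voltage-clamp open-count series (1000 um^2, 500 ms), one
#' spontaneous-spiking trace at 100 um^2 (10 s, thinned), and an OU current
#' series.  All content is a deterministic function of `seed`.
#'
#' @param seed integer seed.
#' @param dir output directory.
#' @param spiking_ms duration of the spiking fixture (ms).
#' @return Named character vector of file paths.
#' @export
make_fixtures <- function(seed, dir = tempdir(), spiking_ms = 10000) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vc <- voltage_clamp(hh_model(1000), v_hold = -65, t_max = 500, seed = seed,
                      thin = 20L)
  p1 <- file.path(dir, "clamp_open_counts.tsv")
  df <- data.frame(t = vc$t, vc$gating, check.names = FALSE)
  utils::write.table(df, p1, sep = "\t", row.names = FALSE, quote = FALSE)

  tr <- simulate_stochastic(hh_model(100), t_max = spiking_ms, seed = seed,
                            thin = 10L)
  p2 <- file.path(dir, "spiking_trace.tsv")
  write_trace(tr, p2)
  p3 <- file.path(dir, "spiking_spikes.tsv")
  utils::write.table(data.frame(spike_ms = tr$spikes), p3, sep = "\t",
                     row.names = FALSE, quote = FALSE)

  ou <- generate_ou(ou_spec(tau = 5, sigma_i = 10), dt = 0.1, t_max = 5000,
                    seed = seed)
  p4 <- file.path(dir, "ou_series.tsv")
  utils::write.table(data.frame(i_pa = ou), p4, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  c(clamp = p1, trace = p2, spikes = p3, ou = p4)
}
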