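#' Load a run configuration from YAML or JSON
#'
#' A configuration file has two optional top-level blocks: `params`
#' (overrides of [model_params()] values, by name) and `config`
#' (arguments of [model_config()]; the stimulus as a nested block with
#' `amplitude`, `t_on`, `duration`). Unknown keys at any level are a hard
#' error listing the offenders, so a typo can never silently fall back to
#' a default. An empty file yields pure defaults.
#'
#' @param path file path; `.yml`/`.yaml` parsed as YAML, else JSON.
#' @return A list with elements `params` (class `ab_params`), `config`
#'   (class `ab_config`) and `resolved` (the fully resolved values, for
#'   provenance sidecars).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path) else jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), c("params", "config"))
  if (length(unknown))
    stop("unknown top-level key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)

  params <- do.call(model_params, as.list(raw$params %||% list()))

  cfg_in <- as.list(raw$config %||% list())
  known_cfg <- names(formals(model_config))
  bad <- setdiff(names(cfg_in), known_cfg)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!is.null(cfg_in$stimulus))
    cfg_in$stimulus <- do.call(stimulus_protocol, as.list(cfg_in$stimulus))
  config <- do.call(model_config, cfg_in)

  list(params = params, config = config,
       resolved = resolve_run(params, config))
}

## full provenance record of a run (JSON-serialisable)
resolve_run <- function(params, config) {
  list(params = unclass(params),
       config = c(unclass(config)[setdiff(names(config), "stimulus")],
                  list(stimulus = unclass(config$stimulus))))
}

#' Read and write trace CSV files
#'
#' Traces are exchanged as CSV with a header row and columns `t`, `c`
#' and any further state variables; values round-trip at double
#' precision. `write_trace()` also writes a JSON sidecar
#' `<path>.meta.json` with the resolved parameters, configuration and
#' solver settings when the trace carries them.
#'
#' @param trace a data frame (e.g. from [simulate_model()]).
#' @param path CSV file path.
#' @return `read_trace()`: a tibble; `write_trace()`: `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  df <- as.data.frame(trace)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = NA),
                   path, row.names = FALSE, quote = FALSE)
  if (!is.null(attr(trace, "config"))) {
    meta <- resolve_run(attr(trace, "params"), attr(trace, "config"))
    meta$solver <- attr(trace, "solver")
    jsonlite::write_json(meta, paste0(path, ".meta.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
}

#' Reproduce a study scenario
#'
#' Each recipe runs the simulations and/or bifurcation scans of one of
#' the study's standard scenarios at its stated parameter values and
#' writes traces (CSV), per-trace classifications and detected
#' bifurcation points (JSON) into `outdir`.
#'
#' Available recipes: `fig2` (constant IP3, a=0: traces at p = 5, 10,
#' 18.5 and the p-branch), `fig3` (p=0 a-branch plus traces at a = 1.15,
#' 1.276), `fig5` (a=0.45 traces at p = 5, 20, 26, 45.5, 45.8, 50),
#' `fig7` (a=0.25, p=10 traces at k_alpha = 0.5, 0.9, 1, 1.25 plus the
#' k_alpha branch), `fig9` (dynamic IP3, a=0), `fig10` (dynamic IP3
#' a-branch plus traces at a = 0.75, 0.875, 1, 1.256), `fig12`
#' (membrane, a=0, p = 5..14 with a 300-unit pulse at t=100 for 50 s),
#' `fig13` (membrane, p in \{10, 15\} x a in \{0.2, 0.25, 0.28\}, same
#' pulse), `fig14` (membrane, p=10, a=0.258, p_s in \{0.5, 0.75, 1,
#' 1.5\}).
#'
#' @param name recipe name.
#' @param outdir output directory (created if needed).
#' @param params base parameters.
#' @return Invisibly, a list with the recipe's traces, classifications
#'   and (where applicable) branch scans.
#' @export
reproduce_figure <- function(name, outdir = ".",
                             params = model_params()) {
  recipes <- list(
    fig2 = function() {
      traces <- lapply(c(5, 10, 18.5), function(p)
        simulate_model(model_config(p = p, tmax = 300), params))
      names(traces) <- paste0("p", c(5, 10, 18.5))
      branch <- scan_branch("p", c(0.2, 60), steps = 120,
                            config = model_config(p = 1), params = params)
      list(traces = traces, branch = branch)
    },
    fig3 = function() {
      traces <- lapply(c(1.15, 1.276), function(a)
        simulate_model(model_config(p = 0, a = a, tmax = 300), params))
      names(traces) <- paste0("a", c(1.15, 1.276))
      branch <- scan_branch("a", c(0, 1.32), steps = 80,
                            config = model_config(p = 0), params = params)
      list(traces = traces, branch = branch)
    },
    fig5 = function() {
      ps <- c(5, 20, 26, 45.5, 45.8, 50)
      traces <- lapply(ps, function(p)
        simulate_model(model_config(p = p, a = 0.45, tmax = 500), params))
      names(traces) <- paste0("p", ps)
      list(traces = traces)
    },
    fig7 = function() {
      ks <- c(0.5, 0.9, 1, 1.25)
      traces <- lapply(ks, function(k)
        simulate_model(model_config(p = 10, a = 0.25, tmax = 500),
                       model_params(kalpha = k)))
      names(traces) <- paste0("kalpha", ks)
      branch <- scan_branch("kalpha", c(0.1, 1.5), steps = 70,
                            config = model_config(p = 10, a = 0.25),
                            params = params)
      list(traces = traces, branch = branch)
    },
    fig9 = function() {
      list(traces = list(
        a0 = simulate_model(model_config(variant = "dynamic_ip3",
                                         tmax = 500), params)))
    },
    fig10 = function() {
      as <- c(0.75, 0.875, 1, 1.256)
      traces <- lapply(as, function(a)
        simulate_model(model_config(variant = "dynamic_ip3", a = a,
                                    tmax = 500), params))
      names(traces) <- paste0("a", as)
      branch <- scan_branch("a", c(0, 1.3), steps = 80,
                            config = model_config(variant = "dynamic_ip3"),
                            params = params)
      list(traces = traces, branch = branch)
    },
    fig12 = function() {
      ps_vals <- c(5, 10, 12, 13, 13.5, 14)
      stim <- stimulus_protocol(300, 100, 50)
      traces <- lapply(ps_vals, function(p)
        simulate_model(model_config(variant = "with_membrane", p = p,
                                    ps = 1, stimulus = stim, tmax = 300),
                       params))
      names(traces) <- paste0("p", ps_vals)
      list(traces = traces)
    },
    fig13 = function() {
      stim <- stimulus_protocol(300, 100, 50)
      combos <- expand.grid(p = c(10, 15), a = c(0.2, 0.25, 0.28))
      traces <- purrr::pmap(combos, function(p, a)
        simulate_model(model_config(variant = "with_membrane", p = p,
                                    a = a, ps = 1, stimulus = stim,
                                    tmax = 300), params))
      names(traces) <- sprintf("p%g_a%g", combos$p, combos$a)
      list(traces = traces)
    },
    fig14 = function() {
      stim <- stimulus_protocol(300, 100, 50)
      pss <- c(0.5, 0.75, 1, 1.5)
      traces <- lapply(pss, function(s)
        simulate_model(model_config(variant = "with_membrane", p = 10,
                                    a = 0.258, ps = s, stimulus = stim,
                                    tmax = 300), params))
      names(traces) <- paste0("ps", pss)
      list(traces = traces)
    }
  )
  if (!name %in% names(recipes))
    stop("unknown recipe '", name, "'; available: ",
         paste(names(recipes), collapse = ", "), call. = FALSE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  res <- recipes[[name]]()

  for (nm in names(res$traces)) {
    tr <- res$traces[[nm]]
    write_trace(tr, file.path(outdir, paste0(name, "_", nm, ".csv")))
  }
  res$classifications <- lapply(res$traces, function(tr)
    tryCatch(classify_trace(tr), error = function(e) NULL))
  cls <- purrr::imap(res$classifications, function(cl, nm)
    if (is.null(cl)) list(trace = nm, label = "unresolved")
    else list(trace = nm, label = cl$label, n_peaks = cl$n_peaks,
              n_amplitude_classes = cl$n_amplitude_classes,
              periodicity_score = cl$periodicity_score,
              period = cl$period))
  jsonlite::write_json(unname(cls),
                       file.path(outdir, paste0(name, "_labels.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(res$branch))
    jsonlite::write_json(
      lapply(seq_len(nrow(res$branch$points)), function(i)
        as.list(res$branch$points[i, ])),
      file.path(outdir, paste0(name, "_bifurcations.json")),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}

#' Generate labelled classifier fixtures
#'
#' Writes a deterministic set of synthetic waveforms (periodic, MMO with
#' two compositions, aberrant, steady — each noiseless and with 1%
#' additive noise) plus two short model reference traces, together with
#' a `manifest.json` mapping file names to ground-truth labels.
#'
#' @param outdir output directory.
#' @param seed integer seed controlling the random components.
#' @return Invisibly, the manifest as a tibble.
#' @export
generate_fixtures <- function(outdir, seed = 1) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  waves <- list(
    periodic        = make_periodic_wave(),
    mmo_1L3s        = make_mmo_wave(composition = c(1, 0.25, 0.25, 0.25)),
    mmo_1L1s        = make_mmo_wave(composition = c(1, 0.3)),
    aberrant        = make_aberrant_wave(),
    steady          = make_steady_wave(),
    periodic_noisy  = make_periodic_wave(noise_sd = 0.006),
    mmo_noisy       = make_mmo_wave(composition = c(1, 0.25, 0.25),
                                    noise_sd = 0.006),
    aberrant_noisy  = make_aberrant_wave(noise_sd = 0.006)
  )
  model_refs <- list(
    model_p5  = simulate_model(model_config(p = 5, tmax = 60, dt = 0.1)),
    model_dyn = simulate_model(model_config(variant = "dynamic_ip3",
                                            tmax = 60, dt = 0.1))
  )
  manifest <- tibble::tibble(
    file = paste0(c(names(waves), names(model_refs)), ".csv"),
    label = c(unname(vapply(waves, attr, "", which = "label")),
              rep("model_reference", length(model_refs))),
    noisy = c(grepl("noisy", names(waves)), rep(FALSE, length(model_refs))))
  for (nm in names(waves))
    write_trace(waves[[nm]], file.path(outdir, paste0(nm, ".csv")))
  for (nm in names(model_refs))
    write_trace(model_refs[[nm]], file.path(outdir, paste0(nm, ".csv")))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       dataframe = "rows", pretty = TRUE)
  invisible(manifest)
}
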