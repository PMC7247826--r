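#' Read and validate a scenario configuration
#'
#' A scenario is a JSON object with fields `scenario_id`,
#' `expected_label`, `variant`, optional `circuit` / `scr` / `axon`
#' overrides (SI units), `duration_s`, optional `dt_max_s`, optional
#' `rules` overrides, and exactly one of:
#' \itemize{
#'   \item `stimulus` -- a single stimulus spec (`kind` plus its
#'     parameters),
#'   \item `stimuli` -- a list of two stimulus specs for the two-run
#'     behaviors (integrator, accommodation),
#'   \item `sweep` -- `{amplitudes, duration_s}` for the excitability
#'     classes, classified through the f-I curve.
#' }
#'
#' @param path path to a scenario JSON file.
#' @return An object of class `"ucn_scenario"`.
#' @export
read_scenario <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  for (f in c("scenario_id", "expected_label", "variant", "duration_s"))
    if (is.null(cfg[[f]]))
      stop("read_scenario: '", basename(path), "' is missing field '", f, "'")
  if (!cfg$expected_label %in% behavior_labels())
    stop("read_scenario: unknown expected_label '", cfg$expected_label, "'")
  n_modes <- sum(!vapply(cfg[c("stimulus", "stimuli", "sweep")], is.null,
                         logical(1)))
  if (n_modes != 1L)
    stop("read_scenario: '", basename(path),
         "' must declare exactly one of stimulus / stimuli / sweep")
  cfg$circuit <- do.call(circuit_params, as.list(cfg$circuit))
  cfg$scr <- do.call(scr_params, as.list(cfg$scr))
  cfg$axon <- do.call(axon_params, as.list(cfg$axon))
  if (!is.null(cfg$stimulus)) cfg$stimulus <- do.call(stimulus, cfg$stimulus)
  if (!is.null(cfg$stimuli)) {
    if (length(cfg$stimuli) != 2L)
      stop("read_scenario: 'stimuli' must hold exactly two runs")
    cfg$stimuli <- lapply(cfg$stimuli, function(s) do.call(stimulus, s))
  }
  if (!is.null(cfg$sweep)) {
    if (is.null(cfg$sweep$amplitudes) || is.null(cfg$sweep$duration_s))
      stop("read_scenario: 'sweep' needs amplitudes and duration_s")
    if (is.unsorted(cfg$sweep$amplitudes))
      stop("read_scenario: sweep amplitudes must be sorted ascending")
  }
  cfg$path <- path
  structure(cfg, class = "ucn_scenario")
}

scenario_rules <- function(scenario) {
  tau <- ucn_tau(scenario$circuit)
  rules <- behavior_rules(tau = tau)
  for (nm in names(scenario$rules)) {
    if (!nm %in% names(rules))
      stop("run_scenario: unknown rule threshold '", nm, "'")
    rules[[nm]] <- scenario$rules[[nm]]
  }
  rules
}

#' Run one scenario end to end
#'
#' Builds the circuit, runs the stimulus (or stimulus set), classifies
#' the outcome, optionally writes the trace CSV, and returns a record.
#' Simulation failures are caught and reported as a failed record so a
#' battery can continue.
#'
#' @param scenario a [read_scenario()] object (or path to one).
#' @param out_dir directory for trace CSV output, or `NULL` to skip
#'   writing.
#' @return A record: list with `scenario_id`, `expected_label`,
#'   `observed_label`, `metrics`, `trace` (file name or `NA`), `pass`,
#'   `status`, `message`.
#' @export
run_scenario <- function(scenario, out_dir = NULL) {
  if (is.character(scenario)) scenario <- read_scenario(scenario)
  rec <- list(scenario_id = scenario$scenario_id,
              expected_label = scenario$expected_label,
              observed_label = "unclassified",
              metrics = list(), trace = NA_character_,
              pass = FALSE, status = "ok", message = "")
  res <- tryCatch({
    sys <- ucn_circuit(scenario$variant, scenario$circuit, scenario$scr,
                       scenario$axon)
    rules <- scenario_rules(scenario)
    dt_max <- if (!is.null(scenario$dt_max_s)) scenario$dt_max_s else 1e-4
    sim <- function(stim, t_end)
      simulate(sys, stimulus = stim, t_end = t_end, dt_max = dt_max)
    traces <- list()

    if (!is.null(scenario$sweep)) {
      fi <- f_i_curve(sys, scenario$sweep$amplitudes,
                      scenario$sweep$duration_s,
                      negative = sys$circuit$polarity < 0, dt_max = dt_max)
      label <- classify_excitability(fi, rules$f_eps, rules$f_jump)
      nz <- fi$frequency[fi$frequency > 0]
      metrics <- list(n_amplitudes = nrow(fi),
                      f_min_nonzero = if (length(nz)) min(nz) else 0,
                      f_max = max(fi$frequency))
      traces$trace <- sim(stimulus("step", t_on = 0,
                                   amplitude = max(scenario$sweep$amplitudes)),
                          scenario$sweep$duration_s)
    } else if (!is.null(scenario$stimuli)) {
      tr1 <- sim(scenario$stimuli[[1L]], scenario$duration_s)
      tr2 <- sim(scenario$stimuli[[2L]], scenario$duration_s)
      n1 <- length(event_times(tr1))
      n2 <- length(event_times(tr2))
      kinds <- vapply(scenario$stimuli, `[[`, character(1), "kind")
      win <- rules$onset_window * rules$tau
      label <- "unclassified"
      if (all(kinds == "paired_pulse")) {
        # fires when the pulses arrive close together, silent when apart
        if (n1 >= 1L && n2 == 0L) label <- "integrator"
      } else if (kinds[1L] == "ramp" && kinds[2L] == "step") {
        # silent under the slow ramp, fires for the equal-amplitude step
        t2 <- event_times(tr2)
        if (n1 == 0L && n2 >= 1L &&
            t2[1L] - scenario$stimuli[[2L]]$t_on <= win)
          label <- "accommodation"
      }
      metrics <- list(n_spikes_run1 = n1, n_spikes_run2 = n2)
      traces$trace_run1 <- tr1
      traces$trace_run2 <- tr2
    } else {
      tr <- sim(scenario$stimulus, scenario$duration_s)
      label <- classify_behavior(tr, scenario$stimulus, rules)
      st <- event_times(tr)
      metrics <- list(n_spikes = length(st))
      if (length(st) >= 3L)
        metrics$adaptation_index <- adaptation_index(diff(st))
      if (length(st) >= 1L)
        metrics$latency_s <- st[1L] - scenario$stimulus$t_on
      traces$trace <- tr
    }
    list(label = label, metrics = metrics, traces = traces)
  }, error = function(e) e)

  if (inherits(res, "error")) {
    rec$status <- "failed"
    rec$message <- conditionMessage(res)
    return(rec)
  }
  rec$observed_label <- res$label
  rec$metrics <- res$metrics
  rec$pass <- identical(res$label, scenario$expected_label)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    suffix <- sub("^trace", "", names(res$traces))
    files <- paste0(scenario$scenario_id, suffix, ".csv")
    for (k in seq_along(res$traces))
      write_trace(res$traces[[k]], file.path(out_dir, files[k]))
    rec$trace <- files[1L]
  }
  rec
}

#' Run a battery of scenarios
#'
#' Executes every scenario JSON in `config_dir` (alphabetically), writes
#' per-scenario trace CSVs and a `report.json` to `out_dir`, and prints a
#' summary. The run is fully deterministic: repeated executions produce
#' byte-identical reports and traces.
#'
#' @param config_dir directory of scenario JSON files; defaults to the
#'   twelve shipped scenarios.
#' @param out_dir output directory, or `NULL` to skip writing.
#' @param quiet suppress the per-scenario progress lines.
#' @return An object of class `"ucn_battery_report"`: list with
#'   `scenarios` (records) and `summary` (`n_pass`, `n_total`).
#' @export
run_battery <- function(config_dir = system.file("extdata", "scenarios",
                                                 package = "ucnsim"),
                        out_dir = NULL, quiet = FALSE) {
  files <- sort(list.files(config_dir, pattern = "\\.json$",
                           full.names = TRUE))
  if (!length(files)) stop("run_battery: no scenario files in ", config_dir)
  scenarios <- lapply(files, read_scenario)
  ids <- vapply(scenarios, `[[`, character(1), "scenario_id")
  if (anyDuplicated(ids))
    stop("run_battery: duplicate scenario_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  records <- vector("list", length(scenarios))
  for (k in seq_along(scenarios)) {
    rec <- run_scenario(scenarios[[k]], out_dir = out_dir)
    if (!quiet)
      message(sprintf("[%s] expected %-26s observed %-26s %s",
                      rec$scenario_id, rec$expected_label,
                      rec$observed_label,
                      if (rec$pass) "PASS" else "FAIL"))
    records[[k]] <- rec
  }
  report <- structure(
    list(scenarios = records,
         summary = list(n_pass = sum(vapply(records, `[[`, logical(1),
                                            "pass")),
                        n_total = length(records))),
    class = "ucn_battery_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(unclass(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if (!quiet) print(report)
  invisible(report)
}

#' Count of distinct behaviors correctly reproduced by a battery
#'
#' @param report a [run_battery()] report.
#' @return Number of distinct behavior labels whose scenario classified
#'   to its intended label.
#' @export
behaviors_reproduced <- function(report) {
  ok <- vapply(report$scenarios, `[[`, logical(1), "pass")
  length(unique(vapply(report$scenarios[ok], `[[`, character(1),
                       "observed_label")))
}

#' @export
print.ucn_battery_report <- function(x, ...) {
  cat(sprintf("UCN behavior battery: %d / %d scenarios reproduced (%d distinct behaviors)\n",
              x$summary$n_pass, x$summary$n_total, behaviors_reproduced(x)))
  for (rec in x$scenarios)
    cat(sprintf("  %-16s %-28s -> %-28s %s\n", rec$scenario_id,
                rec$expected_label, rec$observed_label,
                if (rec$pass) "ok"
                else if (rec$status == "failed")
                  paste("FAILED:", rec$message) else "MISMATCH"))
  invisible(x)
}
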