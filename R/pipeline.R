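#' Write a CoG/g result to CSV and JSON
#'
#' The CSV carries one row per cost category plus a total row; the JSON
#' carries the full result.
#'
#' @param result A `cog_result` from [cog_per_gram()].
#' @param stem Output path without extension.
#' @return The two paths, invisibly.
#' @export
write_cog_result <- function(result, stem) {
  bd <- breakdown_shares(result)
  out <- rbind(
    data.frame(category = bd$category, annual_cost = bd$annual_cost,
               per_gram = bd$per_gram, share = bd$share),
    data.frame(category = "total", annual_cost = sum(bd$annual_cost),
               per_gram = result$cog_per_gram, share = 1)
  )
  csv <- paste0(stem, ".csv"); js <- paste0(stem, ".json")
  utils::write.csv(out, csv, row.names = FALSE)
  jsonlite::write_json(list(
    process = result$process, cog_per_gram = result$cog_per_gram,
    annual_mass = result$annual_mass, batches = result$batches,
    params = result$params,
    category_costs = as.list(result$category_costs)
  ), js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, js))
}

pipeline_commands <- c("cog", "sensitivity", "montecarlo", "surrogate",
                       "overlap", "all")

#' Run the analysis pipeline and write its artifacts
#'
#' Executes one stage (or `"all"`: deterministic CoG/g for the three
#' flowsheets, sensitivity grids, Monte Carlo per flowsheet, surrogate fits
#' on the Monte Carlo output, and the overlap analysis on the packaged
#' reference surrogates) and writes CSV tables, JSON summaries and a run
#' manifest into `out`. Given identical command, configuration and seed the
#' tabular outputs are byte-identical across runs.
#'
#' @param command One of `"cog"`, `"sensitivity"`, `"montecarlo"`,
#'   `"surrogate"`, `"overlap"`, `"all"`.
#' @param config A configuration tree from [load_config()] /
#'   [uricase_config()].
#' @param seed Integer seed used for every stochastic stage and recorded in
#'   the manifest and summaries.
#' @param out Output directory (created if absent).
#' @param n Optional run/draw count override (Monte Carlo runs, overlap
#'   draws).
#' @param processes Flowsheet ids to run (default all three).
#' @return Character vector of the files written, invisibly.
#' @export
run_pipeline <- function(command, config = uricase_config(), seed = 1,
                         out = ".", n = NULL,
                         processes = c("chromatography", "atps",
                                       "atps_recycle")) {
  if (!command %in% pipeline_commands) {
    abort(sprintf("unknown command '%s'; use one of: %s", command,
                  paste(pipeline_commands, collapse = ", ")))
  }
  processes <- match.arg(processes, several.ok = TRUE)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  fs <- uricase_flowsheets(config)[processes]
  models <- setNames(
    purrr::map(processes, function(p) uricase_costing(config, p)), processes)
  dists <- uricase_distributions(config)
  files <- character()
  add <- function(f) files <<- c(files, f)

  if (command %in% c("cog", "all")) {
    for (p in processes) {
      stem <- file.path(out, paste0("cog_", p))
      write_cog_result(cog_per_gram(fs[[p]], models[[p]]), stem)
      add(paste0(stem, c(".csv", ".json")))
    }
  }
  if (command %in% c("sensitivity", "all")) {
    for (p in processes) {
      entries <- tornado_rank(run_scenarios(fs[[p]], models[[p]],
                                            uricase_scenarios(config)))
      f <- file.path(out, paste0("sensitivity_", p, ".csv"))
      utils::write.csv(as.data.frame(entries), f, row.names = FALSE)
      add(f)
    }
  }
  mc_runs <- list()
  if (command %in% c("montecarlo", "surrogate", "all")) {
    n_mc <- n %||% config$monte_carlo$n_max
    for (i in seq_along(processes)) {
      p <- processes[i]
      mc <- run_monte_carlo(fs[[p]], models[[p]], dists, n_max = n_mc,
                            seed = seed + i - 1L,
                            window = config$monte_carlo$window,
                            tol = config$monte_carlo$tol)
      mc_runs[[p]] <- mc
      if (command != "surrogate") {
        f <- file.path(out, paste0("montecarlo_", p, ".csv"))
        utils::write.csv(as.data.frame(mc), f, row.names = FALSE)
        fj <- file.path(out, paste0("montecarlo_", p, "_summary.json"))
        jsonlite::write_json(as.list(glance(mc)), fj, auto_unbox = TRUE,
                             digits = NA)
        add(c(f, fj))
      }
    }
  }
  if (command %in% c("surrogate", "all")) {
    coefs <- dplyr::bind_rows(purrr::imap(mc_runs, function(mc, p) {
      td <- tidy(fit_linear(mc))
      td$process <- p
      td
    }))
    f <- file.path(out, "surrogate_coefficients.csv")
    utils::write.csv(as.data.frame(coefs), f, row.names = FALSE)
    add(f)
  }
  if (command %in% c("overlap", "all")) {
    s <- uricase_surrogates()
    ov <- overlap_analysis(s$chromatography, s$atps, dists,
                           n = n %||% 1e5, seed = seed)
    f <- file.path(out, "overlap.json")
    jsonlite::write_json(as.list(glance(ov)), f, auto_unbox = TRUE,
                         digits = NA)
    add(f)
  }

  manifest <- file.path(out, "manifest.json")
  jsonlite::write_json(list(
    command = command, seed = seed,
    processes = processes,
    package_version = as.character(utils::packageVersion("biocogs")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  ), manifest, auto_unbox = TRUE)
  add(manifest)
  invisible(files)
}
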