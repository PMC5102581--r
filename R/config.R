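#' Load and validate a model configuration
#'
#' Reads a YAML (or JSON) configuration tree describing flowsheets, the
#' costing fixture, ATPS/back-extraction parameters, sensitivity scenarios
#' and Monte Carlo distributions, and checks every embedded invariant.
#' Validation failures name the offending field and rule.
#'
#' @param path Path to a YAML or JSON file.
#' @return A validated configuration list (class `biocogs_config`).
#' @export
#' @examples
#' cfg <- load_config(system.file("extdata", "uricase.yaml", package = "biocogs"))
load_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  validate_config(cfg)
}

#' The packaged uricase configuration
#'
#' @return The validated configuration shipped in `extdata/uricase.yaml`.
#' @export
uricase_config <- function() {
  load_config(system.file("extdata", "uricase.yaml", package = "biocogs"))
}

#' Serialize a configuration tree back to YAML
#'
#' `load_config(write_config(cfg, path))` returns a tree identical to `cfg`.
#'
#' @param config A configuration list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

fail_field <- function(field, rule) {
  abort(sprintf("config field '%s' violates rule: %s", field, rule),
        class = "biocogs_config_error")
}

check_num <- function(x, field, lo = -Inf, hi = Inf, strict_lo = FALSE,
                      strict_hi = FALSE) {
  if (is.null(x) || !is.numeric(x) || length(x) != 1 || is.na(x)) {
    fail_field(field, "must be a single number")
  }
  if (strict_lo && x <= lo) fail_field(field, sprintf("must be > %g", lo))
  if (!strict_lo && x < lo) fail_field(field, sprintf("must be >= %g", lo))
  if (strict_hi && x >= hi) fail_field(field, sprintf("must be < %g", hi))
  if (!strict_hi && x > hi) fail_field(field, sprintf("must be <= %g", hi))
  invisible(x)
}

#' Validate a configuration tree
#'
#' @param cfg A configuration list.
#' @return `cfg` with class `biocogs_config`, or an error naming the field.
#' @export
validate_config <- function(cfg) {
  check_num(cfg$target_output, "target_output", 0, strict_lo = TRUE)
  check_num(cfg$fermenter_volume, "fermenter_volume", 0, strict_lo = TRUE)
  check_num(cfg$base$titer, "base.titer", 0, strict_lo = TRUE)

  if (is.null(cfg$flowsheets) || length(cfg$flowsheets) == 0) {
    fail_field("flowsheets", "at least one flowsheet must be defined")
  }
  for (id in names(cfg$flowsheets)) {
    ops <- cfg$flowsheets[[id]]$operations
    if (is.null(ops) || length(ops) == 0) {
      fail_field(paste0("flowsheets.", id, ".operations"), "must be non-empty")
    }
    for (i in seq_along(ops)) {
      o <- ops[[i]]
      pre <- sprintf("flowsheets.%s.operations[%d]", id, i)
      if (is.null(o$category) || !o$category %in% OP_CATEGORIES) {
        fail_field(paste0(pre, ".category"),
                   paste("must be one of", paste(OP_CATEGORIES, collapse = ", ")))
      }
      check_num(o$step_yield, paste0(pre, ".step_yield"), 0, 1, strict_lo = TRUE)
      check_num(o$volume_factor, paste0(pre, ".volume_factor"), 0, strict_lo = TRUE)
    }
    if (ops[[1]]$category != "fermentation") {
      fail_field(sprintf("flowsheets.%s.operations", id),
                 "must begin with a fermentation operation")
    }
    if (ops[[length(ops)]]$category != "ufdf") {
      fail_field(sprintf("flowsheets.%s.operations", id),
                 "must end with a ufdf operation")
    }
  }

  cst <- cfg$costing
  if (is.null(cst)) fail_field("costing", "section is required")
  for (p in names(cst$targets)) {
    check_num(cst$targets[[p]], paste0("costing.targets.", p), 0, strict_lo = TRUE)
  }
  for (p in names(cst$shares)) {
    sh <- cst$shares[[p]]
    if (!setequal(names(sh), COST_CATEGORIES)) {
      fail_field(paste0("costing.shares.", p),
                 paste("must name exactly the categories",
                       paste(COST_CATEGORIES, collapse = ", ")))
    }
    for (cat in names(sh)) {
      check_num(sh[[cat]], sprintf("costing.shares.%s.%s", p, cat), 0, 1)
    }
    if (abs(sum(unlist(sh)) - 1) > 1e-9) {
      fail_field(paste0("costing.shares.", p), "shares must sum to 1")
    }
  }
  for (i in seq_along(cst$materials)) {
    check_num(cst$materials[[i]]$cost, sprintf("costing.materials[%d].cost", i), 0)
  }
  check_num(cst$ufdf$filter_capacity, "costing.ufdf.filter_capacity", 0, strict_lo = TRUE)
  check_num(cst$ufdf$filter_cost, "costing.ufdf.filter_cost", 0)
  if (is.null(cst$wages[[cst$base_location]])) {
    fail_field("costing.base_location", "must name a location in costing.wages")
  }
  for (loc in names(cst$wages)) {
    for (role in names(cst$wages[[loc]])) {
      check_num(cst$wages[[loc]][[role]],
                sprintf("costing.wages.%s.%s", loc, role), 0)
    }
  }

  asys <- cfg$atps_system
  check_num(asys$system_volume_multiplier, "atps_system.system_volume_multiplier", 10, 20)
  check_num(asys$top_fraction, "atps_system.top_fraction", 0, 1,
            strict_lo = TRUE, strict_hi = TRUE)
  comp <- unlist(asys$composition)
  if (any(comp < 0) || sum(comp) >= 100) {
    fail_field("atps_system.composition",
               "component %w/w must be >= 0 and sum to < 100")
  }
  check_num(asys$second_system$volume_multiplier,
            "atps_system.second_system.volume_multiplier", 0, strict_lo = TRUE)

  rec <- cfg$recycle
  for (f in c("r_peg", "r_ammonium_sulfate", "r_nacl",
              "bottom_fraction_second_system")) {
    check_num(rec[[f]], paste0("recycle.", f), 0, 1)
  }

  for (d in names(cfg$distributions)) {
    tri <- cfg$distributions[[d]]
    tryCatch(triangular_dist(tri$low, tri$mode, tri$high),
             error = function(e) fail_field(paste0("distributions.", d),
                                            conditionMessage(e)))
  }

  structure(cfg, class = c("biocogs_config", "list"))
}

#' Packaged triangular distributions for the Monte Carlo analysis
#'
#' Titer ~ Triangular(0.392, 0.484, 0.577) g/L and DSP-yield delta ~
#' Triangular(-10, 0, +10) percentage points, mirroring the best/base/worst
#' sensitivity limits; an optional material-cost multiplier
#' Triangular(0.75, 1, 1.25) is also defined.
#'
#' @param config A configuration tree from [uricase_config()].
#' @return Named list of [triangular_dist()] objects.
#' @export
uricase_distributions <- function(config = uricase_config()) {
  purrr::map(config$distributions,
             function(d) triangular_dist(d$low, d$mode, d$high))
}
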