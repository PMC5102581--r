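#' Unit-operation categories recognised by the flowsheet model
#'
#' @format Character vector of the seven operation categories.
#' @export
OP_CATEGORIES <- c(
  "fermentation", "centrifugation", "homogenization",
  "chromatography", "atps", "back_extraction", "ufdf"
)

#' Define a single unit operation
#'
#' A unit operation is a yield/volume abstraction: it recovers a fraction
#' `step_yield` of the incoming product mass and multiplies the incoming
#' stream volume by `volume_factor`. No kinetic or physical modelling is
#' attached.
#'
#' @param name Text label.
#' @param category One of [OP_CATEGORIES].
#' @param step_yield Fraction of product recovered, in (0, 1].
#' @param volume_factor Positive multiplier applied to the incoming volume.
#' @param material_items,consumable_items Optional character vectors naming
#'   cost line items consumed by this operation.
#' @return A one-row tibble.
#' @export
#' @examples
#' unit_operation("capture column", "chromatography", 0.8)
unit_operation <- function(name, category, step_yield, volume_factor = 1,
                           material_items = character(),
                           consumable_items = character()) {
  category <- match.arg(category, OP_CATEGORIES)
  if (!is.numeric(step_yield) || length(step_yield) != 1 ||
      step_yield <= 0 || step_yield > 1) {
    abort(sprintf("step_yield of '%s' must be in (0, 1], got %s",
                  name, format(step_yield)))
  }
  if (!is.numeric(volume_factor) || volume_factor <= 0) {
    abort(sprintf("volume_factor of '%s' must be > 0", name))
  }
  tibble(
    name = as.character(name), category = category,
    step_yield = as.numeric(step_yield),
    volume_factor = as.numeric(volume_factor),
    material_items = list(material_items),
    consumable_items = list(consumable_items)
  )
}

#' Assemble a bioprocess flowsheet
#'
#' A flowsheet is an ordered sequence of unit operations starting with a
#' fermentation and ending with an ultrafiltration/diafiltration (UF/DF)
#' step, together with the fermenter working volume and the base titer.
#'
#' @param process_id One of `"chromatography"`, `"atps"`, `"atps_recycle"`
#'   (or any label for ad-hoc flowsheets).
#' @param fermenter_volume Working volume in litres (> 0).
#' @param titer Base product concentration in g/L (> 0).
#' @param operations A tibble of operations, e.g. built by row-binding
#'   [unit_operation()] calls.
#' @return A `flowsheet` object (a tibble of operations with attributes).
#' @export
flowsheet <- function(process_id, fermenter_volume, titer, operations) {
  if (!is_tibble(operations) || nrow(operations) == 0) {
    abort("operations must be a non-empty tibble of unit operations")
  }
  if (operations$category[1] != "fermentation") {
    abort("operations must begin with a fermentation-category operation")
  }
  if (operations$category[nrow(operations)] != "ufdf") {
    abort("operations must end with a ufdf-category operation")
  }
  if (fermenter_volume <= 0) abort("fermenter_volume must be > 0")
  if (titer <= 0) abort("titer must be > 0")
  structure(
    operations,
    process_id = process_id,
    fermenter_volume = as.numeric(fermenter_volume),
    titer = as.numeric(titer),
    class = c("flowsheet", class(operations))
  )
}

#' @export
print.flowsheet <- function(x, ...) {
  cat(sprintf("<flowsheet> %s: %g L fermentation at %g g/L, %d operations\n",
              attr(x, "process_id"), attr(x, "fermenter_volume"),
              attr(x, "titer"), nrow(x)))
  cat(sprintf("  downstream chain yield: %.4f\n", chain_yield(x)))
  NextMethod()
}

#' Composite downstream recovery of a flowsheet
#'
#' The product of `step_yield` over every operation downstream of
#' fermentation (the DSP yield). For the packaged fixtures this composes to
#' exactly 0.432 (chromatography) and 0.66 (ATPS).
#'
#' @param fs A [flowsheet()].
#' @return A fraction in (0, 1].
#' @export
#' @examples
#' chain_yield(uricase_flowsheets()$atps)
chain_yield <- function(fs) {
  if (!inherits(fs, "flowsheet")) abort("fs must be a flowsheet")
  if (nrow(fs) == 0) abort("flowsheet has no operations")
  prod(fs$step_yield[fs$category != "fermentation"])
}

#' Propagate product mass and stream volume through a flowsheet
#'
#' Starting from the fermenter volume and `fermenter_volume x titer` grams of
#' product, each operation multiplies the product mass by its `step_yield`
#' and the stream volume by its `volume_factor`. The stream entering an
#' operation is the stream leaving the previous one; `volume_in` is what
#' sizes volume-driven consumables such as UF/DF filters.
#'
#' @param fs A [flowsheet()].
#' @param titer Optional titer override in g/L (defaults to the flowsheet's).
#' @return A tibble with one row per operation: `name`, `category`,
#'   `volume_in`, `volume`, `product_mass` (post-operation values).
#' @export
propagate_stream <- function(fs, titer = NULL) {
  if (!inherits(fs, "flowsheet")) abort("fs must be a flowsheet")
  titer <- titer %||% attr(fs, "titer")
  if (titer <= 0) abort("titer must be > 0")
  v0 <- attr(fs, "fermenter_volume")
  vol <- v0 * cumprod(fs$volume_factor)
  mass <- v0 * titer * cumprod(fs$step_yield)
  tibble(
    name = fs$name, category = fs$category,
    volume_in = c(v0, head(vol, -1)),
    volume = vol, product_mass = mass
  )
}

#' Volume entering the UF/DF step
#'
#' @param fs A [flowsheet()].
#' @return Litres entering the final UF/DF operation.
#' @keywords internal
ufdf_feed_volume <- function(fs) {
  stream <- propagate_stream(fs)
  stream$volume_in[stream$category == "ufdf"][1]
}

#' Packaged uricase flowsheets
#'
#' Builds the three study flowsheets from the packaged configuration:
#'
#' * `chromatography` - fermentation, biomass centrifuge, homogenizer,
#'   debris centrifuge, three sequential chromatography columns, UF/DF;
#'   downstream composite yield 0.432.
#' * `atps` - the three columns replaced by a single aqueous two-phase
#'   extraction; composite yield 0.66. The forwarded stream is the
#'   product-bearing top phase (40% of a 12x system volume, i.e. 4.8x the
#'   sample).
#' * `atps_recycle` - `atps` with a back-extraction operation inserted after
#'   the ATPS step; the collected second-system bottom phase is 10x the
#'   original sample volume.
#'
#' @param config A configuration tree from [uricase_config()].
#' @return Named list of three [flowsheet()] objects.
#' @export
#' @examples
#' fs <- uricase_flowsheets()
#' sapply(fs, chain_yield)
uricase_flowsheets <- function(config = uricase_config()) {
  purrr::imap(config$flowsheets, function(def, id) {
    ops <- purrr::map(def$operations, function(o) {
      unit_operation(o$name, o$category, o$step_yield, o$volume_factor)
    })
    flowsheet(
      process_id = id,
      fermenter_volume = config$fermenter_volume,
      titer = config$base$titer,
      operations = dplyr::bind_rows(ops)
    )
  })
}
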