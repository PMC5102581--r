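#' Specify an aqueous two-phase system
#'
#' Geometry and composition of the first extraction stage. Mixing the sample
#' with PEG2000 and ammonium sulfate (plus NaCl) forms a system whose total
#' volume is `system_volume_multiplier` times the sample volume; the product
#' partitions all-or-nothing into `product_destination`, scaled by the step
#' recovery. Phase compositions are tracked in %w/w with density 1 kg/L.
#'
#' @param system_volume_multiplier Total system volume / sample volume. The
#'   packaged first system uses 12, inside the reported 10-20x range.
#' @param top_fraction Fraction of the system volume in the top phase (0, 1).
#' @param product_destination `"top"` or `"bottom"`.
#' @param composition Named %w/w of `peg`, `ammonium_sulfate`, `nacl` in the
#'   mixed system.
#' @param top_phase_partition Named fractions of each component partitioning
#'   into the top phase.
#' @return An `atps_spec` list.
#' @export
atps_spec <- function(system_volume_multiplier, top_fraction,
                      product_destination = c("top", "bottom"),
                      composition = c(peg = 14, ammonium_sulfate = 12, nacl = 3),
                      top_phase_partition = c(peg = 0.85,
                                              ammonium_sulfate = 0.30,
                                              nacl = 0.40)) {
  product_destination <- match.arg(product_destination)
  if (system_volume_multiplier <= 1) {
    abort("system_volume_multiplier must be > 1")
  }
  if (top_fraction <= 0 || top_fraction >= 1) {
    abort("top_fraction must be strictly between 0 and 1")
  }
  composition <- unlist(composition)
  if (any(composition < 0) || sum(composition) >= 100) {
    abort("composition %w/w must be >= 0 and sum to < 100")
  }
  structure(list(
    system_volume_multiplier = system_volume_multiplier,
    top_fraction = top_fraction,
    product_destination = product_destination,
    composition = composition,
    top_phase_partition = unlist(top_phase_partition)
  ), class = "atps_spec")
}

#' Specify the back-extraction recycle fractions
#'
#' Fractions of the per-batch component inventory returned to the first
#' system by the second-stage top phase, and the share of the second system
#' collected as the product-bearing bottom phase. The packaged values are
#' 60% PEG, 20% ammonium sulfate, 20% NaCl reuse and a 56% bottom fraction.
#'
#' @param r_peg,r_ammonium_sulfate,r_nacl Reuse fractions in \[0, 1\].
#' @param bottom_fraction_second_system Fraction of the second system's
#'   volume collected as bottom phase; must exceed 0.5 (the bottom phase is
#'   larger than the top in a working back-extraction).
#' @return A `recycle_spec` list.
#' @export
recycle_spec <- function(r_peg = 0.60, r_ammonium_sulfate = 0.20,
                         r_nacl = 0.20, bottom_fraction_second_system = 0.56) {
  for (f in c(r_peg, r_ammonium_sulfate, r_nacl,
              bottom_fraction_second_system)) {
    if (f < 0 || f > 1) abort("recycle fractions must be in [0, 1]")
  }
  structure(list(
    r_peg = r_peg, r_ammonium_sulfate = r_ammonium_sulfate, r_nacl = r_nacl,
    bottom_fraction_second_system = bottom_fraction_second_system
  ), class = "recycle_spec")
}

#' Packaged first-system and recycle specifications
#'
#' @param config A configuration tree from [uricase_config()].
#' @return List with elements `atps` (an [atps_spec()]), `recycle` (a
#'   [recycle_spec()]) and `second_system_volume_multiplier`.
#' @export
uricase_atps <- function(config = uricase_config()) {
  a <- config$atps_system
  list(
    atps = atps_spec(a$system_volume_multiplier, a$top_fraction,
                     a$product_destination, unlist(a$composition),
                     unlist(a$top_phase_partition)),
    recycle = recycle_spec(config$recycle$r_peg,
                           config$recycle$r_ammonium_sulfate,
                           config$recycle$r_nacl,
                           config$recycle$bottom_fraction_second_system),
    second_system_volume_multiplier = a$second_system$volume_multiplier,
    second_system_ammonium_sulfate_pct = a$second_system$ammonium_sulfate_pct
  )
}

#' Split a sample into the two phases of the first ATPS
#'
#' @param sample_volume Litres of sample entering the system (> 0).
#' @param spec An [atps_spec()].
#' @param recovery Product recovery of the extraction step, in (0, 1].
#' @param product_mass Grams of product in the sample.
#' @return List with `top` and `bottom` phases (each `volume` in L,
#'   `product_mass` in g, `components` in kg), the per-batch component
#'   `inventory` (kg), and `sample_volume`.
#' @export
#' @examples
#' split_system(1, atps_spec(12, 0.4), recovery = 1)
split_system <- function(sample_volume, spec, recovery = 1, product_mass = 1) {
  if (sample_volume <= 0) abort("sample_volume must be > 0")
  if (recovery <= 0 || recovery > 1) abort("recovery must be in (0, 1]")
  total_volume <- spec$system_volume_multiplier * sample_volume
  total_mass <- total_volume  # density 1 kg/L
  inventory <- spec$composition / 100 * total_mass
  top_volume <- spec$top_fraction * total_volume
  bottom_volume <- total_volume - top_volume
  p <- spec$top_phase_partition[names(inventory)]
  top_components <- inventory * p
  bottom_components <- inventory * (1 - p)
  dest_top <- spec$product_destination == "top"
  phase <- function(volume, components, mass) {
    list(volume = volume, product_mass = mass, components = components)
  }
  list(
    top = phase(top_volume, top_components,
                if (dest_top) product_mass * recovery else 0),
    bottom = phase(bottom_volume, bottom_components,
                   if (dest_top) 0 else product_mass * recovery),
    inventory = inventory,
    sample_volume = sample_volume
  )
}

#' Two-stage back-extraction with PEG/salt recycle
#'
#' The second system is built from the first system's top phase plus a fresh
#' ammonium sulfate charge that raises the salt content above the polymer
#' content, forcing the product into the (larger) bottom phase. The second
#' system's top phase returns the recycle fractions of the batch component
#' inventory to the first system; the collected bottom phase proceeds to
#' UF/DF.
#'
#' @param first Result of [split_system()] (the whole object, so the batch
#'   inventory and sample volume are available), with the product in the top
#'   phase.
#' @param recycle A [recycle_spec()].
#' @param second_system_volume Total second-system volume in litres. The
#'   packaged configuration uses `10 / 0.56` times the sample volume so the
#'   published bottom fraction (56%) and dilution factor (10x) hold
#'   simultaneously.
#' @param fresh_ammonium_sulfate_pct Target %w/w of ammonium sulfate in the
#'   second system after the fresh charge.
#' @return A `back_extraction` list: `bottom_volume`, `dilution_factor`
#'   (collected bottom volume / initial sample volume), `recycled_stream`
#'   (component kg returned to system 1), `fresh_demand` (steady-state fresh
#'   component kg per batch), `collected` (product-bearing phase),
#'   `discarded` and `fresh_inputs` (kg, for mass-balance audits).
#' @export
back_extract <- function(first, recycle, second_system_volume,
                         fresh_ammonium_sulfate_pct = 12) {
  if (!inherits(recycle, "recycle_spec")) abort("recycle must be a recycle_spec")
  if (recycle$bottom_fraction_second_system <= 0.5) {
    abort(paste("back-extraction requires the second-system bottom phase to",
                "exceed the top phase (bottom fraction > 0.5)"),
          class = "biocogs_phase_error")
  }
  top1 <- first$top
  if (top1$product_mass <= 0) {
    abort("back-extraction expects the product in the first-system top phase")
  }
  if (second_system_volume <= top1$volume) {
    abort("second_system_volume must exceed the first top-phase volume")
  }
  second_mass <- second_system_volume  # density 1 kg/L
  carried <- top1$components
  fresh_as <- max(0, fresh_ammonium_sulfate_pct / 100 * second_mass -
                    carried[["ammonium_sulfate"]])
  second_components <- carried
  second_components[["ammonium_sulfate"]] <-
    carried[["ammonium_sulfate"]] + fresh_as
  salt_pct <- second_components[["ammonium_sulfate"]] / second_mass * 100
  peg_pct <- second_components[["peg"]] / second_mass * 100
  if (salt_pct <= peg_pct) {
    abort(sprintf(paste(
      "back-extraction requires the second-system salt content (%.1f %%w/w)",
      "to exceed the polymer content (%.1f %%w/w)"), salt_pct, peg_pct),
      class = "biocogs_phase_error")
  }

  bottom_volume <- recycle$bottom_fraction_second_system * second_system_volume
  inventory <- first$inventory
  r <- c(peg = recycle$r_peg, ammonium_sulfate = recycle$r_ammonium_sulfate,
         nacl = recycle$r_nacl)[names(inventory)]
  recycled <- r * inventory
  if (any(recycled > second_components + 1e-12)) {
    abort("recycle fractions exceed the component mass present in the second system",
          class = "biocogs_phase_error")
  }
  bottom_components <- second_components - recycled

  structure(list(
    bottom_volume = bottom_volume,
    dilution_factor = bottom_volume / first$sample_volume,
    recycled_stream = recycled,
    fresh_demand = steady_state_fresh_demand(recycle, inventory),
    collected = list(volume = bottom_volume, product_mass = top1$product_mass,
                     components = bottom_components),
    discarded = first$bottom$components,
    fresh_inputs = c(first_system = sum(inventory) - sum(recycled),
                     second_system_as = fresh_as),
    second_system_volume = second_system_volume
  ), class = "back_extraction")
}

#' Steady-state fresh material demand under recycling
#'
#' Cycling batches with recycle fractions `r` converges after the first batch
#' to a fixed point where the fresh make-up per component is
#' `(1 - r) x per_batch_inventory`: reusing 60% of the PEG cuts its fresh
#' demand by 60%.
#'
#' @param recycle A [recycle_spec()].
#' @param per_batch_inventory Named vector of per-batch component masses
#'   (`peg`, `ammonium_sulfate`, `nacl`), any unit.
#' @return Named vector of fresh demand per batch, same unit.
#' @export
#' @examples
#' steady_state_fresh_demand(recycle_spec(), c(peg = 100))
steady_state_fresh_demand <- function(recycle, per_batch_inventory) {
  r <- c(peg = recycle$r_peg, ammonium_sulfate = recycle$r_ammonium_sulfate,
         nacl = recycle$r_nacl)
  inv <- per_batch_inventory
  (1 - r[names(inv)]) * inv
}

#' Run the packaged two-stage back-extraction worked example
#'
#' Convenience wrapper tying [split_system()] and [back_extract()] together
#' at the packaged configuration for an arbitrary sample volume.
#'
#' @param config A configuration tree from [uricase_config()].
#' @param sample_volume Litres entering the first ATPS (default 1).
#' @param product_mass Grams of product in the sample (default 1).
#' @return A `back_extraction` object; see [back_extract()].
#' @export
#' @examples
#' be <- uricase_back_extraction()
#' be$dilution_factor                      # 10
#' be$bottom_volume / be$second_system_volume # 0.56
uricase_back_extraction <- function(config = uricase_config(),
                                    sample_volume = 1, product_mass = 1) {
  spec <- uricase_atps(config)
  first <- split_system(sample_volume, spec$atps, recovery = 1,
                        product_mass = product_mass)
  back_extract(first, spec$recycle,
               spec$second_system_volume_multiplier * sample_volume,
               spec$second_system_ammonium_sulfate_pct)
}
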