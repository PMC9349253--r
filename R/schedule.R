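#' Trim/collect schedule approaching an expected position
#'
#' Reproduces the cutting protocol: coarse trimming in `trim_thickness_um`
#' steps until the blade is `approach_margin_um` short of the expected
#' position, then fine sections of `fine_thickness_um` which are inspected
#' and collected. The plan extends `approach_margin_um` past the expected
#' position so the target is bracketed.
#'
#' @param expected_advance_um Expected cutting-forward position, µm (must
#'   exceed the approach margin).
#' @param trim_thickness_um Trim step, µm (default 20).
#' @param fine_thickness_um Fine section thickness, µm (default 7).
#' @param approach_margin_um Margin before the expected position at which
#'   fine sectioning starts, µm (default 1000).
#' @return A `section_plan` tibble with columns `event`, `advance_start_um`,
#'   `thickness_um`, `kind` (`"trim"` or `"collect"`); events are contiguous
#'   and strictly increasing in advance.
#' @examples
#' plan <- plan_schedule(6100)
#' sum(plan$kind == "trim") # 255
#' @export
plan_schedule <- function(expected_advance_um, trim_thickness_um = 20,
                          fine_thickness_um = 7, approach_margin_um = 1000) {
  stopifnot(
    trim_thickness_um > 0, fine_thickness_um > 0, approach_margin_um >= 0
  )
  if (expected_advance_um <= approach_margin_um) {
    stop("expected advance must exceed the approach margin", call. = FALSE)
  }
  n_trim <- floor((expected_advance_um - approach_margin_um) / trim_thickness_um)
  fine_from <- n_trim * trim_thickness_um
  n_fine <- ceiling(
    (expected_advance_um + approach_margin_um - fine_from) / fine_thickness_um
  )
  events <- tibble::tibble(
    thickness_um = c(
      rep(trim_thickness_um, n_trim),
      rep(fine_thickness_um, n_fine)
    ),
    kind = c(rep("trim", n_trim), rep("collect", n_fine))
  )
  events <- dplyr::mutate(
    events,
    event = dplyr::row_number(),
    advance_start_um = cumsum(.data$thickness_um) - .data$thickness_um
  )
  new_section_plan(
    events[, c("event", "advance_start_um", "thickness_um", "kind")],
    expected_advance_um = expected_advance_um
  )
}

#' Serial survey schedule over a whole block
#'
#' The localization protocol: one collected fine section every
#' `interval_um` of advance, with trimming filling the gap between collected
#' sections. `floor(block_height / interval)` sections are collected;
#' collected mid-planes are spaced `interval_um` apart.
#'
#' @param block_height_um Block extent along the feed axis, µm.
#' @param fine_thickness_um Collected section thickness, µm (default 7).
#' @param interval_um Advance between consecutive collected sections, µm
#'   (default 100). `interval_um == fine_thickness_um` collects every section.
#' @return A `section_plan` tibble (see [plan_schedule()]).
#' @examples
#' sum(plan_serial_survey(6300)$kind == "collect") # 63
#' @export
plan_serial_survey <- function(block_height_um, fine_thickness_um = 7,
                               interval_um = 100) {
  stopifnot(fine_thickness_um > 0, interval_um >= fine_thickness_um)
  if (block_height_um <= interval_um) {
    stop("block height must exceed the survey interval", call. = FALSE)
  }
  n_collect <- floor(block_height_um / interval_um)
  gap <- interval_um - fine_thickness_um
  thick <- rep(c(fine_thickness_um, gap), n_collect)
  kind <- rep(c("collect", "trim"), n_collect)
  keep <- thick > 0
  thick <- thick[keep]
  kind <- kind[keep]
  # fill to the block height after the last collected section
  tail_start <- n_collect * interval_um
  if (block_height_um - tail_start > .tol_geom) {
    thick <- c(thick, block_height_um - tail_start)
    kind <- c(kind, "trim")
  }
  events <- tibble::tibble(thickness_um = thick, kind = kind)
  events <- dplyr::mutate(
    events,
    event = dplyr::row_number(),
    advance_start_um = cumsum(.data$thickness_um) - .data$thickness_um
  )
  new_section_plan(
    events[, c("event", "advance_start_um", "thickness_um", "kind")],
    expected_advance_um = NA_real_
  )
}

new_section_plan <- function(events, expected_advance_um = NA_real_) {
  stopifnot(all(diff(events$advance_start_um) > 0))
  stopifnot(max(abs(
    events$advance_start_um -
      (cumsum(events$thickness_um) - events$thickness_um)
  )) < .tol_geom)
  structure(
    events,
    class = c("section_plan", class(tibble::tibble())),
    expected_advance_um = expected_advance_um
  )
}

#' Total advance of a section plan
#'
#' @param plan A `section_plan` from [plan_schedule()] or
#'   [plan_serial_survey()].
#' @return Total advance in µm (sum of event thicknesses).
#' @export
total_advance <- function(plan) {
  stopifnot(inherits(plan, "section_plan"))
  sum(plan$thickness_um)
}
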