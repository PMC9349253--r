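# Plain-text serialization: CSV for tables (with `#` provenance comments),
# JSON for planes, plans and blocks.

provenance_lines <- function(config = NULL, seed = NULL) {
  h <- if (is.null(config)) {
    "none"
  } else {
    s <- paste(utils::capture.output(utils::str(config)), collapse = ";")
    sprintf("%08x", sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% 0xffffffff)
  }
  c(
    sprintf("# planecut %s", as.character(utils::packageVersion("planecut"))),
    sprintf("# config_hash=%s seed=%s", h, if (is.null(seed)) "NA" else seed)
  )
}

write_csv_prov <- function(df, path, config = NULL, seed = NULL) {
  con <- file(path, open = "w")
  on.exit(close(con))
  writeLines(provenance_lines(config, seed), con)
  utils::write.table(df, con,
    sep = ",", row.names = FALSE,
    col.names = TRUE, quote = FALSE
  )
  invisible(path)
}

#' Read / write target-center tables
#'
#' CSV schema: `name,x_um,y_um,z_um` (optionally `radius_um`,
#' `n_sections`, spreads). Lines starting with `#` are provenance comments.
#'
#' @param path File path.
#' @return A tibble of targets.
#' @export
read_targets <- function(path) {
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  if (nrow(df) == 0) stop("parse error: no target rows in ", path, call. = FALSE)
  as_targets(df)
}

#' @rdname read_targets
#' @param targets Target tibble.
#' @param config,seed Optional provenance recorded as comment lines.
#' @export
write_targets <- function(targets, path, config = NULL, seed = NULL) {
  write_csv_prov(as_targets(targets), path, config, seed)
}

#' Read / write cutting planes as JSON
#'
#' Schema: `{"normal": [nx, ny, nz], "point": [x, y, z]}`.
#'
#' @param path File path.
#' @return A [cutting_plane()].
#' @export
read_plane <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  cutting_plane(j$normal, j$point)
}

#' @rdname read_plane
#' @param plane A [cutting_plane()].
#' @export
write_plane <- function(plane, path) {
  stopifnot(inherits(plane, "cutting_plane"))
  jsonlite::write_json(
    list(normal = plane$normal, point = plane$point),
    path,
    auto_unbox = FALSE, digits = NA
  )
  invisible(path)
}

#' Read / write section observations
#'
#' CSV schema: `section_index,advance_um,target,present,x_um,y_um,rad_um`.
#'
#' @param path File path.
#' @return Observation tibble (column `rad_um` is read back as `radius_um`).
#' @export
read_observations <- function(path) {
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  if (nrow(df) == 0) stop("parse error: no observations in ", path, call. = FALSE)
  if ("rad_um" %in% names(df)) df <- dplyr::rename(df, radius_um = "rad_um")
  need <- c("section_index", "advance_um", "target", "present", "x_um", "y_um")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop(
      "parse error: missing observation columns ",
      paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  df$present <- as.logical(df$present)
  tibble::as_tibble(df)
}

#' @rdname read_observations
#' @param obs Observation tibble.
#' @param config,seed Optional provenance.
#' @export
write_observations <- function(obs, path, config = NULL, seed = NULL) {
  obs <- tibble::as_tibble(obs)
  if ("radius_um" %in% names(obs)) obs <- dplyr::rename(obs, rad_um = "radius_um")
  write_csv_prov(obs, path, config, seed)
}

#' Read / write section plans
#'
#' CSV schema: `section_index,advance_um,thickness_um,kind`.
#'
#' @param path File path.
#' @return A `section_plan` tibble.
#' @export
read_section_plan <- function(path) {
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  new_section_plan(tibble::tibble(
    event = df$section_index,
    advance_start_um = df$advance_um,
    thickness_um = df$thickness_um,
    kind = df$kind
  ))
}

#' @rdname read_section_plan
#' @param plan A `section_plan`.
#' @param config,seed Optional provenance.
#' @export
write_section_plan <- function(plan, path, config = NULL, seed = NULL) {
  stopifnot(inherits(plan, "section_plan"))
  out <- tibble::tibble(
    section_index = plan$event,
    advance_um = plan$advance_start_um,
    thickness_um = plan$thickness_um,
    kind = plan$kind
  )
  write_csv_prov(out, path, config, seed)
}

frame_to_list <- function(frame) {
  list(
    footprint_x = frame$footprint_x,
    footprint_y = frame$footprint_y,
    height = frame$height,
    plate_edge = frame$plate_edge,
    origin = frame$origin
  )
}

frame_from_list <- function(lst) {
  block_frame(
    lst$footprint_x, lst$footprint_y, lst$height,
    plate_edge = matrix(unlist(lst$plate_edge), nrow = 2),
    origin = unlist(lst$origin)
  )
}

#' Read / write virtual blocks as JSON
#'
#' @param path File path.
#' @return A [virtual_block()].
#' @export
read_block <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  blk <- virtual_block(frame_from_list(j$frame), tibble::as_tibble(j$targets))
  if (!is.null(j$seed)) attr(blk, "seed") <- j$seed
  blk
}

#' @rdname read_block
#' @param block A [virtual_block()].
#' @export
write_block <- function(block, path) {
  stopifnot(inherits(block, "virtual_block"))
  jsonlite::write_json(
    list(
      frame = frame_to_list(block$frame),
      targets = block$targets,
      seed = attr(block, "seed")
    ),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Reference validation tables of the three-target phantom study
#'
#' `threetarget_position_runs()` returns the foreknown target positions and
#' the four measurement rounds (µm magnitudes; one row per target and axis).
#' `threetarget_distance_runs()` returns the expected and actual
#' cutting-forward distances of the four sectioning runs (one row per target
#' and run). Both ship as plain-text fixtures under `inst/extdata/`.
#'
#' @return A tibble (see [build_report()] for the expected schemas).
#' @examples
#' build_report(threetarget_position_runs(), threetarget_distance_runs())
#' @export
threetarget_position_runs <- function() {
  readr::read_csv(
    system.file("extdata", "threetarget_positions.csv", package = "planecut"),
    comment = "#", show_col_types = FALSE
  )
}

#' @rdname threetarget_position_runs
#' @export
threetarget_distance_runs <- function() {
  readr::read_csv(
    system.file("extdata", "threetarget_distances.csv", package = "planecut"),
    comment = "#", show_col_types = FALSE
  )
}
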