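#' Per-image model: geometry, beam and observed spots
#'
#' The unit all indexing operates on. Spot centroids (fractional pixels
#' accepted) are back-projected onto the Ewald sphere on construction, so the
#' stored reciprocal coordinates are always consistent with the geometry and
#' beam carried by the object.
#'
#' @param id Image identifier.
#' @param geometry A [detector_geometry()].
#' @param beam A [beam()].
#' @param spots Data frame with columns `id`, `fast`, `slow` (pixels).
#' @return Object of class `"image_model"` with an additional `rlp` matrix
#'   (n x 3, inverse Angstrom).
#' @export
image_model <- function(id, geometry, beam, spots) {
  stopifnot(inherits(geometry, "detector_geometry"), inherits(beam, "beam"),
            is.data.frame(spots), all(c("id", "fast", "slow") %in% names(spots)))
  rlp <- if (nrow(spots) > 0)
    back_project(cbind(spots$fast, spots$slow), geometry, beam)
  else matrix(0, 0, 3)
  structure(list(id = id, geometry = geometry, beam = beam,
                 spots = spots, rlp = rlp),
            class = "image_model")
}

#' @export
print.image_model <- function(x, ...) {
  cat(sprintf("<image_model '%s': %d spots, D = %.2f mm, lambda = %.4f A>\n",
              x$id, nrow(x$spots), x$geometry$distance_mm,
              x$beam$wavelength_A))
  invisible(x)
}

#' Read experiment geometry and beam from a JSON config
#'
#' Expected keys: `wavelength_A`, `bandwidth`, `distance_mm`,
#' `beam_centre_px` (length 2), `pixel_size_mm`, `panel_px` (length 2).
#'
#' @param path JSON file path.
#' @return List with elements `geometry` and `beam`.
#' @export
read_geometry <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("wavelength_A", "distance_mm", "beam_centre_px", "pixel_size_mm",
            "panel_px")
  missing <- setdiff(need, names(cfg))
  if (length(missing) > 0)
    stop("geometry config missing keys: ", paste(missing, collapse = ", "))
  list(geometry = detector_geometry(cfg$distance_mm, cfg$beam_centre_px,
                                    cfg$pixel_size_mm, cfg$panel_px[1L],
                                    cfg$panel_px[2L]),
       beam = beam(cfg$wavelength_A,
                   if (is.null(cfg$bandwidth)) 0 else cfg$bandwidth))
}

#' Write experiment geometry and beam to a JSON config
#' @param geometry A [detector_geometry()].
#' @param beam A [beam()].
#' @param path Output path.
#' @export
write_geometry <- function(geometry, beam, path) {
  jsonlite::write_json(list(wavelength_A = beam$wavelength_A,
                            bandwidth = beam$bandwidth,
                            distance_mm = geometry$distance_mm,
                            beam_centre_px = geometry$beam_centre_px,
                            pixel_size_mm = geometry$pixel_size_mm,
                            panel_px = c(geometry$n_fast, geometry$n_slow)),
                       path, auto_unbox = TRUE, digits = NA)
}

#' Read a spot-centroid CSV as an image model
#'
#' The CSV must have a header with at least `id,fast_px,slow_px` (extra
#' columns are ignored). Rows with missing or non-numeric coordinates are
#' rejected with their row numbers.
#'
#' @param path CSV path.
#' @param geometry A [detector_geometry()].
#' @param beam A [beam()].
#' @param id Image id; defaults to the file name.
#' @return An [image_model()].
#' @export
read_spots <- function(path, geometry, beam, id = basename(path)) {
  if (!file.exists(path)) stop("spot file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "fast_px", "slow_px")
  if (!all(need %in% names(df)))
    stop("spot file must have header columns ", paste(need, collapse = ","),
         "; got: ", paste(names(df), collapse = ","))
  fast <- suppressWarnings(as.numeric(df$fast_px))
  slow <- suppressWarnings(as.numeric(df$slow_px))
  bad <- which(!is.finite(fast) | !is.finite(slow))
  if (length(bad) > 0)
    stop("non-numeric or missing spot coordinates in row(s): ",
         paste(bad, collapse = ", "))
  image_model(id, geometry, beam,
              data.frame(id = df$id, fast = fast, slow = slow))
}

#' Write spot centroids of an image to CSV
#' @param image An [image_model()].
#' @param path Output path.
#' @export
write_spots <- function(image, path) {
  utils::write.csv(data.frame(id = image$spots$id,
                              fast_px = image$spots$fast,
                              slow_px = image$spots$slow),
                   path, row.names = FALSE, quote = FALSE)
}

.solution_record <- function(sol) {
  list(U = matrix(sol$U, 3, 3), R = matrix(sol$R, 3, 3),
       network_size = if (is.null(sol$network_size)) NA else sol$network_size,
       stats = if (is.null(sol$stats)) NULL else
         list(stdev = sol$stats$stdev, peak_height = sol$stats$peak_height,
              n_assigned = sol$stats$n_assigned),
       accepted = isTRUE(sol$accepted))
}

#' Write per-image indexing solutions as JSON lines
#'
#' One JSON object per image: `{image, n_spots, solutions: [{U, R,
#' network_size, stats, accepted}]}`, matrices row-major.
#'
#' @param path Output path.
#' @param results List of per-image results, each a list with `image`
#'   (id), `n_spots`, `solutions` (list of [orientation_solution()]).
#' @export
write_solutions <- function(path, results) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (r in results) {
    rec <- list(image = r$image, n_spots = r$n_spots,
                solutions = lapply(r$solutions, .solution_record))
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA,
                                null = "null"), con)
  }
  invisible(NULL)
}

#' Read back a JSON-lines solution file
#' @param path Path written by [write_solutions()].
#' @return List of per-image records.
#' @export
read_solutions <- function(path) {
  lapply(readLines(path), function(l)
    jsonlite::fromJSON(l, simplifyVector = TRUE, simplifyMatrix = TRUE))
}
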