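#' Plate layout: compound and blank well positions on a 384-well array
#'
#' Maps sensing compounds and saline blank wells to (row, col) positions on
#' a 16 x 24 (or other) well grid. Coordinates are 0-based, row 0 = top
#' (plate row A), col 0 = left.
#'
#' @param compound_wells Data frame with columns `compound`, `row`, `col`.
#' @param blank_wells Data frame with columns `row`, `col`; at least one.
#' @param rows,cols Grid dimensions.
#' @return An object of class `plate_layout`.
#' @seealso [default_layout()] for the standard 190-compound arrangement.
#' @export
plate_layout <- function(compound_wells, blank_wells, rows = 16, cols = 24) {
  stopifnot(is.data.frame(compound_wells),
            all(c("compound", "row", "col") %in% names(compound_wells)),
            is.data.frame(blank_wells),
            all(c("row", "col") %in% names(blank_wells)))
  check_field(nrow(blank_wells) >= 1, "blank_wells",
              "at least one blank well is required")
  all_rc <- rbind(compound_wells[c("row", "col")],
                  blank_wells[c("row", "col")])
  check_field(all(all_rc$row >= 0 & all_rc$row < rows &
                  all_rc$col >= 0 & all_rc$col < cols),
              "wells", sprintf("coordinates must lie within %dx%d", rows, cols))
  key <- paste(all_rc$row, all_rc$col)
  check_field(!anyDuplicated(key), "wells", "no two entries may share a well")
  check_field(!anyDuplicated(compound_wells$compound), "compound_wells",
              "compound names must be unique")
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 compound_wells = compound_wells[c("compound", "row", "col")],
                 blank_wells = blank_wells[c("row", "col")]),
            class = "plate_layout")
}

#' Default 384-well layout
#'
#' Places `n_compounds` compounds row-major starting at well A1, skipping
#' the final column, which is reserved for saline blanks.
#'
#' @param n_compounds Number of compounds (must fit in `rows * (cols - 1)`).
#' @param rows,cols Grid dimensions (default 384-well: 16 x 24).
#' @param compounds Optional compound names; defaults to `C001`, `C002`, ...
#' @return A `plate_layout`.
#' @export
default_layout <- function(n_compounds = 190, rows = 16, cols = 24,
                           compounds = sprintf("C%03d", seq_len(n_compounds))) {
  stopifnot(n_compounds <= rows * (cols - 1),
            length(compounds) == n_compounds)
  idx <- seq_len(n_compounds) - 1L
  cw <- data.frame(compound = compounds,
                   row = idx %/% (cols - 1L),
                   col = idx %% (cols - 1L),
                   stringsAsFactors = FALSE)
  bw <- data.frame(row = seq_len(rows) - 1L, col = cols - 1L)
  plate_layout(cw, bw, rows = rows, cols = cols)
}

#' @export
print.plate_layout <- function(x, ...) {
  cat(sprintf("Plate layout: %dx%d wells, %d compounds, %d blanks\n",
              x$rows, x$cols, nrow(x$compound_wells), nrow(x$blank_wells)))
  invisible(x)
}

#' Write / read a plate layout as YAML
#'
#' @param layout A `plate_layout`.
#' @param path YAML file path.
#' @return `path` (write) or a `plate_layout` (read).
#' @export
write_layout <- function(layout, path) {
  stopifnot(inherits(layout, "plate_layout"))
  yaml::write_yaml(list(rows = layout$rows, cols = layout$cols,
                        compound_wells = layout$compound_wells,
                        blank_wells = layout$blank_wells),
                   path)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  y <- yaml::read_yaml(path)
  plate_layout(as.data.frame(y$compound_wells),
               as.data.frame(y$blank_wells),
               rows = y$rows, cols = y$cols)
}
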