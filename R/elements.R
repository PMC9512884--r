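#' Element lookup table: van der Waals radii and sketch colour channels
#'
#' Builds the table used throughout the package to size atom circles and to
#' encode elements on the red/green channels of a sketch.  Radii are the
#' Bondi van der Waals radii in Angstrom.  The red/green encoding follows the
#' sketch convention: carbon (1, 1), nitrogen (1, 0), oxygen (0, 1),
#' hydrogen (0, 0.5), phosphorus (0.5, 0.5).  Every element not listed is
#' treated as carbon for the colour channels, so lookups never fail.
#'
#' @return A data frame with one row per element and columns `element`,
#'   `vdw_radius`, `r_channel`, `g_channel`.
#' @examples
#' tab <- element_table()
#' element_channels("N", tab)   # c(1, 0)
#' element_channels("FE", tab)  # carbon fallback c(1, 1)
#' @export
element_table <- function() {
  tab <- data.frame(
    element    = c("H",  "C",  "N",  "O",  "P",  "S",  "D"),
    vdw_radius = c(1.20, 1.70, 1.55, 1.52, 1.80, 1.80, 1.20),
    r_channel  = c(0.0,  1.0,  1.0,  0.0,  0.5,  1.0,  0.0),
    g_channel  = c(0.5,  1.0,  0.0,  1.0,  0.5,  1.0,  0.5),
    stringsAsFactors = FALSE
  )
  class(tab) <- c("element_table", class(tab))
  tab
}

# Row of the table for one element symbol; unknown symbols fall back to the
# carbon row (radius 1.70, channels 1/1).  Deuterium shares hydrogen's role.
element_row <- function(element, table = element_table()) {
  stopifnot(is.character(element), nzchar(element))
  i <- match(toupper(element), table$element)
  i[is.na(i)] <- match("C", table$element)
  table[i, , drop = FALSE]
}

#' Red/green sketch channels for an element
#'
#' @param element Chemical symbol (case-insensitive). Unknown symbols are
#'   encoded as carbon.
#' @param table An [element_table()].
#' @return Numeric length-2 vector `c(r, g)` in `[0, 1]`.
#' @export
element_channels <- function(element, table = element_table()) {
  row <- element_row(element, table)
  c(r = row$r_channel[1], g = row$g_channel[1])
}

#' Van der Waals radius of an element (Angstrom)
#'
#' Vectorised; unknown symbols get the carbon radius (1.70 A).
#'
#' @inheritParams element_channels
#' @return Numeric vector of radii.
#' @export
vdw_radius <- function(element, table = element_table()) {
  element_row(element, table)$vdw_radius
}

#' Blue-channel depth encoding
#'
#' Maps a normalized depth (1 = nearest to the camera, 0 = farthest) to the
#' blue channel of the sketch.  The mapping is linear with the stated
#' endpoints: 100 percent blue for the nearest atoms, 0 for the most distant.
#'
#' @param depth_norm Numeric in `[0, 1]`.
#' @return The blue intensity, identical to `depth_norm`.
#' @export
depth_channel <- function(depth_norm) {
  stopifnot(all(depth_norm >= -1e-9 & depth_norm <= 1 + 1e-9))
  pmin(pmax(depth_norm, 0), 1)
}
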