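#' Schematic 64-channel 10-10 montage coordinates
#'
#' Returns the bundled 2-D head-circle layout of the 64-channel 10-10
#' electrode set used by common motor-imagery corpora: channel label plus
#' `(x, y)` in a unit head circle (nose up, left ear at `x = -1`). The
#' coordinates are schematic display positions for topographic and
#' connectogram exports, not digitized electrode locations.
#'
#' @return Data frame with columns `channel`, `x`, `y` (64 rows).
#' @examples
#' head(montage_10_10())
#' @export
montage_10_10 <- function() {
  utils::read.csv(system.file("extdata", "montage_10_10_64.csv",
                              package = "kcsfcnet"))
}
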