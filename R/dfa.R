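#' Signed disc-fovea angle from the two region centers
#'
#' The disc-fovea angle (DFA) is the angle between the line joining the
#' optic-disc center to the macular (foveal) center and the horizontal line
#' through the disc center. Its magnitude is
#' \deqn{\arctan(|OY - MY| / |OX - MX|) \cdot 180/\pi}
#' with the vertical case (`OX == MX`) defined as 90 degrees. Because image
#' y coordinates grow downward, the angle takes the opposite sign when the
#' macular center lies below the disc center (`MY > OY`).
#'
#' @param disc_center Numeric `(x, y)` of the optic-disc center, pixels.
#' @param macula_center Numeric `(x, y)` of the macular center, pixels.
#' @return The signed DFA in degrees, in `[-90, 90]`.
#' @examples
#' compute_dfa(c(1000, 1000), c(1600, 940))   #  +5.71: fovea above disc
#' compute_dfa(c(1000, 1000), c(1600, 1060))  #  -5.71: fovea below disc
#' @export
compute_dfa <- function(disc_center, macula_center) {
  stopifnot(length(disc_center) == 2, length(macula_center) == 2,
            is.finite(disc_center), is.finite(macula_center))
  ox <- disc_center[[1]]; oy <- disc_center[[2]]
  mx <- macula_center[[1]]; my <- macula_center[[2]]
  if (ox == mx && oy == my)
    stop_dfameter("coincident_centers",
                  "disc and macula centers coincide; the angle is undefined")
  ang <- if (ox == mx) 90 else atan(abs(oy - my) / abs(ox - mx)) * 180 / pi
  if (my > oy) ang <- -ang
  ang
}

#' Absolute disc-fovea angle error
#'
#' @param predicted,truth Angles in degrees (vectorized).
#' @return `|predicted - truth|`, degrees.
#' @export
dfa_error <- function(predicted, truth) {
  stopifnot(is.finite(predicted), is.finite(truth))
  abs(predicted - truth)
}
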