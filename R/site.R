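#' Describe an observation site
#'
#' A site bundles the geographic and soil properties that the environment and
#' habitat sub-models need: latitude (for daylength), altitude, and the soil
#' water-holding capacity `w_star` that bounds the soil water bucket and
#' normalises the soil moisture ratio `W / W*`.
#'
#' @param latitude Decimal degrees, between -90 and 90.
#' @param longitude Decimal degrees east.
#' @param altitude Metres above sea level.
#' @param w_star Soil water-holding capacity (mm), strictly positive.  The
#'   maximum plant-available soil water; the soil moisture ratio that scales
#'   the larval carrying capacity is `soil_water / w_star`.
#'
#' @return An object of class `pcmp_site` (a named list).
#' @examples
#' tokyo_site()
#' @export
pcmp_site <- function(latitude, longitude = 0, altitude = 0, w_star = 150) {
  if (!is.numeric(latitude) || length(latitude) != 1 || is.na(latitude) ||
      abs(latitude) > 90) {
    abort("`latitude` must be a single number in [-90, 90].", class = "pcmp_invalid_site")
  }
  if (!is.numeric(w_star) || length(w_star) != 1 || is.na(w_star) || w_star <= 0) {
    abort("`w_star` must be a single positive number (mm).", class = "pcmp_invalid_site")
  }
  structure(
    list(latitude = latitude, longitude = longitude,
         altitude = altitude, w_star = w_star),
    class = "pcmp_site"
  )
}

#' @rdname pcmp_site
#' @details `tokyo_site()` is the default study site: the Tokyo mosquito
#'   monitoring location (35.6917 N, 139.75 E, 25 m).
#' @export
tokyo_site <- function(w_star = 150) {
  pcmp_site(latitude = 35.6917, longitude = 139.75, altitude = 25, w_star = w_star)
}

#' @export
print.pcmp_site <- function(x, ...) {
  cat(sprintf("<pcmp_site> lat %.4f, lon %.4f, alt %.0f m, W* = %g mm\n",
              x$latitude, x$longitude, x$altitude, x$w_star))
  invisible(x)
}
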