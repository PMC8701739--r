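# Floor plan: six axis-aligned rectangular zones in a local metric frame
# (origin at the southwest corner), plus the channel -> zone placement map.

#' Construct and validate a six-zone floor plan
#'
#' A zone map partitions the dwelling into exactly six non-overlapping
#' axis-aligned rectangles (meters, origin at the southwest corner) and maps
#' each installed sensor channel to the zone it is placed in. Six zones are
#' the granularity used for the indoor wandering analysis.
#'
#' @param zones Data frame with columns `zone_id` (1-6), `name`, and rectangle
#'   corners `x0`, `y0`, `x1`, `y1` (meters).
#' @param sensor_placements Named integer vector: `channel_id -> zone_id`.
#' @return A `zone_map` list with elements `zones` and `sensor_placements`.
#' @export
zone_map <- function(zones, sensor_placements = integer()) {
  zones <- as_tibble(zones)
  if (nrow(zones) != 6) stop_config("a zone map must have exactly 6 zones")
  if (!setequal(zones$zone_id, 1:6)) stop_config("zone ids must be 1..6")
  if (any(zones$x1 <= zones$x0) || any(zones$y1 <= zones$y0)) {
    stop_config("degenerate zone rectangle")
  }
  # pairwise interior-overlap check
  for (i in 1:5) for (j in (i + 1):6) {
    ov <- overlap_s(zones$x0[i], zones$x1[i], zones$x0[j], zones$x1[j]) *
      overlap_s(zones$y0[i], zones$y1[i], zones$y0[j], zones$y1[j])
    if (ov > 1e-9) stop_config("zone rectangles overlap")
  }
  if (length(sensor_placements) &&
    !all(sensor_placements %in% zones$zone_id)) {
    stop_config("sensor placed in a zone that does not exist")
  }
  structure(list(zones = zones, sensor_placements = sensor_placements),
    class = "zone_map"
  )
}

#' Default six-zone floor plan
#'
#' A 10 x 8 m one-person flat: entrance, living room, kitchen along the south
#' side; bedroom, bathroom, storage room along the north side.
#'
#' @return A [zone_map()].
#' @export
default_zone_map <- function() {
  zones <- tibble(
    zone_id = 1:6,
    name = c(
      "entrance", "living_room", "kitchen",
      "bedroom", "bathroom", "storage"
    ),
    x0 = c(0, 2, 6, 0, 4, 7),
    y0 = c(0, 0, 0, 4, 4, 4),
    x1 = c(2, 6, 10, 4, 7, 10),
    y1 = c(4, 4, 4, 8, 8, 8)
  )
  zone_map(zones)
}

zone_centroid <- function(zm, zone_id) {
  z <- zm$zones[match(zone_id, zm$zones$zone_id), ]
  c(x = (z$x0 + z$x1) / 2, y = (z$y0 + z$y1) / 2)
}

# Zone id for each (x, y) point; points outside every zone get the nearest
# zone (by rectangle distance) and are counted in the `n_outside` attribute.
locate_zone <- function(zm, x, y) {
  z <- zm$zones
  ids <- rep(NA_integer_, length(x))
  for (i in seq_len(nrow(z))) {
    inside <- x >= z$x0[i] & x < z$x1[i] & y >= z$y0[i] & y < z$y1[i]
    ids[inside & is.na(ids)] <- z$zone_id[i]
  }
  out <- is.na(ids)
  if (any(out)) {
    for (k in which(out)) {
      dx <- pmax(z$x0 - x[k], 0, x[k] - z$x1)
      dy <- pmax(z$y0 - y[k], 0, y[k] - z$y1)
      ids[k] <- z$zone_id[which.min(sqrt(dx^2 + dy^2))]
    }
  }
  attr(ids, "n_outside") <- sum(out)
  ids
}
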