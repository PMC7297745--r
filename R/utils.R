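# internal helpers shared across modules

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# reduce an angle in degrees to [0, 360)
norm_deg <- function(x) {
  out <- x %% 360
  # guard against -0 / 360 from floating point
  out[out >= 360] <- out[out >= 360] - 360
  out
}

# angle (degrees CCW from +x) of the vector (dx, dy)
vector_angle_deg <- function(dx, dy) norm_deg(rad2deg(atan2(dy, dx)))

euclid <- function(x1, y1, x2, y2) sqrt((x2 - x1)^2 + (y2 - y1)^2)

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}
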