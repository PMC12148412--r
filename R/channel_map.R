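#' TMT channel-to-temperature map
#'
#' A `channel_map` pairs the ordered TMT reporter channel labels of a
#' TPP-TR experiment with the heating temperatures they encode. The first
#' temperature is the reference temperature Tmin used to anchor fractional
#' solubility at 1.
#'
#' @param channel_labels character vector of reporter channel labels, in
#'   gradient order.
#' @param temperatures_c numeric vector of temperatures in degrees Celsius,
#'   strictly increasing, same length as `channel_labels`.
#' @return An object of class `channel_map`: a list with elements
#'   `channel_labels` and `temperatures_c`.
#' @examples
#' cm <- default_channel_map()
#' cm$temperatures_c[1]  # Tmin = 37
#' @export
channel_map <- function(channel_labels, temperatures_c) {
  channel_labels <- as.character(channel_labels)
  temperatures_c <- as.numeric(temperatures_c)
  if (length(channel_labels) != length(temperatures_c)) {
    stop("channel_labels and temperatures_c must have equal length")
  }
  if (length(temperatures_c) < 2) {
    stop("a channel map needs at least two temperatures")
  }
  if (anyNA(temperatures_c) || any(!is.finite(temperatures_c))) {
    stop("temperatures must be finite")
  }
  if (any(diff(temperatures_c) <= 0)) {
    stop("temperatures must be strictly increasing")
  }
  if (anyDuplicated(channel_labels)) {
    stop("channel labels must be unique")
  }
  structure(
    list(channel_labels = channel_labels, temperatures_c = temperatures_c),
    class = "channel_map"
  )
}

#' @rdname channel_map
#' @details `default_channel_map()` returns the standard TMT10 layout:
#'   channels 126, 127L, 127H, 128L, 128H, 129L, 129H, 130L, 130H, 131
#'   encoding 37, 41, 44, 47, 50, 53, 56, 59, 63, 67 degrees Celsius.
#' @export
default_channel_map <- function() {
  channel_map(
    c("126", "127L", "127H", "128L", "128H",
      "129L", "129H", "130L", "130H", "131"),
    c(37, 41, 44, 47, 50, 53, 56, 59, 63, 67)
  )
}

#' @export
print.channel_map <- function(x, ...) {
  cat("TMT channel map (", length(x$channel_labels), " channels)\n", sep = "")
  print(data.frame(channel = x$channel_labels,
                   temperature_c = x$temperatures_c),
        row.names = FALSE)
  invisible(x)
}
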