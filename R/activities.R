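#' Activity codes and channel layout
#'
#' The package works with seven daily activities recorded by a thigh-worn
#' sensor node that combines an airbag pressure sensor (tracking muscle
#' deformation) with an IMU fused on-chip to Euler angles.  The channel
#' order is fixed so that feature-vector layouts are reproducible.
#'
#' @format `har_activities()` returns a character vector of the 7 activity
#'   codes; `har_channels()` the 10 channel names in canonical order.
#' @export
har_activities <- function() {
  c("SIT", "STAND", "LIE", "WALK", "RUN", "UP", "DOWN")
}

#' @rdname har_activities
#' @export
har_channels <- function() {
  c("pressure",
    "acc_x", "acc_y", "acc_z",
    "gyro_x", "gyro_y", "gyro_z",
    "euler_roll", "euler_pitch", "euler_yaw")
}

# label sentinel for samples without an activity code
UNLABELED <- "UNLABELED"

# map arbitrary labels onto integer codes 1..C over a fixed class order
.encode_labels <- function(labels, classes) {
  idx <- match(as.character(labels), classes)
  if (anyNA(idx)) {
    bad <- unique(as.character(labels)[is.na(idx)])
    stop("unknown label(s) ", paste(bad, collapse = ", "),
         "; valid codes: ", paste(classes, collapse = ", "), call. = FALSE)
  }
  idx
}
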