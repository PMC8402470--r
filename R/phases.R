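#' Gait phase labels
#'
#' Ordered labels of the gait phases used throughout the package. The stride
#' starts at initial contact; because the initial-contact phase occupies only
#' about 8\% of the cycle at an eight-phase granularity, it is merged with
#' the loading-response phase into a single label.
#'
#' @return Character vector of the seven phase labels in stride order.
#' @export
#' @examples
#' gait_phases()
gait_phases <- function() {
  c(
    "initial_contact_loading_response",
    "mid_stance",
    "terminal_stance",
    "pre_swing",
    "initial_swing",
    "mid_swing",
    "terminal_swing"
  )
}

# Variable names of the six grip-pressure channels and their derivatives.
BASE_CHANNELS <- c("CoMXUp", "CoMXDown", "CoMX", "CoMZ", "MPUp", "MPDown")
DERIV_CHANNELS <- paste0("d", BASE_CHANNELS)
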