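#' State space for the nine-variable cattle activity chain
#'
#' The chain mixes six mutually exclusive behavioural states -- Feeding (F),
#' Moving (M), Lying (L), Standing (S), Rumination while standing (RS),
#' Rumination while lying (RL) -- with three environmental variables --
#' Temperature (T), Humidity (H) and the Temperature-Humidity Index (THI).
#' The default label order (T, H, THI, F, M, L, S, RS, RL) is the order used
#' by every matrix and vector in the package; a custom state space may be
#' supplied wherever a `state_space` argument is accepted.
#'
#' @param labels character vector of unique state labels.
#' @param behavioral labels forming the behavioural subset (states a cow
#'   physically occupies); must be contained in `labels`.
#' @param environmental labels forming the environmental subset; together
#'   with `behavioral` it must cover `labels`.
#' @return An object of class `state_space`: a list with elements `labels`,
#'   `behavioral` and `environmental`.
#' @examples
#' ss <- state_space()
#' ss$labels
#' @export
state_space <- function(labels = c("T", "H", "THI", "F", "M", "L", "S", "RS", "RL"),
                        behavioral = c("F", "M", "L", "S", "RS", "RL"),
                        environmental = c("T", "H", "THI")) {
  labels <- as.character(labels)
  if (anyDuplicated(labels)) {
    stop("state labels must be unique")
  }
  if (!all(behavioral %in% labels) || !all(environmental %in% labels)) {
    stop("behavioral and environmental subsets must be drawn from 'labels'")
  }
  if (!setequal(c(behavioral, environmental), labels)) {
    stop("behavioral and environmental subsets must together cover all labels")
  }
  structure(
    list(labels = labels,
         behavioral = as.character(behavioral),
         environmental = as.character(environmental)),
    class = "state_space"
  )
}

#' @export
print.state_space <- function(x, ...) {
  cat("State space with", length(x$labels), "states\n")
  cat("  order:        ", paste(x$labels, collapse = " "), "\n")
  cat("  behavioral:   ", paste(x$behavioral, collapse = " "), "\n")
  cat("  environmental:", paste(x$environmental, collapse = " "), "\n")
  invisible(x)
}

#' @export
length.state_space <- function(x) length(x$labels)

is_state_space <- function(x) inherits(x, "state_space")
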