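#' @keywords internal
abort2 <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "prminsol_error")))
}

config_error <- function(msg) abort2(msg, "config_error")
validation_error <- function(msg) abort2(msg, "validation_error")
mapping_error <- function(msg) abort2(msg, "mapping_error")
ordering_error <- function(msg) abort2(msg, "ordering_error")
insufficient_data_error <- function(msg) abort2(msg, "insufficient_data_error")
format_error <- function(msg) abort2(msg, "format_error")
integrity_error <- function(msg) abort2(msg, "file_integrity_error")

#' Significance star annotation for p-values
#'
#' Bins p-values at the conventional 0.05 / 0.01 / 0.001 cut points used in
#' the figure annotations ("*", "**", "***"; empty string otherwise).
#'
#' @param p numeric vector of p-values.
#' @return character vector of star labels.
#' @export
significance_stars <- function(p) {
  out <- character(length(p))
  out[!is.na(p) & p < 0.05] <- "*"
  out[!is.na(p) & p < 0.01] <- "**"
  out[!is.na(p) & p < 0.001] <- "***"
  out[is.na(p)] <- NA_character_
  out
}
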