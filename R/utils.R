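# classed conditions: swhunt_invalid_input, swhunt_identifiability,
# swhunt_exhausted, swhunt_parse, swhunt_numeric
sw_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "swhunt_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

sw_check <- function(cond, msg, class = "swhunt_invalid_input") {
  if (!isTRUE(cond)) sw_stop(msg, class)
  invisible(TRUE)
}

# "nearest integer", half-up (no ties arise for even K since K-1 is odd)
round_half_up <- function(x) floor(x + 0.5)

is_count <- function(x, min = 1L) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == as.integer(x) && x >= min
}
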