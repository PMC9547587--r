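#' @importFrom rlang .data abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# Round half away from zero, as printed association tables do (round() in R
# rounds half to even, which would turn 0.175 into 0.18 or 0.17 depending on
# representation).
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# -log10 with a documented cap for p-value underflow; ranking among capped
# values is resolved elsewhere (odds ratio, then name).
neg_log10 <- function(p, cap = 320) {
  pmin(-log10(p), cap)
}

`%na%` <- function(x, y) ifelse(is.na(x), y, x)
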