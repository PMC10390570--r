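#' Round half away from zero
#'
#' Rounding with ties going up (as in most spreadsheet and SPSS output),
#' unlike base [round()], which rounds half to even. Used for all reported
#' percentages so that formatted tables match conventional half-up output.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up to `digits` places.
#' @export
round_half_up <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Format a percentage to three decimals
#'
#' @param x numeric vector of percentages.
#' @return character vector, `"NA"` for missing values.
#' @export
format_pct <- function(x) {
  out <- sprintf("%.3f", round_half_up(x, 3))
  out[is.na(x)] <- NA_character_
  out
}

# Normalize a raw logical-ish flag to "true"/"false"/"none"/NA/"other".
# AIRR writes T/F; 10x writes True/False/None (older runs TRUE/FALSE).
normalize_flag <- function(x) {
  v <- tolower(trimws(as.character(x)))
  out <- rep("other", length(v))
  out[v %in% c("true", "t")] <- "true"
  out[v %in% c("false", "f")] <- "false"
  out[v %in% "none"] <- "none"
  out[is.na(x) | v == ""] <- NA_character_
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
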