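#' Round half-up
#'
#' Rounds to `digits` decimal places with ties away from zero (the convention
#' used for percentage cells in clinical characteristics tables), unlike
#' [base::round()] which rounds half to even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(c(0.125, 0.135), 2) # 0.13 0.14
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  # small epsilon guards against representation error in x * scale
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

#' Percentage of a denominator, rounded half-up to two decimals
#'
#' @param count Numeric vector of counts.
#' @param denominator Single denominator (or vector recycled against `count`).
#' @return Percentages on the 0-100 scale, rounded half-up to 2 decimals;
#'   `NA` where the denominator is zero.
#' @export
#' @examples
#' percent_of(95959, 107123) # 89.58
percent_of <- function(count, denominator) {
  out <- round_half_up(100 * count / denominator, 2)
  out[denominator == 0] <- NA_real_
  out
}

#' Parse FAERS numeric date fields
#'
#' FAERS encodes dates as `YYYYMMDD`, with partial dates truncated to
#' `YYYYMM` or `YYYY`. Partial dates are kept at reduced precision: the date
#' is anchored to the first day of the period and flagged imprecise, so that
#' downstream time-to-onset computations can refuse to use them.
#'
#' @param x Character or numeric vector of raw date fields.
#' @return A data frame with columns `date` (class `Date`, `NA` if unparseable)
#'   and `precision` (`"day"`, `"month"`, `"year"`, or `NA`).
#' @export
parse_faers_date <- function(x) {
  x <- trimws(as.character(x))
  x[x %in% c("", "NA")] <- NA_character_
  n <- length(x)
  date <- rep(as.Date(NA), n)
  precision <- rep(NA_character_, n)

  ok8 <- !is.na(x) & grepl("^[0-9]{8}$", x)
  if (any(ok8)) {
    d <- as.Date(x[ok8], format = "%Y%m%d")
    date[ok8] <- d
    precision[ok8] <- ifelse(is.na(d), NA_character_, "day")
  }
  ok6 <- !is.na(x) & grepl("^[0-9]{6}$", x)
  if (any(ok6)) {
    d <- as.Date(paste0(x[ok6], "01"), format = "%Y%m%d")
    date[ok6] <- d
    precision[ok6] <- ifelse(is.na(d), NA_character_, "month")
  }
  ok4 <- !is.na(x) & grepl("^[0-9]{4}$", x)
  if (any(ok4)) {
    d <- as.Date(paste0(x[ok4], "0101"), format = "%Y%m%d")
    date[ok4] <- d
    precision[ok4] <- ifelse(is.na(d), NA_character_, "year")
  }
  data.frame(date = date, precision = precision, stringsAsFactors = FALSE)
}

# Normalize free-text drug names for matching: trim, collapse internal
# whitespace, fold case.
normalize_name <- function(x) {
  toupper(gsub("[[:space:]]+", " ", trimws(as.character(x))))
}

# log(sum(exp(.))) along two vectors, numerically stable
log_add <- function(la, lb) {
  m <- pmax(la, lb)
  out <- m + log(exp(la - m) + exp(lb - m))
  # both -Inf -> -Inf
  out[is.infinite(la) & is.infinite(lb) & la < 0 & lb < 0] <- -Inf
  out
}
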