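# Internal numeric and date helpers.

# log(sum(exp(x))) without overflow
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# row-wise logsumexp of a matrix
row_logsumexp <- function(M) {
  m <- M[cbind(seq_len(nrow(M)), max.col(M, ties.method = "first"))]
  m + log(rowSums(exp(M - m)))
}

# half-up rounding (R's round() is round-half-even); x assumed non-negative
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

# deterministic per-substream seed below 2^31, so that subsetting
# participants (or repeating a stage) is reproducible under one master seed
sub_seed <- function(master, i) {
  as.integer((abs(as.double(master)) * 48271 + as.double(i) * 3571) %% 2147483629)
}

days_in_month <- function(year, month) {
  base <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
  d <- base[month]
  leap <- (year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0
  d[month == 2L & leap] <- 29L
  d
}

# calendar-month arithmetic with day-of-month clamped to the month end
# (Jan 31 + 1 month -> Feb 28/29), vectorised over `date`
add_months <- function(date, k) {
  lt <- as.POSIXlt(date)
  m0 <- lt$year * 12L + lt$mon + as.integer(k)
  year <- m0 %/% 12L + 1900L
  month <- m0 %% 12L + 1L
  day <- pmin(lt$mday, days_in_month(year, month))
  as.Date(sprintf("%04d-%02d-%02d", year, month, day))
}
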