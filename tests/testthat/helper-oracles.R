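# Independent oracles used across the suite.

# brute-force tight extents of a binary mask by exhaustive pixel scan
scan_extents <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  c(rows = diff(range(idx[, 1])) + 1, cols = diff(range(idx[, 2])) + 1)
}

# OLS by explicit normal equations (independent of stats::lm)
ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x^2); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  yhat <- intercept + slope * x
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r_squared = r2)
}

# interval-scan oracle for weight classification
size_class_oracle <- function(weight, sc = default_size_classes()) {
  w <- round(weight, 2)
  for (i in seq_len(nrow(sc))) {
    if (sc$low[i] <= w && w <= sc$high[i]) return(as.integer(sc$class[i]))
  }
  NA_integer_
}

# per-size decay models: slope, intercept (fitted normalised-weight lines)
decay_models <- function() {
  data.frame(
    size = c(0:4, NA),
    slope = c(-0.0023, -0.0028, -0.0029, -0.0031, -0.0029, -0.0028),
    intercept = c(1.0030, 1.0023, 1.0027, 1.0028, 1.0039, 1.0030),
    label = c(paste0("size", 0:4), "average"))
}
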