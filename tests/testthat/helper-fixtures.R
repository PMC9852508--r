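# Shared fixtures and independent oracles.

# A random non-negative width profile (uniform, away from zero unless asked).
random_profile <- function(id = "rnd", min = 0.2, max = 5) {
  width_profile(id, stats::runif(9, min, max), stats::runif(9, min, max))
}

# Apply rotation (radians) + translation + uniform scale to landmarks.
rigid_transform <- function(lm, theta = 0, shift = c(0, 0), scale = 1) {
  rot <- rbind(c(cos(theta), -sin(theta)),
               c(sin(theta),  cos(theta)))
  tf <- function(m) {
    t(scale * rot %*% t(m)) + rep(shift, each = nrow(m))
  }
  tfp <- function(p) as.numeric(scale * rot %*% p + shift)
  subject_landmarks(lm$subject_id, tf(lm$left), tf(lm$right),
                    tfp(lm$anterior), tfp(lm$posterior))
}

# Brute-force plumb-width oracle: densely resample the polyline and take
# max |x| among samples whose axial coordinate is within unit/1000 of each
# division point.
dense_widths_oracle <- function(contour, unit, n_samples = 1e5) {
  seg_len <- sqrt(rowSums(diff(contour)^2))
  cum <- c(0, cumsum(seg_len))
  s <- seq(0, cum[length(cum)], length.out = n_samples)
  idx <- findInterval(s, cum, rightmost.closed = TRUE)
  idx[idx >= nrow(contour)] <- nrow(contour) - 1L
  t <- (s - cum[idx]) / pmax(seg_len[idx], .Machine$double.eps)
  pts <- contour[idx, , drop = FALSE] +
    (contour[idx + 1L, , drop = FALSE] - contour[idx, , drop = FALSE]) * t
  vapply(1:9, function(k) {
    near <- abs(pts[, 2] - k * unit) <= unit / 1000
    if (!any(near)) 0 else max(abs(pts[near, 1])) / unit
  }, numeric(1))
}

# Textbook two-group Levene W (mean centering): one-way ANOVA F on the
# absolute deviations from each group's mean.
levene_oracle <- function(x, y) {
  zx <- abs(x - mean(x)); zy <- abs(y - mean(y))
  z <- c(zx, zy); n1 <- length(x); n2 <- length(y); N <- n1 + n2
  between <- n1 * (mean(zx) - mean(z))^2 + n2 * (mean(zy) - mean(z))^2
  within <- sum((zx - mean(zx))^2) + sum((zy - mean(zy))^2)
  W <- (N - 2) * between / within
  list(W = W, p = stats::pf(W, 1, N - 2, lower.tail = FALSE))
}

# Textbook pooled and Welch two-sample t statistics and p-values.
pooled_t_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, p = 2 * stats::pt(-abs(t), n1 + n2 - 2))
}
welch_t_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  v1 <- stats::var(x) / n1; v2 <- stats::var(y) / n2
  t <- (mean(x) - mean(y)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = t, p = 2 * stats::pt(-abs(t), df))
}

# Cohort data frame built directly from width-profile objects with
# arbitrary metadata (defaults: age 30, nulliparous, no labiaplasty).
cohort_from_profiles <- function(profiles, age = 30, births = 0,
                                 labiaplasty = FALSE) {
  df <- profiles_as_df(profiles)
  meta <- data.frame(subject_id = df$subject_id, age = age, births = births,
                     labiaplasty = labiaplasty)
  assemble_cohort(df, meta)
}
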