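# Independent brute-force oracles and toy fixtures used across the suite.

compass_deg <- c(E = 0, NE = 45, N = 90, NW = 135,
                 W = 180, SW = 225, S = 270, SE = 315)

# axial mean of set-flag directions, re-derived with floating-point trig
# (the implementation uses an exact integer doubled-angle table)
oracle_axial_mean <- function(flags) {
  flags <- as.numeric(flags)
  if (sum(flags) %in% c(0, 8)) return(NA_real_)
  rad <- 2 * compass_deg * pi / 180
  vx <- sum(flags * cos(rad))
  vy <- sum(flags * sin(rad))
  # zap the ~1e-16 residue of cos(k*pi/2) so exact zeros stay zero
  if (abs(vx) < 1e-9) vx <- 0
  if (abs(vy) < 1e-9) vy <- 0
  if (sqrt(vx^2 + vy^2) < 1e-9) return(NA_real_)
  (atan2(vy, vx) / 2 * 180 / pi) %% 180
}

oracle_entropy <- function(p, base = 2) {
  total <- 0
  for (pi in p) if (pi > 0) total <- total - pi * log(pi, base = base)
  total
}

# exhaustive O(n^2) pair enumeration over defined-angle pixels
oracle_alcm <- function(field, n_bins = 8) {
  d <- field[!is.na(field$angle_deg), ]
  w <- 180 / n_bins
  b <- pmin(n_bins, floor(d$angle_deg / w) + 1)
  m <- matrix(0, n_bins, n_bins)
  tot <- 0
  n <- nrow(d)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j &&
          max(abs(d$row[i] - d$row[j]), abs(d$col[i] - d$col[j])) == 1) {
        m[b[i], b[j]] <- m[b[i], b[j]] + 1
        m[b[j], b[i]] <- m[b[j], b[i]] + 1
        tot <- tot + 2
      }
    }
  }
  m / tot
}

oracle_homogeneity <- function(m, circular = FALSE) {
  n <- nrow(m)
  total <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d <- abs(i - j)
      if (circular) d <- min(d, n - d)
      total <- total + m[i, j] / (1 + d)
    }
  }
  total
}

# explicit sums-of-squares one-way ANOVA
oracle_anova <- function(values, group) {
  g <- factor(group)
  grand <- mean(values)
  ss_b <- sum(tapply(values, g, function(x) length(x) * (mean(x) - grand)^2))
  ss_w <- sum(tapply(values, g, function(x) sum((x - mean(x))^2)))
  df_b <- nlevels(g) - 1
  df_w <- length(values) - nlevels(g)
  f <- (ss_b / df_b) / (ss_w / df_w)
  list(f = f, p = stats::pf(f, df_b, df_w, lower.tail = FALSE))
}

# ICC(3,1) through stats::aov rather than explicit sums
oracle_icc31 <- function(x) {
  df <- data.frame(
    y = as.vector(x),
    s = factor(rep(seq_len(nrow(x)), times = ncol(x))),
    r = factor(rep(seq_len(ncol(x)), each = nrow(x)))
  )
  tab <- summary(stats::aov(y ~ s + r, data = df))[[1]]
  msr <- tab$`Mean Sq`[1]
  mse <- tab$`Mean Sq`[3]
  (msr - mse) / (msr + (ncol(x) - 1) * mse)
}

# analytic mean of a normal censored to [lo, hi]
oracle_censored_mean <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  lo * stats::pnorm(a) + hi * stats::pnorm(b, lower.tail = FALSE) +
    mu * (stats::pnorm(b) - stats::pnorm(a)) -
    sd * (stats::dnorm(b) - stats::dnorm(a))
}

# pairwise Tukey p from the studentized-range formula written out
oracle_tukey_p <- function(values, group, g1, g2) {
  g <- factor(group)
  k <- nlevels(g)
  n <- length(values)
  msw <- sum(tapply(values, g, function(x) sum((x - mean(x))^2))) / (n - k)
  na <- sum(g == g1)
  nb <- sum(g == g2)
  diff <- abs(mean(values[g == g2]) - mean(values[g == g1]))
  q <- diff / sqrt(msw / 2 * (1 / na + 1 / nb))
  stats::ptukey(q, nmeans = k, df = n - k, lower.tail = FALSE)
}

# simple regression by normal equations
oracle_lm <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  list(intercept = beta[1], slope = beta[2], r_squared = r2)
}

# closed-form Welch t
oracle_welch_t <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df,
       p = 2 * stats::pt(abs(t), df, lower.tail = FALSE))
}

# one-row profile tibble for controlled phantoms
toy_profile <- function(grade = 0, uncalc = 400, uncalc_sd = 0,
                        calc = 80, calc_sd = 0, plate = 120, plate_sd = 0,
                        amp = 0, wl = c(200, 100, 50), fen = 0,
                        oarsi_mean = 2, oarsi_sd = 0.5, trab = 0.3) {
  tibble::tibble(
    grade = grade,
    uncalc_cart_mean = uncalc, uncalc_cart_sd = uncalc_sd,
    calc_cart_mean = calc, calc_cart_sd = calc_sd,
    plate_mean = plate, plate_sd = plate_sd,
    roughness_amplitude = amp, roughness_wavelengths = list(wl),
    fenestra_rate = fen, oarsi_mean = oarsi_mean, oarsi_sd = oarsi_sd,
    entropy_mean = 1.5, entropy_sd = 0.1,
    homogeneity_mean = 0.8, homogeneity_sd = 0.03,
    trabecular_fraction = trab
  )
}

# horizontal two-level step image: rows 1..edge are `low`, the rest `high`
step_image <- function(n, edge, low = 100, high = 200) {
  img <- matrix(low, n, n)
  img[(edge + 1):n, ] <- high
  img
}
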