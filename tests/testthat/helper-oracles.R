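# Independent oracles used across the suite. These deliberately avoid the
# package's own computation paths: hand normal equations, element-wise
# double loops, and brute-force time-grid integration.

f18 <- radionuclide("F-18", 109.77)
tc99m <- radionuclide("Tc-99m", 360.6)

# OLS line by the normal equations, plus brute-force R^2
ols_oracle <- function(t, y) {
  n <- length(t)
  sx <- sum(t); sy <- sum(y); sxx <- sum(t^2); sxy <- sum(t * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  pred <- intercept + slope * t
  ss_res <- sum((y - pred)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(intercept = intercept, slope = slope,
       r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1)
}

# MIRD sum as an explicit element-wise double loop
mird_oracle <- function(a, s) {
  out <- stats::setNames(numeric(length(s$targets)), s$targets)
  for (tg in s$targets) {
    acc <- 0
    for (src in names(a)) acc <- acc + a[[src]] * s$values[tg, src]
    out[tg] <- acc
  }
  out
}

# Bladder-contents time integral by brute-force trapezoid on a fine time
# grid: body-to-bladder transfer simulated step by step, contents zeroed at
# every voiding time, integrated out to many physical half-lives.
bladder_oracle <- function(excreted_fraction, nuclide, scenario,
                           dt = 0.05, n_half_lives = 40) {
  lambda <- nuclide$decay_constant
  kb <- log(2) / scenario$bladder_entry_halftime_min
  T_void <- scenario$voiding_interval_h * 60
  t_end <- n_half_lives * nuclide$half_life
  times <- seq(0, t_end, by = dt)
  bladder <- numeric(length(times))
  b <- 0
  next_void <- T_void
  for (i in seq_along(times)[-1]) {
    t_mid <- (times[i - 1] + times[i]) / 2
    inflow <- excreted_fraction * kb * exp(-kb * t_mid) * exp(-lambda * t_mid)
    # integrating-factor step: exact decay, midpoint inflow
    b <- b * exp(-lambda * dt) + inflow * dt * exp(-lambda * dt / 2)
    if (times[i] >= next_void - 1e-12) {
      # half-jump value at the discontinuity node keeps the trapezoid exact
      bladder[i] <- b / 2
      b <- 0
      next_void <- next_void + T_void
    } else {
      bladder[i] <- b
    }
  }
  sum((bladder[-1] + bladder[-length(bladder)]) / 2 * dt) / 60  # hours
}

# a labeling run with all compartments measured at one common time
run_at <- function(activities, t_min = 0, nuclide = f18,
                   initial = sum(activities) * 1.01) {
  comps <- c("cells", "supernatant", "wash_1", "wash_2", "wash_3")
  n <- length(activities)
  labeling_run(
    nuclide,
    data.frame(compartment = comps[seq_len(n)],
               activity_mbq = activities, t_min = t_min),
    initial_activity_mbq = initial / decay_factor(t_min, nuclide),
    balance_tol = 0.10
  )
}
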