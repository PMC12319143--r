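# Shared fixtures and independent brute-force oracles. All fixtures are
# built in code; oracles deliberately use naive loops, independent of the
# package's implementation paths.

# A straight-line constant-velocity trial (m, ms).
linear_trial <- function(speed = 2, duration_ms = 500, rate = 120,
                         axis = "x1") {
  t <- seq(0, duration_ms, by = 1000 / rate)
  d <- data.frame(t_ms = t, x1_m = 0, x2_m = 0, x3_m = 0)
  d[[paste0(sub("x", "x", axis), "_m")]] <- speed * t / 1000
  d
}

# Noise-free minimum-jerk go trial via the generator.
minjerk_trial <- function(D = 0.6, T_ms = 1000, it = 200, rate = 120,
                          arcs = TRUE) {
  cfg <- study_config(position_noise_sd = 0, object_depth = D,
                      sample_rate = rate,
                      lateral_amp = if (arcs) 0.02 else 0,
                      height_amp = if (arcs) 0.04 else 0)
  generate_vr_trial(NULL, "neutral", "go", cfg, it = it, reach_ms = T_ms)
}

# Brute-force earliest-argmax segmentation oracle.
oracle_segment_end <- function(x1) {
  best <- x1[1]; k <- 1L
  for (i in seq_along(x1)) if (x1[i] > best) { best <- x1[i]; k <- i }
  if (best <= x1[1]) k <- length(x1)
  max(k, 2L)
}

# Brute-force z-filtered mean oracle (single pass, n-1 SD).
oracle_filtered_mean <- function(x, z_cut = 2.5) {
  x <- x[!is.na(x)]
  if (length(x) < 3) return(mean(x))
  s <- stats::sd(x)
  if (is.na(s) || s == 0) return(mean(x))
  mean(x[abs(x - mean(x)) <= z_cut * s])
}

# Brute-force dwell oracle: scan runs with gap bridging.
oracle_dwell <- function(hits, tol = 1L, rate = 120) {
  n <- length(hits)
  runs <- list(); i <- 1
  while (i <= n) {
    if (hits[i]) {
      j <- i
      repeat {
        k <- j + 1
        while (k <= n && !hits[k] && (k - j) <= tol) k <- k + 1
        if (k <= n && hits[k]) j <- k else break
      }
      runs[[length(runs) + 1]] <- c(i, j)
      i <- j + 1
    } else i <- i + 1
  }
  if (!length(runs))
    return(list(first = 0, total = 0, bouts = 0L))
  lens <- vapply(runs, function(r) r[2] - r[1] + 1, numeric(1))
  list(first = lens[1] * 1000 / rate, total = sum(lens) * 1000 / rate,
       bouts = length(runs))
}

# Brute-force D-score oracle following the scoring rules directly.
oracle_dscore <- function(session, penalty = 600) {
  s <- session[session$rt_ms <= 10000, ]
  vals <- list()
  for (b in c("compatible", "incompatible")) {
    bl <- s[s$block == b, ]
    m_ok <- mean(bl$rt_ms[bl$correct])
    rt <- ifelse(bl$correct, bl$rt_ms, m_ok + penalty)
    vals[[b]] <- rt
  }
  (mean(vals$incompatible) - mean(vals$compatible)) /
    stats::sd(c(vals$compatible, vals$incompatible))
}

# Random SC-IAT session with controllable block means.
random_iat_session <- function(n = 30, m_comp = 600, m_inc = 700, sd = 80,
                               p_err = 0.1) {
  rt <- c(stats::rnorm(n, m_comp, sd), stats::rnorm(n, m_inc, sd))
  data.frame(block = rep(c("compatible", "incompatible"), each = n),
             rt_ms = pmax(rt, 320),
             correct = stats::runif(2 * n) > p_err)
}

# Small stop-signal session table from explicit vectors.
sst_table <- function(go_rt, go_responded = rep(TRUE, length(go_rt)),
                      stop_responded, ssd, stop_rt = NULL) {
  ns <- length(stop_responded)
  if (is.null(stop_rt)) stop_rt <- rep(NA_real_, ns)
  data.frame(
    trial_type = c(rep("go", length(go_rt)), rep("stop", ns)),
    rt_ms = c(ifelse(go_responded, go_rt, NA), stop_rt),
    responded = c(go_responded, stop_responded),
    ssd_ms = c(rep(NA_real_, length(go_rt)), ssd))
}
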