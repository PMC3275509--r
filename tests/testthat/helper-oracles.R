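# Independent oracles and fixture builders used across the suite.

# Noiseless "mean tissue" generator parameters for a tissue, by mode.
mean_params <- function(tissue, mode = "relative") {
  prof <- zero_sd_profile(builtin_profiles()[[tissue]])
  sample_suture_params(prof, mode = mode)
}

# Fast sensor configs: the analysis path decimates to 1 Hz, so most checks
# run the generator at a reduced acquisition rate.
sens_noiseless <- function(hz = 5, duration_s = 3600)
  sensor_config(sampling_hz = hz, noise_sd_n = 0, duration_s = duration_s)
sens_pure <- function(hz = 5, duration_s = 3600)  # no noise, no quantization
  sensor_config(sampling_hz = hz, noise_sd_n = 0, quantization_step_n = 0,
                duration_s = duration_s)

make_trace <- function(times, forces, tissue = "liver", id = "t1",
                       hz = 1 / median(diff(times)))
  tension_trace(id, tissue, times, forces, hz)

# Brute-force Mann-Whitney: U (x-based, ties as 1/2) and exact two-sided p
# by enumeration of all C(m+n, m) group assignments of the pooled values.
oracle_mw_u <- function(x, y)
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))

oracle_mw_exact_p <- function(x, y) {
  pooled <- c(x, y); m <- length(x); n <- length(y)
  u_obs <- oracle_mw_u(x, y)
  us <- apply(utils::combn(m + n, m), 2, function(idx)
    oracle_mw_u(pooled[idx], pooled[-idx]))
  p <- 2 * min(mean(us <= u_obs + 1e-9), mean(us >= u_obs - 1e-9))
  min(p, 1)
}

# Tie-corrected Kruskal-Wallis H via the general rank-variance formula,
# independent of kruskal.test's implementation.
oracle_kw_h <- function(groups) {
  x <- unlist(groups); g <- rep(seq_along(groups), lengths(groups))
  r <- rank(x); N <- length(x); rbar <- (N + 1) / 2
  num <- sum(tapply(r, g, function(ri) length(ri) * (mean(ri) - rbar)^2))
  den <- sum((r - rbar)^2)
  (N - 1) * num / den
}

# Exact permutation p for the H statistic (small pooled n only).
oracle_kw_exact_p <- function(groups) {
  x <- unlist(groups); sizes <- lengths(groups)
  h_obs <- oracle_kw_h(groups)
  perms <- combinat_assignments(length(x), sizes)
  hs <- vapply(perms, function(idx)
    oracle_kw_h(split(x[idx], rep(seq_along(sizes), sizes))), numeric(1))
  mean(hs >= h_obs - 1e-9)
}

# all distinct ordered assignments of n items into groups of given sizes
combinat_assignments <- function(n, sizes) {
  rec <- function(remaining, sizes) {
    if (!length(sizes)) return(list(integer(0)))
    picks <- utils::combn(remaining, sizes[1], simplify = FALSE)
    out <- list()
    for (p in picks) {
      for (tail in rec(setdiff(remaining, p), sizes[-1]))
        out[[length(out) + 1L]] <- c(p, tail)
    }
    out
  }
  rec(seq_len(n), sizes)
}
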