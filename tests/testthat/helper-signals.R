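# Shared fixtures, all generated in code.

# Stationary AR process via recursive filtering, with burn-in discarded.
sim_ar <- function(n, phi, seed = NULL, sd = 1, burn = 500L) {
  if (!is.null(seed)) set.seed(seed)
  x <- as.numeric(stats::filter(stats::rnorm(n + burn, sd = sd), phi,
                                "recursive"))
  x[(burn + 1L):(burn + n)]
}

# Smooth lowpass AR(4): four real poles, the kind of strongly oversampled
# process a band-limited breath sound resembles. Returns phi (x[n] = sum
# phi_k x[n-k] + v) for pole radii r.
lowpass_ar4_phi <- function(r = c(0.92, 0.9, 0.88, 0.85)) {
  p <- 1
  for (ri in r) p <- c(p, 0) - ri * c(0, p)  # multiply by (1 - ri B)
  -p[-1]
}

# Linearly interpolated time (ms) of the carrier's first zero crossing.
carrier_first_zero_ms <- function(idw_ms, two_cd_ms, n_grid = 5000L) {
  t <- seq(0, 1, length.out = n_grid)
  gamma <- log(0.25) / log(idw_ms / two_cd_ms)
  carrier <- sin(4 * pi * t^gamma)
  i <- which(carrier[-n_grid][-1] * carrier[-1][-1] <= 0)[1] + 1L
  t0 <- t[i] - carrier[i] * (t[i + 1] - t[i]) / (carrier[i + 1] - carrier[i])
  t0 * two_cd_ms
}

# Crackle-free normalized background used in detector tests.
ar4_background <- function(n = 20000L, seed = 1L) {
  peak_normalize(sim_ar(n, lowpass_ar4_phi(), seed = seed))
}

# Insert one crackle at `on` with variance-ratio gain; returns re-normalized
# signal.
insert_one_crackle <- function(x, on, kind = "fine", gain = 3.5) {
  ck <- crackle_wave(kind)
  supp <- on:(on + length(ck) - 1L)
  scale <- sqrt(gain * stats::var(x[supp]) / stats::var(ck))
  x[supp] <- x[supp] + scale * ck
  peak_normalize(x)
}

# Brute-force maximum-cardinality matching between truth and detection
# onsets within tolerance; exponential search, for tiny instances only.
brute_force_match_count <- function(truth, dets, tol) {
  if (length(truth) == 0L) return(0L)
  best <- 0L
  recurse <- function(ti, used) {
    if (ti > length(truth)) {
      best <<- max(best, sum(used))
      return(invisible())
    }
    recurse(ti + 1L, used)  # leave this truth unmatched
    ok <- which(!used & abs(dets - truth[ti]) <= tol)
    for (j in ok) {
      used[j] <- TRUE
      recurse(ti + 1L, used)
      used[j] <- FALSE
    }
  }
  recurse(1L, logical(length(dets)))
  best
}
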