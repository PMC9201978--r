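# Internal numerical helpers: zero-phase IIR filtering, run-length utilities,
# local-extremum search with prominence, debounced threshold crossings.

# Steady-state initial conditions for a direct-form-II-transposed IIR filter,
# so that a step input produces no start-up transient (scipy lfilter_zi).
.lfilter_zi <- function(b, a) {
  if (a[1] != 1) { b <- b / a[1]; a <- a / a[1] }
  n <- max(length(a), length(b))
  a <- c(a, rep(0, n - length(a)))
  b <- c(b, rep(0, n - length(b)))
  m <- n - 1L
  IminusA <- diag(1, m)
  for (i in seq_len(m)) {
    IminusA[i, 1] <- IminusA[i, 1] + a[i + 1]
    if (i < m) IminusA[i, i + 1] <- IminusA[i, i + 1] - 1
  }
  B <- b[2:n] - a[2:n] * b[1]
  solve(IminusA, B)
}

# One-pass IIR filter (direct form II transposed) with initial state zi.
.lfilter <- function(b, a, x, zi) {
  if (a[1] != 1) { b <- b / a[1]; a <- a / a[1] }
  n <- max(length(a), length(b))
  a <- c(a, rep(0, n - length(a)))
  b <- c(b, rep(0, n - length(b)))
  m <- n - 1L
  y <- numeric(length(x))
  z <- zi
  for (i in seq_along(x)) {
    xi <- x[i]
    yi <- b[1] * xi + z[1]
    if (m > 1) {
      for (j in seq_len(m - 1L)) z[j] <- b[j + 1] * xi + z[j + 1] - a[j + 1] * yi
    }
    z[m] <- b[n] * xi - a[n] * yi
    y[i] <- yi
  }
  y
}

# Zero-phase filtering: odd-reflection padding, forward and backward passes,
# each seeded with steady-state initial conditions scaled to the first sample.
.filtfilt <- function(b, a, x) {
  n <- length(x)
  # generous reflection padding so start-up transients decay well below
  # signal level at the segment edges
  padlen <- min(100L, n - 1L)
  if (n < 3L * (max(length(a), length(b)) - 1L) + 1L) {
    stop("signal too short for zero-phase filtering")
  }
  front <- 2 * x[1] - x[(padlen + 1L):2L]
  back  <- 2 * x[n] - x[(n - 1L):(n - padlen)]
  xp <- c(front, x, back)
  zi <- .lfilter_zi(b, a)
  y <- .lfilter(b, a, xp, zi * xp[1])
  y <- rev(y)
  y <- .lfilter(b, a, y, zi * y[1])
  y <- rev(y)
  y[(padlen + 1L):(padlen + n)]
}

# Maximal runs of TRUE in a logical vector -> data.frame(start, end, length).
.true_runs <- function(flag) {
  flag[is.na(flag)] <- FALSE
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep],
             length = r$lengths[keep])
}

# Local maxima of x (use -x for minima). Plateaus yield their first sample.
# Prominence computed against the lower of the two flanking saddle points;
# min_distance enforced greedily from the highest peak down.
.find_peaks <- function(x, min_distance = 1L, prominence = 0) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  d <- diff(x)
  s <- sign(d)
  # propagate the last nonzero slope through plateaus
  for (i in seq_along(s)) if (s[i] == 0 && i > 1L) s[i] <- s[i - 1L]
  idx <- which(s[-length(s)] > 0 & s[-1L] < 0) + 1L
  if (!length(idx)) return(integer(0))
  prom <- vapply(idx, function(p) {
    lmin <- x[p]; i <- p
    while (i > 1L && x[i - 1L] <= x[p]) { i <- i - 1L; if (x[i] < lmin) lmin <- x[i] }
    rmin <- x[p]; i <- p
    while (i < n && x[i + 1L] <= x[p]) { i <- i + 1L; if (x[i] < rmin) rmin <- x[i] }
    x[p] - max(lmin, rmin)
  }, numeric(1))
  idx <- idx[prom >= prominence]
  if (!length(idx) || min_distance <= 1L) return(sort(idx))
  ord <- idx[order(x[idx], decreasing = TRUE)]
  keep <- integer(0)
  for (p in ord) {
    if (!length(keep) || all(abs(keep - p) >= min_distance)) keep <- c(keep, p)
  }
  sort(keep)
}

# Debounced threshold crossings on a (possibly NA-holed) series.
# Returns indices i of the FIRST sample satisfying the inequality after the
# condition had been continuously unsatisfied for at least min_sep seconds.
# NA samples reset the arming state.
.threshold_crossings <- function(x, fs, threshold,
                                 direction = c("below", "above"),
                                 min_sep = 0.2) {
  direction <- match.arg(direction)
  sat <- if (direction == "below") x < threshold else x > threshold
  need <- max(1L, as.integer(round(min_sep * fs)))
  out <- integer(0)
  armed <- 0L  # consecutive valid unsatisfied samples seen
  for (i in seq_along(sat)) {
    si <- sat[i]
    if (is.na(si)) { armed <- 0L; next }
    if (si) {
      if (armed >= need) out <- c(out, i)
      armed <- 0L
    } else {
      armed <- armed + 1L
    }
  }
  out
}

.unwrap <- function(theta) {
  d <- diff(theta)
  d <- d - 2 * pi * round(d / (2 * pi))
  c(theta[1], theta[1] + cumsum(d))
}

.norm3 <- function(m) sqrt(rowSums(m * m))

.unit_rows <- function(m) {
  n <- .norm3(m)
  n[n == 0] <- NA_real_
  m / n
}

.cross_rows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}
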