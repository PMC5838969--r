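# Independent change-point oracle: exhaustive double-loop scan over every
# circular arc, with the same permutation protocol as the package
# implementation (so that, when the two scans agree, the final breakpoints
# must agree). Deliberately written without reusing any package internals.

oracle_scan <- function(x, min_len = 2L) {
  n <- length(x)
  best <- -Inf; bi <- 0L; bj <- n
  if (n < 2 * min_len) return(list(stat = best, i = bi, j = bj))
  s <- c(0, cumsum(x))
  for (i in 0:(n - min_len)) {
    j <- (i + min_len):min(n, i + n - min_len)
    k <- j - i
    arc_mean <- (s[j + 1] - s[i + 1]) / k
    comp_mean <- (s[n + 1] - s[j + 1] + s[i + 1]) / (n - k)
    stat <- abs(arc_mean - comp_mean) / sqrt(1 / k + 1 / (n - k))
    w <- which.max(stat)
    if (stat[w] > best) { best <- stat[w]; bi <- i; bj <- j[w] }
  }
  list(stat = best, i = bi, j = bj)
}

oracle_significant <- function(x, stat_obs, alpha, n_perm, min_len = 2L) {
  max_exceed <- floor(alpha * (1 + n_perm))
  exceed <- 0L
  for (p in seq_len(n_perm)) {
    if (oracle_scan(sample(x), min_len)$stat >= stat_obs) exceed <- exceed + 1L
    if (exceed > max_exceed) return(FALSE)
  }
  (1 + exceed) / (1 + n_perm) <= alpha
}

oracle_recurse <- function(x, lo, alpha, n_perm, min_len) {
  n <- length(x)
  if (n < 2 * min_len) return(integer(0))
  sc <- oracle_scan(x, min_len)
  if (!is.finite(sc$stat)) return(integer(0))
  if (!oracle_significant(x, sc$stat, alpha, n_perm, min_len)) return(integer(0))
  cuts <- c(if (sc$i > 0) sc$i, if (sc$j < n) sc$j)
  bounds <- c(0L, cuts, n)
  out <- cuts + lo
  for (b in seq_len(length(bounds) - 1)) {
    seg <- (bounds[b] + 1):bounds[b + 1]
    out <- c(out, oracle_recurse(x[seg], lo + bounds[b], alpha, n_perm,
                                 min_len))
  }
  sort(unique(out))
}

oracle_merge <- function(breaks, x, min_probes) {
  repeat {
    bounds <- c(0L, breaks, length(x))
    sizes <- diff(bounds)
    if (all(sizes >= min_probes) || length(breaks) == 0) return(breaks)
    s <- which.min(sizes)
    means <- vapply(seq_along(sizes), function(b) {
      mean(x[(bounds[b] + 1):bounds[b + 1]])
    }, numeric(1))
    drop_left <- if (s == 1) FALSE
    else if (s == length(sizes)) TRUE
    else abs(means[s] - means[s - 1]) <= abs(means[s] - means[s + 1])
    breaks <- if (drop_left) breaks[-(s - 1)] else breaks[-s]
  }
}

oracle_cbs_breaks <- function(x, alpha = 0.01, n_perm = 150L,
                              min_probes = 20L, seed = 1L) {
  if (length(x) < min_probes) return(integer(0))
  withr::with_seed(seed, {
    b <- oracle_recurse(x, 0L, alpha, n_perm, min_len = 2L)
    oracle_merge(b, x, min_probes)
  })
}
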