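# Circular binary segmentation.
#
# The split statistic for an arc (i, j] of a series of length n is the
# mean-shift z-statistic |mean(arc) - mean(complement)| / sqrt(1/k + 1/(n-k))
# (the residual-sd factor is constant under permutation and therefore
# omitted). The scan below is vectorized over start positions for each arc
# length; the test suite checks it against an exhaustive double-loop oracle.

# max over all arcs with both pieces >= min_len; returns stat and arc (i, j]
max_arc_stat <- function(x, min_len = 2L) {
  n <- length(x)
  if (n < 2 * min_len) return(list(stat = -Inf, i = 0L, j = n))
  s <- cumsum(x)
  total <- s[n]
  best <- -Inf; best_i <- 0L; best_j <- n
  for (k in min_len:(n - min_len)) {
    # arc sums for i = 0 .. n-k  (arc = (i, i+k])
    d <- c(s[k], s[(k + 1):n] - s[seq_len(n - k)])
    stat <- abs(d / k - (total - d) / (n - k)) / sqrt(1 / k + 1 / (n - k))
    w <- which.max(stat)
    if (stat[w] > best) {
      best <- stat[w]
      best_i <- w - 1L
      best_j <- w - 1L + k
    }
  }
  list(stat = best, i = best_i, j = best_j)
}

# permutation p-value for the observed max statistic, with early stopping
# once significance can no longer be reached
arc_stat_significant <- function(x, stat_obs, alpha, n_permutations,
                                 min_len = 2L) {
  max_exceed <- floor(alpha * (1 + n_permutations))
  exceed <- 0L
  for (p in seq_len(n_permutations)) {
    stat_p <- max_arc_stat(sample(x), min_len)$stat
    if (stat_p >= stat_obs) exceed <- exceed + 1L
    if (exceed > max_exceed) return(FALSE)
  }
  (1 + exceed) / (1 + n_permutations) <= alpha
}

cbs_recurse <- function(x, lo, alpha, n_permutations, min_len) {
  n <- length(x)
  if (n < 2 * min_len) return(integer(0))
  sc <- max_arc_stat(x, min_len)
  if (!is.finite(sc$stat)) return(integer(0))
  if (!arc_stat_significant(x, sc$stat, alpha, n_permutations, min_len)) {
    return(integer(0))
  }
  cuts <- c(if (sc$i > 0) sc$i, if (sc$j < n) sc$j)
  bounds <- c(0L, cuts, n)
  out <- cuts + lo
  for (b in seq_len(length(bounds) - 1)) {
    seg <- (bounds[b] + 1):bounds[b + 1]
    out <- c(out, cbs_recurse(x[seg], lo + bounds[b], alpha, n_permutations,
                              min_len))
  }
  sort(unique(out))
}

# merge segments shorter than min_probes into the neighbor with closer mean
merge_short_segments <- function(breaks, x, min_probes) {
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

#' Circular binary segmentation of an ordered series
#'
#' Recursive maximal-statistic binary/circular splitting: at each level the
#' arc maximizing the mean-shift statistic is tested by permutation
#' (`n_permutations` shuffles of the segment; accepted when the permutation
#' p-value is at most `alpha`), and accepted splits are refined
#' recursively. Segments shorter than `min_probes` are merged into the
#' neighboring segment with the closer mean. Deterministic for a fixed
#' seed.
#'
#' @param series Tibble with `position` and `value`, ordered by position
#'   (a bare numeric vector is also accepted; positions default to the
#'   index).
#' @param alpha Permutation significance level (default 0.01).
#' @param n_permutations Permutations per split test (default 1000).
#' @param min_probes Minimum probes per reported segment (default 20).
#' @param seed RNG seed for the permutations.
#' @return Tibble `start_index`, `end_index`, `start_position`,
#'   `end_position`, `n_probes`, `mean_value`.
#' @export
cbs_segment <- function(series, alpha = 0.01, n_permutations = 1000L,
                        min_probes = 20L, seed = 1L) {
  if (is.numeric(series)) {
    series <- tibble::tibble(position = seq_along(series), value = series)
  }
  if (min_probes < 2) stop("min_probes must be >= 2", call. = FALSE)
  if (is.unsorted(series$position)) {
    stop("series must be ordered by position", call. = FALSE)
  }
  x <- series$value
  n <- length(x)
  if (n < min_probes) {
    breaks <- integer(0)
  } else {
    breaks <- withr::with_seed(seed, {
      b <- cbs_recurse(x, 0L, alpha, n_permutations, min_len = 2L)
      merge_short_segments(b, x, min_probes)
    })
  }
  bounds <- c(0L, breaks, n)
  purrr::map_dfr(seq_len(length(bounds) - 1), function(b) {
    idx <- (bounds[b] + 1):bounds[b + 1]
    tibble::tibble(start_index = idx[1], end_index = idx[length(idx)],
                   start_position = series$position[idx[1]],
                   end_position = series$position[idx[length(idx)]],
                   n_probes = length(idx), mean_value = mean(x[idx]))
  })
}
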