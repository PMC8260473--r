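# Local maxima and topographic prominence for 1-D signals.
# Prominence of a peak: height above the higher of the two lowest valleys
# separating it from the nearest higher terrain (or the signal edge).

local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

peak_prominence <- function(x, peaks) {
  vapply(peaks, function(i) {
    h <- x[i]
    j <- i - 1L
    left_min <- h
    while (j >= 1L && x[j] <= h) {
      if (x[j] < left_min) left_min <- x[j]
      j <- j - 1L
    }
    j <- i + 1L
    right_min <- h
    n <- length(x)
    while (j <= n && x[j] <= h) {
      if (x[j] < right_min) right_min <- x[j]
      j <- j + 1L
    }
    h - max(left_min, right_min)
  }, numeric(1))
}

# peaks with prominence >= fraction * max(prominence); scale-free per trace
prominent_peaks <- function(x, prominence_fraction) {
  pk <- local_maxima(x)
  if (length(pk) == 0) return(list(peaks = integer(0), prominence = numeric(0)))
  prom <- peak_prominence(x, pk)
  keep <- prom >= prominence_fraction * max(prom) & prom > 0
  list(peaks = pk[keep], prominence = prom[keep])
}
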