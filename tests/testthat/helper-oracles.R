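# independent all-pairs oracle for nearest-neighbor distances
brute_mean_nnd <- function(pts) {
  n <- nrow(pts)
  nn <- numeric(n)
  for (i in seq_len(n)) {
    best <- Inf
    for (j in seq_len(n)) {
      if (i == j) next
      d <- sqrt(sum((pts[i, ] - pts[j, ])^2))
      if (d < best) best <- d
    }
    nn[i] <- best
  }
  mean(nn)
}
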