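# small, fast configurations and hand-built fixtures shared across tests

small_synth_config <- function(...) {
  args <- utils::modifyList(list(dtm_extent_m = c(1, 1.5),
                                 images_per_transect = 60), list(...))
  do.call(synth_config, args)
}

toy_scenario <- function(...) {
  plume_scenario(0.05, 0.05, 2.6, ...)
}

# brute-force windowed sample SD, the independent oracle for local_sd()
brute_local_sd <- function(h, w) {
  nr <- nrow(h); nc <- ncol(h); half <- (w - 1) %/% 2
  out <- matrix(NA_real_, nr, nc)
  for (i in (half + 1):(nr - half)) {
    for (j in (half + 1):(nc - half)) {
      win <- h[(i - half):(i + half), (j - half):(j + half)]
      if (all(is.finite(win))) out[i, j] <- stats::sd(win)
    }
  }
  out
}

# independent enumeration oracle for the two-sided exact rank-sum p-value
brute_rank_sum_p <- function(a, b) {
  na <- length(a); N <- na + length(b)
  r <- rank(c(a, b))
  W <- sum(r[seq_len(na)])
  mu <- na * (N + 1) / 2
  Ws <- apply(utils::combn(N, na), 2, function(idx) sum(r[idx]))
  mean(abs(Ws - mu) >= abs(W - mu) - 1e-9)
}
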