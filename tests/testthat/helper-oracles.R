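# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# two-pass population SD
brute_sd <- function(x) {
  mu <- sum(x) / length(x)
  sqrt(sum((x - mu)^2) / length(x))
}

# fixed-step RK4 integration of dF/dt = (kn + ke F)(T - F)
rk4_kinetics <- function(total, kn, ke, f0, times, dt) {
  deriv <- function(f) (kn + ke * f) * (total - f)
  f <- f0
  t <- 0
  out <- numeric(length(times))
  for (k in seq_along(times)) {
    while (t < times[k] - 1e-12) {
      h <- min(dt, times[k] - t)
      k1 <- deriv(f); k2 <- deriv(f + h / 2 * k1)
      k3 <- deriv(f + h / 2 * k2); k4 <- deriv(f + h * k3)
      f <- f + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + h
    }
    out[k] <- f
  }
  out / total
}

# exhaustive enumeration of all global alignments under the package's gap
# convention (a gap run of length L costs open + (L-1) * extend)
brute_align_score <- function(a, b, sub, open, ext) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  rec <- function(i, j, last) {
    if (i > length(av) && j > length(bv)) return(0)
    best <- -Inf
    if (i <= length(av) && j <= length(bv)) {
      best <- max(best, sub[av[i], bv[j]] + rec(i + 1, j + 1, 1L))
    }
    if (i <= length(av)) {
      best <- max(best, (if (last == 2L) ext else open) + rec(i + 1, j, 2L))
    }
    if (j <= length(bv)) {
      best <- max(best, (if (last == 3L) ext else open) + rec(i, j + 1, 3L))
    }
    best
  }
  rec(1L, 1L, 0L)
}

# random ultrametric (coalescent) tree with unique labels
random_ultrametric <- function(n, seed) {
  set.seed(seed)
  ape::rcoal(n, tip.label = paste0("t", sample(1000:9999, n)))
}

random_peptide <- function(len) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y"), len, replace = TRUE),
        collapse = "")
}

# small rendering defaults so image tests stay fast
tiny_imaging <- function(...) imaging_params(height = 64, width = 64, ...)
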