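# Independent oracles and small fixture builders used across the suite.

# Pure-R double-precision forward pass of the conv-pool-conv-pool-fc network,
# written directly from the layer definitions and independent of the C++
# implementation path.
ref_forward <- function(X, w, nc) {
  H <- nc$h; W <- nc$w; C <- nc$c
  conv_same <- function(img, Wt, b, K) {
    d <- dim(img); nf <- nrow(Wt); pad <- K %/% 2
    out <- array(0, c(d[1], d[2], nf))
    padded <- array(0, c(d[1] + 2 * pad, d[2] + 2 * pad, d[3]))
    padded[pad + seq_len(d[1]), pad + seq_len(d[2]), ] <- img
    for (f in seq_len(nf)) {
      acc <- matrix(b[f], d[1], d[2])
      for (c in seq_len(d[3])) for (kx in 1:K) for (ky in 1:K) {
        wgt <- Wt[f, (ky - 1) + K * (kx - 1) + K * K * (c - 1) + 1]
        acc <- acc + wgt *
          padded[(ky - 1) + seq_len(d[1]), (kx - 1) + seq_len(d[2]), c]
      }
      out[, , f] <- acc
    }
    out
  }
  pool2 <- function(a) {
    d <- dim(a); Ho <- d[1] %/% 2; Wo <- d[2] %/% 2
    out <- array(0, c(Ho, Wo, d[3]))
    for (f in seq_len(d[3])) for (x in seq_len(Wo)) for (y in seq_len(Ho))
      out[y, x, f] <- max(a[2 * y - 1:0, 2 * x - 1:0, f])
    out
  }
  vapply(seq_len(ncol(X)), function(j) {
    img <- array(X[, j], c(H, W, C))
    a <- pool2(conv_same(img, w$W1, w$b1, nc$conv1_kernel))
    a <- pool2(conv_same(a, w$W2, w$b2, nc$conv2_kernel))
    h <- pmax(w$W3 %*% as.vector(a) + w$b3, 0)
    as.numeric(w$W4 %*% h + w$b4)
  }, numeric(1))
}

# Brute-force box statistics: manual type-7 quartiles plus a linear scan for
# whiskers and outliers.
ref_box_stats <- function(v, w = 1.5) {
  v <- sort(v[!is.na(v)])
  n <- length(v)
  q7 <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h)
    v[lo] + (h - lo) * (v[min(lo + 1, n)] - v[lo])
  }
  q1 <- q7(0.25); q3 <- q7(0.75)
  lo_lim <- q1 - w * (q3 - q1); hi_lim <- q3 + w * (q3 - q1)
  inside <- v[v >= lo_lim & v <= hi_lim]
  list(median = q7(0.5), q1 = q1, q3 = q3,
       whisker_lo = min(inside), whisker_hi = max(inside),
       outliers = v[v < lo_lim | v > hi_lim])
}

# Wrap a raw image matrix as a plot_samples object.
as_plot_samples <- function(x, dim, targets, bay = "A", stage = 1L) {
  structure(list(
    x = x, dim = as.integer(dim),
    meta = data.frame(plot_id = sprintf("p%03d", seq_len(ncol(x))),
                      bay = rep_len(bay, ncol(x)),
                      stage = rep_len(stage, ncol(x)),
                      target_vi = targets, stringsAsFactors = FALSE),
    excluded = data.frame(plot_id = character(0), reason = character(0))),
    class = "plot_samples")
}

# Small network configuration used where the full-size architecture would be
# wasteful.
tiny_net <- function(in_channels = 3, h = 12, w = 32) {
  net_config(input_hw = c(h, w), in_channels = in_channels, conv1_maps = 4,
             conv2_maps = 6, fc_hidden = 16, dropout_rate = 0.5)
}

# Random plot-sample set whose targets follow a known linear rule in the
# channel means; used for parameter-recovery checks.
linear_rule_samples <- function(n, nc, seed, noise = 0) {
  with_seed_local <- function(seed, expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    expr
  }
  with_seed_local(seed, {
    npx <- nc$h * nc$w
    x <- matrix(runif(npx * nc$c * n, 0, 0.4), npx * nc$c, n)
    mr <- colMeans(x[seq_len(npx), , drop = FALSE])
    mg <- colMeans(x[npx + seq_len(npx), , drop = FALSE])
    y <- 0.2 * mr + 0.5 * mg + 0.1 + rnorm(n, 0, noise)
    as_plot_samples(x, c(nc$h, nc$w, nc$c), y)
  })
}
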