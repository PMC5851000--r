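# Internal helpers: seed fan-out, scoped RNG, clipping, validation.

# Deterministic sub-stream seed derived from a base seed and a sequence of
# labels (characters or integers). Keeps the result in [1, 2^31 - 2] so it is
# always a valid R/mt19937 seed.
substream_seed <- function(seed, ...) {
  labels <- unlist(lapply(list(...), as.character))
  h <- as.double(seed %% 2147483647L)
  for (lab in labels) {
    for (cp in utf8ToInt(lab)) {
      h <- (h * 131 + cp) %% 2147483647
    }
  }
  as.integer(h %% 2147483645) + 1L
}

# Evaluate expr with the R RNG seeded to `seed`, restoring the caller's RNG
# state afterwards. Generator kinds are pinned for reproducibility.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

stopifnot_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi)
    stop(sprintf("`%s` must be a finite number in [%s, %s]", name, lo, hi),
         call. = FALSE)
  invisible(x)
}

BAND_NAMES <- c("blue", "green", "red", "rededge", "nir")

# md5 of the canonical YAML rendering of a configuration list; used to stamp
# experiment outputs so a report can be traced to the exact configuration.
config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  writeLines(yaml::as.yaml(cfg, precision = 15), tf)
  unname(tools::md5sum(tf))
}

# Shared rasterization convention: floor with a small epsilon so rectangle
# edges that sit exactly on pixel boundaries are not shifted by float
# round-trip error.
raster_floor <- function(x) floor(x + 1e-7)
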