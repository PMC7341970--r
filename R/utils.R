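# internal helpers

# round half-up to whole percent (printed-report convention)
.halfUpPercent <- function(frac) floor(frac * 100 + 0.5)

# rolling means of x over windows of length w, advancing by `step`
.windowMeans <- function(x, w, step = 1L) {
  n <- length(x)
  stopifnot(w >= 1L, w <= n)
  cs <- cumsum(c(0, x))
  starts <- seq.int(1L, n - w + 1L, by = step)
  (cs[starts + w] - cs[starts]) / w
}

# derive a per-stage seed from a base seed; keeps results < 2^31
.stageSeed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(stage))) %% 10000L
  as.integer((abs(seed) * 10007 + h * 101 + 17) %% 2147483629)
}

# integer-uniform draw inclusive of both ends
.runifInt <- function(n, lo, hi) lo + floor(stats::runif(n) * (hi - lo + 1))

.assertScalarNum <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("'", name, "' must be a finite numeric scalar", call. = FALSE)
  if (positive && x <= 0)
    stop("'", name, "' must be > 0", call. = FALSE)
  invisible(x)
}
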