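#' Round half away from zero
#'
#' Rounding used for all printed-style percentages in reports: ties go up
#' (0.5 -> 1), unlike [base::round()]'s banker's rounding.
#'
#' @param x numeric vector.
#' @param digits number of decimal digits to keep.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage with half-up integer rounding
#'
#' @param num,den numerator and denominator counts.
#' @return integer-valued percentage; `NA` where `den == 0`.
#' @export
pct_half_up <- function(num, den) {
  out <- rep(NA_real_, length(num))
  ok <- !is.na(den) & den != 0
  out[ok] <- round_half_up(100 * num[ok] / den[ok])
  out
}

# Deterministic 31-bit hash of strings, for deriving named RNG substreams
# from a single run seed. Polynomial rolling hash mod (2^31 - 1), done in
# doubles (intermediate values stay < 2^53).
hash31 <- function(...) {
  s <- paste(vapply(list(...), as.character, ""), collapse = "\x1f")
  m <- 2147483647
  h <- 0
  for (cp in utf8ToInt(s)) h <- (h * 131 + cp) %% m
  as.integer(h)
}

#' Derive a named substream seed from a run seed
#'
#' Each participant/purpose pair gets its own reproducible stream so that
#' editing one part of a simulation config does not shift random draws in
#' unrelated parts.
#'
#' @param seed integer run seed.
#' @param ... stream name components (e.g. participant id, purpose).
#' @return an integer seed < 2^31.
#' @export
substream_seed <- function(seed, ...) {
  hash31(as.integer(seed), ...)
}

# A lightweight RNG stream: stores a .Random.seed state and replays it on
# demand, so independent streams do not perturb each other or the caller.
new_rng_stream <- function(seed) {
  e <- new.env(parent = emptyenv())
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  set.seed(seed)
  e$state <- get(".Random.seed", globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, globalenv())
  }
  e
}

with_stream <- function(stream, expr) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  assign(".Random.seed", stream$state, globalenv())
  on.exit({
    stream$state <- get(".Random.seed", globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, globalenv())
    }
  })
  force(expr)
}

stop_rw <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "remotewear_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

# Merge sorted, possibly touching/overlapping [start, end) intervals.
merge_intervals <- function(start, end) {
  if (length(start) == 0) {
    return(data.frame(start = numeric(0), end = numeric(0)))
  }
  o <- order(start)
  start <- start[o]
  end <- end[o]
  ms <- start[1]
  me <- end[1]
  out_s <- numeric(0)
  out_e <- numeric(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms)
      out_e <- c(out_e, me)
      ms <- start[i]
      me <- end[i]
    }
  }
  data.frame(start = c(out_s, ms), end = c(out_e, me))
}

# Group sums over a factor, keeping empty levels as zeros (rowsum() drops
# them, which would misalign grouped statistics on gappy records).
rowsum_full <- function(v, f) {
  rs <- rowsum(v, f, reorder = FALSE)
  out <- numeric(nlevels(f))
  names(out) <- levels(f)
  out[rownames(rs)] <- rs[, 1]
  unname(out)
}

# Rolling windowed sums of length w over x (step 1); result[i] covers
# x[i..i+w-1]; length(result) = length(x) - w + 1.
roll_sum <- function(x, w) {
  n <- length(x)
  if (n < w) return(numeric(0))
  cs <- cumsum(c(0, x))
  cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]
}
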