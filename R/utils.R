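#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `code` with the global random-number generator seeded to `seed`,
#' then restores the previous RNG state. With `seed = NULL` the expression
#' is evaluated against the current RNG state unchanged.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Derive a deterministic sub-seed from a root seed and string labels
#'
#' Deterministic polynomial string hash folded with the root seed, kept
#' below 2^31 so it is a valid R integer seed. Used to give every synthetic
#' recording its own reproducible random stream.
#'
#' @param root Integer root seed.
#' @param ... Character or numeric labels (e.g. subject id, motion).
#' @return A single integer in `[0, 2^31 - 2]`.
#' @keywords internal
derive_seed <- function(root, ...) {
  s <- paste(c(as.character(root), vapply(list(...), as.character, "")),
             collapse = "\r")
  h <- as.double(root %% 2147483647)
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

# Centered moving-window mean with shrink-to-valid edges. `width` samples:
# floor((width-1)/2) to the left, the rest to the right.
moving_average <- function(x, width) {
  stopifnot(width >= 1)
  n <- length(x)
  left <- (width - 1L) %/% 2L
  right <- width - 1L - left
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - left, 1L)
  hi <- pmin(seq_len(n) + right, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Centered moving-window RMS with shrink-to-valid edges.
moving_rms <- function(x, width) {
  sqrt(moving_average(x^2, width))
}

# Local maxima of x filtered by topographic prominence and minimum
# separation. Plateaus count once, at their middle sample. Returns sorted
# peak indices.
find_peaks <- function(x, prominence = 0, min_dist = 1) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- integer(0)
  i <- 2L
  while (i < n) {
    if (x[i] > x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[i]) j <- j + 1L
      if (j < n && x[j + 1L] < x[i]) {
        cand <- c(cand, (i + j) %/% 2L)
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!length(cand)) return(integer(0))
  prom <- vapply(cand, function(p) {
    lmin <- x[p]
    k <- p - 1L
    while (k >= 1L && x[k] <= x[p]) {
      if (x[k] < lmin) lmin <- x[k]
      k <- k - 1L
    }
    rmin <- x[p]
    k <- p + 1L
    while (k <= n && x[k] <= x[p]) {
      if (x[k] < rmin) rmin <- x[k]
      k <- k + 1L
    }
    x[p] - max(lmin, rmin)
  }, 0)
  keep <- cand[prom >= prominence]
  if (!length(keep)) return(integer(0))
  # enforce minimum separation, keeping higher peaks first
  ord <- keep[order(-x[keep], keep)]
  sel <- integer(0)
  for (p in ord) {
    if (!length(sel) || all(abs(sel - p) >= min_dist)) sel <- c(sel, p)
  }
  sort(sel)
}

# All ordered selections (arrangements) of `r` elements out of 1..n,
# returned as a list of integer vectors. Feasible here because the synergy
# count never exceeds the channel count (<= 4).
ordered_selections <- function(n, r) {
  if (r == 0L) return(list(integer(0)))
  out <- list()
  for (combo in as.list(as.data.frame(combn(n, r)))) {
    out <- c(out, permutations_of(combo))
  }
  out
}

permutations_of <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in permutations_of(v[-i])) out <- c(out, list(c(v[i], rest)))
  }
  out
}

# Format numbers so that read-back via as.numeric is bit-identical.
format_full <- function(x) {
  formatC(x, digits = 17, format = "g")
}
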