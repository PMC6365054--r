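# Internal helpers: reproducible seeding and frame/window arithmetic.

#' Evaluate an expression under a fixed RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `code`, and
#' restores the previous state on exit, so seeded operations never perturb the
#' surrounding random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  seed <- as.integer(seed %% .Machine$integer.max)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  code
}

#' Derive a child seed from a master seed and a string key
#'
#' Deterministic 32-bit FNV-1a hash of `paste(master, key)`, reduced below
#' 2^31 so the result is a valid R integer seed. Used to give every stochastic
#' stage of the pipeline its own independent, reproducible stream.
#'
#' @param master integer master seed.
#' @param key character tag naming the consumer.
#' @return integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, key) {
  stopifnot(length(master) == 1L, length(key) == 1L)
  bytes <- utf8ToInt(paste0(format(master, scientific = FALSE), "/", key))
  as.integer(.fnv1a(bytes) %% 2147483647)
}

# Frame indices (1-based columns) covering the half-open time window
# [t0, t1) seconds, frame j sampling time (j - 1) / rate.
window_frames <- function(t0, t1, rate, n_frames = Inf) {
  j0 <- floor(t0 * rate + 1e-9) + 1L
  j1 <- ceiling(t1 * rate - 1e-9)
  if (j1 < j0) return(integer(0))
  j0 <- max(j0, 1L)
  j1 <- min(j1, n_frames)
  if (j1 < j0) return(integer(0))
  seq.int(j0, j1)
}

# sd with n - 1 denominator, NA-free input assumed
.sem <- function(x) stats::sd(x) / sqrt(length(x))

# Format a double so that read-back with as.numeric() is bit-exact.
.num_chr <- function(x) sprintf("%.17g", x)

.stop_field <- function(field, msg) {
  stop(sprintf("[%s] %s", field, msg), call. = FALSE)
}

# 32-bit FNV-1a over a vector of byte values; h is carried as a double in
# [0, 2^32), so the XOR (low byte only) is done by arithmetic split because
# bitwXor() cannot take values >= 2^31.
.fnv1a <- function(bytes) {
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    # h * 16777619 mod 2^32 without exceeding 2^53: split h into 16-bit halves
    lo16 <- h %% 65536
    hi16 <- (h - lo16) / 65536
    h <- (lo16 * 16777619 + ((hi16 * 16777619) %% 65536) * 65536) %% 4294967296
  }
  h
}

# Pooled-variance two-sample t that tolerates zero-variance input (identical
# samples give t = 0, p = 1; separated constant samples give +/-Inf, p = 0),
# which t.test() rejects; noise-free synthetic data hits both cases.
.safe_ttest <- function(x, y) {
  sp2 <- ((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
    (length(x) + length(y) - 2)
  if (sp2 == 0) {
    d <- mean(x) - mean(y)
    t <- if (d == 0) 0 else sign(d) * Inf
    return(list(statistic = c(t = t), p.value = if (d == 0) 1 else 0))
  }
  tryCatch(stats::t.test(x, y, var.equal = TRUE), error = function(e) {
    # variance below t.test's internal constancy threshold: use the formula
    t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
    df <- length(x) + length(y) - 2
    list(statistic = c(t = t), p.value = 2 * stats::pt(-abs(t), df))
  })
}

# tiny FNV-1a hex digest of a character scalar (config fingerprinting in reports)
.fnv1a_hex <- function(txt) {
  h <- .fnv1a(utf8ToInt(txt))
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
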