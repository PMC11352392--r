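# Seed plumbing: evaluate code under a temporary RNG state, restoring the
# caller's stream afterwards so independent sub-stages stay reproducible.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a named sub-stream seed from a master seed; stays below 2^31.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483587)
}

local_rng <- function(seed) {
  # returns a restore closure after seeding; used where with_seed() is clumsy
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  set.seed(seed)
  function() {
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }
}

# ---- minimal nonnegative big integers (base 2^15 limb vectors) ----
# Only what exact volume powers need: construct, add, multiply, power,
# round-to-double. Limb convolutions stay well inside double's exact-integer
# range (2^30 * n_limbs << 2^53).

BIG_BASE <- 32768

big_carry <- function(x) {
  repeat {
    carry <- floor(x / BIG_BASE)
    x <- x - carry * BIG_BASE
    if (all(carry == 0)) break
    x <- c(x, 0)[seq_len(max(length(x), length(carry) + 1L))]
    x[seq_along(carry) + 1L] <- x[seq_along(carry) + 1L] + carry
  }
  while (length(x) > 1L && x[length(x)] == 0) x <- x[-length(x)]
  x
}

big_from_num <- function(v) {
  stopifnot(v >= 0, v == floor(v), v < 2^53)
  if (v == 0) return(0)
  out <- numeric(0)
  while (v > 0) {
    out <- c(out, v %% BIG_BASE)
    v <- floor(v / BIG_BASE)
  }
  out
}

big_add <- function(a, b) {
  n <- max(length(a), length(b))
  big_carry(c(a, rep(0, n - length(a))) + c(b, rep(0, n - length(b))))
}

big_mul <- function(a, b) {
  n <- length(a) + length(b) - 1L
  out <- numeric(n)
  for (i in seq_along(a)) {
    if (a[i] == 0) next
    idx <- i + seq_along(b) - 1L
    out[idx] <- out[idx] + a[i] * b
    # interleave carries so partial sums stay exactly representable
    if (max(out) > 2^52) out <- c(big_carry(out), numeric(0))
  }
  big_carry(out)
}

big_pow <- function(a, k) {
  out <- 1
  base <- a
  while (k > 0) {
    if (k %% 2 == 1) out <- big_mul(out, base)
    k <- k %/% 2
    if (k > 0) base <- big_mul(base, base)
  }
  out
}

big_to_double <- function(a) {
  v <- 0
  for (i in rev(seq_along(a))) v <- v * BIG_BASE + a[i]
  v
}
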