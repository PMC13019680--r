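# Deterministic derived seeds: one master seed fans out into independent,
# reproducible streams, one per named stage. Kept below 2^31 - 1 and with
# all intermediates inside the exactly-representable double range.
.deriveSeed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * (seq_len(nchar(label)) %% 31L + 1L))
  as.integer(((seed %% 94906265) * 22695477 + h * 7919 + 1) %% 2147483647)
}

# Split R-hat (rank-free version): each chain is split in half, then the
# classic potential-scale-reduction statistic is computed on the 2*C
# half-chains.
.splitRhat <- function(draws) {
  # draws: iterations x chains
  n <- nrow(draws)
  if (n < 4L) return(NA_real_)
  half <- floor(n / 2)
  sub <- cbind(draws[seq_len(half), , drop = FALSE],
               draws[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sub)
  mu <- colMeans(sub)
  s2 <- apply(sub, 2, var)
  W <- mean(s2)
  B <- half * var(mu)
  if (!is.finite(W) || W <= 0) {
    # constant chains: identical constants are converged by definition
    return(if (isTRUE(all.equal(max(mu), min(mu)))) 1 else Inf)
  }
  varplus <- (half - 1) / half * W + B / half
  sqrt(varplus / W)
}

.essTotal <- function(draws) {
  # draws: iterations x chains; total ESS summed over chains
  sum(apply(draws, 2, function(x) {
    if (var(x) == 0) return(length(x))
    as.numeric(coda::effectiveSize(x))
  }))
}

.isCount <- function(x) length(x) == 1L && is.finite(x) && x == floor(x)

.asSeed <- function(seed) {
  if (!.isCount(seed)) stop("seed must be a single integer", call. = FALSE)
  as.integer(seed)
}
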