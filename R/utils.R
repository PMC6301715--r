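#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a per-stage random seed from a master seed
#'
#' All randomness in the package flows from one master seed; each stage
#' draws from its own substream so that toggling one stage never perturbs
#' another. Derived seeds stay below 2^31 - 1.
#'
#' @param seed master integer seed
#' @param stage character stage name
#' @return an integer seed
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) %% 1000003L) * 1009L + (h %% 99991L))
}

# Largest-remainder allocation of n items to proportions p (sums to ~1).
# Guarantees sum(counts) == n and |n*p_i - counts_i| < 1.
allocate_counts <- function(n, p) {
  stopifnot(abs(sum(p) - 1) < 1e-9)
  raw <- n * p
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(p))
}

# Lognormal draws with expectation `mean_val` and log-sd `sdlog`.
rlnorm_mean <- function(n, mean_val, sdlog) {
  stats::rlnorm(n, meanlog = log(mean_val) - sdlog^2 / 2, sdlog = sdlog)
}

#' Adjusted Rand index between two label vectors
#'
#' Used to score recovery of planted cluster structure.
#'
#' @param a,b label vectors of equal length
#' @return numeric in [-1, 1]; 1 means identical partitions
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(length(a), 2)
  expected <- ai * bj / n2
  maxi <- (ai + bj) / 2
  if (maxi == expected) return(1)
  (nij - expected) / (maxi - expected)
}
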