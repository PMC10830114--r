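## Internal helpers shared across modules.

#' @importFrom methods is new validObject slot
#' @importFrom stats median quantile rbeta rbinom rnbinom rpois rhyper runif
#'   rnorm p.adjust wilcox.test fisher.test sd dnorm setNames optimize
#' @importFrom utils read.delim write.table head tail
NULL

## Evaluate `expr` under a temporary RNG state seeded with `seed`;
## the caller's RNG stream is untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Derive a reproducible child seed from a root seed and a stream name,
## kept inside 32-bit integer range.
child_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 1103L + h) %% 2147483647)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

msg <- function(...) message("[remethylome] ", ...)

## Beta-binomial draws: size n, trials `size`, mean mu, overdispersion rho
## in [0,1). rho = 0 reduces to binomial. Var = size*mu*(1-mu)*(1+(size-1)*rho).
rbetabinom <- function(n, size, mu, rho) {
  stopifnot(all(mu >= 0 & mu <= 1), all(rho >= 0 & rho < 1))
  mu <- rep_len(mu, n); size <- rep_len(size, n); rho <- rep_len(rho, n)
  out <- integer(n)
  plain <- rho == 0 | mu == 0 | mu == 1
  if (any(plain)) out[plain] <- rbinom(sum(plain), size[plain], mu[plain])
  if (any(!plain)) {
    i <- which(!plain)
    a <- mu[i] * (1 - rho[i]) / rho[i]
    b <- (1 - mu[i]) * (1 - rho[i]) / rho[i]
    p <- rbeta(length(i), a, b)
    out[i] <- rbinom(length(i), size[i], p)
  }
  out
}

## Read depth: negative binomial with mean `mu` and dispersion `disp`
## (Var = mu + disp*mu^2); Poisson in the disp -> 0 limit.
rdepth <- function(n, mu, disp) {
  stopifnot(mu > 0, disp >= 0)
  if (disp < 1e-8) rpois(n, mu) else rnbinom(n, size = 1 / disp, mu = mu)
}

## 0-based half-open <-> 1-based inclusive interval converters (pure inverses).
to1based <- function(start0, end0) list(start = start0 + 1L, end = end0)
to0based <- function(start1, end1) list(start = start1 - 1L, end = end1)

## Round half to even at integer precision (base round() already does this);
## wrapper exists so the behaviour is named where it matters.
round_half_even <- function(x) round(x)
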