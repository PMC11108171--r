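#' @useDynLib tsrquant, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats quantile rnorm runif rexp rbinom sd uniroot pchisq predict median
#' @importFrom utils read.csv write.csv head
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a reproducible child seed (kept < 2^31) from a base seed and index.
child_seed <- function(seed, k) {
  as.integer((as.double(seed %% 65536L) * 30269 + as.double(k) * 7907 + 101) %% 2147483629)
}

gaussian_kernel <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  x <- seq(-r, r)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Gaussian blur of a matrix (reflected borders).
blur_mat <- function(m, sigma) {
  if (sigma <= 0) return(m)
  cpp_sepconv(m, gaussian_kernel(sigma))
}

# Local standard deviation within a Gaussian window.
local_sd_mat <- function(m, sigma) {
  mu <- blur_mat(m, sigma)
  mu2 <- blur_mat(m * m, sigma)
  sqrt(pmax(mu2 - mu * mu, 0))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# md5 fingerprint of an in-memory object (for artifact provenance).
object_md5 <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(x, con, version = 2)
  close(con)
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

disk_offsets <- function(r) {
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g <- g[g$dr^2 + g$dc^2 <= r^2 + 1e-9, ]
  as.matrix(g)
}
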