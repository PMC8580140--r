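# internal helpers

# Run `code` under a fixed seed, restoring the caller's RNG state after.
local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

sub_seeds <- function(seed, n) {
  local_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# population (not sample) standard deviation
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# AR(1) correlation matrix with unit diagonal
ar1_cor <- function(n, phi) stats::toeplitz(phi^(0:(n - 1)))
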