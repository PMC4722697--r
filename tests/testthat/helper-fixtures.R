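# Shared fixtures, built once per test run.

# A default-configuration simulated run reused by several files.
default_run_env <- new.env()
shared_default_run <- function() {
  if (is.null(default_run_env$run)) {
    default_run_env$refs <- reference_set(seed = 101)
    default_run_env$run <- simulate_run(sim_config(),
                                        default_run_env$refs, seed = 102)
  }
  default_run_env
}

zero_error_config <- function(...) {
  sim_config(miscall_rate = 0, ins_rate = 0, del_rate = 0,
             error_sdlog = 0, ...)
}

# Independent full-matrix affine-gap alignment oracle (no band), used to
# check the banded aligner. Gap of length k costs gap_open + k*gap_extend.
# Plain three-matrix dynamic programme over all cells.
full_gotoh_score <- function(read, ref, match = 1, mismatch = -1,
                             gap_open = -2, gap_extend = -1) {
  a <- strsplit(read, "", fixed = TRUE)[[1]]
  b <- strsplit(ref, "", fixed = TRUE)[[1]]
  n <- length(a); m <- length(b)
  NEG <- -Inf
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)  # gap in read (consumes ref)
  Y <- matrix(NEG, n + 1, m + 1)  # gap in ref (consumes read)
  M[1, 1] <- 0
  if (m >= 1) for (j in 2:(m + 1)) X[1, j] <- gap_open + (j - 1) * gap_extend
  if (n >= 1) for (i in 2:(n + 1)) Y[i, 1] <- gap_open + (i - 1) * gap_extend
  for (i in 1:(n + 1)) {
    for (j in 1:(m + 1)) {
      if (i > 1 && j > 1) {
        s <- if (a[i - 1] == b[j - 1]) match else mismatch
        M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1],
                       Y[i - 1, j - 1]) + s
      }
      if (j > 1)
        X[i, j] <- max(X[i, j], max(M[i, j - 1], Y[i, j - 1]) +
                         gap_open + gap_extend,
                       X[i, j - 1] + gap_extend)
      if (i > 1)
        Y[i, j] <- max(Y[i, j], max(M[i - 1, j], X[i - 1, j]) +
                         gap_open + gap_extend,
                       Y[i - 1, j] + gap_extend)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
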