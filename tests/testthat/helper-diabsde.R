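# Canonical parameterisation used throughout the tests.
default_p <- function(K3 = 5) model_params(noise = noise_spec(K3))

# Constant coefficient matrix of the canonical model.
canonical_M <- function() matrix(c(-0.03, -0.007, 0.02, -0.002), 2, 2)

# Independent matrix-exponential oracle (eigendecomposition written out
# here so it does not share code with the package internals).
oracle_expm <- function(A) {
  e <- eigen(A)
  Re(e$vectors %*% diag(exp(e$values), 2) %*% solve(e$vectors))
}

# Euclidean norm of a 2-vector.
enorm <- function(x) sqrt(sum(x^2))

# Write a surveillance CSV from a data.frame-like list of columns.
write_table_csv <- function(df, file = tempfile(fileext = ".csv")) {
  write.csv(df, file, row.names = FALSE, quote = FALSE)
  file
}
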