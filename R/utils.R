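# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed_ <- function(seed, expr) {
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has_seed) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# All permutations of 1:n as an (n!) x n matrix, lexicographic order.
all_permutations <- function(n) {
  stopifnot(n >= 1)
  if (n > 8L) stop("exhaustive enumeration limited to n <= 8 (", n, "! is too large)")
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    idx <- row:(row + nrow(sub) - 1L)
    out[idx, 1L] <- k
    out[idx, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
    row <- row + nrow(sub)
  }
  out
}

# Lower-triangle (i > j) values of a square matrix, column-major.
lower_tri_ <- function(m) m[lower.tri(m)]

check_square_labeled <- function(m, name = "matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop(name, " must be a square matrix")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop(name, " must have row and column labels")
  if (!identical(rownames(m), colnames(m)))
    stop(name, " row and column labels differ")
  invisible(m)
}

# Integer codes for unambiguous bases; 0 for gaps/ambiguity codes.
BASE_CODE <- {
  x <- integer(256)
  x[utf8ToInt("A")] <- 1L; x[utf8ToInt("C")] <- 2L
  x[utf8ToInt("G")] <- 3L; x[utf8ToInt("T")] <- 4L
  x
}

encode_bases <- function(s) BASE_CODE[as.integer(charToRaw(s))]

decode_bases <- function(v) {
  rawToChar(as.raw(utf8ToInt("ACGT")[v]))
}
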