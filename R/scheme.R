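#' Two-shell diffusion acquisition scheme
#'
#' Builds the acquisition scheme used throughout the package: a number of
#' non-diffusion-weighted (b = 0) volumes followed by one block of
#' diffusion-weighted volumes per nonzero shell. The same set of gradient
#' directions, laid out by the spherical Fibonacci rule (a deterministic,
#' approximately uniform covering of the sphere), is reused across shells.
#'
#' b-values are given in s/mm\eqn{^2} as on the scanner; internally all
#' diffusion computations use ms/\eqn{\mu}m\eqn{^2} (1000 s/mm\eqn{^2} =
#' 1 ms/\eqn{\mu}m\eqn{^2}).
#'
#' @param n_b0 Number of b = 0 volumes (default 15).
#' @param dirs_per_shell Number of gradient directions per nonzero shell
#'   (default 58). At least 6 are required for tensor identifiability.
#' @param b_values Shell b-values in s/mm^2, containing exactly one zero
#'   entry (default `c(0, 1000, 2000)`).
#' @return An object of class `dwi_scheme`: a list with `bvals` (per-volume
#'   b-values, s/mm^2), `bvecs` (3 x n_volumes unit direction matrix, zero
#'   columns for b = 0 volumes), `shells` (the nonzero shell b-values),
#'   `n_b0`, `dirs_per_shell`, and `directions` (3 x dirs_per_shell).
#' @examples
#' sch <- make_scheme()
#' length(sch$bvals)  # 15 + 58 + 58 = 131
#' @export
make_scheme <- function(n_b0 = 15, dirs_per_shell = 58,
                        b_values = c(0, 1000, 2000)) {
  if (dirs_per_shell < 6) {
    stop("at least 6 gradient directions are required for tensor identifiability")
  }
  if (any(b_values < 0)) stop("b-values must be non-negative")
  if (sum(b_values == 0) != 1) {
    stop("b_values must contain exactly one b = 0 entry")
  }
  if (anyDuplicated(b_values)) stop("duplicate shell b-values")
  if (n_b0 < 1) stop("at least one b = 0 volume is required")

  shells <- sort(b_values[b_values > 0])
  dirs <- fibonacci_sphere(dirs_per_shell)

  bvals <- c(rep(0, n_b0), rep(shells, each = dirs_per_shell))
  bvecs <- cbind(matrix(0, 3, n_b0),
                 do.call(cbind, rep(list(dirs), length(shells))))
  structure(list(bvals = bvals, bvecs = bvecs, shells = shells,
                 n_b0 = n_b0, dirs_per_shell = dirs_per_shell,
                 directions = dirs),
            class = "dwi_scheme")
}

#' @export
print.dwi_scheme <- function(x, ...) {
  cat("DWI acquisition scheme:", length(x$bvals), "volumes\n")
  cat("  b = 0 volumes:", x$n_b0, "\n")
  cat("  shells (s/mm^2):", paste(x$shells, collapse = ", "),
      "with", x$dirs_per_shell, "directions each\n")
  invisible(x)
}

# Deterministic, approximately uniform unit vectors on the upper
# hemisphere (spherical Fibonacci lattice). The diffusion signal is even
# in g, so antipodal directions are redundant; covering a hemisphere
# avoids near-duplicate measurements. Returns a 3 x n matrix of unit
# columns.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 1
  z <- (i + 0.5) / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  d <- matrix(c(r * cos(phi), r * sin(phi), z), nrow = 3, byrow = TRUE)
  sweep(d, 2, sqrt(colSums(d^2)), "/")
}

#' Number of volumes implied by a scheme
#' @param scheme A `dwi_scheme`.
#' @return Integer volume count.
#' @export
n_volumes <- function(scheme) length(scheme$bvals)

#' Write FSL-style bval/bvec text files
#'
#' `bvals` is one whitespace-separated row; `bvecs` is three rows (x, y, z).
#'
#' @param scheme A `dwi_scheme`.
#' @param bval_path,bvec_path Output file paths.
#' @return Invisibly, the two paths.
#' @export
write_bval_bvec <- function(scheme, bval_path, bvec_path) {
  writeLines(paste(format(scheme$bvals, trim = TRUE, scientific = FALSE),
                   collapse = " "), bval_path)
  writeLines(apply(scheme$bvecs, 1, function(row) {
    paste(format(row, trim = TRUE, digits = 10, scientific = FALSE),
          collapse = " ")
  }), bvec_path)
  invisible(c(bval_path, bvec_path))
}

#' Read FSL-style bval/bvec text files into a scheme
#'
#' Reconstructs a `dwi_scheme` from per-volume b-values and directions.
#' Shell membership is recovered from the unique nonzero b-values; the
#' direction set of the first nonzero shell is stored as `directions`.
#'
#' @param bval_path,bvec_path Input file paths.
#' @return A `dwi_scheme`.
#' @export
read_bval_bvec <- function(bval_path, bvec_path) {
  bvals <- scan(bval_path, quiet = TRUE)
  bvecs <- matrix(scan(bvec_path, quiet = TRUE), nrow = 3, byrow = TRUE)
  if (ncol(bvecs) != length(bvals)) {
    stop("bval and bvec files disagree on the number of volumes")
  }
  shells <- sort(unique(bvals[bvals > 0]))
  first <- bvals == shells[1]
  structure(list(bvals = bvals, bvecs = bvecs, shells = shells,
                 n_b0 = sum(bvals == 0), dirs_per_shell = sum(first),
                 directions = bvecs[, first, drop = FALSE]),
            class = "dwi_scheme")
}

# Convert scanner-convention b (s/mm^2) to model units (ms/um^2).
b_to_model_units <- function(b_smm2) b_smm2 / 1000
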