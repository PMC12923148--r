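#' Build the block-structured random coupling matrix
#'
#' Generates the four synaptic blocks \eqn{J^{EE}, J^{EI}, J^{IE}, J^{II}}
#' with exact in-degrees: every row of the E-sourced blocks has exactly
#' \eqn{K_E} nonzeros drawn uniformly without replacement, every row of the
#' I-sourced blocks exactly \eqn{K_I}. Nonzero values follow the
#' \eqn{1/\sqrt{K}} scaling:
#' \deqn{J^{EE}_{ij} = J_0 j_E/\sqrt{K_E},\quad
#'       J^{IE}_{ij} = J_0 j_I/\sqrt{K_E},\quad
#'       J^{EI}_{ij} = -J_0 g_E j_E/\sqrt{K_I},\quad
#'       J^{II}_{ij} = -J_0 g_I j_I/\sqrt{K_I}.}
#' Self-connections are excluded within the EE and II blocks (a common
#' convention; it only affects O(1/N) terms). Because in-degrees are exact,
#' row sums are deterministic: \eqn{J_0 j_E \sqrt{K_E}} for EE rows,
#' \eqn{-J_0 g_E j_E \sqrt{K_I}} for EI rows, and so on.
#'
#' Reproducibility: the global \code{seed} is expanded into one sub-seed per
#' row via a seeded draw, so each row's presynaptic set can be regenerated
#' independently.
#'
#' @param params a [model_params()] object.
#' @param seed integer seed for the sparsity pattern.
#' @return An object of class \code{std_connectivity}: list with sparse
#'   row-compressed blocks \code{EE}, \code{EI}, \code{IE}, \code{II}
#'   (\code{Matrix::dgRMatrix}), the \code{params} and the \code{seed}.
#' @export
build_connectivity <- function(params, seed = 1L) {
  stopifnot(inherits(params, "std_params"))
  if (params$N > 2e6)
    stop("explicit connectivity is limited to N <= 2e6; use the mean-field ",
         "and random-matrix routines for larger sizes")
  N_E <- as.integer(params$N_E); N_I <- as.integer(params$N_I)
  K_E <- as.integer(params$K_E); K_I <- as.integer(params$K_I)
  if (K_E > N_E - 1) stop("EE rows need K_E <= N_E - 1 (no self-connections)")
  if (K_I > N_I - 1) stop("II rows need K_I <= N_I - 1 (no self-connections)")

  set.seed(seed)
  row_seeds <- sample.int(.Machine$integer.max - 1L, 2L * (N_E + N_I))

  vEE <- params$J0 * params$j_E / sqrt(K_E)
  vIE <- params$J0 * params$j_I / sqrt(K_E)
  vEI <- -params$J0 * params$g_E * params$j_E / sqrt(K_I)
  vII <- -params$J0 * params$g_I * params$j_I / sqrt(K_I)

  sample_rows <- function(nrow_, ncol_, K, seeds, exclude_diag) {
    cols <- matrix(0L, nrow = K, ncol = nrow_)
    for (i in seq_len(nrow_)) {
      set.seed(seeds[i])
      if (exclude_diag) {
        # draw from ncol_-1 candidates, shift indices >= i up by one
        s <- sample.int(ncol_ - 1L, K)
        s[s >= i] <- s[s >= i] + 1L
        cols[, i] <- s
      } else {
        cols[, i] <- sample.int(ncol_, K)
      }
    }
    cols
  }
  mk <- function(cols, nrow_, ncol_, val) {
    K <- nrow(cols)
    Matrix::sparseMatrix(i = rep(seq_len(nrow_), each = K),
                         j = as.vector(cols), x = val,
                         dims = c(nrow_, ncol_), repr = "R")
  }
  sEE <- row_seeds[seq_len(N_E)]
  sEI <- row_seeds[N_E + seq_len(N_E)]
  sIE <- row_seeds[2L * N_E + seq_len(N_I)]
  sII <- row_seeds[2L * N_E + N_I + seq_len(N_I)]
  conn <- list(
    EE = mk(sample_rows(N_E, N_E, K_E, sEE, TRUE), N_E, N_E, vEE),
    EI = mk(sample_rows(N_E, N_I, K_I, sEI, FALSE), N_E, N_I, vEI),
    IE = mk(sample_rows(N_I, N_E, K_E, sIE, FALSE), N_I, N_E, vIE),
    II = mk(sample_rows(N_I, N_I, K_I, sII, TRUE), N_I, N_I, vII),
    params = params, seed = as.integer(seed))
  class(conn) <- "std_connectivity"
  conn
}

#' @export
print.std_connectivity <- function(x, ...) {
  p <- x$params
  cat(sprintf("Block connectivity: N = %g, K_E = %g, K_I = %g, J0 = %g, seed = %d\n",
              p$N, p$K_E, p$K_I, p$J0, x$seed))
  invisible(x)
}

#' Rescale the global coupling of an existing connectivity
#'
#' The sparsity pattern is quenched; only the scalar \code{J0} changes, so
#' sweeps over the coupling reuse one realization.
#'
#' @param conn a \code{std_connectivity}.
#' @param J0 new global synaptic scale.
#' @return A \code{std_connectivity} with rescaled values.
#' @export
rescale_connectivity <- function(conn, J0) {
  stopifnot(inherits(conn, "std_connectivity"), J0 >= 0)
  old <- conn$params$J0
  if (old == 0) stop("cannot rescale a connectivity built with J0 = 0")
  fac <- J0 / old
  for (b in c("EE", "EI", "IE", "II")) conn[[b]]@x <- conn[[b]]@x * fac
  conn$params <- update_params(conn$params, J0 = J0)
  conn
}

#' Assemble the full signed coupling matrix
#'
#' Stacks the four blocks into the \eqn{N \times N} matrix with E columns
#' first. Mostly useful for eigen-analysis and export at small \eqn{N}.
#'
#' @param conn a \code{std_connectivity}.
#' @param dense return a base dense matrix instead of a sparse one.
#' @return A \code{Matrix} (or base matrix if \code{dense}).
#' @export
connectivity_matrix <- function(conn, dense = FALSE) {
  J <- rbind(cbind(conn$EE, conn$EI), cbind(conn$IE, conn$II))
  if (dense) as.matrix(J) else J
}

#' Export the coupling matrix in Matrix Market format
#'
#' @param conn a \code{std_connectivity}.
#' @param file output path (\code{.mtx}).
#' @return \code{file}, invisibly.
#' @export
write_connectivity_mtx <- function(conn, file) {
  Matrix::writeMM(methods::as(connectivity_matrix(conn), "CsparseMatrix"), file)
  invisible(file)
}

# CSR slot access for the C++ simulators (0-based column indices already).
csr_parts <- function(block) {
  list(p = block@p, j = block@j, x = block@x)
}

conn_csr_args <- function(conn) {
  b <- lapply(conn[c("EE", "EI", "IE", "II")], csr_parts)
  list(b$EE$p, b$EE$j, b$EE$x, b$EI$p, b$EI$j, b$EI$x,
       b$IE$p, b$IE$j, b$IE$x, b$II$p, b$II$j, b$II$x)
}
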