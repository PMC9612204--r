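#' Spherical-spline scalp-potential interpolation
#'
#' Perrin-style spherical splines: the kernel is the Legendre series
#' \deqn{g(x) = \frac{1}{4\pi} \sum_{n=1}^{N} \frac{2n+1}{(n(n+1))^m} P_n(x)}
#' evaluated at the cosine of the inter-electrode angle. A recording at the
#' source electrodes determines spline coefficients through the linear system
#' with a constant-offset constraint; interpolation is then linear in the
#' data, so one solve per electrode set serves every time sample.
#'
#' @param source_positions n x 3 matrix of unit vectors (or an
#'   [eeg_layout()]).
#' @param order_m spline stiffness order m (>= 2); 4 is the literature
#'   standard for scalp potentials.
#' @param n_terms number of Legendre terms N (>= 7).
#' @param regularization ridge added to the kernel matrix diagonal;
#'   0 gives exact interpolation at the sources.
#' @return a `spline_model` object.
#' @export
fit_spline <- function(source_positions, order_m = 4, n_terms = 50,
                       regularization = 1e-5) {
  if (inherits(source_positions, "eeg_layout") ||
      is.data.frame(source_positions)) {
    source_positions <- layout_positions(source_positions)
  }
  pos <- as.matrix(source_positions)
  stopifnot(ncol(pos) == 3)
  if (order_m < 2) stop("order_m must be >= 2", call. = FALSE)
  if (n_terms < 7) stop("n_terms must be >= 7", call. = FALSE)
  if (regularization < 0) stop("regularization must be >= 0", call. = FALSE)
  n <- nrow(pos)
  if (n < 4) stop("need at least 4 source positions", call. = FALSE)
  # require non-coplanar sources: rank of centered positions must be 3
  if (qr(sweep(pos, 2, colMeans(pos)))$rank < 3) {
    stop("source positions are coplanar; spline system is degenerate",
         call. = FALSE)
  }
  gram <- pos %*% t(pos)
  gram[gram > 1] <- 1; gram[gram < -1] <- -1
  G <- spline_kernel(gram, order_m, n_terms)
  A <- rbind(cbind(G + diag(regularization, n), rep(1, n)),
             c(rep(1, n), 0))
  # factor once; reused for every data vector. The m = 4 kernel is very
  # smooth, so the unregularized system is ill-conditioned but still solvable;
  # only refuse when it is numerically singular.
  cond <- kappa(A, exact = FALSE)
  if (!is.finite(cond) || cond > 1e15) {
    stop(sprintf(
      "spline system singular after regularization (condition ~ %.3g)", cond),
      call. = FALSE)
  }
  qr_A <- qr(A, LAPACK = TRUE)
  structure(list(positions = pos, order_m = order_m, n_terms = n_terms,
                 regularization = regularization, qr = qr_A),
            class = "spline_model")
}

# Legendre-series kernel g(x), vectorized over a matrix of cosines.
# P_n via the Bonnet recurrence (n+1)P_{n+1} = (2n+1) x P_n - n P_{n-1}.
spline_kernel <- function(x, order_m, n_terms) {
  p_prev <- array(1, dim = dim(x))        # P_0
  p_cur <- x                              # P_1
  acc <- (3 / (2^order_m)) * p_cur        # n = 1 term: (2n+1)/(n(n+1))^m
  if (n_terms >= 2) {
    for (n in 2:n_terms) {
      p_next <- ((2 * n - 1) * x * p_cur - (n - 1) * p_prev) / n
      acc <- acc + (2 * n + 1) / (n * (n + 1))^order_m * p_next
      p_prev <- p_cur
      p_cur <- p_next
    }
  }
  acc / (4 * pi)
}

#' @export
print.spline_model <- function(x, ...) {
  cat(sprintf(
    "<spline_model: %d sources, m = %d, N = %d, regularization = %g>\n",
    nrow(x$positions), x$order_m, x$n_terms, x$regularization))
  invisible(x)
}

#' Interpolate values onto target positions
#'
#' @param model a `spline_model` from [fit_spline()].
#' @param values numeric vector (one value per source electrode) or a matrix
#'   sources x samples; columns are interpolated independently.
#' @param targets k x 3 matrix of unit vectors (or an [eeg_layout()]).
#' @return numeric vector of length k, or a k x samples matrix when `values`
#'   is a matrix.
#' @export
interpolate_spline <- function(model, values, targets) {
  stopifnot(inherits(model, "spline_model"))
  if (inherits(targets, "eeg_layout") || is.data.frame(targets)) {
    targets <- layout_positions(targets)
  }
  targets <- matrix(as.numeric(targets), ncol = 3)
  n <- nrow(model$positions)
  vec_in <- is.null(dim(values))
  V <- if (vec_in) matrix(values, ncol = 1) else as.matrix(values)
  if (nrow(V) != n) {
    stop("need one value per source electrode (", n, "), got ", nrow(V),
         call. = FALSE)
  }
  if (any(!is.finite(V))) stop("non-finite values", call. = FALSE)
  rhs <- rbind(V, rep(0, ncol(V)))
  coef <- qr.coef(model$qr, rhs)        # (n+1) x samples: c then c0
  gram_t <- targets %*% t(model$positions)
  gram_t[gram_t > 1] <- 1; gram_t[gram_t < -1] <- -1
  Gt <- spline_kernel(gram_t, model$order_m, model$n_terms)
  out <- Gt %*% coef[seq_len(n), , drop = FALSE] +
    matrix(coef[n + 1, ], nrow = nrow(targets), ncol = ncol(V), byrow = TRUE)
  if (vec_in) drop(out) else out
}
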