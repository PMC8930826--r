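# Radau pseudospectral grid: flipped Legendre-Gauss-Radau collocation
# nodes on (0, 1] (right endpoint included), the differentiation matrix
# of the Lagrange interpolant anchored at the segment start, and the
# quadrature weights.
#
# The interior flipped-LGR nodes are the (negated) eigenvalues of the
# symmetric Jacobi matrix of the Jacobi(0, 1) orthogonal polynomials;
# quadrature weights come from exactness on the Legendre basis, and the
# differentiation matrix from barycentric interpolation on the n + 1
# support points {0, nodes}.

legendre_eval <- function(k, x) {
  # P_k(x) by recurrence, vectorized in x
  if (k == 0) return(rep(1, length(x)))
  if (k == 1) return(x)
  pm <- rep(1, length(x)); p <- x
  for (j in 2:k) {
    pn <- ((2 * j - 1) * x * p - (j - 1) * pm) / j
    pm <- p; p <- pn
  }
  p
}

#' Radau collocation grid
#'
#' Flipped Legendre-Gauss-Radau scheme of a given order on the unit
#' interval: `order` collocation nodes in (0, 1] including the right
#' endpoint, the differentiation matrix of the degree-`order` Lagrange
#' interpolant supported on the segment start 0 plus the nodes, and
#' positive quadrature weights summing to one (exact for polynomials up
#' to degree `2 * order - 2`).
#'
#' @param order Number of collocation nodes (>= 1).
#' @return List with `nodes` (length `order`), `D`
#'   (`order` x `order + 1`; column 1 corresponds to the segment start)
#'   and `weights` (length `order`).
#' @export
radau_grid <- function(order) {
  if (!is.numeric(order) || length(order) != 1L || order < 1 ||
      order != round(order)) {
    stop("order must be an integer >= 1", call. = FALSE)
  }
  n <- as.integer(order)
  if (n == 1L) {
    nodes <- 1
  } else {
    # interior standard-LGR nodes on (-1, 1): eigenvalues of the
    # Jacobi(0, 1) tridiagonal matrix of size n - 1
    m <- n - 1L
    kk <- seq_len(m) - 1
    diag_a <- 1 / ((2 * kk + 1) * (2 * kk + 3))
    kk2 <- seq_len(m - 1)
    off_b <- sqrt(kk2 * (kk2 + 1) / (2 * kk2 + 1)^2)
    J <- diag(diag_a, m, m)
    if (m > 1) {
      J[cbind(seq_len(m - 1), 2:m)] <- off_b
      J[cbind(2:m, seq_len(m - 1))] <- off_b
    }
    interior <- sort(eigen(J, symmetric = TRUE, only.values = TRUE)$values)
    # standard LGR = {-1, interior}; flipped = negate and reverse
    x <- sort(-c(-1, interior))           # in (-1, 1]
    nodes <- (x + 1) / 2
    nodes[n] <- 1                          # exact endpoint
  }
  # quadrature weights: exactness on Legendre basis over [-1, 1]
  x <- 2 * nodes - 1
  V <- t(vapply(0:(n - 1), function(k) legendre_eval(k, x),
                numeric(n)))
  rhs <- c(2, rep(0, n - 1))
  w <- solve(V, rhs) / 2                   # scaled to [0, 1]
  # differentiation matrix on support {0, nodes}
  supp <- c(0, nodes)
  D <- barycentric_diff(supp)[-1, , drop = FALSE]
  list(nodes = nodes, D = D, weights = w)
}

# full (n+1)x(n+1) differentiation matrix via barycentric weights
barycentric_diff <- function(x) {
  n <- length(x)
  wb <- vapply(seq_len(n), function(j) {
    1 / prod(x[j] - x[-j])
  }, numeric(1))
  D <- matrix(0, n, n)
  for (j in seq_len(n)) {
    for (k in seq_len(n)) {
      if (j != k) D[j, k] <- (wb[k] / wb[j]) / (x[j] - x[k])
    }
  }
  diag(D) <- -rowSums(D)
  D
}

# Legendre-Gauss-Lobatto points on [0, 1] (used to place segment
# boundaries within a phase); npts >= 2 includes both endpoints
lgl_points <- function(npts) {
  if (npts < 2) stop("need at least 2 LGL points", call. = FALSE)
  if (npts == 2) return(c(0, 1))
  m <- npts - 2L
  # interior LGL nodes: eigenvalues of the Jacobi(1, 1) matrix
  kk <- seq_len(m) - 1
  diag_a <- rep(0, m)
  kk2 <- seq_len(max(m - 1, 0))
  off_b <- sqrt(kk2 * (kk2 + 2) / ((2 * kk2 + 1) * (2 * kk2 + 3)))
  J <- diag(diag_a, m, m)
  if (m > 1) {
    J[cbind(seq_len(m - 1), 2:m)] <- off_b
    J[cbind(2:m, seq_len(m - 1))] <- off_b
  }
  interior <- sort(eigen(J, symmetric = TRUE, only.values = TRUE)$values)
  (c(-1, interior, 1) + 1) / 2
}
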