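#' Sparse generator of the truncated chemical master equation
#'
#' Builds the infinitesimal generator of the continuous-time Markov chain on
#' the truncated state space \eqn{\{(D_0, n), (D_1, n): n = 0..N\}} with
#' transitions
#' \itemize{
#'   \item \eqn{(D_0, n) \to (D_1, n)} at \eqn{\gamma_1},
#'   \item \eqn{(D_1, n) \to (D_0, n)} at \eqn{\gamma_0 + f n},
#'   \item \eqn{(D_0, n) \to (D_0, n+1)} at \eqn{\lambda_0},
#'   \item \eqn{(D_1, n) \to (D_1, n+1)} at \eqn{\lambda_1},
#'   \item \eqn{(D_s, n) \to (D_s, n-1)} at \eqn{d\,n}.
#' }
#' Truncation is reflecting: synthesis out of `n = N` is suppressed, which
#' keeps the matrix a proper stochastic generator (columns sum to zero), so
#' its null space is a genuine probability vector rather than a
#' quasi-stationary one.
#'
#' States are ordered `(D0,0), (D1,0), (D0,1), (D1,1), ...`; entry `[i, j]`
#' is the rate from state `j` to state `i`.
#'
#' @param params a [gene_params()] object (normalized internally).
#' @param n_max truncation point `N >= 1`.
#' @return A sparse `dgCMatrix` of dimension `2(N+1) x 2(N+1)`.
#' @export
cme_generator <- function(params, n_max) {
  p <- normalize_params(params)
  n_max <- as.integer(n_max)
  stopifnot(n_max >= 1)
  idx <- function(state, n) 2L * n + state + 1L  # state 0/1, n = 0..N
  ns <- 0:n_max
  from <- integer(0); to <- integer(0); rate <- numeric(0)
  add <- function(j, i, r) {
    keep <- r > 0
    from <<- c(from, j[keep]); to <<- c(to, i[keep]); rate <<- c(rate, r[keep])
  }
  # promoter switching
  add(idx(0L, ns), idx(1L, ns), rep(p$gamma1, n_max + 1))
  add(idx(1L, ns), idx(0L, ns), p$gamma0 + p$f * ns)
  # synthesis (suppressed out of n = N)
  nsyn <- 0:(n_max - 1L)
  add(idx(0L, nsyn), idx(0L, nsyn + 1L), rep(p$lambda0, n_max))
  add(idx(1L, nsyn), idx(1L, nsyn + 1L), rep(p$lambda1, n_max))
  # degradation
  ndeg <- 1:n_max
  add(idx(0L, ndeg), idx(0L, ndeg - 1L), p$d * ndeg)
  add(idx(1L, ndeg), idx(1L, ndeg - 1L), p$d * ndeg)

  dim <- 2L * (n_max + 1L)
  G <- Matrix::sparseMatrix(i = to, j = from, x = rate, dims = c(dim, dim))
  Matrix::diag(G) <- Matrix::diag(G) - Matrix::colSums(G)
  G
}

#' Steady state of the truncated chemical master equation
#'
#' Independent brute-force solver used as ground truth for every analytic
#' result: the unique stationary probability vector of the generator of
#' [cme_generator()], obtained by a sparse linear solve in which one balance
#' equation is replaced by the normalization constraint
#' \eqn{\sum_n [P_0(n) + P_1(n)] = 1}. Uniqueness holds because the
#' truncated chain is irreducible whenever \eqn{\gamma_1 > 0} and `d > 0`.
#'
#' If the marginal mass at the truncation boundary exceeds `tail_tol`, `N`
#' is doubled and the solve repeated (up to `max_doublings` times).
#'
#' @param params a [gene_params()] object.
#' @param n_max truncation point, or `"auto"` (mean + 10 sd from the
#'   analytic moments where the closed form is trusted, otherwise a bound
#'   from the larger synthesis rate; floor 50).
#' @param tail_tol maximum tolerated marginal mass at `n = N`.
#' @param max_doublings escalation limit before a truncation error.
#' @return An object of class `promoter_pmf`: list with `p0`, `p1` (mass in
#'   each promoter state, indexed by `n = 0..N`) and `n_max`.
#' @seealso [marginal_pmf()] to collapse over the promoter state.
#' @export
cme_steady_state <- function(params, n_max = "auto", tail_tol = 1e-8,
                             max_doublings = 3L) {
  p <- normalize_params(params)
  if (p$gamma1 <= 0 && p$lambda0 == 0 && p$gamma0 + p$f > 0) {
    stop("truncated chain not irreducible: gamma1 = 0 with no leakage", call. = FALSE)
  }
  if (identical(n_max, "auto")) {
    lam <- p$lambda1 - p$lambda0
    R <- lam - p$f * p$lambda0
    mom <- NULL
    if ((p$lambda1 == p$lambda0 && p$f == 0 && p$lambda0 > 0) ||
        (lam > 0 && abs(R) > 1e-10 * max(p$lambda1, p$lambda0, 1))) {
      mom <- tryCatch(moments(p), error = function(e) NULL)
    }
    if (!is.null(mom)) {
      n_max <- max(50, ceiling(mom$mean + 10 * sqrt(max(mom$variance, 0))))
    } else {
      top <- max(p$lambda1, p$lambda0)
      n_max <- max(50, ceiling(top + 10 * sqrt(max(top, 1))))
    }
  }
  n_max <- as.integer(n_max)
  for (attempt in 0:max_doublings) {
    G <- cme_generator(p, n_max)
    dim <- 2L * (n_max + 1L)
    # replace the last balance equation by the normalization row
    G[dim, ] <- 1
    rhs <- c(rep(0, dim - 1L), 1)
    sol <- as.numeric(Matrix::solve(G, rhs))
    sol[sol < 0 & sol > -1e-12] <- 0
    p0 <- sol[seq(1, dim, by = 2)]
    p1 <- sol[seq(2, dim, by = 2)]
    tail_mass <- p0[n_max + 1] + p1[n_max + 1]
    if (tail_mass <= tail_tol) {
      return(structure(list(p0 = p0, p1 = p1, n_max = n_max,
                            tail_mass = tail_mass),
                       class = "promoter_pmf"))
    }
    n_max <- 2L * n_max
  }
  stop("cme_steady_state: tail mass still above tolerance after ",
       max_doublings, " doublings of the truncation point", call. = FALSE)
}

#' @export
print.promoter_pmf <- function(x, ...) {
  cat(sprintf("<promoter_pmf> support 0..%d, P(D1) = %.4g, tail mass %.3g\n",
              x$n_max, sum(x$p1), x$tail_mass))
  invisible(x)
}

#' Marginal copy-number distribution of a promoter-resolved steady state
#'
#' @param x a `promoter_pmf` from [cme_steady_state()].
#' @return A [discrete_pmf()] with masses `p0 + p1`.
#' @export
marginal_pmf <- function(x) {
  stopifnot(inherits(x, "promoter_pmf"))
  discrete_pmf(x$p0 + x$p1)
}
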