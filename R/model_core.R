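#' Bundle generalized Lotka-Volterra parameters
#'
#' The generalized Lotka-Volterra (gLV) equations describe a community of `S`
#' interacting species through
#' \deqn{\dot x_i = \lambda_i + g_i x_i + \sum_j \omega_{ij} x_i x_j,}
#' where \eqn{x_i} is the abundance, \eqn{\lambda_i \ge 0} the immigration
#' rate and \eqn{g_i} the growth rate of species `i`, and \eqn{\omega_{ij}}
#' the per-capita effect of species `j` on species `i`.  The self-interactions
#' \eqn{\omega_{ii}} must be strictly negative (density-dependent
#' self-limitation); with a diagonal interaction matrix the system reduces to
#' independent logistic equations with carrying capacities
#' \eqn{g_i/|\omega_{ii}|}.
#'
#' @param growth numeric vector of growth rates \eqn{g_i} (1/time).
#' @param interactions square numeric matrix \eqn{\omega} with
#'   \eqn{\omega_{ii} < 0}; units 1/(abundance x time).
#' @param immigration immigration rates \eqn{\lambda_i \ge 0}
#'   (abundance/time); scalar recycled. Default 0.
#' @param species optional character vector of species labels; defaults to
#'   `sp01, sp02, ...`.
#' @return An object of class `glv_params`: a list with elements `S`,
#'   `growth`, `interactions`, `immigration`, `species`.
#' @examples
#' p <- glv_params(growth = c(1, 2), interactions = diag(c(-1, -2)))
#' solve_steady_state(p)
#' @export
glv_params <- function(growth, interactions, immigration = 0, species = NULL) {
  interactions <- as.matrix(interactions)
  S <- length(growth)
  if (nrow(interactions) != S || ncol(interactions) != S) {
    stop("`interactions` must be an S x S matrix matching length(growth) = ", S)
  }
  if (any(!is.finite(growth)) || any(!is.finite(interactions))) {
    stop("growth rates and interactions must be finite")
  }
  if (any(diag(interactions) >= 0)) {
    stop("all self-interactions (diagonal of `interactions`) must be negative")
  }
  if (length(immigration) == 1) immigration <- rep(immigration, S)
  if (length(immigration) != S) {
    stop("`immigration` must have length 1 or S = ", S)
  }
  if (any(immigration < 0)) stop("immigration rates must be non-negative")
  if (is.null(species)) {
    species <- sprintf("sp%0*d", max(2L, nchar(S)), seq_len(S))
  }
  if (length(species) != S) stop("`species` must have length S = ", S)
  structure(
    list(S = S, growth = as.numeric(growth), interactions = interactions,
         immigration = as.numeric(immigration), species = as.character(species)),
    class = "glv_params"
  )
}

#' @export
print.glv_params <- function(x, ...) {
  cat("<glv_params> ", x$S, " species\n", sep = "")
  cat("  growth rates:      ", paste(signif(head(x$growth, 4), 3), collapse = ", "),
      if (x$S > 4) ", ...", "\n", sep = "")
  cat("  self-interactions: ", paste(signif(head(diag(x$interactions), 4), 3),
                                     collapse = ", "),
      if (x$S > 4) ", ...", "\n", sep = "")
  off <- x$interactions[row(x$interactions) != col(x$interactions)]
  cat("  off-diagonal sd:   ", signif(if (length(off)) sd(off) else 0, 3), "\n",
      sep = "")
  invisible(x)
}

#' Sample a random interaction matrix
#'
#' Off-diagonal interaction coefficients are drawn i.i.d. from
#' \eqn{N(0, \alpha^2)} (the classic random-community ensemble); the diagonal
#' is set to the supplied self-interactions, which must be strictly negative.
#' With `alpha = 0` the result is diagonal, i.e. the logistic special case.
#'
#' @param S number of species.
#' @param alpha standard deviation \eqn{\alpha \ge 0} of off-diagonal entries.
#' @param self_interactions numeric vector (length `S` or scalar) of negative
#'   diagonal entries.
#' @param seed optional integer seed (calls [set.seed()]).
#' @return An `S` x `S` numeric matrix.
#' @export
sample_interactions <- function(S, alpha, self_interactions, seed = NULL) {
  if (S < 1) stop("S must be >= 1")
  if (alpha < 0) stop("`alpha` must be >= 0")
  if (length(self_interactions) == 1) self_interactions <- rep(self_interactions, S)
  if (length(self_interactions) != S) {
    stop("`self_interactions` must have length 1 or S")
  }
  if (any(self_interactions >= 0)) {
    stop("self-interactions must be strictly negative")
  }
  if (!is.null(seed)) set.seed(seed)
  omega <- matrix(0, S, S)
  if (alpha > 0) {
    omega[] <- rnorm(S * S, sd = alpha)
  }
  diag(omega) <- self_interactions
  omega
}

#' Impose growth rates from a target steady state
#'
#' Given an interaction matrix and a desired steady-state abundance vector
#' \eqn{x^*}, returns the growth-rate vector \eqn{\hat g = -\omega x^*} that
#' makes \eqn{x^*} a fixed point of the gLV equations without immigration.
#' This is how a heavy-tailed rank abundance profile is enforced on an
#' otherwise random community.
#'
#' @param interactions interaction matrix \eqn{\omega}.
#' @param x_star non-negative steady-state abundances.
#' @return Growth-rate vector `g`.
#' @export
impose_growth <- function(interactions, x_star) {
  interactions <- as.matrix(interactions)
  if (ncol(interactions) != length(x_star)) {
    stop("dimension mismatch between `interactions` and `x_star`")
  }
  if (any(x_star < 0)) stop("`x_star` must be non-negative")
  as.numeric(-interactions %*% x_star)
}

#' Solve the interior steady state of a gLV system
#'
#' Solves \eqn{\omega x^* = -g} (immigration must be zero).  The fixed point
#' is feasible only if all components are non-negative; an infeasible solution
#' raises an error.
#'
#' @param params a [glv_params()] object with zero immigration.
#' @return Named numeric vector `x_star`.
#' @export
solve_steady_state <- function(params) {
  stopifnot(inherits(params, "glv_params"))
  if (any(params$immigration != 0)) {
    stop("steady-state solver requires zero immigration")
  }
  x_star <- tryCatch(
    solve(params$interactions, -params$growth),
    error = function(e) stop("singular interaction matrix: ", conditionMessage(e))
  )
  if (any(x_star < 0)) {
    stop("infeasible steady state: negative abundance for species ",
         paste(params$species[x_star < 0], collapse = ", "))
  }
  setNames(as.numeric(x_star), params$species)
}

#' Linear stability of a gLV fixed point
#'
#' Evaluates the Jacobian
#' \eqn{J_{ij} = \delta_{ij}(g_i + \sum_k \omega_{ik} x^*_k) + \omega_{ij} x^*_i}
#' at the fixed point and reports whether all eigenvalues have negative real
#' part.  At an interior fixed point without immigration the bracket vanishes
#' and \eqn{J = \mathrm{diag}(x^*)\,\omega}.
#'
#' @param params a [glv_params()] object.
#' @param x_star positive abundances at the fixed point.
#' @return A list of class `glv_stability` with elements `stable` (logical)
#'   and `leading_real` (largest eigenvalue real part).
#' @export
linear_stability <- function(params, x_star) {
  stopifnot(inherits(params, "glv_params"))
  if (length(x_star) != params$S) stop("`x_star` must have length S")
  if (any(x_star <= 0)) stop("`x_star` must be strictly positive")
  omega <- params$interactions
  J <- diag(params$growth + as.numeric(omega %*% x_star), params$S) +
    omega * x_star
  ev <- eigen(J, only.values = TRUE)$values
  leading <- max(Re(ev))
  structure(list(stable = leading < 0, leading_real = leading),
            class = "glv_stability")
}

#' @export
print.glv_stability <- function(x, ...) {
  cat("<glv_stability> ", if (x$stable) "stable" else "unstable",
      " (leading eigenvalue real part ", signif(x$leading_real, 4), ")\n",
      sep = "")
  invisible(x)
}

#' @rdname linear_stability
#' @param x a `glv_stability` object.
#' @param ... unused.
#' @export
glance.glv_stability <- function(x, ...) {
  tibble::tibble(stable = x$stable, leading_real = x$leading_real)
}
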