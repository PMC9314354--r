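#' Solve coupled 1:1 host-guest competitive-binding equilibria
#'
#' Computes the equilibrium speciation of a solution holding an arbitrary
#' number of hosts (receptor site populations) and guests (dyes and
#' analytes) that form 1:1 complexes only. Every (host j, guest i) pair with
#' association constant `Ka_ij > 0` contributes a complex with concentration
#' `Ka_ij * H_j_free * G_i_free`. The solver enforces the mass balances
#'
#' \deqn{H_{j,t} = H_{j,f}\,(1 + \sum_i K_{ij} G_{i,f}), \qquad
#'       G_{i,t} = G_{i,f}\,(1 + \sum_j K_{ij} H_{j,f})}
#'
#' by damped fixed-point iteration on the free-host concentrations: at each
#' sweep the guest frees are eliminated analytically from the current host
#' frees, the host frees are re-estimated from the host balances, and the
#' update is damped geometrically (exponent 0.5) to keep the iterates
#' positive and contractive. Once the residual is small a Newton polish on
#' the host balances takes the solution to the requested tolerance.
#'
#' Species with zero total concentration are retained in the output with a
#' free concentration of exactly zero, so that array layouts stay
#' rectangular.
#'
#' @param comp A [composition()].
#' @param affinities An [affinity_table()]; pairs absent from the table bind
#'   with Ka = 0.
#' @param tol Relative mass-balance tolerance (> 0), default `1e-10`.
#' @param max_iter Maximum number of fixed-point sweeps, default `10000`.
#' @param damping Damping exponent in (0, 1], default `0.5`.
#' @return An object of class `equilibrium_state`: list with `free` (named
#'   vector over all species), `complexes` (matrix, guests x hosts),
#'   `residual` (maximum relative mass-balance violation), `iterations` and
#'   `condition`.
#' @examples
#' aff <- affinity_table(data.frame(host = "H1", guest = "D1", Ka_per_M = 1e7))
#' st <- solve_equilibrium(composition(c(H1 = 1e-6), c(D1 = 1e-6)), aff)
#' st$complexes["D1", "H1"]
#' @export
solve_equilibrium <- function(comp, affinities, tol = 1e-10, max_iter = 10000L,
                              damping = 0.5) {
  stopifnot(inherits(comp, "composition"), inherits(affinities, "affinity_table"))
  if (!is.numeric(tol) || tol <= 0) stop("tol must be > 0", call. = FALSE)
  hosts <- names(comp$host_totals)
  gt <- guest_totals(comp)
  guests <- names(gt)
  Ht <- unname(comp$host_totals)
  Gt <- unname(gt)
  K <- ka_matrix(affinities, hosts, guests, comp$condition)

  free <- stats::setNames(c(Ht, Gt), c(hosts, guests))
  complexes <- matrix(0, nrow = length(guests), ncol = length(hosts),
                      dimnames = list(guests, hosts))

  act_h <- Ht > 0
  act_g <- Gt > 0
  Ka <- K[act_g, act_h, drop = FALSE]
  iterations <- 0L
  residual <- 0

  if (any(act_h) && any(act_g) && any(Ka > 0)) {
    Hta <- Ht[act_h]
    Gta <- Gt[act_g]
    h <- Hta
    resid_of <- function(h) {
      g <- Gta / (1 + as.vector(Ka %*% h))
      list(g = g,
           res = max(abs(Hta - h * (1 + as.vector(crossprod(Ka, g)))) / Hta))
    }
    r <- resid_of(h)
    repeat {
      iterations <- iterations + 1L
      if (r$res <= tol || iterations > max_iter) break
      if (r$res < 1e-3) {
        # Newton polish on f_j(h) = h_j (1 + sum_i K_ij g_i(h)) - H_jt
        g <- r$g
        s <- 1 + as.vector(Ka %*% h)                 # guest denominators
        fh <- h * (1 + as.vector(crossprod(Ka, g))) - Hta
        # J_jk = delta_jk (1 + sum_i K_ij g_i) - h_j sum_i K_ij g_i K_ik / s_i
        D <- diag(1 + as.vector(crossprod(Ka, g)), nrow = length(h))
        Corr <- crossprod(Ka * (g / s), Ka)          # sum_i K_ij (g_i/s_i) K_ik
        J <- D - h * Corr
        step <- tryCatch(solve(J, fh), error = function(e) NULL)
        if (!is.null(step) && all(is.finite(step))) {
          lambda <- 1
          improved <- FALSE
          for (half in 1:30) {
            h_try <- h - lambda * step
            if (all(h_try > 0)) {
              r_try <- resid_of(h_try)
              if (r_try$res < r$res) {
                h <- h_try; r <- r_try; improved <- TRUE
                break
              }
            }
            lambda <- lambda / 2
          }
          if (improved) next
        }
      }
      # damped fixed-point sweep (geometric damping keeps h > 0)
      h_cand <- Hta / (1 + as.vector(crossprod(Ka, r$g)))
      h <- h * (h_cand / h)^damping
      r <- resid_of(h)
    }
    residual <- r$res
    if (residual > tol) {
      cond <- structure(
        class = c("sensarray_convergence_error", "error", "condition"),
        list(message = sprintf(
          "equilibrium solver did not converge: residual %.3e > tol %.3e after %d iterations",
          residual, tol, max_iter),
          call = sys.call(-1), residual = residual)
      )
      stop(cond)
    }
    free[hosts[act_h]] <- h
    free[guests[act_g]] <- r$g
    complexes[act_g, act_h] <- Ka * outer(r$g, h)
  }
  # guests facing no binding partner stay fully free; zero-total species stay 0
  structure(
    list(free = free, complexes = complexes, residual = residual,
         iterations = iterations, condition = comp$condition),
    class = "equilibrium_state"
  )
}

#' @export
print.equilibrium_state <- function(x, ...) {
  cat(sprintf("<equilibrium_state> %d species, residual %.2e (%d iterations)\n",
              length(x$free), x$residual, x$iterations))
  invisible(x)
}

#' Closed-form 1:1 binding for a single host-guest pair
#'
#' Analytic root of the 1:1 mass balance
#' `Ka x^2 - (Ka (H_t + G_t) + 1) x + Ka H_t G_t = 0`
#' lying in `[0, min(H_t, G_t)]`, evaluated in the cancellation-safe form
#' `x = 2 Ka H_t G_t / (b + sqrt(b^2 - 4 Ka^2 H_t G_t))` with
#' `b = Ka (H_t + G_t) + 1`. Serves as the analytic oracle for the
#' iterative solver.
#'
#' @param host_total,guest_total Total concentrations (M, >= 0).
#' @param Ka Association constant (M^-1, >= 0).
#' @return Bound (complex) concentration in M.
#' @examples
#' closed_form_pair(1e-6, 1e-6, 1e7)
#' @export
closed_form_pair <- function(host_total, guest_total, Ka) {
  if (any(c(host_total, guest_total, Ka) < 0)) {
    stop("inputs must be >= 0", call. = FALSE)
  }
  if (Ka == 0 || host_total == 0 || guest_total == 0) return(0)
  b <- Ka * (host_total + guest_total) + 1
  disc <- b * b - 4 * Ka * Ka * host_total * guest_total
  x <- 2 * Ka * host_total * guest_total / (b + sqrt(max(disc, 0)))
  min(x, host_total, guest_total)
}

#' Audit mass balance of an equilibrium state
#'
#' Recomputes, for every species, `|total - (free + sum of its complexes)|`
#' divided by `max(total, floor)` and returns the maximum over species.
#' Returns exactly 0 for an exact solution.
#'
#' @param state An `equilibrium_state` (or a hand-built list with `free`
#'   and `complexes` of matching shape).
#' @param comp The [composition()] the state is supposed to satisfy.
#' @param floor Denominator floor in M protecting species with zero total;
#'   default `1e-15`.
#' @return Maximum relative mass-balance violation (dimensionless).
#' @export
speciation_residual <- function(state, comp, floor = 1e-15) {
  stopifnot(inherits(comp, "composition"))
  hosts <- names(comp$host_totals)
  gt <- guest_totals(comp)
  guests <- names(gt)
  if (!setequal(names(state$free), c(hosts, guests)) ||
      !setequal(rownames(state$complexes), guests) ||
      !setequal(colnames(state$complexes), hosts)) {
    stop("species sets of state and composition do not match", call. = FALSE)
  }
  cx <- state$complexes[guests, hosts, drop = FALSE]
  host_rec <- state$free[hosts] + colSums(cx)
  guest_rec <- state$free[guests] + rowSums(cx)
  totals <- c(comp$host_totals, gt)
  recovered <- c(host_rec, guest_rec)[names(totals)]
  max(abs(totals - recovered) / pmax(totals, floor))
}
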