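# Mean-field (macroscopic) steady states by damped Newton iteration with an
# ODE-relaxation continuation fallback. Conservation laws (promoter on/off
# pairs, total repressor, ...) are detected from the stoichiometry matrix and
# eliminated so the Newton system is full rank.

# structural decomposition of a system: dynamic species, conservation laws,
# independent coordinates, and the affine lift x_dep(x_ind)
conservation_structure <- function(system) {
  nu <- system$nu
  dyn <- which(rowSums(abs(nu)) > 0)
  fixed <- setdiff(seq_len(nrow(nu)), dyn)
  S <- nu[dyn, , drop = FALSE]
  out <- list(dyn = dyn, fixed = fixed)
  if (length(dyn) == 0) return(c(out, list(ind = integer(), dep = integer())))
  sv <- svd(S, nu = nrow(S))
  tol <- max(dim(S)) * max(sv$d, 0) * .Machine$double.eps * 100
  r <- sum(sv$d > tol)
  # rows of L span the left null space: L %*% S = 0, L %*% x conserved
  L <- if (r < nrow(S)) t(sv$u[, seq(r + 1, nrow(S)), drop = FALSE]) else
    matrix(0, 0, nrow(S))
  qrt <- qr(t(S))
  ind <- sort(qrt$pivot[seq_len(r)])   # independent dynamic species
  dep <- setdiff(seq_len(nrow(S)), ind)
  A <- if (length(dep)) {
    Ld <- L[, dep, drop = FALSE]
    -solve(Ld, L[, ind, drop = FALSE]) # d x_dep = A d x_ind
  } else matrix(0, 0, r)
  c(out, list(S = S, L = L, ind = ind, dep = dep, A = A))
}

# full state from independent coordinates given a reference state x_ref
# satisfying the conservation totals
lift_state <- function(cs, x_ref, x_ind) {
  x <- x_ref
  x[cs$dyn[cs$ind]] <- x_ind
  if (length(cs$dep))
    x[cs$dyn[cs$dep]] <- x_ref[cs$dyn[cs$dep]] +
      drop(cs$A %*% (x_ind - x_ref[cs$dyn[cs$ind]]))
  x
}

reduced_deriv <- function(system, cs, x_ref, x_ind) {
  x <- lift_state(cs, x_ref, x_ind)
  macro_deriv(system, x)[cs$dyn[cs$ind]]
}

num_jacobian <- function(fn, x, rel_step = 1e-6) {
  n <- length(x)
  f0 <- fn(x)
  J <- matrix(0, length(f0), n)
  for (i in seq_len(n)) {
    h <- rel_step * max(abs(x[i]), 1e-2)
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    J[, i] <- (fn(xp) - fn(xm)) / (2 * h)
  }
  J
}

#' Mean-field steady state of a reaction system
#'
#' Finds a fixed point of the macroscopic rate equations by damped Newton
#' iteration from the initial copies, falling back to ODE relaxation
#' (continuation) when Newton stalls. Conserved units (e.g. a promoter's
#' on/off pair) are eliminated before solving and reported at their
#' stationary occupancy. Systems without a finite fixed point (e.g. an
#' upstream flux exceeding a downstream enzyme's maximal capacity) are
#' reported with `diverged = TRUE`, never silently.
#'
#' @param system a [reaction_system()].
#' @param tol convergence tolerance: `||dx/dt|| < tol * scale` where `scale`
#'   is the total macroscopic flux magnitude (floored at 1).
#' @param max_iter Newton iteration cap.
#' @return list with `state` (named vector), `deriv_norm`, `diverged`
#'   (logical), `message`.
#' @export
steady_state_mean_field <- function(system, tol = 1e-9, max_iter = 200) {
  cs <- conservation_structure(system)
  nm <- system$species$name
  x0 <- stats::setNames(as_state(system, initial_state(system)), nm)
  if (length(cs$dyn) == 0)
    return(list(state = stats::setNames(x0, nm), deriv_norm = 0,
                diverged = FALSE, message = "no dynamic species"))

  newton <- function(x_ref) {
    xi <- x_ref[cs$dyn[cs$ind]]
    for (iter in seq_len(max_iter)) {
      g <- reduced_deriv(system, cs, x_ref, xi)
      scale <- max(1, sum(abs(macro_rates(system, lift_state(cs, x_ref, xi)))))
      if (sqrt(sum(g^2)) < tol * scale)
        return(list(ok = TRUE, x = lift_state(cs, x_ref, xi)))
      J <- num_jacobian(function(z) reduced_deriv(system, cs, x_ref, z), xi)
      step <- tryCatch(-solve(J, g), error = function(e) NULL)
      if (is.null(step)) return(list(ok = FALSE, x = lift_state(cs, x_ref, xi)))
      lambda <- 1
      g0 <- sqrt(sum(g^2))
      repeat {
        xn <- xi + lambda * step
        xf <- lift_state(cs, x_ref, xn)
        if (all(xf > -1e-9)) {
          gn <- reduced_deriv(system, cs, x_ref, pmax(xn, 0))
          if (sqrt(sum(gn^2)) < g0 || lambda < 1e-6) { xi <- pmax(xn, 0); break }
        }
        lambda <- lambda / 2
        if (lambda < 1e-10) return(list(ok = FALSE, x = lift_state(cs, x_ref, xi)))
      }
    }
    list(ok = FALSE, x = lift_state(cs, x_ref, xi))
  }

  res <- newton(x0)
  if (!res$ok) {
    # continuation: relax the ODE toward the attractor, then polish
    rhs <- function(t, y, parms) list(macro_deriv(system, pmax(y, 0)))
    y <- x0
    diverged <- FALSE
    for (horizon in c(1e4, 1e5, 1e6)) {
      sol <- tryCatch(
        deSolve::lsoda(y, c(0, horizon), rhs, parms = NULL,
                       rtol = 1e-8, atol = 1e-8),
        error = function(e) NULL, warning = function(w) NULL)
      if (is.null(sol) || nrow(sol) < 2 || any(!is.finite(sol[nrow(sol), -1]))) {
        diverged <- TRUE; break
      }
      y <- pmax(sol[nrow(sol), -1], 0)
      if (max(y) > 1e9) { diverged <- TRUE; break }
      res <- newton(y)
      if (res$ok) break
    }
    if (diverged || !res$ok) {
      g <- macro_deriv(system, pmax(y, 0))
      growing <- any(g > tol * max(1, sum(abs(macro_rates(system, y))))) ||
        max(y) > 1e8
      return(list(state = stats::setNames(pmax(y, 0), nm),
                  deriv_norm = sqrt(sum(g^2)),
                  diverged = TRUE,
                  message = if (growing) "no finite steady state (flux imbalance)"
                            else "steady-state solver did not converge"))
    }
  }
  g <- macro_deriv(system, res$x)
  list(state = stats::setNames(res$x, nm), deriv_norm = sqrt(sum(g^2)),
       diverged = FALSE, message = "converged")
}
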