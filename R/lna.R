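# Linear noise approximation: fluctuation-dissipation (Lyapunov) covariances
# around the macroscopic steady state, normalized covariances eta_ij =
# sigma_ij / (<x_i><x_j>), CV^2 per species, logarithmic gains, and the
# cotranscribed-vs-uncoupled CV^2 difference with its predicted sign.

#' Build a linear-noise-approximation model
#'
#' Computes the macroscopic steady state, the Jacobian `M` of the reduced
#' (conservation-eliminated) system by central finite differences, and the
#' diffusion matrix `N = S diag(f) S' / omega`. The model is rejected, with
#' the offending eigenvalues named, unless all eigenvalues of `M` have
#' negative real part.
#'
#' @param system a [reaction_system()].
#' @param rel_step relative finite-difference step for the Jacobian.
#' @return an object of class `lna_model` with fields `x_star`, `M`
#'   (reduced), `N` (reduced), `omega`, plus the index bookkeeping needed to
#'   lift covariances back to the full species set.
#' @export
build_lna <- function(system, rel_step = 1e-6) {
  ss <- steady_state_mean_field(system)
  if (ss$diverged)
    stop("LNA unavailable: ", ss$message)
  cs <- conservation_structure(system)
  x_star <- ss$state
  if (length(cs$dyn) == 0) stop("no dynamic species; LNA is trivial")
  xi <- x_star[cs$dyn[cs$ind]]
  M <- num_jacobian(function(z) reduced_deriv(system, cs, x_star, z), xi,
                    rel_step = rel_step)
  f <- macro_rates(system, x_star)
  S_ind <- cs$S[cs$ind, , drop = FALSE]
  N <- S_ind %*% diag(f, length(f)) %*% t(S_ind) / system$omega
  ev <- eigen(M, only.values = TRUE)$values
  if (any(Re(ev) >= 0))
    stop("unstable or non-hyperbolic steady state; eigenvalues: ",
         paste(format(ev, digits = 4), collapse = ", "))
  structure(list(x_star = x_star, M = M, N = N, omega = system$omega,
                 cs = cs, species = system$species$name,
                 eigenvalues = ev),
            class = "lna_model")
}

#' @export
print.lna_model <- function(x, ...) {
  cat("<lna_model> ", length(x$species), " species (",
      length(x$cs$ind), " independent), slowest eigenvalue ",
      format(max(Re(x$eigenvalues)), digits = 4), " 1/s\n", sep = "")
  invisible(x)
}

#' Solve the stationary fluctuation-dissipation (Lyapunov) equation
#'
#' Solves `M Sigma + Sigma M' + omega N = 0` for the stationary covariance
#' matrix by Kronecker vectorization, lifts it back to the full species set
#' through the conservation constraints, and reports normalized covariances
#' `eta_ij = sigma_ij / (<x_i><x_j>)` and per-species `CV^2 = eta_ii`.
#'
#' @param model an [build_lna()] result.
#' @return an object of class `lna_result` with `Sigma`, `eta` (matrices over
#'   all species), `cv2` (named vector), `mean` (steady state), `residual`.
#' @export
solve_lyapunov <- function(model) {
  M <- model$M
  B <- model$omega * model$N
  n <- nrow(M)
  K <- kronecker(diag(n), M) + kronecker(M, diag(n))
  sig <- tryCatch(solve(K, -as.vector(B)), error = function(e)
    stop("singular Lyapunov system: ", conditionMessage(e)))
  Sr <- matrix(sig, n, n)
  Sr <- (Sr + t(Sr)) / 2
  resid <- norm(M %*% Sr + Sr %*% t(M) + B, "F")
  if (norm(B, "F") > 0 && resid > 1e-8 * norm(B, "F"))
    stop("Lyapunov residual too large: ", format(resid))
  cs <- model$cs
  nsp <- length(model$species)
  # fluctuation lift: d x_full = T d x_ind (fixed species do not fluctuate)
  Tm <- matrix(0, nsp, n)
  Tm[cs$dyn[cs$ind], ] <- diag(n)
  if (length(cs$dep)) Tm[cs$dyn[cs$dep], ] <- cs$A
  Sigma <- Tm %*% Sr %*% t(Tm)
  dimnames(Sigma) <- list(model$species, model$species)
  mu <- model$x_star
  eta <- Sigma / outer(mu, mu)
  eta[!is.finite(eta)] <- NA_real_
  cv2 <- diag(eta)
  structure(list(Sigma = Sigma, eta = eta, cv2 = cv2, mean = mu,
                 residual = resid), class = "lna_result")
}

#' @export
print.lna_result <- function(x, ...) {
  print(tidy(x))
  invisible(x)
}

#' Tidy an LNA result into one row per species
#'
#' @param x an `lna_result`.
#' @param ... unused.
#' @return tibble with `species`, `mean`, `variance`, `cv2`, `cv`.
#' @method tidy lna_result
#' @export
tidy.lna_result <- function(x, ...) {
  tibble::tibble(species = names(x$mean), mean = unname(x$mean),
                 variance = unname(diag(x$Sigma)),
                 cv2 = unname(x$cv2), cv = sqrt(unname(x$cv2)))
}

#' @method glance lna_result
#' @export
glance.lna_result <- function(x, ...) {
  tibble::tibble(n_species = length(x$mean), residual = x$residual)
}

#' Full LNA analysis of a system
#'
#' Convenience wrapper: [build_lna()] then [solve_lyapunov()].
#'
#' @inheritParams build_lna
#' @return an `lna_result`.
#' @export
lna_analysis <- function(system) solve_lyapunov(build_lna(system))

#' Closed-form normalized protein covariance for a two-gene expression model
#'
#' For two stable proteins expressed without posttranslational reactions or
#' promoter bursting, the stationary normalized covariance
#' `eta_AB = sigma_AB / (<A><B>)` has a closed form in the mean mRNA copy
#' number and the mRNA and protein lifetimes:
#' * uncoupled transcription: `eta_AB = 0`;
#' * one polycistronic mRNA, independent translation of A and B:
#'   `eta_AB = (1/<m>) * tau_m / (tau_m + tau_p)` (the shared-mRNA
#'   fluctuations are the only source of covariance);
#' * cotranslation (one ribosome binding site producing A and B together):
#'   the same term plus `1/(2<A>)` from shared translation events.
#'
#' The form is validated against [solve_lyapunov()] to 1e-8 relative in the
#' package tests.
#'
#' @param expr an [expression_params()] object.
#' @param mode one of `"cotranslated"`, `"cotranscribed"`, `"uncoupled"`.
#' @return the normalized covariance `eta_AB` (dimensionless).
#' @export
eta_operon_closed_form <- function(expr, mode = c("cotranslated",
                                                  "cotranscribed",
                                                  "uncoupled")) {
  mode <- match.arg(mode)
  m_mean <- expr$k_tx / expr$delta_m
  a_mean <- expr$k_tl * m_mean / expr$k_deg
  tau_m <- 1 / expr$delta_m
  tau_p <- 1 / expr$k_deg
  shared_mrna <- (1 / m_mean) * tau_m / (tau_m + tau_p)
  switch(mode,
         uncoupled = 0,
         cotranscribed = shared_mrna,
         cotranslated = shared_mrna + 1 / (2 * a_mean))
}

#' Logarithmic gain of a flux ratio with respect to a variable
#'
#' `H = (y/R) dR/dy` evaluated at the steady state by central differences
#' with relative step 1e-6. `flux_ratio` must be positive at `x_star`.
#'
#' @param flux_ratio function taking a named state vector, returning a
#'   positive scalar (a flux ratio or an output).
#' @param x_star named steady-state vector.
#' @param y species name to perturb.
#' @param rel_step relative finite-difference step.
#' @return dimensionless logarithmic gain.
#' @export
log_gain <- function(flux_ratio, x_star, y, rel_step = 1e-6) {
  R0 <- flux_ratio(x_star)
  if (!is.finite(R0) || R0 <= 0) stop("flux ratio must be positive at x_star")
  y0 <- x_star[[y]]
  h <- rel_step * max(abs(y0), 1e-8)
  xp <- x_star; xp[[y]] <- y0 + h
  xm <- x_star; xm[[y]] <- y0 - h
  (y0 / R0) * (flux_ratio(xp) - flux_ratio(xm)) / (2 * h)
}

#' Noise difference between uncoupled and cotranscribed configurations
#'
#' `delta_cv2 = CV2_uncoupled - CV2_cotranscribed` for a species, from the
#' Lyapunov solution of both members of a comparison pair. A positive value
#' means the cotranscribed configuration is the low-noise one.
#'
#' @param pair a [comparison_pair()].
#' @param species species name(s); defaults to the pair's designated readout.
#' @return tibble with `species`, `cv2_uncoupled`, `cv2_cotranscribed`,
#'   `value`, and `predicted_sign` (from [predict_sign()] when the pair
#'   carries a module class).
#' @export
delta_cv2 <- function(pair, species = NULL) {
  species <- species %||% pair$readout
  r_c <- lna_analysis(pair$coupled_system)
  r_u <- lna_analysis(pair$uncoupled_system)
  stopifnot(all(species %in% names(r_c$cv2)), all(species %in% names(r_u$cv2)))
  pred <- if (!is.null(pair$module_class))
    vapply(species, function(sp)
      predict_sign(pair$module_class, sp), character(1))
  else rep(NA_character_, length(species))
  tibble::tibble(species = species,
                 cv2_uncoupled = unname(r_u$cv2[species]),
                 cv2_cotranscribed = unname(r_c$cv2[species]),
                 value = unname(r_u$cv2[species] - r_c$cv2[species]),
                 predicted_sign = unname(pred))
}

#' Predicted sign of the cotranscribed-vs-uncoupled noise difference
#'
#' Encodes the per-module sign table for
#' `delta_cv2 = CV2_uncoupled - CV2_cotranscribed`: positive means the
#' cotranscribed configuration has lower noise, negative means the uncoupled
#' one does, and `small_either` marks species whose difference is small and
#' parameter-dependent (linear-pathway product; modified protein in the
#' covalent module).
#'
#' @param cls module class (see [module_classes]).
#' @param species_role species name within the built module (`"I"`, `"P"`,
#'   `"s"`, `"A"`, `"B"`, `"AB"`, `"Astar"`).
#' @return `"positive"`, `"negative"`, or `"small_either"`.
#' @export
predict_sign <- function(cls, species_role) {
  cls <- match.arg(cls, module_classes())
  key <- paste(cls, species_role, sep = ".")
  tab <- c(
    linear_pathway.I = "positive",
    linear_pathway.P = "small_either",
    redundant_enzymes.P = "negative",
    branch_point.s = "negative",
    dual_regulators_or.P = "negative",
    physical_interaction.A = "positive",
    physical_interaction.B = "positive",
    physical_interaction.AB = "negative",
    covalent_modification.A = "positive",
    covalent_modification.Astar = "small_either"
  )
  if (!key %in% names(tab)) stop("no sign prediction for ", key)
  unname(tab[key])
}
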