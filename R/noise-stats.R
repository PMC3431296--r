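# Ensemble statistics at stationarity: mean, CV, covariance, correlation,
# degree of decorrelation, time cross-correlation, bootstrap error bars.
#
# Estimator: each trajectory contributes its time-averaged first and second
# moments over the stationary window (one statistic sample per trajectory, so
# samples are independent across trajectories); second moments are centered
# on the ensemble grand mean, which keeps the variance estimate unbiased even
# when the window is short relative to the autocorrelation time. Bootstrap
# SDs come from resampling trajectories with replacement.

ensemble_moments <- function(ensemble) {
  nsp <- length(ensemble$species)
  n <- length(ensemble$trajectories)
  M1 <- matrix(0, n, nsp)
  M2 <- matrix(0, n, nsp * nsp)
  M3 <- matrix(0, n, nsp) # raw third moments, for the skew guard
  for (i in seq_len(n)) {
    m <- ensemble$trajectories[[i]]
    nt <- nrow(m)
    M1[i, ] <- colMeans(m)
    M2[i, ] <- as.vector(crossprod(m) / nt)
    M3[i, ] <- colMeans(m^3)
  }
  list(M1 = M1, M2 = M2, M3 = M3, nsp = nsp, n = n)
}

moment_stats <- function(mom, w) {
  mu <- colMeans(mom$M1[w, , drop = FALSE])
  S2 <- matrix(colMeans(mom$M2[w, , drop = FALSE]), mom$nsp, mom$nsp)
  Sigma <- S2 - outer(mu, mu)
  m3 <- colMeans(mom$M3[w, , drop = FALSE])
  v <- pmax(diag(Sigma), 0)
  skew <- ifelse(v > 0, (m3 - 3 * mu * v - mu^3) / v^1.5, 0)
  list(mu = mu, Sigma = Sigma, skew = skew)
}

#' Summarize a stationary ensemble
#'
#' Per-species mean, variance, CV and CV^2, pairwise covariances, Pearson
#' correlations and normalized covariances `eta`, each with a bootstrap SD
#' from resampling trajectories with replacement. Species whose stationary
#' distribution is strongly skewed (|skewness| > 2) are flagged, since CV
#' estimates are then unstable.
#'
#' @param ensemble an [simulate_ensemble()] result.
#' @param burn_in burn-in fraction handed to [stationary_window()]; use 0 if
#'   the ensemble is already windowed.
#' @param n_boot bootstrap resamples (default 1000).
#' @return an object of class `ensemble_summary`: list with tibbles
#'   `species` and `pairs`, plus `n_trajectories`.
#' @export
summarize_ensemble <- function(ensemble, burn_in = 0, n_boot = 1000) {
  if (burn_in > 0) ensemble <- stationary_window(ensemble, burn_in)
  mom <- ensemble_moments(ensemble)
  n <- mom$n
  est <- moment_stats(mom, seq_len(n))
  boot <- lapply(seq_len(n_boot), function(b)
    moment_stats(mom, sample.int(n, n, replace = TRUE)))
  sd_over <- function(f) {
    vals <- vapply(boot, f, numeric(length(f(est))))
    if (is.null(dim(vals))) stats::sd(vals) else apply(vals, 1, stats::sd)
  }
  nm <- ensemble$species
  v <- pmax(diag(est$Sigma), 0)
  cv <- ifelse(est$mu > 0, sqrt(v) / est$mu, NA_real_)
  sp <- tibble::tibble(
    species = nm, mean = est$mu, variance = v, cv = cv, cv2 = cv^2,
    skewness = est$skew, skewed = abs(est$skew) > 2,
    sd_mean = sd_over(function(s) s$mu),
    sd_cv = sd_over(function(s) {
      vv <- pmax(diag(s$Sigma), 0)
      ifelse(s$mu > 0, sqrt(vv) / s$mu, NA_real_)
    }),
    sd_cv2 = sd_over(function(s) {
      vv <- pmax(diag(s$Sigma), 0)
      ifelse(s$mu > 0, vv / s$mu^2, NA_real_)
    }))
  if (length(nm) < 2) {
    return(structure(list(species = sp,
                          pairs = tibble::tibble(species_a = character(),
                                                 species_b = character(),
                                                 covariance = numeric(),
                                                 r = numeric(),
                                                 eta = numeric(),
                                                 sd_covariance = numeric(),
                                                 sd_r = numeric(),
                                                 sd_eta = numeric()),
                          n_trajectories = n),
                     class = "ensemble_summary"))
  }
  pr <- utils::combn(seq_along(nm), 2)
  pair_stat <- function(s) {
    cov <- s$Sigma[cbind(pr[1, ], pr[2, ])]
    va <- pmax(diag(s$Sigma), 0)
    r <- cov / sqrt(va[pr[1, ]] * va[pr[2, ]])
    eta <- cov / (s$mu[pr[1, ]] * s$mu[pr[2, ]])
    c(cov, r, eta)
  }
  np <- ncol(pr)
  pest <- pair_stat(est)
  pboot <- vapply(boot, pair_stat, numeric(3 * np))
  psd <- if (np == 1) apply(matrix(pboot, nrow = 3), 1, stats::sd) else
    apply(pboot, 1, stats::sd)
  pairs <- tibble::tibble(
    species_a = nm[pr[1, ]], species_b = nm[pr[2, ]],
    covariance = pest[seq_len(np)],
    r = pest[np + seq_len(np)],
    eta = pest[2 * np + seq_len(np)],
    sd_covariance = psd[seq_len(np)],
    sd_r = psd[np + seq_len(np)],
    sd_eta = psd[2 * np + seq_len(np)])
  structure(list(species = sp, pairs = pairs, n_trajectories = n),
            class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat("<ensemble_summary> over", x$n_trajectories, "trajectories\n")
  print(x$species)
  invisible(x)
}

#' @method tidy ensemble_summary
#' @export
tidy.ensemble_summary <- function(x, ...) x$species

#' @method glance ensemble_summary
#' @export
glance.ensemble_summary <- function(x, ...)
  tibble::tibble(n_trajectories = x$n_trajectories,
                 n_species = nrow(x$species),
                 any_skewed = any(x$species$skewed))

#' Degree of decorrelation between two species
#'
#' `1 - r(A, B)`: 0 for perfectly correlated partners, ~1 for independent
#' ones, up to 2 for perfect anticorrelation. This is the package's stand-in
#' measure for the loss of correlation between uncoupled gene products.
#'
#' @param summary an [summarize_ensemble()] result.
#' @param pair character vector of two species names (default A, B).
#' @return list with `value` and its bootstrap `sd`.
#' @export
decorrelation_degree <- function(summary, pair = c("A", "B")) {
  row <- dplyr::filter(summary$pairs,
                       (.data$species_a == pair[1] & .data$species_b == pair[2]) |
                       (.data$species_a == pair[2] & .data$species_b == pair[1]))
  if (nrow(row) != 1) stop("pair not found in summary")
  if (!is.finite(row$r)) return(list(value = NA_real_, sd = NA_real_,
                                     flagged = TRUE))
  list(value = 1 - row$r, sd = row$sd_r, flagged = FALSE)
}

#' Ensemble-averaged time cross-correlation between two species
#'
#' Normalized cross-covariance
#' `C_ab(tau) = <(a(t) - mu_a)(b(t + tau) - mu_b)> / (sigma_a sigma_b)`
#' pooled over trajectories and window times, with the standard error of the
#' mean across trajectories. At lag 0 this equals the pooled Pearson r.
#'
#' @param ensemble a (windowed) ensemble.
#' @param species_a,species_b species names.
#' @param lags lag grid in seconds; must be representable on the sampling
#'   grid and within the trajectory span.
#' @return tibble of class `cross_correlation`: `lag`, `value`, `sem`.
#' @export
cross_correlation <- function(ensemble, species_a, species_b, lags = 0) {
  ia <- match(species_a, ensemble$species)
  ib <- match(species_b, ensemble$species)
  stopifnot(!is.na(ia), !is.na(ib))
  dt <- diff(ensemble$times)
  stopifnot(max(abs(dt - dt[1])) < 1e-9 * dt[1]) # uniform grid required
  dt <- dt[1]
  nt <- length(ensemble$times)
  offs <- round(lags / dt)
  if (any(abs(offs) >= nt)) stop("lag exceeds trajectory span")
  if (any(abs(offs * dt - lags) > 1e-6 * max(dt, 1)))
    stop("lags must be multiples of the sampling interval (", dt, " s)")
  mats <- ensemble$trajectories
  mu_a <- mean(vapply(mats, function(m) mean(m[, ia]), numeric(1)))
  mu_b <- mean(vapply(mats, function(m) mean(m[, ib]), numeric(1)))
  v_a <- mean(vapply(mats, function(m) mean((m[, ia] - mu_a)^2), numeric(1)))
  v_b <- mean(vapply(mats, function(m) mean((m[, ib] - mu_b)^2), numeric(1)))
  norm <- sqrt(v_a * v_b)
  out <- purrr::map_dfr(seq_along(offs), function(q) {
    k <- offs[q]
    per <- vapply(mats, function(m) {
      if (k >= 0) {
        ta <- seq_len(nt - k); tb <- ta + k
      } else {
        tb <- seq_len(nt + k); ta <- tb - k
      }
      mean((m[ta, ia] - mu_a) * (m[tb, ib] - mu_b))
    }, numeric(1)) / norm
    tibble::tibble(lag = lags[q], value = mean(per),
                   sem = stats::sd(per) / sqrt(length(per)))
  })
  class(out) <- c("cross_correlation", class(out))
  out
}

#' Write an ensemble summary as CSV
#'
#' One row per species plus one row per pair (long format, `kind` column).
#'
#' @param summary an [summarize_ensemble()] result.
#' @param path output file.
#' @export
write_summary_csv <- function(summary, path) {
  sp <- dplyr::mutate(summary$species, kind = "species")
  pr <- dplyr::mutate(summary$pairs, kind = "pair")
  utils::write.csv(dplyr::bind_rows(sp, pr), path, row.names = FALSE)
  invisible(path)
}
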