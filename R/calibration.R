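#' Observable concentrations from a trajectory
#'
#' The tube NMR experiment resolves four observables by integrating distinct
#' chemical-shift regions: propargyl acetate, allyl acetate, propyl acetate
#' and the catalyst region. These map to the FREE species `3`, `4`, `5` and
#' `1`; catalyst-bound complexes are not added into the integrals (an
#' approximation, since bound cyclooctadiene tracks the precursor).
#'
#' @param trajectory A `phip_trajectory`.
#' @param times Observation times (s); defaults to the trajectory grid.
#'   Values are linearly interpolated and must lie within the trajectory
#'   span.
#' @return Numeric matrix `length(times) x 4` with columns `propargyl`,
#'   `allyl`, `propyl`, `catalyst` (mM).
#' @export
predict_observables <- function(trajectory, times = NULL) {
  if (is.null(times)) times <- trajectory$time
  tr <- range(trajectory$time)
  if (any(times < tr[1] - 1e-9) || any(times > tr[2] + 1e-9)) {
    stop(sprintf("observation times outside trajectory span [%g, %g] s",
                 tr[1], tr[2]))
  }
  map <- c(propargyl = "3", allyl = "4", propyl = "5", catalyst = "1")
  out <- vapply(map, function(sp) {
    stats::approx(trajectory$time, trajectory$conc[, sp], xout = times,
                  rule = 2)$y
  }, numeric(length(times)))
  out <- matrix(out, nrow = length(times),
                dimnames = list(NULL, names(map)))
  out
}

.observable_names <- c("propargyl", "allyl", "propyl", "catalyst")

#' Construct a tube-experiment dataset
#'
#' @param times Observation times, s (non-negative, strictly increasing).
#' @param observables Matrix `length(times) x 4`, columns `propargyl`,
#'   `allyl`, `propyl`, `catalyst`, mM.
#' @param sigma Per-point standard deviations (mM): scalar, length-4 vector
#'   (one per observable), or full matrix. Must be > 0.
#' @param propargyl0,catalyst0 Initial concentrations, mM.
#' @param hydrogen_clamp_mM Dissolved-hydrogen concentration maintained
#'   during the experiment, mM.
#' @return A `phip_dataset`.
#' @export
phip_dataset <- function(times, observables, sigma,
                         propargyl0 = 20, catalyst0 = 5,
                         hydrogen_clamp_mM = 20) {
  times <- as.numeric(times)
  if (any(times < 0) || any(diff(times) <= 0)) {
    stop("times must be non-negative and strictly increasing")
  }
  observables <- as.matrix(observables)
  if (ncol(observables) != 4) stop("observables must have 4 columns")
  colnames(observables) <- .observable_names
  if (!all(is.finite(observables))) stop("observables must be finite")
  if (length(sigma) == 1) sigma <- matrix(sigma, nrow(observables), 4)
  if (is.vector(sigma) && length(sigma) == 4) {
    sigma <- matrix(sigma, nrow(observables), 4, byrow = TRUE)
  }
  sigma <- as.matrix(sigma)
  colnames(sigma) <- .observable_names
  if (any(sigma <= 0) || !all(is.finite(sigma))) stop("sigma must be > 0")
  if (!all(dim(sigma) == dim(observables))) stop("sigma dimension mismatch")
  structure(
    list(times = times, observables = observables, sigma = sigma,
         initial = list(propargyl0 = propargyl0, catalyst0 = catalyst0,
                        hydrogen_clamp_mM = hydrogen_clamp_mM)),
    class = "phip_dataset"
  )
}

#' @export
print.phip_dataset <- function(x, ...) {
  cat(sprintf(
    "phip_dataset: %d observations over [%g, %g] s, 4 observables\n",
    length(x$times), min(x$times), max(x$times)))
  cat(sprintf("  initial: propargyl %g mM, catalyst %g mM, H2 clamp %g mM\n",
              x$initial$propargyl0, x$initial$catalyst0,
              x$initial$hydrogen_clamp_mM))
  invisible(x)
}

# model prediction used by the fit: clamped-hydrogen integration at k,
# mapped to the four observables at the dataset times
.predict_dataset <- function(k5vec, data, rtol = 1e-8, atol = 1e-10) {
  ks <- c(k5vec, k6 = 0)
  names(ks) <- paste0("k", 1:6)
  net <- build_network(ks, relaxation_enabled = FALSE,
                       hydrogen_clamp = data$initial$hydrogen_clamp_mM)
  tgrid <- sort(unique(c(0, data$times)))
  init <- phip_state(c("1" = data$initial$catalyst0,
                       "3" = data$initial$propargyl0,
                       "2" = data$initial$hydrogen_clamp_mM))
  traj <- integrate_network(net, init, tgrid, rtol = rtol, atol = atol)
  predict_observables(traj, data$times)
}

# Deterministic multistart candidates for the rate-constant fit. The
# likelihood surface has distinct basins in which different reactions play
# the rate-limiting role (e.g. activation-limited vs binding-limited), so a
# single Levenberg-Marquardt descent can stall in the wrong basin. The
# candidates span three decades per constant: three uniform vectors plus
# one-factor-at-a-time spreads around the centre.
.fit_start_candidates <- function() {
  out <- lapply(c(0.003, 0.03, 0.3), function(b) rep(b, 5))
  for (i in 1:5) {
    for (b in c(0.003, 0.3)) {
      v <- rep(0.03, 5)
      v[i] <- b
      out[[length(out) + 1]] <- v
    }
  }
  out
}

#' Fit the five hydrogenation rate constants to tube data
#'
#' Weighted nonlinear least squares: the clamped-hydrogen kinetic model is
#' integrated at trial constants, mapped to the four observables, and the
#' inverse-variance weighted residual sum of squares is minimised with a
#' bounded Levenberg-Marquardt algorithm. Because the objective has distinct
#' basins (different steps can play the rate-limiting role), the default
#' start is chosen by screening a deterministic grid of candidate constants
#' and descending from the best ones; supplying `initial_guess` disables the
#' multistart and descends from that single point. 95% confidence intervals
#' are linearised (Wald) intervals from the parameter covariance
#' `(J'J)^{-1}` of the sigma-weighted residuals (sigmas treated as known;
#' see `sigma_known`).
#'
#' @param data A `phip_dataset`.
#' @param initial_guess Optional numeric of length 5 (`k1`..`k5`), 1/(mM s);
#'   `NULL` (default) uses the screened multistart.
#' @param lower,upper Box bounds on each constant, default `[0, 10]`.
#' @param max_iter Maximum Levenberg-Marquardt iterations per start.
#' @param n_starts Number of screened candidates descended from (default 2).
#' @param sigma_known When `TRUE` (default) the per-point sigmas are treated
#'   as known measurement errors and the covariance is `(J'J)^{-1}`; when
#'   `FALSE` (sigmas used as relative weights only) it is scaled by the
#'   reduced chi-square `s^2 = WRSS / (n - p)`.
#' @param rtol,atol Integrator tolerances used inside the objective.
#' @return A `phip_fit` with `estimates`, `se`, `ci` (95% Wald), `covariance`,
#'   `wrss`, `niter`, `degenerate` flag and optimiser diagnostics.
#' @export
fit_rate_constants <- function(data, initial_guess = NULL,
                               lower = rep(0, 5), upper = rep(10, 5),
                               max_iter = 200, n_starts = 2,
                               sigma_known = TRUE,
                               rtol = 1e-7, atol = 1e-9) {
  stopifnot(inherits(data, "phip_dataset"))
  if (length(data$times) < 5) stop("need at least 5 time points to fit")
  if (all(data$observables == 0)) {
    stop("all-zero observables: the fit is singular")
  }
  resid_fun <- function(par) {
    pred <- .predict_dataset(par, data, rtol = rtol, atol = atol)
    as.vector((pred - data$observables) / data$sigma)
  }
  if (!is.null(initial_guess)) {
    guess <- unname(as.numeric(initial_guess))
    if (length(guess) != 5) stop("initial_guess must have length 5")
    if (any(guess < lower) || any(guess > upper)) {
      stop("initial guess outside bounds")
    }
    starts <- list(guess)
  } else {
    cands <- .fit_start_candidates()
    cands <- Filter(function(v) all(v >= lower & v <= upper), cands)
    score <- vapply(cands, function(v) sum(resid_fun(v)^2), 0)
    starts <- cands[order(score)[seq_len(min(n_starts, length(cands)))]]
  }
  fit <- NULL
  for (st in starts) {
    f <- minpack.lm::nls.lm(
      par = st, lower = lower, upper = upper, fn = resid_fun,
      # epsfcn matches the integrator accuracy: forward-difference steps of
      # ~1e-3 relative keep the numeric Jacobian above the ODE solution
      # noise, which otherwise hides the weakly identified directions
      control = minpack.lm::nls.lm.control(maxiter = max_iter,
                                           ftol = 1e-12, ptol = 1e-12,
                                           epsfcn = 1e-6)
    )
    if (is.null(fit) || f$deviance < fit$deviance) fit <- f
  }
  est <- stats::setNames(as.numeric(fit$par), paste0("k", 1:5))
  if (fit$info == 5) {
    cond <- structure(
      class = c("phip_nonconvergence", "error", "condition"),
      list(message = paste0(
             "fit did not converge within ", max_iter,
             " iterations; best-so-far estimates: ",
             paste(signif(est, 4), collapse = ", ")),
           call = sys.call(-1), best = est))
    stop(cond)
  }
  n <- length(data$observables)
  p <- 5L
  wrss <- fit$deviance
  s2 <- if (sigma_known) 1 else wrss / (n - p)
  jtj <- as.matrix(fit$hessian)  # J'J of the weighted residuals
  degenerate <- FALSE
  covmat <- tryCatch(s2 * solve(jtj), error = function(e) NULL)
  if (is.null(covmat) || any(!is.finite(covmat))) {
    # a direction with (numerically) no curvature has unbounded variance:
    # floor the singular values so such directions get very wide intervals,
    # and flag the result rather than failing silently
    sv <- svd(jtj)
    dfl <- pmax(sv$d, max(sv$d) * 1e-14)
    covmat <- s2 * (sv$v %*% (t(sv$u) / dfl))
    degenerate <- TRUE
    warning("singular parameter covariance; intervals flagged wide")
  }
  covmat <- (covmat + t(covmat)) / 2
  dimnames(covmat) <- list(names(est), names(est))
  se <- sqrt(pmax(diag(covmat), 0))
  # a constant whose Jacobian column vanished (typically after running to a
  # bound on a flat direction) is unidentified by this dataset: its interval
  # is the whole feasible range, flagged wide
  unidentified <- diag(jtj) <= max(diag(jtj)) * 1e-10
  if (any(unidentified)) degenerate <- TRUE
  out <- structure(
    list(estimates = est, se = se, covariance = covmat,
         wrss = wrss, s2 = s2, niter = fit$niter, info = fit$info,
         message = fit$message, degenerate = degenerate,
         unidentified = stats::setNames(unidentified, names(est)),
         lower = lower, upper = upper,
         n_obs = n, n_par = p),
    class = "phip_fit"
  )
  out$ci <- confidence_intervals(out, 0.95)
  out
}

#' Wald confidence intervals for fitted rate constants
#'
#' Linearised intervals `estimate +/- z * SE` with `z` the two-sided normal
#' quantile for the requested level, with the covariance `(J'J)^{-1}` for
#' known per-point sigmas (the default). A zero covariance yields zero-width
#' intervals which are flagged via the `degenerate` attribute; a constant
#' left unidentified by the data (vanishing Jacobian column, typically after
#' running to a bound on a flat direction) gets the whole feasible range as
#' its interval, also flagged.
#'
#' @param fit A `phip_fit`.
#' @param level Coverage level in (0, 1); default 0.95.
#' @return Data frame with columns `constant`, `estimate`, `lower`, `upper`,
#'   `level`; attribute `degenerate` is `TRUE` when the intervals are not
#'   trustworthy (singular or zero covariance).
#' @export
confidence_intervals <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "phip_fit"), level > 0, level < 1)
  z <- stats::qnorm((1 + level) / 2)
  lo <- fit$estimates - z * fit$se
  hi <- fit$estimates + z * fit$se
  if (!is.null(fit$unidentified) && any(fit$unidentified)) {
    lo[fit$unidentified] <- fit$lower[fit$unidentified]
    hi[fit$unidentified] <- fit$upper[fit$unidentified]
  }
  out <- data.frame(
    constant = names(fit$estimates),
    estimate = as.numeric(fit$estimates),
    lower = as.numeric(lo), upper = as.numeric(hi),
    level = level, stringsAsFactors = FALSE
  )
  degen <- fit$degenerate || all(fit$se == 0)
  attr(out, "degenerate") <- degen
  out
}

#' @export
print.phip_fit <- function(x, ...) {
  cat("phip_fit: weighted nonlinear least squares (Levenberg-Marquardt)\n")
  ci <- x$ci
  for (i in seq_len(nrow(ci))) {
    cat(sprintf("  %s = %.4f  95%% CI (%.4f, %.4f)  [1/(mM s)]\n",
                ci$constant[i], ci$estimate[i], ci$lower[i], ci$upper[i]))
  }
  cat(sprintf("  WRSS %.4g over %d observations, %d iterations\n",
              x$wrss, x$n_obs, x$niter))
  if (x$degenerate) cat("  WARNING: degenerate covariance\n")
  invisible(x)
}

#' Write a dataset as tidy CSV
#'
#' Columns `time_s`, `species`, `concentration_mM`, `sigma_mM`, with species
#' labels `propargyl`, `allyl`, `propyl`, `catalyst`.
#'
#' @param dataset A `phip_dataset`.
#' @param path Output file path.
#' @export
write_dataset_csv <- function(dataset, path) {
  df <- data.frame(
    time_s = rep(dataset$times, times = 4),
    species = rep(.observable_names, each = length(dataset$times)),
    concentration_mM = as.vector(dataset$observables),
    sigma_mM = as.vector(dataset$sigma),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}

#' Read a dataset written by [write_dataset_csv()]
#'
#' @param path CSV file path.
#' @param propargyl0,catalyst0,hydrogen_clamp_mM Initial-condition record
#'   (not stored in the CSV body).
#' @return A `phip_dataset`.
#' @export
read_dataset_csv <- function(path, propargyl0 = 20, catalyst0 = 5,
                             hydrogen_clamp_mM = 20) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "species", "concentration_mM", "sigma_mM")
  if (!all(need %in% names(df))) {
    stop("CSV must have columns: ", paste(need, collapse = ", "))
  }
  times <- sort(unique(df$time_s))
  obs <- sig <- matrix(NA_real_, length(times), 4,
                       dimnames = list(NULL, .observable_names))
  for (sp in .observable_names) {
    sub <- df[df$species == sp, ]
    sub <- sub[order(sub$time_s), ]
    if (nrow(sub) != length(times)) stop("incomplete series for ", sp)
    obs[, sp] <- sub$concentration_mM
    sig[, sp] <- sub$sigma_mM
  }
  phip_dataset(times, obs, sig, propargyl0, catalyst0, hydrogen_clamp_mM)
}

#' Write a fit result as JSON
#'
#' @param fit A `phip_fit`.
#' @param path Output file path.
#' @export
write_fit_json <- function(fit, path) {
  obj <- list(
    estimates = as.list(fit$estimates),
    ci95 = stats::setNames(
      lapply(seq_len(nrow(fit$ci)), function(i)
        c(fit$ci$lower[i], fit$ci$upper[i])),
      fit$ci$constant),
    covariance = unname(as.matrix(fit$covariance)),
    wrss = fit$wrss,
    n_obs = fit$n_obs,
    iterations = fit$niter,
    degenerate = fit$degenerate
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(obj)
}
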