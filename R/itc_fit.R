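# One-site isothermal titration calorimetry: forward model and fitter.
#
# Forward model with perfusion dilution: each injection of volume v
# displaces v from the fixed-volume cell, so pre-existing contents are
# diluted by f = 1 - v/V0 per injection. After injection i the total cell
# concentrations are
#   M_t(i) = M0 * f^i          (macromolecule, never replenished)
#   X_t(i) = X0 * (1 - f^i)    (titrant, approaches syringe concentration)
# The bound complex follows the closed-form single-site equilibrium
#   B = ( X_t + N*M_t + Kd - sqrt((X_t + N*M_t + Kd)^2 - 4*N*M_t*X_t) ) / 2
# (physical root: B <= min(X_t, N*M_t)), and the heat evolved during
# injection i is dH * V0 * (B_i - f * B_{i-1}) -- material swept out of
# the cell leaves at its pre-injection composition and evolves no heat.
# Heats are normalized per mole of injectant (X0 * v), the vendor
# convention, with a fitted constant baseline offset absorbing dilution
# heats.

#' Define an ITC titration protocol
#'
#' Defaults follow a standard small-cell instrument protocol: 200 uL cell,
#' 400 uM syringe, 40 uM cell concentration, 19 injections of 3 uL.
#'
#' @param V0 cell volume in litres.
#' @param M0 initial cell (macromolecule) concentration, molar.
#' @param X0 syringe (titrant) concentration, molar.
#' @param v injection volume in litres.
#' @param n_injections number of injections.
#' @param temperature kelvin (carried for reporting; the model is
#'   temperature-implicit).
#' @return List of class `titration_protocol`.
#' @export
titration_protocol <- function(V0 = 200e-6, M0 = 40e-6, X0 = 400e-6,
                               v = 3e-6, n_injections = 19L,
                               temperature = 298.15) {
  vals <- c(V0 = V0, M0 = M0, X0 = X0, v = v,
            n_injections = n_injections, temperature = temperature)
  if (any(vals <= 0)) stop("all protocol parameters must be positive")
  if (X0 <= M0)
    stop("titrant excess convention requires X0 > M0")
  structure(list(V0 = V0, M0 = M0, X0 = X0, v = v,
                 n_injections = as.integer(n_injections),
                 temperature = temperature), class = "titration_protocol")
}

# total concentrations after each injection under perfusion dilution
.titration_totals <- function(protocol) {
  i <- seq_len(protocol$n_injections)
  f <- 1 - protocol$v / protocol$V0
  list(i = i, f = f,
       Mt = protocol$M0 * f^i,
       Xt = protocol$X0 * (1 - f^i))
}

.bound_conc <- function(Xt, Mt, N, Kd) {
  s <- Xt + N * Mt + Kd
  disc <- s^2 - 4 * N * Mt * Xt
  disc[disc < 0] <- 0
  (s - sqrt(disc)) / 2
}

# noise-free per-injection heats (kcal per mole of injectant)
.model_heats <- function(protocol, N, Kd, dH, q0 = 0) {
  tot <- .titration_totals(protocol)
  B <- .bound_conc(tot$Xt, tot$Mt, N, Kd)
  Bprev <- c(0, B[-length(B)])
  dH * protocol$V0 * (B - tot$f * Bprev) / (protocol$X0 * protocol$v) + q0
}

#' Simulate a one-site titration curve
#'
#' Computes noise-free per-injection heats from the forward model and adds
#' optional Gaussian noise. The random stream is seeded locally and does
#' not disturb the caller's RNG state.
#'
#' @param protocol a [titration_protocol()].
#' @param N stoichiometry (sites per macromolecule).
#' @param Kd dissociation constant, molar (> 0).
#' @param dH binding enthalpy, kcal/mol.
#' @param noise_sd Gaussian noise standard deviation in kcal per mole of
#'   injectant (0 = noise-free).
#' @param seed integer seed used when `noise_sd > 0`.
#' @return data.frame of class `titration_curve` with columns `injection`,
#'   `heat_kcal_per_mol`, `molar_ratio` (cumulative X_t/M_t); the
#'   generating parameters are attached as the `truth` attribute.
#' @export
simulate_titration <- function(protocol = titration_protocol(), N = 1,
                               Kd = 1e-6, dH = -10, noise_sd = 0,
                               seed = 1L) {
  stopifnot(inherits(protocol, "titration_protocol"))
  if (!is.finite(Kd) || Kd <= 0) stop("Kd must be finite and positive")
  if (!is.finite(dH)) stop("dH must be finite")
  if (N <= 0) stop("stoichiometry N must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  q <- .model_heats(protocol, N, Kd, dH)
  if (noise_sd > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    q <- q + stats::rnorm(length(q), 0, noise_sd)
  }
  tot <- .titration_totals(protocol)
  out <- data.frame(injection = tot$i, heat_kcal_per_mol = q,
                    molar_ratio = tot$Xt / tot$Mt)
  attr(out, "truth") <- list(N = N, Kd = Kd, dH = dH, noise_sd = noise_sd,
                             seed = seed)
  class(out) <- c("titration_curve", "data.frame")
  out
}

#' Fit a one-site binding model to a titration curve
#'
#' Nonlinear least squares (Levenberg-Marquardt) on the per-injection
#' heats, with Kd positivity enforced by log-parameterization and a fitted
#' constant baseline offset. Default initialization: N = 1, dH = first
#' injection heat, Kd = M0/10; `init_strategy = "grid"` additionally
#' multistarts Kd over `M0 * c(0.001, 0.01, 0.1, 1)` and keeps the best
#' residual sum. Standard errors come from the Jacobian at the optimum
#' (delta method for Kd); non-convergence and singular Jacobians are
#' flagged, never silent. A c-value `N*M0/Kd` below 1 flags the fit
#' `low_c` (the isotherm is too shallow for this protocol; a wider
#' titration range is advisable): in that regime the stoichiometry is not
#' identifiable from the curve, so the fit is automatically repeated with
#' N held at `nominal_n` (the standard low-c practice) and the fixed-N
#' result is reported, flagged `n_fixed`. Pass `fix_n` to force a fixed-N
#' fit from the start.
#'
#' @param curve a `titration_curve` (or data.frame with columns
#'   `injection` and `heat_kcal_per_mol`).
#' @param protocol the [titration_protocol()] that produced the curve.
#' @param init_strategy `"default"` or `"grid"`.
#' @param fix_n `NULL` (free stoichiometry) or a numeric value at which N
#'   is held fixed.
#' @param nominal_n stoichiometry used for the automatic low-c refit.
#' @return List of class `one_site_fit`: `N`, `Kd`, `dH`, `q0`,
#'   standard errors `se` (named), `converged`, `rss`, `c_value`,
#'   `low_c`, `n_fixed`, `fitted`, `residuals`.
#' @export
fit_one_site <- function(curve, protocol = titration_protocol(),
                         init_strategy = c("default", "grid"),
                         fix_n = NULL, nominal_n = 1) {
  init_strategy <- match.arg(init_strategy)
  stopifnot(inherits(protocol, "titration_protocol"))
  q <- curve$heat_kcal_per_mol
  if (length(q) < 6L)
    stop("at least 6 injections are required for a one-site fit")
  if (length(q) != protocol$n_injections)
    stop("curve has ", length(q), " injections but the protocol specifies ",
         protocol$n_injections)
  if (all(abs(q) < 1e-12))
    stop("no signal: all injection heats are zero")

  kd_inits <- if (init_strategy == "default") protocol$M0 / 10 else
    protocol$M0 * c(0.001, 0.01, 0.1, 1)
  run_fit <- function(n_fixed_at) {
    free_n <- is.null(n_fixed_at)
    resid_fun <- function(par) {
      N <- if (free_n) par[["N"]] else n_fixed_at
      q - .model_heats(protocol, N = N, Kd = exp(par[["logKd"]]),
                       dH = par[["dH"]], q0 = par[["q0"]])
    }
    run1 <- function(kd_init) {
      start <- c(if (free_n) c(N = 1), logKd = log(kd_init), dH = q[1L],
                 q0 = 0)
      minpack.lm::nls.lm(par = start, fn = resid_fun,
                         control = minpack.lm::nls.lm.control(maxiter = 200))
    }
    fits <- lapply(kd_inits, run1)
    rss <- vapply(fits, function(f) sum(f$fvec^2), numeric(1L))
    fits[[which.min(rss)]]
  }
  finish <- function(fit, n_fixed_at) {
    par <- fit$par
    free_n <- is.null(n_fixed_at)
    n_par <- length(par)
    dof <- length(q) - n_par
    sigma2 <- sum(fit$fvec^2) / max(dof, 1L)
    se <- rep(NA_real_, n_par)
    singular <- FALSE
    cov <- tryCatch(sigma2 * solve(fit$hessian), error = function(e) NULL)
    if (is.null(cov) || anyNA(diag(cov)) || any(diag(cov) < 0)) {
      singular <- TRUE
    } else {
      se <- sqrt(diag(cov))
    }
    names(se) <- names(par)
    Kd <- exp(par[["logKd"]])
    N <- if (free_n) par[["N"]] else n_fixed_at
    se_named <- c(N = if (free_n) se[["N"]] else NA_real_,
                  Kd = Kd * se[["logKd"]],  # delta method for log-scale
                  dH = se[["dH"]], q0 = se[["q0"]])
    c_value <- N * protocol$M0 / Kd
    structure(list(
      N = N, Kd = Kd, dH = par[["dH"]], q0 = par[["q0"]],
      se = se_named, converged = fit$info %in% 1:3,
      singular_jacobian = singular,
      rss = sum(fit$fvec^2), c_value = c_value, low_c = c_value < 1,
      n_fixed = !free_n,
      fitted = q - fit$fvec, residuals = fit$fvec),
      class = "one_site_fit")
  }
  out <- finish(run_fit(fix_n), fix_n)
  if (is.null(fix_n) && out$low_c) {
    # shallow isotherm: N is unidentifiable, repeat with fixed stoichiometry
    out <- finish(run_fit(nominal_n), nominal_n)
    out$low_c <- TRUE
  }
  out
}

#' @export
print.one_site_fit <- function(x, ...) {
  cat(sprintf(
    "<one_site_fit> N = %.3f, Kd = %.3g M (%.2f uM), dH = %.2f kcal/mol%s\n",
    x$N, x$Kd, x$Kd * 1e6, x$dH,
    if (!x$converged) " [NOT CONVERGED]" else if (x$low_c) " [low-c]" else ""))
  invisible(x)
}

#' Write / read a titration curve as TSV
#'
#' @param curve a `titration_curve`.
#' @param path TSV path.
#' @return `path` (write) or a `titration_curve` (read).
#' @export
write_titration <- function(curve, path) {
  utils::write.table(curve, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_titration
#' @export
read_titration <- function(path) {
  out <- utils::read.delim(path)
  class(out) <- c("titration_curve", "data.frame")
  out
}
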