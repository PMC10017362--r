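# Kinetic and quantitative characterization: initial rates from quenched
# time courses, Michaelis-Menten fitting by nonlinear least squares,
# product quantification with cyclization/hydrolysis (C/H) ratios, and
# pH/temperature optimum profiling.

#' Estimate an initial rate from a quenched time course
#'
#' Fits an ordinary least-squares line (free intercept) through the samples
#' whose conversion does not exceed \code{max_conversion} of the substrate.
#' The early-linear window stands in for the usual eyeballed linear range
#' of quench-sampled progress curves.
#'
#' @param time Sampling times in seconds (strictly increasing).
#' @param product Product quantity at each time, in the same concentration
#'   unit as \code{substrate_conc} (typically uM).
#' @param substrate_conc Initial substrate concentration (uM).
#' @param max_conversion Conversion cutoff as a fraction (default 0.15).
#' @return A list of class \code{"initial_rate"}: \code{rate} (slope, conc
#'   unit per second), \code{intercept}, \code{r_squared}, \code{n_used},
#'   \code{points_used} (logical), \code{conversion}.
#' @export
estimate_initial_rate <- function(time, product, substrate_conc,
                                  max_conversion = 0.15) {
  stopifnot(length(time) == length(product), substrate_conc > 0,
            all(product >= 0))
  if (is.unsorted(time, strictly = TRUE))
    stop("times must be strictly increasing", call. = FALSE)
  conv <- product / substrate_conc
  use <- conv <= max_conversion
  if (sum(use) < 3L)
    stop("fewer than 3 samples at or below ", max_conversion * 100,
         "% conversion (conversions: ",
         paste(sprintf("%.3f", conv), collapse = ", "), ")", call. = FALSE)
  fit <- stats::lm(product[use] ~ time[use])
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((product[use] - mean(product[use]))^2)
  structure(list(
    rate = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
    n_used = sum(use), points_used = use, conversion = conv),
    class = "initial_rate")
}

#' Fit Michaelis-Menten kinetics by nonlinear least squares
#'
#' Fits \code{v = Vmax * S / (KM + S)} directly (no Lineweaver-Burk or
#' other linearization) with \code{Vmax0 = 1.1 * max(rate)} and
#' \code{KM0 = median(S)} as starting values. Non-convergence is reported
#' as a structured failure (\code{converged = FALSE} with the final
#' residuals), never silently.
#'
#' @param substrate_uM Substrate concentrations in uM (>= 4 distinct
#'   values).
#' @param rate_uM_per_s Initial rates in uM/s.
#' @param enzyme_conc Total enzyme concentration in molar (e.g.
#'   \code{10e-9} for 10 nM).
#' @return An object of class \code{"kinetic_fit"}: \code{vmax} (uM/s),
#'   \code{km} (uM), \code{kcat} (1/s), \code{kcat_over_km} (1/M/s),
#'   \code{standard_errors}, \code{residuals}, \code{n_points},
#'   \code{converged}, \code{message}.
#' @examples
#' s <- c(1, 2, 5, 10, 20, 40, 70, 100)
#' v <- 16.52 * 0.01 * s / (31.89 + s)  # 10 nM enzyme = 0.01 uM
#' fit_michaelis_menten(s, v, 10e-9)
#' @export
fit_michaelis_menten <- function(substrate_uM, rate_uM_per_s, enzyme_conc) {
  stopifnot(length(substrate_uM) == length(rate_uM_per_s),
            all(substrate_uM > 0), enzyme_conc > 0)
  if (length(unique(substrate_uM)) < 4L)
    stop("need at least 4 distinct substrate concentrations", call. = FALSE)
  e0_uM <- enzyme_conc * 1e6
  # normalize rates to max 1 so convergence tolerances are scale-free and
  # the fit is exactly scale-equivariant; Vmax is rescaled afterwards
  vscale <- max(rate_uM_per_s)
  if (vscale <= 0) stop("all rates are zero", call. = FALSE)
  df <- data.frame(S = substrate_uM, v = rate_uM_per_s / vscale)
  start <- list(Vmax = 1.1 * max(df$v), KM = stats::median(df$S))
  # "port" copes with the zero-residual (noiseless) case and enforces
  # positivity; abs.tol 1e-10 is the residual-norm convergence tolerance
  # (on the normalized scale)
  fit <- tryCatch(
    stats::nls(v ~ Vmax * S / (KM + S), data = df, start = start,
               algorithm = "port", lower = c(Vmax = 0, KM = 0),
               control = list(maxiter = 200, abs.tol = 1e-10)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    pred <- start$Vmax * df$S / (start$KM + df$S)
    return(structure(list(
      vmax = NA_real_, km = NA_real_, kcat = NA_real_,
      kcat_over_km = NA_real_, standard_errors = c(Vmax = NA, KM = NA),
      residuals = (df$v - pred) * vscale, n_points = nrow(df),
      converged = FALSE,
      message = conditionMessage(fit)), class = "kinetic_fit"))
  }
  co <- stats::coef(fit)
  se <- summary(fit)$coefficients[, "Std. Error"]
  se[["Vmax"]] <- se[["Vmax"]] * vscale
  vmax <- unname(co[["Vmax"]]) * vscale; km <- unname(co[["KM"]])
  # a KM driven to the boundary (or with a non-finite SE) means the design
  # does not identify it (e.g. saturation-only data); report as failure
  if (km <= 0 || vmax <= 0 || !all(is.finite(se)))
    return(structure(list(
      vmax = vmax, km = km, kcat = NA_real_, kcat_over_km = NA_real_,
      standard_errors = c(Vmax = unname(se[["Vmax"]]),
                          KM = unname(se[["KM"]])),
      residuals = unname(stats::residuals(fit)) * vscale, n_points = nrow(df),
      converged = FALSE,
      message = "KM not identifiable (boundary or unbounded)"),
      class = "kinetic_fit"))
  kcat <- vmax / e0_uM
  structure(list(
    vmax = vmax, km = km, kcat = kcat,
    kcat_over_km = kcat / (km * 1e-6),
    standard_errors = c(Vmax = unname(se[["Vmax"]]),
                        KM = unname(se[["KM"]])),
    residuals = unname(stats::residuals(fit)) * vscale, n_points = nrow(df),
    converged = TRUE, message = "converged"), class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<kinetic_fit> NOT CONVERGED: ", x$message, "\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf(paste0("<kinetic_fit> kcat = %.4g /s, KM = %.4g uM, ",
                     "kcat/KM = %.6g /M/s (n = %d)\n"),
              x$kcat, x$km, x$kcat_over_km, x$n_points))
  invisible(x)
}

#' Quantify product distribution and the C/H ratio
#'
#' Converts per-species signals (HPLC peak areas) into percentage shares
#' after optional response-factor calibration (signals are divided by
#' their factor; default 1, i.e. equal response). The C/H ratio is
#' cyclized over hydrolyzed percent; when nothing is hydrolyzed it is NA
#' (undefined), and 0 when nothing is cyclized.
#'
#' @param species Species labels.
#' @param signal Non-negative signals (at least one positive).
#' @param role Role per species: \code{"substrate"}, \code{"hydrolysis"}
#'   or \code{"cyclic"}.
#' @param response_factors Optional named vector of response factors per
#'   species.
#' @param condition Optional condition descriptor (e.g. list(pH = 7.5)).
#' @return A list of class \code{"product_quant"}:
#'   \code{percent_hydrolyzed}, \code{percent_cyclized},
#'   \code{percent_remaining}, \code{ch_ratio}, \code{shares} (per-species
#'   percent), \code{condition}.
#' @examples
#' quantify_products(c("GN10-GL", "GN10", "cGN10"), c(55, 19, 26),
#'                   c("substrate", "hydrolysis", "cyclic"))
#' @export
quantify_products <- function(species, signal, role,
                              response_factors = NULL, condition = NULL) {
  stopifnot(length(species) == length(signal),
            length(species) == length(role), all(signal >= 0))
  role <- match.arg(role, c("substrate", "hydrolysis", "cyclic"),
                    several.ok = TRUE)
  if (all(signal == 0)) stop("all signals are zero", call. = FALSE)
  if (!is.null(response_factors)) {
    rf <- response_factors[species]
    rf[is.na(rf)] <- 1
    signal <- signal / rf
  }
  shares <- 100 * signal / sum(signal)
  ph <- sum(shares[role == "hydrolysis"])
  pc <- sum(shares[role == "cyclic"])
  pr <- sum(shares[role == "substrate"])
  structure(list(
    percent_hydrolyzed = ph, percent_cyclized = pc, percent_remaining = pr,
    ch_ratio = if (ph > 0) pc / ph else if (pc > 0) NA_real_ else 0,
    shares = stats::setNames(shares, species), condition = condition),
    class = "product_quant")
}

#' @export
print.product_quant <- function(x, ...) {
  cat(sprintf(paste0("<product_quant> hydrolyzed %.1f%% | cyclized %.1f%% ",
                     "| remaining %.1f%% | C/H = %s\n"),
              x$percent_hydrolyzed, x$percent_cyclized, x$percent_remaining,
              if (is.na(x$ch_ratio)) "undefined"
              else sprintf("%.2f", x$ch_ratio)))
  invisible(x)
}

#' Cyclization yield implied by a C/H ratio
#'
#' Among converted substrate, the cyclized share is
#' \code{r / (1 + r)}; e.g. C/H = 20 corresponds to a 95.2\% cyclization
#' yield.
#'
#' @param ch_ratio C/H ratio (non-negative).
#' @return Cyclization yield in percent of converted substrate.
#' @export
ch_to_yield <- function(ch_ratio) {
  stopifnot(all(ch_ratio >= 0))
  100 * ch_ratio / (1 + ch_ratio)
}

#' Locate the pH/temperature optimum on a measured grid
#'
#' Replicate rates are averaged per (pH, temperature) condition and the
#' optimum is the grid argmax — no surface interpolation. Ties are all
#' reported.
#'
#' @param ph,temperature,rate Vectors of equal length (replicates allowed).
#' @return A list of class \code{"optimum_profile"}: \code{grid} (mean rate
#'   per condition) and \code{optimum} (rows attaining the maximum).
#' @export
profile_optimum <- function(ph, temperature, rate) {
  stopifnot(length(ph) == length(temperature),
            length(ph) == length(rate), length(ph) >= 1L)
  grid <- stats::aggregate(list(mean_rate = rate),
                           by = list(pH = ph, temperature = temperature),
                           FUN = mean)
  grid <- grid[order(grid$pH, grid$temperature), , drop = FALSE]
  rownames(grid) <- NULL
  best <- grid[grid$mean_rate == max(grid$mean_rate), , drop = FALSE]
  structure(list(grid = grid, optimum = best), class = "optimum_profile")
}

#' @export
print.optimum_profile <- function(x, ...) {
  cat("<optimum_profile> ", nrow(x$grid), " conditions; optimum at ",
      paste(sprintf("pH %.1f / %g degC", x$optimum$pH,
                    x$optimum$temperature), collapse = "; "), "\n", sep = "")
  invisible(x)
}
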