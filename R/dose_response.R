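#' Build a titration object from tidy dose-response data
#'
#' Holds one microscale-thermophoresis (MST) titration: normalized
#' fluorescence (Fnorm, in per-mille) measured at a dilution series of
#' cell concentrations, with equal replicate counts at every point. The
#' canonical design is a 16-step 1:1 dilution from 2e7 cells/mL (see
#' [mst_dilution_series()]).
#'
#' @param concentrations Strictly positive concentration values
#'   (cells/mL), one per titration point; stored sorted ascending.
#' @param fnorm Numeric matrix of Fnorm values (rows = titration points in
#'   the order of `concentrations`, columns = replicates), or a vector for
#'   a single replicate.
#' @return An object of class `titration`.
#' @export
titration <- function(concentrations, fnorm) {
  concentrations <- as.numeric(concentrations)
  if (length(concentrations) < 2L) {
    stop("a titration needs at least 2 concentration points", call. = FALSE)
  }
  if (any(!is.finite(concentrations)) || any(concentrations <= 0)) {
    stop("concentrations must be strictly positive and finite", call. = FALSE)
  }
  if (anyDuplicated(concentrations)) {
    stop("concentrations must be distinct", call. = FALSE)
  }
  if (is.vector(fnorm)) fnorm <- matrix(fnorm, ncol = 1L)
  fnorm <- as.matrix(fnorm)
  if (nrow(fnorm) != length(concentrations)) {
    stop("fnorm must have one row per concentration point", call. = FALSE)
  }
  if (any(!is.finite(fnorm))) {
    stop("fnorm values must be finite (equal replicates at every point)",
         call. = FALSE)
  }
  ord <- order(concentrations)
  structure(
    list(concentrations = concentrations[ord],
         fnorm = fnorm[ord, , drop = FALSE]),
    class = "titration"
  )
}

#' 1:1 serial dilution series
#'
#' @param top Starting concentration (default 2e7 cells/mL).
#' @param steps Number of titration points (default 16).
#' @return Numeric vector of concentrations, descending: `top / 2^(0:(steps-1))`.
#' @export
mst_dilution_series <- function(top = 2e7, steps = 16L) {
  stopifnot(top > 0, steps >= 2L)
  top / 2^(seq_len(steps) - 1L)
}

#' Read a tidy titration CSV
#'
#' Expects columns `concentration`, `replicate`, `fnorm`; every
#' concentration must carry the same set of replicates.
#'
#' @param path CSV path.
#' @return A [titration()] object.
#' @export
read_titration <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("concentration", "replicate", "fnorm")
  if (!all(need %in% names(tab))) {
    stop("titration CSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  conc <- sort(unique(tab$concentration))
  reps <- sort(unique(tab$replicate))
  m <- matrix(NA_real_, nrow = length(conc), ncol = length(reps))
  for (j in seq_along(reps)) {
    sub <- tab[tab$replicate == reps[j], ]
    m[match(sub$concentration, conc), j] <- sub$fnorm
  }
  titration(conc, m)
}

#' Baseline-subtracted Fnorm transform
#'
#' Transforms per-point Fnorm means to delta-Fnorm (per-mille) by
#' subtracting the baseline Fnorm from all points of the same curve,
#' correcting for baseline differences between curves. The baseline
#' defaults to the lowest-concentration titration point; an explicit
#' `baseline_index` (into the ascending concentration order) supports
#' designs with a dedicated zero-target well instead.
#'
#' delta-Fnorm is invariant to adding any constant to all Fnorm values,
#' and is exactly 0 at the baseline point by construction.
#'
#' @param titr A [titration()] object.
#' @param baseline_index Index of the baseline point (default 1, the
#'   lowest concentration).
#' @return data.frame with columns `concentration`, `fnorm_mean`,
#'   `fnorm_sd`, `delta_fnorm`.
#' @export
delta_fnorm <- function(titr, baseline_index = 1L) {
  stopifnot(inherits(titr, "titration"),
            baseline_index >= 1L,
            baseline_index <= length(titr$concentrations))
  mean_f <- rowMeans(titr$fnorm)
  sd_f <- apply(titr$fnorm, 1L, stats::sd)
  baseline <- mean_f[baseline_index]
  data.frame(
    concentration = titr$concentrations,
    fnorm_mean = mean_f,
    fnorm_sd = sd_f,
    delta_fnorm = mean_f - baseline
  )
}

#' Fit a saturation dose-response curve
#'
#' Least-squares fit of the one-site saturation model to
#' baseline-subtracted MST data. Because the data are baseline-subtracted
#' (see [delta_fnorm()]), the fitted curve is subtracted at the baseline
#' concentration as well, so model and transform agree:
#' `delta_fnorm = A * (c/(m+c) - cb/(m+cb))` with `cb` the baseline
#' point's concentration. `A` is the response amplitude (per-mille,
#' relative to zero concentration; may be negative — the sign of a
#' thermophoresis response is assay-dependent) and `m` is the
#' concentration at half-maximal response. For whole-cell titrations the
#' target's molar concentration is unknown, so `m` is reported as a
#' response midpoint in concentration units, never as an equilibrium
#' dissociation constant.
#'
#' The fit is initialized from the data (amplitude from the largest
#' absolute response, midpoint from the concentration nearest
#' half-response, refined over a log-spaced midpoint grid) and optimized
#' with Levenberg-Marquardt least squares. A flat or non-converging
#' response yields a flagged result (`converged = FALSE`, amplitude and
#' midpoint `NA`) with the delta-Fnorm values still returned.
#'
#' @param titr A [titration()] object.
#' @param baseline_index Passed to [delta_fnorm()].
#' @return An object of class `dose_response_curve`: list with `points`
#'   (the [delta_fnorm()] table plus fitted values), `amplitude`,
#'   `midpoint`, `signal_to_noise` (|amplitude| / residual SD),
#'   `residual_sd`, `converged`.
#' @export
fit_saturation <- function(titr, baseline_index = 1L) {
  stopifnot(inherits(titr, "titration"))
  pts <- delta_fnorm(titr, baseline_index)
  if (nrow(pts) < 4L) {
    stop("saturation fit needs at least 4 titration points", call. = FALSE)
  }
  out <- list(points = pts, amplitude = NA_real_, midpoint = NA_real_,
              signal_to_noise = NA_real_, residual_sd = NA_real_,
              converged = FALSE)
  class(out) <- "dose_response_curve"

  y <- pts$delta_fnorm
  conc <- pts$concentration
  if (all(abs(y) < sqrt(.Machine$double.eps))) {
    out$points$fitted <- rep(0, length(y))
    out$residual_sd <- 0
    return(out)  # flat curve: flagged non-binding result
  }

  cb <- conc[baseline_index]
  a0 <- y[which.max(abs(y))]
  grid_m <- exp(seq(log(min(conc)), log(max(conc)), length.out = 25L))
  sse <- vapply(grid_m, function(m) {
    x <- conc / (m + conc) - cb / (m + cb)
    a <- sum(x * y) / sum(x * x)  # profiled amplitude, linear in A
    sum((y - a * x)^2)
  }, 0)
  m0 <- grid_m[which.min(sse)]

  fit <- tryCatch(
    minpack.lm::nlsLM(
      delta_fnorm ~ A * (concentration / (m + concentration) - cb / (m + cb)),
      data = cbind(pts, cb = cb), start = list(A = a0, m = m0),
      lower = c(A = -Inf, m = min(conc) * 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL
  )
  if (is.null(fit)) return(out)

  est <- stats::coef(fit)
  resid_sd <- stats::sd(stats::residuals(fit))
  out$amplitude <- unname(est["A"])
  out$midpoint <- unname(est["m"])
  out$residual_sd <- resid_sd
  out$signal_to_noise <- if (is.finite(resid_sd) && resid_sd > 0) {
    abs(out$amplitude) / resid_sd
  } else {
    Inf
  }
  out$points$fitted <- stats::fitted(fit)
  out$converged <- TRUE
  out
}

#' @export
print.dose_response_curve <- function(x, ...) {
  if (x$converged) {
    cat(sprintf(
      "saturation fit: amplitude %.3f permille, midpoint %.4g, S/N %.2f\n",
      x$amplitude, x$midpoint, x$signal_to_noise))
  } else {
    cat("saturation fit: not converged (flat or ill-conditioned response)\n")
  }
  invisible(x)
}

#' Summarize a dose-response fit as JSON
#'
#' @param curve A `dose_response_curve`.
#' @param path Optional output path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly, when written to a file).
#' @export
dose_response_json <- function(curve, path = NULL) {
  stopifnot(inherits(curve, "dose_response_curve"))
  obj <- list(converged = curve$converged,
              amplitude_permille = curve$amplitude,
              midpoint = curve$midpoint,
              signal_to_noise = curve$signal_to_noise,
              residual_sd = curve$residual_sd,
              n_points = nrow(curve$points))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
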