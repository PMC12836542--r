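# Vehicle normalization and five-parameter log-logistic (5PL) dose-response
# modelling with ED50/GI50 and sensitivity ranking.

#' Exact geometric dose ladder
#'
#' Generates the geometric concentration sequence \code{min, min*fold, ...}
#' up to \code{max}. The ladder must be exact: \code{max} has to equal
#' \code{min * fold^k} for an integer k, otherwise an error lists the nearest
#' valid endpoints. The default reproduces the 5-step, 10-fold ladder from
#' 0.1 to 1000 nM.
#'
#' @param min,max smallest and largest concentration, nM (min > 0).
#' @param fold ratio between consecutive steps (> 1).
#' @return numeric vector of concentrations.
#' @examples
#' dose_ladder(0.1, 1000, 10) # 0.1 1 10 100 1000
#' @export
dose_ladder <- function(min = 0.1, max = 1000, fold = 10) {
  if (min <= 0) stop("min must be > 0")
  if (max < min) stop("max must be >= min")
  if (fold <= 1) stop("fold must be > 1")
  k <- log(max / min) / log(fold)
  kr <- round(k)
  if (abs(k - kr) > 1e-8)
    stop(sprintf(
      "inexact ladder: max is not min * fold^k; nearest valid endpoints are %g or %g",
      min * fold^floor(k), min * fold^ceiling(k)))
  out <- min * fold^(0:kr)
  out[length(out)] <- max  # exact endpoint
  out
}

#' Normalize treated wells to the vehicle-control mean
#'
#' Divides each treated replicate's readout value by the mean of the vehicle
#' (dose 0) technical replicates of the same sample, day and readout. One
#' dose-response point is produced per treated replicate (not pre-averaged),
#' so later fits see the replicate scatter. Vehicle wells never appear as
#' points; they only define the denominator.
#'
#' @param wells per-well, per-day readout data.frame with columns
#'   \code{well_id}, \code{sample_id}, \code{concentration_nM},
#'   \code{replicate}, \code{is_vehicle}, \code{day} and readout columns.
#' @param readout readout column to normalize (default the primary growth
#'   readout, relative total area).
#' @param days days to include (default: all days present).
#' @return data.frame of dose-response points: \code{sample_id}, \code{day},
#'   \code{concentration_nM}, \code{replicate}, \code{readout},
#'   \code{response}. Treated wells with a missing value are skipped (and
#'   reported in attribute \code{"skipped"}).
#' @export
normalize_to_control <- function(wells, readout = "relative_total_area",
                                 days = sort(unique(wells$day))) {
  if (!readout %in% names(wells)) stop("readout column not found: ", readout)
  pts <- list(); skipped <- list()
  for (s in unique(wells$sample_id)) {
    for (d in days) {
      sub <- wells[wells$sample_id == s & wells$day == d, , drop = FALSE]
      if (!nrow(sub)) next
      veh <- sub[[readout]][sub$is_vehicle]
      veh <- veh[!is.na(veh)]
      if (!length(veh) || mean(veh) == 0)
        stop(sprintf("no usable vehicle value for sample %s, day %s", s, d))
      vmean <- mean(veh)
      trt <- sub[!sub$is_vehicle & sub$concentration_nM > 0, , drop = FALSE]
      for (i in seq_len(nrow(trt))) {
        v <- trt[[readout]][i]
        if (is.na(v)) {
          skipped[[length(skipped) + 1L]] <- trt$well_id[i]
          next
        }
        pts[[length(pts) + 1L]] <- data.frame(
          sample_id = s, day = d, concentration_nM = trt$concentration_nM[i],
          replicate = trt$replicate[i], readout = readout,
          response = v / vmean, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(pts)) do.call(rbind, pts) else
    data.frame(sample_id = character(0), day = numeric(0),
               concentration_nM = numeric(0), replicate = integer(0),
               readout = character(0), response = numeric(0))
  attr(out, "skipped") <- unlist(skipped)
  out
}

#' Five-parameter log-logistic function
#'
#' \code{ll5(x) = c + (d - c) / (1 + exp(b * (log(x) - log(e))))^f}: an
#' asymmetric sigmoid in log-dose with slope \code{b}, lower asymptote
#' \code{c}, upper asymptote \code{d}, location \code{e} and asymmetry
#' \code{f}. For \code{b > 0} the response falls from \code{d} (x -> 0)
#' to \code{c} (x -> Inf); \code{f = 1} recovers the symmetric 4-parameter
#' log-logistic.
#'
#' @param x dose(s), > 0.
#' @param b,c,d,e,f model parameters; \code{e > 0}, \code{f > 0}.
#' @return response value(s).
#' @examples
#' ll5(10, b = 1, c = 0, d = 1, e = 10, f = 2) # 0.25
#' @export
ll5 <- function(x, b, c, d, e, f) {
  if (any(x <= 0)) stop("doses must be > 0")
  if (e <= 0) stop("e must be > 0")
  if (f <= 0) stop("f must be > 0")
  c + (d - c) / (1 + exp(b * (log(x) - log(e))))^f
}

# residual function in theta = (b, c, d, log e, log f); f optionally fixed
.ll5_resid <- function(theta, x, y, f_fixed = NULL) {
  f <- if (is.null(f_fixed)) exp(theta[5L]) else f_fixed
  y - ll5(x, theta[1L], theta[2L], theta[3L], exp(theta[4L]), f)
}

#' Fit a five-parameter log-logistic dose-response model
#'
#' Least-squares fit of [ll5()] in log-dose space over per-replicate
#' dose-response points, with deterministic multi-start initialization:
#' the slope sign and magnitude come from a linear regression of response on
#' log dose, the asymptotes from the extreme per-dose mean responses, the
#' location from the dose whose mean response is nearest the midpoint, and a
#' fixed 3x3 grid of (slope, asymmetry) perturbations guards against local
#' minima. No random starts are used, so fits are reproducible.
#'
#' With fewer than 5 distinct concentrations the asymmetry cannot be
#' identified and the model falls back to the symmetric 4-parameter form
#' (f fixed at 1, flagged). The same fallback is applied when the e-f
#' Jacobian block is numerically ill-conditioned. The upper asymptote is not
#' constrained to 1: control-normalized responses may exceed it.
#'
#' @param formula model formula \code{response ~ dose}, evaluated in
#'   \code{data}.
#' @param data data.frame of dose-response points, e.g. from
#'   [normalize_to_control()].
#' @param f_fixed fix the asymmetry at this value (NULL = estimate).
#' @return object of class \code{ll5_fit} with components
#'   \code{coefficients} (b, c, d, e, f), \code{fitted.values},
#'   \code{residuals}, \code{rss}, \code{n_points}, \code{converged},
#'   \code{four_param} (asymmetry held at 1?), \code{data}, \code{call}.
#' @seealso [ed50()], [gi50()], [rank_sensitivity()]
#' @examples
#' x <- rep(dose_ladder(), each = 2)
#' y <- ll5(x, 1, 0.1, 1, 15, 1)
#' fit <- fit_ll5(y ~ x, data.frame(x = x, y = y))
#' coef(fit)
#' @export
fit_ll5 <- function(formula = response ~ concentration_nM, data,
                    f_fixed = NULL) {
  mf <- model.frame(formula, data)
  y <- model.response(mf)
  x <- mf[[2L]]
  if (any(x <= 0)) stop("doses must be > 0 (vehicle wells are not fitted points)")
  if (length(y) < 4L) stop("need at least 4 points to fit")
  if (diff(range(y)) == 0) stop("degenerate fit: all responses identical")
  n_conc <- length(unique(x))
  four_param <- FALSE
  if (is.null(f_fixed) && n_conc < 5L) {
    f_fixed <- 1
    four_param <- TRUE
  }

  dose_means <- tapply(y, x, mean)
  doses_sorted <- sort(unique(x))
  dm <- dose_means[as.character(doses_sorted)]
  c0 <- min(dm); d0 <- max(dm)
  sl <- coef(lm(y ~ log(x)))[2L]
  span <- max(d0 - c0, 1e-6)
  lrange <- diff(range(log(x)))
  b0 <- -sl * 4 / span * (lrange / max(lrange, 1)) # scaled logistic slope guess
  if (!is.finite(b0) || b0 == 0) b0 <- if (sl <= 0) 1 else -1
  e0 <- doses_sorted[which.min(abs(dm - (c0 + d0) / 2))]

  # response orientation: for b > 0 the curve falls with dose, so the upper
  # asymptote is the low-dose end
  if (b0 > 0) { cc <- c0; dd <- d0 } else { cc <- c0; dd <- d0 }

  starts <- list()
  for (bm in c(0.5, 1, 2)) for (fm in c(0.5, 1, 2))
    starts[[length(starts) + 1L]] <- c(b = b0 * bm, c = cc, d = dd,
                                       loge = log(e0), logf = log(fm))
  best <- NULL
  for (st in starts) {
    th <- if (is.null(f_fixed)) st else st[1:4]
    res <- try(minpack.lm::nls.lm(
      par = th, fn = .ll5_resid, x = x, y = y, f_fixed = f_fixed,
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (inherits(res, "try-error")) next
    rss <- sum(res$fvec^2)
    if (is.null(best) || rss < best$rss - 1e-12)
      best <- list(fit = res, rss = rss)
  }
  if (is.null(best)) stop("5PL fit failed from every start")
  fitobj <- best$fit
  converged <- fitobj$info %in% 1:3

  # identifiability guard: ill-conditioned e-f coupling -> symmetric refit
  if (is.null(f_fixed)) {
    J <- fitobj$hessian
    cn <- tryCatch(kappa(J, exact = TRUE), error = function(e) Inf)
    if (!is.finite(cn) || cn > 1e10) {
      refit <- fit_ll5(formula, data, f_fixed = 1)
      refit$f_conditioning <- cn
      refit$call <- match.call()
      return(refit)
    }
  }

  th <- fitobj$par
  cf <- c(b = unname(th[1L]), c = unname(th[2L]), d = unname(th[3L]),
          e = unname(exp(th[4L])),
          f = if (is.null(f_fixed)) unname(exp(th[5L])) else f_fixed)
  fitted <- ll5(x, cf["b"], cf["c"], cf["d"], cf["e"], cf["f"])
  structure(list(coefficients = cf, fitted.values = fitted,
                 residuals = y - fitted, rss = sum((y - fitted)^2),
                 n_points = length(y), n_conc = n_conc,
                 converged = converged,
                 four_param = four_param || !is.null(f_fixed) && f_fixed == 1,
                 f_fixed = f_fixed,
                 data = data.frame(dose = x, response = y),
                 call = match.call()),
            class = "ll5_fit")
}

#' @export
print.ll5_fit <- function(x, digits = 4, ...) {
  cat("Five-parameter log-logistic dose-response fit\n")
  cat("  ", x$n_points, "points at", x$n_conc, "concentrations;",
      if (x$converged) "converged" else "NOT converged",
      if (isTRUE(x$four_param)) "(symmetric 4PL fallback, f = 1)" else "", "\n")
  print(round(coef(x), digits))
  cat("  rss:", format(x$rss, digits = digits),
      " ed50:", format(ed50(x), digits = digits), "nM",
      " gi50:", format(gi50(x), digits = digits), "nM\n")
  invisible(x)
}

#' @export
coef.ll5_fit <- function(object, ...) object$coefficients

#' @export
fitted.ll5_fit <- function(object, ...) object$fitted.values

#' @export
residuals.ll5_fit <- function(object, ...) object$residuals

#' @rdname fit_ll5
#' @param object,x an \code{ll5_fit}.
#' @param newdata optional data.frame with a \code{dose} (or original dose
#'   column) to predict at.
#' @param ... unused.
#' @export
predict.ll5_fit <- function(object, newdata = NULL, ...) {
  cf <- coef(object)
  x <- if (is.null(newdata)) object$data$dose
       else if (is.data.frame(newdata)) newdata[[1L]] else newdata
  ll5(x, cf["b"], cf["c"], cf["d"], cf["e"], cf["f"])
}

#' @export
summary.ll5_fit <- function(object, ...) {
  out <- list(coefficients = coef(object), rss = object$rss,
              sigma = sqrt(object$rss / max(1, object$n_points - 5)),
              n_points = object$n_points, converged = object$converged,
              four_param = object$four_param,
              ed50 = ed50(object), gi50 = gi50(object))
  class(out) <- "summary.ll5_fit"
  out
}

#' @export
print.summary.ll5_fit <- function(x, digits = 4, ...) {
  cat("5PL fit:", x$n_points, "points, rss", format(x$rss, digits = digits),
      ", residual sigma", format(x$sigma, digits = digits), "\n")
  print(round(x$coefficients, digits))
  cat("ED50:", format(x$ed50, digits = digits), "nM;  GI50:",
      format(x$gi50, digits = digits), "nM\n")
  invisible(x)
}

#' @rdname fit_ll5
#' @export
plot.ll5_fit <- function(x, ...) {
  d <- x$data
  plot(d$dose, d$response, log = "x", xlab = "concentration (nM)",
       ylab = "response (fraction of control)", ...)
  xs <- exp(seq(log(min(d$dose)), log(max(d$dose)), length.out = 200))
  lines(xs, predict(x, xs), col = "firebrick", lwd = 2)
  abline(h = 0.5, lty = 3, col = "grey40")
  invisible(x)
}

#' ED50: dose at the midpoint of the fitted span
#'
#' Solves \code{ll5(x) = (c + d) / 2} in closed form:
#' \code{e * (2^(1/f) - 1)^(1/b)}. This is the dose producing 50% of the
#' fitted maximal inhibition (midpoint between the fitted asymptotes), the
#' convention of standard dose-response tooling. Undefined (NA, with a
#' warning) for a flat curve.
#'
#' @param fit an [fit_ll5()] result, or a named coefficient vector with
#'   b, c, d, e, f.
#' @param tol minimal |d - c| span regarded as non-flat.
#' @return dose in nM, or NA if undefined.
#' @export
ed50 <- function(fit, tol = 1e-8) {
  cf <- if (inherits(fit, "ll5_fit")) coef(fit) else fit
  if (abs(cf["d"] - cf["c"]) < tol * max(1, abs(cf["d"]), abs(cf["c"]))) {
    warning("flat curve: ED50 undefined")
    return(NA_real_)
  }
  unname(cf["e"] * (2^(1 / cf["f"]) - 1)^(1 / cf["b"]))
}

#' GI50: dose giving a response of 0.5 relative to control
#'
#' Inverts the fitted model at the absolute response 0.5 (50% growth
#' inhibition relative to vehicle):
#' \code{e * (((d - c)/(0.5 - c))^(1/f) - 1)^(1/b)}. Undefined (NA, flagged
#' rather than an error) when 0.5 lies outside the open span between the
#' fitted asymptotes, i.e. the curve never crosses 50% of control.
#'
#' @inheritParams ed50
#' @return dose in nM, or NA when the curve never reaches 0.5.
#' @export
gi50 <- function(fit) {
  cf <- if (inherits(fit, "ll5_fit")) coef(fit) else fit
  lo <- min(cf["c"], cf["d"]); hi <- max(cf["c"], cf["d"])
  if (!(0.5 > lo && 0.5 < hi)) return(NA_real_)
  R <- (cf["d"] - cf["c"]) / (0.5 - cf["c"])
  unname(cf["e"] * (R^(1 / cf["f"]) - 1)^(1 / cf["b"]))
}

#' Rank samples by drug sensitivity
#'
#' Orders samples by one of three criteria: maximal inhibition
#' \code{1 - c} (descending), ED50 (ascending) or GI50 (ascending).
#' Undefined values rank last. All three criteria are reported side by side
#' so disagreements between them are visible.
#'
#' @param fits named list of [fit_ll5()] objects, one per sample.
#' @param criterion ranking criterion.
#' @return data.frame ordered by the criterion, with columns
#'   \code{sample_id}, \code{max_inhibition}, \code{ed50}, \code{gi50},
#'   \code{rank}.
#' @export
rank_sensitivity <- function(fits, criterion = c("max_inhibition", "ed50", "gi50")) {
  criterion <- match.arg(criterion)
  if (length(fits) < 2L) stop("need >= 2 samples with usable fits")
  tab <- do.call(rbind, lapply(names(fits), function(s) {
    cf <- coef(fits[[s]])
    data.frame(sample_id = s, max_inhibition = unname(1 - cf["c"]),
               ed50 = suppressWarnings(ed50(fits[[s]])),
               gi50 = gi50(fits[[s]]), stringsAsFactors = FALSE)
  }))
  key <- switch(criterion,
                max_inhibition = -tab$max_inhibition,
                ed50 = tab$ed50, gi50 = tab$gi50)
  key[is.na(key)] <- Inf  # undefined ranks last
  tab <- tab[order(key), , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  attr(tab, "criterion") <- criterion
  tab
}
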