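#' Dynamic PET frame schedule
#'
#' @param start_min,end_min frame start/end times in minutes post-injection;
#'   nonoverlapping and increasing; at least 3 frames are needed for fitting.
#' @return object of class `frame_schedule` with frame midpoints in hours.
#' @export
frame_schedule <- function(start_min, end_min) {
  stopifnot(length(start_min) == length(end_min))
  if (length(start_min) < 3) stop("need at least 3 frames", call. = FALSE)
  if (any(end_min <= start_min) ||
      any(diff(start_min) <= 0) ||
      any(start_min[-1] < end_min[-length(end_min)] - 1e-9)) {
    stop("frames must be nonoverlapping and increasing", call. = FALSE)
  }
  structure(list(start_min = start_min, end_min = end_min,
                 mid_h = (start_min + end_min) / 2 / 60,
                 duration_h = (end_min - start_min) / 60,
                 n = length(start_min)),
            class = "frame_schedule")
}

#' Read / write a frame schedule as JSON
#' @param path JSON file with keys `start_min`, `end_min`.
#' @param schedule a [frame_schedule()] (for writing).
#' @return a `frame_schedule` (`write_frame_schedule` returns `path`).
#' @export
read_frame_schedule <- function(path) {
  j <- jsonlite::fromJSON(path)
  frame_schedule(j$start_min, j$end_min)
}

#' @rdname read_frame_schedule
#' @export
write_frame_schedule <- function(schedule, path) {
  jsonlite::write_json(list(start_min = schedule$start_min,
                            end_min = schedule$end_min),
                       path, digits = NA)
  invisible(path)
}

# log-linear initial estimate for A(t) = A0 exp(-l t) from positive samples
.loglin_init <- function(t, a) {
  pos <- a > 0
  if (sum(pos) >= 2) {
    f <- stats::lm.fit(cbind(1, t[pos]), log(a[pos]))
    c(exp(f$coefficients[1]), -f$coefficients[2])
  } else {
    c(max(a), 0.1)
  }
}

#' Fit a mono-exponential time-activity curve
#'
#' Least-squares fit of `A(t) = A0 exp(-lambda_eff t)` via
#' Levenberg-Marquardt ([minpack.lm::nlsLM]) started from a log-linear
#' regression on the positive frames (deterministic; no random starts).
#' The effective decay constant is bounded below at `0.1 * lambda_phy`
#' (i.e. `lambda_bio >= -0.9 lambda_phy`); hitting that bound, or any
#' negative `lambda_bio`, flags tracer accumulation. The cumulated
#' activity is the full time integral `A_tilde = A0 / lambda_eff`, the
#' fitted exponential serving as the tail beyond the last frame.
#'
#' @param times_h frame midpoint times in hours.
#' @param activities frame activities (Bq, or any amount-like unit; the
#'   cumulated activity comes back in unit-hours). Assumed
#'   decay-UNcorrected by default.
#' @param lambda_phy physical decay constant (1/h).
#' @param decay_corrected set `TRUE` if the scanner already removed
#'   physical decay; the curve is then un-corrected before fitting.
#' @return object of class `kinetic_fit`: `A0`, `lambda_eff`, `lambda_bio`,
#'   `cumulated_activity` (= A0/lambda_eff), `rss`, `ok`, `flag`.
#' @export
fit_tac <- function(times_h, activities, lambda_phy,
                    decay_corrected = FALSE) {
  stopifnot(length(times_h) == length(activities))
  if (length(times_h) < 3) stop("need at least 3 frames", call. = FALSE)
  if (any(activities < 0)) stop("activities must be >= 0", call. = FALSE)
  if (lambda_phy <= 0) stop("lambda_phy must be > 0", call. = FALSE)
  mk <- function(A0, lam, rss, ok, flag) {
    structure(list(A0 = A0, lambda_eff = lam, lambda_bio = lam - lambda_phy,
                   cumulated_activity = if (lam > 0) A0 / lam else 0,
                   rss = rss, ok = ok, flag = flag),
              class = "kinetic_fit")
  }
  if (decay_corrected) activities <- activities * exp(-lambda_phy * times_h)
  if (sum(activities > 0) < 2) {
    return(mk(0, lambda_phy, 0, FALSE, "all-zero"))
  }
  init <- .loglin_init(times_h, activities)
  lo <- 0.1 * lambda_phy
  fit <- tryCatch(
    minpack.lm::nlsLM(a ~ A0 * exp(-lam * t),
                      data = data.frame(t = times_h, a = activities),
                      start = list(A0 = max(init[1], 1e-12),
                                   lam = min(max(init[2], lo), 50)),
                      lower = c(0, lo), upper = c(Inf, 1e3),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(mk(init[1], max(init[2], lo), NA_real_, FALSE, "non-convergence"))
  }
  cf <- stats::coef(fit)
  flag <- if (cf["lam"] <= lo * (1 + 1e-6)) "accumulation-bound"
          else if (cf["lam"] < lambda_phy) "negative-lambda-bio"
          else "none"
  mk(unname(cf["A0"]), unname(cf["lam"]),
     sum(stats::residuals(fit)^2), TRUE, flag)
}

# Vectorized Gauss-Newton mono-exponential fit over many curves at once
# (rows = curves). Same model and bounds as fit_tac; used voxelwise where
# one nlsLM call per voxel would dominate the runtime. Consistency with
# fit_tac is covered by tests. lam_hi bounds the decay rate at a value far
# above any physical tracer clearance; rates at the bound mark voxels
# whose counts are too sparse for the model (handled by the caller).
.fit_exp_matrix <- function(Y, t, lam_lo, lam_hi = 50, n_iter = 60,
                            tol = 1e-12) {
  a0 <- pmax(Y[, 1], 1e-300)
  # log-linear init (closed form, unweighted, on values floored at a tiny
  # positive number; negative/zero frames get weight 0)
  W <- (Y > 0) * 1
  L <- log(pmax(Y, 1e-300))
  sw <- rowSums(W); swt <- W %*% t; swt2 <- W %*% t^2
  swl <- rowSums(W * L); swtl <- (W * L) %*% t
  den <- sw * swt2 - swt^2
  slope <- ifelse(den > 0, (sw * swtl - swt * swl) / den, -0.1)
  icpt <- ifelse(sw > 0, (swl - slope * swt) / sw, log(a0))
  lam <- pmin(pmax(-as.vector(slope), lam_lo), lam_hi)
  A0 <- pmin(pmax(exp(as.vector(icpt)), 1e-300), 1e300)
  rss <- function(A0, lam) {
    M <- exp(-outer(lam, t))
    r <- rowSums((Y - A0 * M)^2)
    r[!is.finite(r)] <- Inf
    r
  }
  r_old <- rss(A0, lam)
  for (it in seq_len(n_iter)) {
    M <- exp(-outer(lam, t))      # n x T
    Fv <- A0 * M
    R <- Y - Fv
    # J columns: dF/dA0 = M ; dF/dlam = -A0 t M
    g11 <- rowSums(M * M)
    g12 <- rowSums(M * (-Fv) * rep(t, each = nrow(M)))
    g22 <- rowSums((Fv * rep(t, each = nrow(M)))^2)
    b1 <- rowSums(R * M)
    b2 <- rowSums(R * (-Fv) * rep(t, each = nrow(M)))
    det <- g11 * g22 - g12^2
    det <- ifelse(abs(det) < 1e-300, 1e-300, det)
    dA <- (g22 * b1 - g12 * b2) / det
    dl <- (g11 * b2 - g12 * b1) / det
    dA[!is.finite(dA)] <- 0
    dl[!is.finite(dl)] <- 0
    step <- rep(1, length(A0))
    for (h in 1:8) {
      A0n <- pmax(A0 + step * dA, 0)
      lamn <- pmin(pmax(lam + step * dl, lam_lo), lam_hi)
      r_new <- rss(A0n, lamn)
      worse <- r_new > r_old * (1 + 1e-12)
      if (!any(worse)) break
      step[worse] <- step[worse] / 2
    }
    A0 <- pmax(A0 + step * dA, 0)
    lam <- pmin(pmax(lam + step * dl, lam_lo), lam_hi)
    r_new <- rss(A0, lam)
    delta <- abs(r_old - r_new) / pmax(r_old, 1e-300)
    delta[!is.finite(delta)] <- 0
    if (max(delta) < tol) break
    r_old <- r_new
  }
  list(A0 = A0, lambda_eff = lam, rss = r_old)
}

#' Voxelwise kinetic fitting of a dynamic PET series
#'
#' Applies the mono-exponential model to every voxel inside the mask with
#' a vectorized Gauss-Newton solver (same model, bounds and initialisation
#' as [fit_tac()]). Voxels whose peak value falls below `floor_frac` of the
#' in-mask maximum, and voxels whose fit fails, fall back to trapezoidal
#' integration over the frames plus a physical-decay tail, and are flagged.
#'
#' @param pet4d 4-D array (x, y, z, frame) of activity concentration
#'   (Bq/mL), decay-uncorrected unless `decay_corrected`.
#' @param schedule a [frame_schedule()]; frame count must match.
#' @param lambda_phy physical decay constant (1/h).
#' @param mask logical 3-D array; fits are computed inside it.
#' @param voxel_volume_ml voxel volume used to convert concentration to
#'   per-voxel activity.
#' @param floor_frac peak-fraction floor for attempting a fit.
#' @param decay_corrected as in [fit_tac()].
#' @return list of 3-D arrays `cum_act` (Bq h per voxel), `lambda_bio`
#'   (1/h), `a0` (Bq), integer `flags` (0 fit ok, 1 fallback integrator),
#'   plus `n_fallback`.
#' @export
fit_activity_map <- function(pet4d, schedule, lambda_phy, mask,
                             voxel_volume_ml, floor_frac = 1e-4,
                             decay_corrected = FALSE) {
  stopifnot(inherits(schedule, "frame_schedule"))
  d <- dim(pet4d)
  if (length(d) != 4 || d[4] != schedule$n) {
    stop("pet4d shape does not match the frame schedule", call. = FALSE)
  }
  if (!identical(dim(mask), d[1:3])) {
    stop("mask shape does not match pet4d", call. = FALSE)
  }
  idx <- which(mask)
  if (length(idx) == 0) stop("empty mask", call. = FALSE)
  nv <- prod(d[1:3])
  Y <- matrix(pet4d, nrow = nv)[idx, , drop = FALSE] * voxel_volume_ml
  t <- schedule$mid_h
  if (decay_corrected) Y <- Y * exp(-lambda_phy * rep(t, each = nrow(Y)))
  peak <- apply(Y, 1, max)
  try_fit <- peak >= floor_frac * max(peak) & rowSums(Y > 0) >= 2
  A0 <- numeric(length(idx)); lam <- rep(lambda_phy, length(idx))
  cum <- numeric(length(idx)); flags <- rep(1L, length(idx))
  if (any(try_fit)) {
    f <- .fit_exp_matrix(Y[try_fit, , drop = FALSE], t, 0.1 * lambda_phy)
    # reject fits that extrapolate far beyond the observed curve (sparse
    # spiky count patterns can send the t = 0 intercept astray) or that
    # hit the rate ceiling; those voxels use the fallback integrator
    sane <- is.finite(f$A0) & is.finite(f$lambda_eff) &
      f$A0 <= 10 * peak[try_fit] & f$lambda_eff < 50 * (1 - 1e-9)
    ok <- which(try_fit)[sane]
    A0[ok] <- f$A0[sane]
    lam[ok] <- f$lambda_eff[sane]
    cum[ok] <- ifelse(f$lambda_eff[sane] > 0,
                      f$A0[sane] / f$lambda_eff[sane], 0)
    flags[ok] <- 0L
  }
  fb <- which(flags == 1L & peak > 0)
  if (length(fb)) {
    # trapezoid across frames (from t = 0 holding the first value) plus an
    # exponential physical tail on the last frame value
    tt <- c(0, t)
    for (i in fb) {
      yy <- c(Y[i, 1], Y[i, ])
      cum[i] <- sum(diff(tt) * (yy[-1] + yy[-length(yy)]) / 2) +
        Y[i, schedule$n] / lambda_phy
      A0[i] <- Y[i, 1]
    }
  }
  shape <- d[1:3]
  out <- function(v) { a <- array(0, shape); a[idx] <- v; a }
  list(cum_act = out(cum), lambda_bio = out(lam - lambda_phy),
       a0 = out(A0), flags = out(flags), n_fallback = length(fb))
}

#' Residence time
#'
#' @param cumulated_activity time-integrated activity in Bq h.
#' @param injected_activity injected activity in Bq (> 0).
#' @return residence time in hours.
#' @export
residence_time <- function(cumulated_activity, injected_activity) {
  if (any(injected_activity <= 0)) {
    stop("injected_activity must be > 0", call. = FALSE)
  }
  cumulated_activity / injected_activity
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf(
    "<kinetic_fit>  A0 %.4g, lambda_eff %.4g /h (lambda_bio %.4g /h)\n  cumulated activity %.4g unit-h, rss %.3g, ok %s, flag %s\n",
    x$A0, x$lambda_eff, x$lambda_bio, x$cumulated_activity, x$rss,
    x$ok, x$flag))
  invisible(x)
}
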