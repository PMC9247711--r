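# Landmark-based pupil geometry: eyelid parabola contour, pupil-marker
# validation, direct least-squares ellipse fitting, and diameter/velocity
# time series.

#' Eyelid contour from the four eye markers
#'
#' Constructs two parabolas in a rotated frame whose abscissa is the
#' medial-to-lateral axis: the upper parabola passes through the medial,
#' superior and lateral markers, the lower through the medial, inferior and
#' lateral markers. The region between them is the eye shape. Sanity checks
#' invalidate the frame: the medial marker must be strictly medial of
#' (i.e. distinct from) the lateral marker along the eye axis, the superior
#' marker must lie strictly above the medial-lateral chord and the inferior
#' marker strictly below it (collinear configurations give a zero-height
#' contour and are invalid).
#'
#' @param medial,lateral,superior,inferior numeric `c(x, y)` coordinates.
#' @return an `eye_contour` list: `valid`, rotation `origin` and unit axes,
#'   parabola coefficients `upper` and `lower` (in the rotated frame), and
#'   `reason` when invalid.
#' @export
eye_contour <- function(medial, lateral, superior, inferior) {
  pts <- rbind(medial, lateral, superior, inferior)
  invalid <- function(reason) {
    structure(
      list(
        valid = FALSE, reason = reason, origin = NULL, ex = NULL,
        ey = NULL, upper = NULL, lower = NULL
      ),
      class = "eye_contour"
    )
  }
  if (!all(is.finite(pts))) {
    return(invalid("non-finite eye marker"))
  }
  # coordinate convention: Cartesian, y increasing upward; the medial
  # corner must lie strictly medial (smaller x) of the lateral corner
  if (medial[1] >= lateral[1]) {
    return(invalid("medial eye marker lateral to the lateral eye marker"))
  }
  axis <- lateral - medial
  len <- sqrt(sum(axis^2))
  ex <- axis / len
  ey <- c(-ex[2], ex[1]) # +90 deg rotation of the eye axis (up)
  to_frame <- function(p) {
    d <- p - medial
    c(sum(d * ex), sum(d * ey))
  }
  sup <- to_frame(superior)
  inf <- to_frame(inferior)
  if (sup[2] <= 0) {
    return(invalid("superior marker not above the medial-lateral chord"))
  }
  if (inf[2] >= 0) {
    return(invalid("inferior marker not below the medial-lateral chord"))
  }
  # parabola y = c * x * (x - len) through (0,0), (len,0) and the apex point
  parab <- function(apex) {
    c_coef <- apex[2] / (apex[1] * (apex[1] - len))
    if (!is.finite(c_coef)) {
      return(NULL)
    }
    c_coef
  }
  cu <- parab(sup)
  cl <- parab(inf)
  if (is.null(cu) || is.null(cl)) {
    return(invalid("eyelid apex collinear with the eye corners"))
  }
  structure(
    list(
      valid = TRUE, reason = NULL, origin = medial, ex = ex, ey = ey,
      len = len, upper = cu, lower = cl
    ),
    class = "eye_contour"
  )
}

#' Test whether points lie strictly inside the eye contour
#'
#' A point is inside when it lies strictly between the lower and upper
#' eyelid parabolas; the boundary counts as outside.
#'
#' @param points numeric matrix (n x 2) of `x, y` coordinates.
#' @param contour a valid `eye_contour`.
#' @return logical vector of length n.
#' @export
in_eye_contour <- function(points, contour) {
  stopifnot(contour$valid)
  points <- matrix(points, ncol = 2)
  d <- sweep(points, 2, contour$origin)
  u <- d %*% cbind(contour$ex, contour$ey)
  yu <- contour$upper * u[, 1] * (u[, 1] - contour$len)
  yl <- contour$lower * u[, 1] * (u[, 1] - contour$len)
  u[, 2] < yu & u[, 2] > yl
}

#' Validate pupil markers against the eye contour
#'
#' Discards pupil markers falling outside (or on the boundary of) the eye
#' shape. If the contour itself is invalid, all markers are discarded.
#'
#' @param pupil_markers 8 x 2 matrix of marker coordinates (rows may
#'   contain NA for markers already missing).
#' @param contour an `eye_contour`.
#' @return logical vector: which markers are valid.
#' @export
validate_markers <- function(pupil_markers, contour) {
  pupil_markers <- matrix(pupil_markers, ncol = 2)
  ok <- stats::complete.cases(pupil_markers)
  if (!contour$valid) {
    return(rep(FALSE, nrow(pupil_markers)))
  }
  ok[ok] <- in_eye_contour(pupil_markers[ok, , drop = FALSE], contour)
  ok
}

# conic (A,B,C,D,E,F) -> list(center, semi-axes, rotation deg), NULL if not
# an ellipse
.conic_to_ellipse <- function(v) {
  A <- v[1]
  B <- v[2]
  C <- v[3]
  D <- v[4]
  E <- v[5]
  F_ <- v[6]
  disc <- B^2 - 4 * A * C
  if (!is.finite(disc) || disc >= 0) {
    return(NULL)
  }
  cx <- (2 * C * D - B * E) / disc
  cy <- (2 * A * E - B * D) / disc
  # value of the quadratic form at the center
  Fc <- A * cx^2 + B * cx * cy + C * cy^2 + D * cx + E * cy + F_
  M <- matrix(c(A, B / 2, B / 2, C), 2, 2)
  eg <- eigen(M, symmetric = TRUE)
  ax2 <- -Fc / eg$values
  if (any(ax2 <= 0)) {
    return(NULL)
  }
  semi <- sqrt(ax2)
  ord <- order(semi, decreasing = TRUE)
  major_vec <- eg$vectors[, ord[1]]
  list(
    center = c(cx, cy),
    semi_axes = semi[ord],
    rotation = (atan2(major_vec[2], major_vec[1]) * 180 / pi) %% 180
  )
}

#' Fit an ellipse to valid pupil markers
#'
#' Direct algebraic least-squares conic fit with the ellipse constraint
#' (4AC - B^2 = 1), requiring at least six valid markers; with fewer the
#' fit abstains (`valid = FALSE`). Collinear or otherwise degenerate marker
#' sets also abstain. The reported diameter is the major-axis length.
#'
#' @param markers n x 2 matrix of valid marker coordinates.
#' @return a `pupil_ellipse` list: `valid`, `center`, `semi_axes`
#'   (major, minor), `rotation` (deg), `diameter`, `n_valid_markers`.
#' @export
fit_pupil_ellipse <- function(markers) {
  markers <- matrix(markers, ncol = 2)
  abstain <- function(n) {
    structure(
      list(
        valid = FALSE, center = c(NA_real_, NA_real_),
        semi_axes = c(NA_real_, NA_real_), rotation = NA_real_,
        diameter = NA_real_, n_valid_markers = n
      ),
      class = "pupil_ellipse"
    )
  }
  n <- nrow(markers)
  if (n < 6L) {
    return(abstain(n))
  }
  # center the data for conditioning
  mx <- mean(markers[, 1])
  my <- mean(markers[, 2])
  x <- markers[, 1] - mx
  y <- markers[, 2] - my
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  T_ <- tryCatch(-solve(S3, t(S2)), error = function(e) NULL)
  if (is.null(T_)) {
    return(abstain(n))
  }
  M <- S1 + S2 %*% T_
  # constraint matrix inverse applied: rows (C3, -C2/... ) for 4AC - B^2
  Mc <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  eg <- tryCatch(eigen(Mc), error = function(e) NULL)
  if (is.null(eg)) {
    return(abstain(n))
  }
  evec <- Re(eg$vectors)
  cond <- 4 * evec[1, ] * evec[3, ] - evec[2, ]^2
  ok <- which(cond > 0)
  if (!length(ok)) {
    return(abstain(n))
  }
  a1 <- evec[, ok[1]]
  coefs <- c(a1, as.vector(T_ %*% a1))
  ell <- .conic_to_ellipse(coefs)
  if (is.null(ell)) {
    return(abstain(n))
  }
  structure(
    list(
      valid = TRUE,
      center = ell$center + c(mx, my),
      semi_axes = ell$semi_axes,
      rotation = ell$rotation,
      diameter = 2 * ell$semi_axes[1],
      n_valid_markers = n
    ),
    class = "pupil_ellipse"
  )
}

# split one pupil.csv row into eye points and pupil marker matrix
.parse_pupil_row <- function(row) {
  get_pt <- function(nm) {
    c(row[[paste0(nm, "_x")]], row[[paste0(nm, "_y")]])
  }
  eye <- lapply(
    c("eye_medial", "eye_lateral", "eye_superior", "eye_inferior"), get_pt
  )
  names(eye) <- c("medial", "lateral", "superior", "inferior")
  pup <- t(vapply(paste0("pupil_", 1:8), get_pt, numeric(2)))
  flags <- vapply(
    paste0("pupil_", 1:8, "_valid"),
    function(f) isTRUE(as.logical(row[[f]])), logical(1)
  )
  pup[!flags, ] <- NA_real_
  list(eye = eye, pupil = pup)
}

#' Pupil diameter and eye-velocity time series
#'
#' Processes a per-frame landmark table: builds the eyelid contour, drops
#' pupil markers outside it (all markers when the contour sanity checks
#' fail, e.g. during blinks), fits the ellipse when six or more markers
#' remain, and derives the frame-to-frame eye movement velocity from the
#' ellipse center (missing across invalid gaps).
#'
#' @param frames pupil landmark table as produced by
#'   [simulate_pupil_frames()] or read from `pupil.csv`.
#' @return data.frame per frame: `frame_time`, `diameter`, `center_x`,
#'   `center_y`, `n_valid_markers`, `valid`, `velocity` (px/s; NA on the
#'   first frame and across invalid frames).
#' @export
pupil_timeseries <- function(frames) {
  nfr <- nrow(frames)
  if (nfr < 2L) stop("need at least 2 frames")
  out <- data.frame(
    frame_time = frames$frame_time, diameter = NA_real_,
    center_x = NA_real_, center_y = NA_real_,
    n_valid_markers = 0L, valid = FALSE, velocity = NA_real_
  )
  for (i in seq_len(nfr)) {
    parsed <- .parse_pupil_row(frames[i, ])
    contour <- eye_contour(
      parsed$eye$medial, parsed$eye$lateral,
      parsed$eye$superior, parsed$eye$inferior
    )
    ok <- validate_markers(parsed$pupil, contour)
    out$n_valid_markers[i] <- sum(ok)
    ell <- fit_pupil_ellipse(parsed$pupil[ok, , drop = FALSE])
    if (ell$valid) {
      out$diameter[i] <- ell$diameter
      out$center_x[i] <- ell$center[1]
      out$center_y[i] <- ell$center[2]
      out$valid[i] <- TRUE
    }
  }
  for (i in 2:nfr) {
    if (out$valid[i] && out$valid[i - 1L]) {
      dt <- out$frame_time[i] - out$frame_time[i - 1L]
      out$velocity[i] <- sqrt(
        (out$center_x[i] - out$center_x[i - 1L])^2 +
          (out$center_y[i] - out$center_y[i - 1L])^2
      ) / dt
    }
  }
  if (!any(out$valid)) warning("all frames invalid; empty pupil series")
  out
}
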