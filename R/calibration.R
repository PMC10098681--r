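#' Rigid (or similarity) transform between sensor reference frames
#'
#' Maps points from one sensor's coordinate frame into another's via
#' `x -> s * R x + t`. `scale` defaults to 1 (rigid); a uniform scale is
#' supported for the similarity reading of the calibration.
#'
#' @param rotation 3 x 3 rotation matrix (orthonormal, det +1).
#' @param translation Length-3 translation vector (mm).
#' @param scale Positive uniform scale, default 1.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            scale = 1) {
  rotation <- unname(as.matrix(rotation))
  translation <- as.numeric(translation)
  stopifnot(identical(dim(rotation), c(3L, 3L)), length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rotation is not orthonormal within 1e-9")
  if (abs(det(rotation) - 1) > 1e-9)
    stop("rotation determinant is not +1 within 1e-9")
  if (!is.numeric(scale) || scale <= 0) stop("scale must be positive")
  structure(list(rotation = rotation, translation = translation,
                 scale = as.numeric(scale)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  e <- euler_zyx_deg(x)
  cat(sprintf("<rigid_transform> euler ZYX [%s] deg, t = [%s] mm, s = %g\n",
              paste(signif(e, 5), collapse = ", "),
              paste(signif(x$translation, 5), collapse = ", "), x$scale))
  invisible(x)
}

#' Paired calibration point cloud
#'
#' Holds corresponded measurements of the same physical positions (a
#' stick tip moved through the shared working volume) as seen by sensor
#' A and sensor B. At least three non-collinear pairs are needed to
#' constrain a rotation.
#'
#' @param a,b Numeric n x 3 matrices (mm); row i of `a` and of `b`
#'   measure the same physical point.
#' @return An object of class `calibration_cloud`.
#' @export
calibration_cloud <- function(a, b) {
  a <- unname(as.matrix(a)); b <- unname(as.matrix(b))
  stopifnot(ncol(a) == 3L, ncol(b) == 3L, nrow(a) == nrow(b))
  structure(list(a = a, b = b, n = nrow(a)), class = "calibration_cloud")
}

#' Read / write a calibration cloud as CSV
#'
#' The file format has columns `ax,ay,az,bx,by,bz` in millimetres.
#'
#' @param path CSV file path.
#' @return `read_cloud_csv` returns a [calibration_cloud()];
#'   `write_cloud_csv` returns `path` invisibly.
#' @export
read_cloud_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("ax", "ay", "az", "bx", "by", "bz")
  if (!all(need %in% names(d)))
    stop("calibration cloud CSV must have columns ", paste(need, collapse = ","))
  calibration_cloud(as.matrix(d[, c("ax", "ay", "az")]),
                    as.matrix(d[, c("bx", "by", "bz")]))
}

#' @rdname read_cloud_csv
#' @param cloud A [calibration_cloud()].
#' @export
write_cloud_csv <- function(cloud, path) {
  d <- data.frame(cloud$a, cloud$b)
  names(d) <- c("ax", "ay", "az", "bx", "by", "bz")
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Estimate the rigid transform between two sensors by SVD
#'
#' Least-squares (Kabsch/Umeyama) registration of corresponded point
#' clouds: minimizes `sum_i || s R a_i + t - b_i ||^2`. Centroids are
#' subtracted, the rotation comes from the SVD of the cross-covariance
#' with the determinant sign corrected so the result is a proper
#' rotation (never a reflection), and the optimal uniform scale is
#' computed only when `with_scale = TRUE` (otherwise fixed at 1, the
#' rigid default).
#'
#' @param cloud A [calibration_cloud()] with at least 3 pairs.
#' @param with_scale Estimate a uniform scale (similarity transform)?
#' @return A [rigid_transform()] mapping sensor-A coordinates onto
#'   sensor-B coordinates.
#' @details Degenerate geometry (fewer than 3 pairs, or a centered cloud
#'   whose smallest singular value is below 1e-9 times its largest, as
#'   for collinear sticks) raises an error: such clouds leave a rotation
#'   axis unconstrained or ill-conditioned.
#' @references Umeyama, S. (1991) Least-squares estimation of
#'   transformation parameters between two point patterns. IEEE TPAMI
#'   13(4), 376-380.
#' @export
estimate_rigid_transform <- function(cloud, with_scale = FALSE) {
  stopifnot(inherits(cloud, "calibration_cloud"))
  n <- cloud$n
  if (n < 3L) stop("degenerate geometry: need at least 3 point pairs")
  ca <- colMeans(cloud$a); cb <- colMeans(cloud$b)
  A0 <- sweep(cloud$a, 2L, ca); B0 <- sweep(cloud$b, 2L, cb)
  sv <- svd(A0, nu = 0, nv = 0)$d
  if (sv[3L] < 1e-9 * sv[1L])
    stop("degenerate geometry: calibration cloud is rank-deficient ",
         "(collinear or coplanar stick positions)")
  H <- crossprod(A0, B0) / n          # cross-covariance, maps A-dirs to B-dirs
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  S <- diag(c(1, 1, d))
  R <- s$v %*% S %*% t(s$u)
  scale <- 1
  if (with_scale) {
    var_a <- mean(rowSums(A0^2))
    scale <- sum(s$d * diag(S)) / var_a
  }
  t <- cb - scale * as.numeric(R %*% ca)
  rigid_transform(R, t, scale)
}

#' Root-mean-square registration residual
#'
#' Quality metric for a calibration: RMS of `|| s R a_i + t - b_i ||`
#' over the pairs of a cloud, in millimetres.
#'
#' @param transform A [rigid_transform()].
#' @param cloud A non-empty [calibration_cloud()].
#' @return Non-negative scalar (mm).
#' @export
registration_residual <- function(transform, cloud) {
  stopifnot(inherits(cloud, "calibration_cloud"))
  if (cloud$n < 1L) stop("empty calibration cloud")
  pred <- transform_points(transform, cloud$a)
  sqrt(mean(rowSums((pred - cloud$b)^2)))
}

#' Second calibration step: per-axis bias between the two sensors
#'
#' After the SVD registration, internal differences between the sensors
#' are measured by placing each sensor in turn at identical physical
#' poses; the residual per-axis mean offset is a small axial translation
#' to be folded into the transform (`t <- t + bias`, see
#' [integrate_axial_bias()]).
#'
#' @param transform The step-1 [rigid_transform()].
#' @param cloud Refinement pairs measured with the sensors swapped into
#'   identical physical poses.
#' @return Length-3 numeric vector: per-axis mean of
#'   `b - (s R a + t)` (mm).
#' @export
estimate_axial_bias <- function(transform, cloud) {
  stopifnot(inherits(cloud, "calibration_cloud"))
  if (cloud$n < 1L) stop("empty refinement cloud")
  colMeans(cloud$b - transform_points(transform, cloud$a))
}

#' @rdname estimate_axial_bias
#' @param bias Length-3 axial bias as returned by [estimate_axial_bias()].
#' @return `integrate_axial_bias` returns the refined transform.
#' @export
integrate_axial_bias <- function(transform, bias) {
  transform$translation <- transform$translation + as.numeric(bias)
  transform
}

#' Apply a rigid transform to points, frames or streams
#'
#' Landmark positions are mapped by `s R x + t`; palm normals by the
#' rotation alone (then renormalized). Source tags, timestamps and
#' reliability scores are preserved.
#'
#' @param transform A [rigid_transform()].
#' @param x An n x 3 matrix, a [hand_frame()] or a [session_stream()].
#' @return Object of the same class as `x`, transformed.
#' @export
apply_transform <- function(transform, x) UseMethod("apply_transform", x)

#' @rdname apply_transform
#' @export
transform_points <- function(transform, x) {
  sweep(transform$scale * x %*% t(transform$rotation), 2L,
        transform$translation, `+`)
}

#' @export
apply_transform.default <- function(transform, x) {
  transform_points(transform, as.matrix(x))
}

#' @export
apply_transform.hand_frame <- function(transform, x) {
  lm <- transform_points(transform, x$landmarks)
  dimnames(lm) <- dimnames(x$landmarks)
  x$landmarks <- lm
  pn <- as.numeric(transform$rotation %*% x$palm_normal)
  x$palm_normal <- pn / sqrt(sum(pn^2))
  x
}

#' @export
apply_transform.session_stream <- function(transform, x) {
  x$records <- lapply(x$records, function(rec) {
    rec$models <- lapply(rec$models, function(f) apply_transform(transform, f))
    rec
  })
  x
}

#' Invert and compose rigid transforms
#'
#' `invert_transform(T)` undoes `T`; `compose_transforms(t2, t1)` is the
#' transform applying `t1` first, then `t2`.
#'
#' @param transform,t1,t2 [rigid_transform()] objects.
#' @return A [rigid_transform()].
#' @export
invert_transform <- function(transform) {
  Rt <- t(transform$rotation)
  s <- 1 / transform$scale
  rigid_transform(Rt, -s * as.numeric(Rt %*% transform$translation), s)
}

#' @rdname invert_transform
#' @export
compose_transforms <- function(t2, t1) {
  rigid_transform(
    t2$rotation %*% t1$rotation,
    t2$scale * as.numeric(t2$rotation %*% t1$translation) + t2$translation,
    t2$scale * t1$scale)
}

#' Intrinsic Z-Y-X Euler angles of a transform's rotation
#'
#' Export convention for game-engine-style consumers: intrinsic
#' rotations about Z, then Y, then X, in degrees. The matrix remains the
#' internal truth; angles are derived for interoperability only.
#'
#' @param transform A [rigid_transform()].
#' @return Numeric length-3 vector `c(z, y, x)` in degrees.
#' @export
euler_zyx_deg <- function(transform) {
  R <- transform$rotation
  # R = Rz(z) %*% Ry(y) %*% Rx(x)
  y <- asin(-R[3, 1])
  if (abs(abs(R[3, 1]) - 1) < 1e-12) {        # gimbal lock
    z <- atan2(-R[1, 2], R[2, 2])
    x <- 0
  } else {
    z <- atan2(R[2, 1], R[1, 1])
    x <- atan2(R[3, 2], R[3, 3])
  }
  c(z, y, x) * 180 / pi
}

#' Persist / load a transform as JSON
#'
#' The JSON document stores the rotation as 9 row-major numbers, the
#' translation, the scale, the derived Z-Y-X Euler angles in degrees and
#' (optionally) the registration residual in mm.
#'
#' @param transform A [rigid_transform()].
#' @param path JSON file path.
#' @param residual_mm Optional residual to record alongside.
#' @return `write_transform` returns `path` invisibly; `read_transform`
#'   returns a [rigid_transform()].
#' @export
write_transform <- function(transform, path, residual_mm = NULL) {
  doc <- list(R = as.numeric(t(transform$rotation)),
              t = transform$translation,
              s = transform$scale,
              euler_zyx_deg = euler_zyx_deg(transform))
  if (!is.null(residual_mm)) doc$residual_mm <- residual_mm
  writeLines(.tojson(doc), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  doc <- jsonlite::fromJSON(path)
  rigid_transform(matrix(doc$R, 3, 3, byrow = TRUE), doc$t, doc$s)
}
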