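#' Enumerate the candidate point pairings for the symmetry search
#'
#' The reflection-symmetry search pairs outline reference points by walking
#' clockwise and counterclockwise from a starting location and grouping the
#' next unpaired point on each side. With `L` (even) reference points there
#' are exactly `L` distinct pairings: `L/2` whose start falls between two
#' reference points (giving `L/2` pairs) and `L/2` whose start is itself a
#' reference point (giving `L/2 + 1` pairs, the start point and the point
#' `L/2` positions away being paired with themselves).
#'
#' @param n_points Even number of reference points `L >= 4`.
#' @return List of `L` pairings. Each pairing is a two-column integer matrix
#'   of 0-based point indices (`i == j` marks a self-paired point), with
#'   attribute `"start"` describing the start location.
#' @export
enumerate_pairings <- function(n_points) {
  L <- as.integer(n_points)
  if (L < 4L || L %% 2L != 0L) stop("n_points must be even and >= 4")
  half <- L %/% 2L
  out <- vector("list", L)
  for (k in 0:(half - 1L)) {
    # start between points k and k+1
    m <- seq_len(half)
    p <- cbind(i = (k + m) %% L, j = (k + 1L - m) %% L)
    attr(p, "start") <- sprintf("between points %d,%d", k, (k + 1L) %% L)
    out[[k + 1L]] <- p
    # start at point k
    m2 <- seq_len(half - 1L)
    q <- rbind(c(k, k),
               cbind((k + m2) %% L, (k - m2) %% L),
               c((k + half) %% L, (k + half) %% L))
    colnames(q) <- c("i", "j")
    attr(q, "start") <- sprintf("at point %d", k)
    out[[half + k + 1L]] <- q
  }
  out
}

# reflect points (n x 2 matrix) across the line through the origin at `angle`
reflect_points <- function(pts, angle) {
  c2 <- cos(2 * angle); s2 <- sin(2 * angle)
  cbind(pts[, 1] * c2 + pts[, 2] * s2,
        pts[, 1] * s2 - pts[, 2] * c2)
}

#' Optimal reflection axis for a given pairing
#'
#' Finds the axis through the centroid (the origin, for a normalized outline)
#' that minimizes the mean squared distance between the reference points and
#' their closest mirror-symmetric configuration under the given pairing. The
#' optimum is analytic: writing the objective as
#' `C - (A cos 2t + B sin 2t) / L`, it is minimized at `2t = atan2(B, A)`
#' with value `(sum |p|^2 / 2 - sqrt(A^2 + B^2)) / L`, where cross-paired
#' points contribute `x_i x_j - y_i y_j` to `A` and `x_i y_j + x_j y_i` to
#' `B`, and self-paired points contribute half of `x^2 - y^2` and `x y`.
#'
#' @param points Data frame with `x`, `y`, normalized (see
#'   [normalize_outline()]).
#' @param pairing One pairing from [enumerate_pairings()].
#' @return List with `angle` (radians in `[0, pi)`), `point` (`c(0, 0)`, the
#'   centroid the axis passes through) and `objective` (the minimized mean
#'   squared distance for this pairing).
#' @export
optimal_axis <- function(points, pairing) {
  P <- cbind(points$x, points$y)
  L <- nrow(P)
  self <- pairing[, 1] == pairing[, 2]
  i <- pairing[!self, 1] + 1L; j <- pairing[!self, 2] + 1L
  s <- pairing[self, 1] + 1L
  A <- sum(P[i, 1] * P[j, 1] - P[i, 2] * P[j, 2]) +
    0.5 * sum(P[s, 1]^2 - P[s, 2]^2)
  B <- sum(P[i, 1] * P[j, 2] + P[j, 1] * P[i, 2]) + sum(P[s, 1] * P[s, 2])
  angle <- atan2(B, A) / 2
  angle <- angle %% pi
  obj <- (0.5 * sum(P^2) - sqrt(A^2 + B^2)) / L
  list(angle = angle, point = c(0, 0), objective = max(obj, 0))
}

#' Closest mirror-symmetric configuration under a pairing and axis
#'
#' For each cross-pair `(i, j)` one member is reflected across the axis and
#' averaged with its pair-mate; the partner point is the reflection of that
#' average back across the axis. Self-paired points are projected onto the
#' axis. The resulting point set is exactly mirror-symmetric about the axis
#' and is the closest such configuration (in mean squared distance) under the
#' given pairing. The result does not depend on which pair member is
#' reflected first.
#'
#' @inheritParams optimal_axis
#' @param axis List with `angle` (and optionally `point`), as returned by
#'   [optimal_axis()].
#' @return Tibble with `x`, `y`: the symmetry transform, in input point order.
#' @export
symmetry_transform <- function(points, pairing, axis) {
  P <- cbind(points$x, points$y)
  Q <- matrix(NA_real_, nrow(P), 2L)
  self <- pairing[, 1] == pairing[, 2]
  i <- pairing[!self, 1] + 1L; j <- pairing[!self, 2] + 1L
  s <- pairing[self, 1] + 1L
  if (length(i)) {
    qj <- (reflect_points(P[i, , drop = FALSE], axis$angle) +
             P[j, , drop = FALSE]) / 2
    Q[j, ] <- qj
    Q[i, ] <- reflect_points(qj, axis$angle)
  }
  if (length(s)) {
    u <- c(cos(axis$angle), sin(axis$angle))
    proj <- (P[s, , drop = FALSE] %*% u)
    Q[s, ] <- cbind(proj * u[1], proj * u[2])
  }
  tibble::tibble(x = Q[, 1], y = Q[, 2])
}

msd_between <- function(points, transform) {
  mean((points$x - transform$x)^2 + (points$y - transform$y)^2)
}

csm_evaluate <- function(norm, pairing) {
  axis <- optimal_axis(norm, pairing)
  transform <- symmetry_transform(norm, pairing, axis)
  list(value = msd_between(norm, transform), axis = axis, transform = transform)
}

new_csm_result <- function(value, pairing, axis, transform, points, forced) {
  structure(
    list(csm = value, pairing = pairing, axis = axis, transform = transform,
         points = points, forced = forced),
    class = "csm_result")
}

#' Continuous Symmetry Measure of an outline
#'
#' `csm()` computes the Continuous Symmetry Measure (CSM) of bilateral
#' symmetry: the minimum, over all candidate point pairings (see
#' [enumerate_pairings()]), of the mean squared distance between the
#' normalized outline points and the closest mirror-symmetric configuration.
#' Zero means the outline is perfectly bilaterally symmetric; the measure is
#' dimensionless (coordinates are normalized so the maximum centroid-to-point
#' distance is 1) and invariant to rotation, translation and scale.
#'
#' `csm_forced()` evaluates only the pairing whose symmetry axis is forced
#' through the reference point with the greatest distance from the centroid —
#' for a frond, the putative symmetry axis through the pointy tip. By
#' construction `csm_forced() >= csm()`. Ties in the farthest point are
#' resolved by evaluating every tied candidate and keeping the minimum.
#'
#' @param outline Data frame with `x`, `y` columns and an even number of rows.
#'   Normalization (centroid to origin, max radius 1) is applied internally;
#'   already-normalized outlines pass through unchanged.
#' @return A `csm_result` object: list with elements `csm` (the measure),
#'   `pairing`, `axis` (list with `angle`, `point`), `transform` (tibble, the
#'   closest symmetric polygon) and `points` (the normalized outline).
#' @examples
#' ellipse <- tibble::tibble(
#'   x = 2 * cos(seq(0, 2 * pi, length.out = 9)[-9]),
#'   y = sin(seq(0, 2 * pi, length.out = 9)[-9]))
#' csm(ellipse)$csm            # 0: a sampled ellipse is mirror-symmetric
#' csm_forced(ellipse)$csm
#' @export
csm <- function(outline) {
  norm <- normalize_outline(outline)
  L <- nrow(norm)
  if (L %% 2L != 0L) stop("CSM requires an even number of reference points")
  pairings <- enumerate_pairings(L)
  best <- NULL
  for (p in pairings) {
    ev <- csm_evaluate(norm, p)
    if (is.null(best) || ev$value < best$value) {
      best <- ev
      best$pairing <- p
    }
  }
  new_csm_result(best$value, best$pairing, best$axis, best$transform, norm,
                 forced = FALSE)
}

#' @rdname csm
#' @export
csm_forced <- function(outline) {
  norm <- normalize_outline(outline)
  L <- nrow(norm)
  if (L %% 2L != 0L) stop("CSM requires an even number of reference points")
  half <- L %/% 2L
  r2 <- norm$x^2 + norm$y^2
  far <- which(r2 >= max(r2) - 1e-12) - 1L          # 0-based candidates
  starts <- unique(far %% half)                     # at-point k == at-point k+L/2
  pairings <- enumerate_pairings(L)
  best <- NULL
  for (k in starts) {
    p <- pairings[[half + k + 1L]]                  # the at-point-k pairing
    ev <- csm_evaluate(norm, p)
    if (is.null(best) || ev$value < best$value) {
      best <- ev
      best$pairing <- p
    }
  }
  new_csm_result(best$value, best$pairing, best$axis, best$transform, norm,
                 forced = TRUE)
}

#' @export
print.csm_result <- function(x, ...) {
  cat(sprintf("<csm_result>  %s = %.6g\n",
              if (x$forced) "CSM_forced" else "CSM", x$csm))
  cat(sprintf("  axis angle: %.4f rad (through the centroid)\n", x$axis$angle))
  cat(sprintf("  reference points: %d\n", nrow(x$points)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.csm_result <- function(x, ...) {
  tibble::tibble(
    measure = if (x$forced) "csm_forced" else "csm",
    value = x$csm,
    axis_angle = x$axis$angle,
    n_points = nrow(x$points))
}

#' Plot an outline against its closest bilaterally symmetric shape
#'
#' Draws the observed (normalized) outline, the best symmetry transform and
#' the optimal reflection axis.
#'
#' @param object A `csm_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.csm_result <- function(object, ...) {
  obs <- dplyr::mutate(object$points, which = "observed outline")
  tr <- dplyr::mutate(object$transform, which = "symmetry transform")
  a <- object$axis$angle
  ggplot2::ggplot(rbind(obs, tr), ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_polygon(ggplot2::aes(fill = .data$which,
                                       colour = .data$which),
                          alpha = 0.25, linewidth = 0.4) +
    ggplot2::geom_abline(slope = tan(a), intercept = 0, linetype = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = sprintf("%s = %.4g",
                      if (object$forced) "CSM_forced" else "CSM", object$csm),
      fill = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
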