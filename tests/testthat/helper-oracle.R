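# Independent brute-force oracles used to validate the implementation.
# These deliberately re-derive everything from first principles (explicit
# reflect / average / reflect-back geometry, dense angle grids, literal
# clockwise/counterclockwise pairing walks) and share no code with R/.

# -- random fixtures ----------------------------------------------------------

random_polygon <- function(n, seed = NULL) {
  gen <- function() {
    th <- sort(stats::runif(n, 0, 2 * pi))
    r <- stats::runif(n, 0.3, 1)
    tibble::tibble(x = r * cos(th), y = r * sin(th))
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

rotate_outline <- function(outline, phi) {
  tibble::tibble(
    x = outline$x * cos(phi) - outline$y * sin(phi),
    y = outline$x * sin(phi) + outline$y * cos(phi))
}

# union of random disks, cleaned to a single component: a "fat blob" mask
random_blob_mask <- function(h = 40, w = 40, n_disks = 4, seed = NULL) {
  gen <- function() {
    m <- matrix(FALSE, h, w)
    r0 <- stats::runif(1, h * 0.35, h * 0.65)
    c0 <- stats::runif(1, w * 0.35, w * 0.65)
    for (i in seq_len(n_disks)) {
      rad <- stats::runif(1, 3, 7)
      rc <- r0 + stats::runif(1, -6, 6)
      cc <- c0 + stats::runif(1, -6, 6)
      m <- m | ((row(m) - rc)^2 + (col(m) - cc)^2 <= rad^2)
    }
    m
  }
  m <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  suppressWarnings(clean_mask(m))
}

# -- mask oracles (matrix-shift flood fill, structurally unlike the BFS) ------

shift_up <- function(m) rbind(m[-1, , drop = FALSE], FALSE)
shift_down <- function(m) rbind(FALSE, m[-nrow(m), , drop = FALSE])
shift_left <- function(m) cbind(m[, -1, drop = FALSE], FALSE)
shift_right <- function(m) cbind(FALSE, m[, -ncol(m), drop = FALSE])

grow_region <- function(seed_mask, within) {
  repeat {
    grown <- seed_mask | shift_up(seed_mask) | shift_down(seed_mask) |
      shift_left(seed_mask) | shift_right(seed_mask)
    grown <- grown & within
    if (identical(grown, seed_mask)) return(grown)
    seed_mask <- grown
  }
}

oracle_components <- function(mask) {
  out <- list()
  left <- mask
  while (any(left)) {
    seed <- matrix(FALSE, nrow(mask), ncol(mask))
    seed[which(left)[1]] <- TRUE
    comp <- grow_region(seed, mask)
    out[[length(out) + 1L]] <- comp
    left <- left & !comp
  }
  out
}

# 4-def boundary pixels as 0-based (row, col) pairs, by direct inspection
oracle_boundary_set <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  at <- function(r, c) r >= 1 && r <= h && c >= 1 && c <= w && mask[r, c]
  res <- NULL
  for (r in seq_len(h)) for (c in seq_len(w)) {
    if (!mask[r, c]) next
    if (!at(r - 1, c) || !at(r + 1, c) || !at(r, c - 1) || !at(r, c + 1)) {
      res <- rbind(res, c(r - 1, c - 1))
    }
  }
  res
}

# -- CSM oracle ---------------------------------------------------------------

# literal pairing walk: start between points k,k+1 or at point k; repeatedly
# group the next clockwise and counterclockwise unpaired points
oracle_pairings <- function(L) {
  seen <- character(0)
  out <- list()
  canon <- function(pr) {
    m <- t(apply(pr, 1, sort))
    paste(m[order(m[, 1]), ], collapse = ",")
  }
  add <- function(pr) {
    key <- canon(pr)
    if (!key %in% seen) {
      seen <<- c(seen, key)
      out[[length(out) + 1L]] <<- pr
    }
  }
  for (k in 0:(L - 1)) {
    # start at point k
    unpaired <- rep(TRUE, L)
    prs <- matrix(c(k, k), 1)
    unpaired[k + 1] <- FALSE
    cw <- k; ccw <- k
    while (any(unpaired)) {
      repeat { cw <- (cw + 1) %% L; if (unpaired[cw + 1]) break }
      unpaired[cw + 1] <- FALSE
      if (!any(unpaired)) { prs <- rbind(prs, c(cw, cw)); break }
      repeat { ccw <- (ccw - 1) %% L; if (unpaired[ccw + 1]) break }
      if (ccw == cw) { prs <- rbind(prs, c(cw, cw)); break }
      unpaired[ccw + 1] <- FALSE
      prs <- rbind(prs, c(cw, ccw))
    }
    add(prs)
    # start between points k and k+1
    unpaired <- rep(TRUE, L)
    prs <- NULL
    cw <- k; ccw <- (k + 1) %% L
    while (any(unpaired)) {
      if (unpaired[ccw + 1] && unpaired[cw + 1] && cw != ccw) {
        prs <- rbind(prs, c(ccw, cw))
        unpaired[c(cw, ccw) + 1] <- FALSE
      } else if (sum(unpaired) == 1) {
        last <- which(unpaired) - 1
        prs <- rbind(prs, c(last, last))
        unpaired[last + 1] <- FALSE
      }
      cw <- (cw - 1) %% L
      ccw <- (ccw + 1) %% L
    }
    add(prs)
  }
  out
}

oracle_normalize <- function(outline) {
  x <- outline$x - mean(outline$x)
  y <- outline$y - mean(outline$y)
  s <- sqrt(max(x^2 + y^2))
  cbind(x / s, y / s)
}

# mean squared distance at one axis angle, by explicit fold/average/unfold;
# vectorised over a vector of angles
oracle_msd <- function(P, pairing, theta) {
  ux <- cos(theta); uy <- sin(theta)
  L <- nrow(P)
  total <- 0
  for (row in seq_len(nrow(pairing))) {
    i <- pairing[row, 1] + 1L; j <- pairing[row, 2] + 1L
    if (i == j) {
      d <- P[i, 1] * ux + P[i, 2] * uy
      qx <- d * ux; qy <- d * uy
      total <- total + (P[i, 1] - qx)^2 + (P[i, 2] - qy)^2
    } else {
      di <- P[i, 1] * ux + P[i, 2] * uy
      rix <- 2 * di * ux - P[i, 1]; riy <- 2 * di * uy - P[i, 2]
      qjx <- (rix + P[j, 1]) / 2; qjy <- (riy + P[j, 2]) / 2
      dq <- qjx * ux + qjy * uy
      qix <- 2 * dq * ux - qjx; qiy <- 2 * dq * uy - qjy
      total <- total + (P[i, 1] - qix)^2 + (P[i, 2] - qiy)^2 +
        (P[j, 1] - qjx)^2 + (P[j, 2] - qjy)^2
    }
  }
  total / L
}

# golden-section refinement of the best grid angle
oracle_refine <- function(P, pairing, lo, hi, iters = 80) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
  f1 <- oracle_msd(P, pairing, c1); f2 <- oracle_msd(P, pairing, c2)
  for (i in seq_len(iters)) {
    if (f1 < f2) {
      b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - gr * (b - a); f1 <- oracle_msd(P, pairing, c1)
    } else {
      a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + gr * (b - a); f2 <- oracle_msd(P, pairing, c2)
    }
  }
  min(f1, f2)
}

oracle_best_for_pairing <- function(P, pairing, n_angles = 3600) {
  th <- seq(0, pi, length.out = n_angles + 1)[-(n_angles + 1)]
  vals <- oracle_msd(P, pairing, th)
  k <- which.min(vals)
  step <- pi / n_angles
  oracle_refine(P, pairing, th[k] - step, th[k] + step)
}

oracle_csm <- function(outline, n_angles = 3600) {
  P <- oracle_normalize(outline)
  min(vapply(oracle_pairings(nrow(P)), function(pr) {
    oracle_best_for_pairing(P, pr, n_angles)
  }, numeric(1)))
}

oracle_csm_forced <- function(outline, n_angles = 3600) {
  P <- oracle_normalize(outline)
  L <- nrow(P)
  r2 <- P[, 1]^2 + P[, 2]^2
  far <- which(r2 >= max(r2) - 1e-12) - 1L
  prs <- oracle_pairings(L)
  # at-point pairings are those containing a self-pair at the farthest point
  keep <- Filter(function(pr) {
    any(pr[, 1] == pr[, 2] & pr[, 1] %in% c(far, (far + L / 2) %% L))
  }, prs)
  min(vapply(keep, function(pr) oracle_best_for_pairing(P, pr, n_angles),
             numeric(1)))
}
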