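#' Read a frond photograph
#'
#' Reads an 8-bit RGB PNG or TIFF image into the array form used by the
#' extraction pipeline: an `H x W x 3` numeric array with intensities on
#' `[0, 255]`.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return Numeric array `H x W x 3`, intensities in `[0, 255]`.
#' @export
read_frond_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: '", ext, "' (expected png/tif/tiff)")
  )
  if (length(dim(img)) == 2L) {
    img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  }
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  img * 255
}

#' Otsu threshold of the inverse blue channel
#'
#' Segments a frond photograph into foreground (frond) and background. The
#' blue channel is inverted (fronds are green, hence dark in blue; the pale
#' background is bright in blue) and thresholded at the cutoff that maximizes
#' the between-class variance over a 256-bin histogram; pixels strictly above
#' the threshold become foreground.
#'
#' @param image `H x W x 3` numeric array, intensities in `[0, 255]`.
#' @param bins Number of histogram bins (default 256, one per 8-bit level).
#' @return Logical `H x W` matrix (`TRUE` = foreground) with the chosen
#'   threshold attached as attribute `"threshold"`.
#' @export
extract_mask <- function(image, bins = 256L) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
  inv_blue <- 255 - image[, , 3]
  if (max(inv_blue) - min(inv_blue) < .Machine$double.eps^0.5) {
    stop("degenerate image: inverse blue channel is constant, no two-class split")
  }
  thr <- otsu_threshold(inv_blue, bins = bins)
  mask <- inv_blue > thr
  attr(mask, "threshold") <- thr
  mask
}

#' Otsu's threshold on a 256-level histogram
#'
#' Exhaustively scans all candidate cutoffs and returns the one maximizing the
#' between-class variance of the two resulting classes (ties broken by the
#' smallest such cutoff).
#'
#' @param values Numeric vector or matrix of intensities in `[0, 255]`.
#' @param bins Number of histogram bins.
#' @return The threshold on the intensity scale; classify as `value > threshold`.
#' @export
otsu_threshold <- function(values, bins = 256L) {
  v <- as.numeric(values)
  # bin b holds intensities in [b, b+1) on the 0..255 scale (levels for 8-bit)
  idx <- pmin(pmax(floor(v / 256 * bins), 0), bins - 1L)
  h <- tabulate(idx + 1L, nbins = bins)
  p <- h / sum(h)
  levels_ <- (seq_len(bins) - 1L) * (256 / bins)
  w0 <- cumsum(p)
  mu <- cumsum(p * levels_)
  mu_t <- mu[bins]
  w1 <- 1 - w0
  between <- ifelse(w0 > 0 & w1 > 0, (mu_t * w0 - mu)^2 / (w0 * w1), -Inf)
  # candidate t means classes {<= level t} vs {> level t}; ties (flat plateaus
  # between well-separated modes) resolved by the midpoint of the tied range
  best <- which(between >= max(between) * (1 - 1e-12))
  mean(levels_[best])
}

## -- connected components ----------------------------------------------------

# 4-connected component labels by frontier flood fill (vectorised BFS).
# Returns an integer matrix, 0 = background, components numbered from 1 in
# order of their first (column-major) foreground pixel.
label_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  fg <- which(mask)
  unvisited <- rep(TRUE, h * w)
  next_lab <- 0L
  for (seed in fg) {
    if (!unvisited[seed]) next
    next_lab <- next_lab + 1L
    frontier <- seed
    unvisited[seed] <- FALSE
    lab[seed] <- next_lab
    while (length(frontier)) {
      r <- (frontier - 1L) %% h + 1L
      up    <- frontier[r > 1L] - 1L
      down  <- frontier[r < h] + 1L
      left  <- frontier[frontier > h] - h
      right <- frontier[frontier <= h * (w - 1L)] + h
      nb <- c(up, down, left, right)
      nb <- unique(nb[unvisited[nb] & mask[nb]])
      if (length(nb)) {
        unvisited[nb] <- FALSE
        lab[nb] <- next_lab
      }
      frontier <- nb
    }
  }
  lab
}

#' Clean a binary mask to a single hole-free frond component
#'
#' Keeps only the largest 4-connected foreground component (removing specks
#' that survived thresholding), then fills interior holes: background pixels
#' not reachable from the image border by 4-connected background steps are
#' flipped to foreground.
#'
#' Ties in largest-component size are broken deterministically in favour of
#' the component containing the lexicographically smallest `(row, col)` pixel.
#'
#' @param mask Logical matrix, `TRUE` = foreground; must contain at least one
#'   foreground pixel.
#' @return Logical matrix with attributes `"n_removed"` (foreground pixels
#'   deleted with smaller components) and `"n_filled"` (hole pixels filled).
#' @export
clean_mask <- function(mask) {
  mask <- mask == TRUE
  if (!any(mask)) stop("empty mask: no foreground pixels")
  h <- nrow(mask); w <- ncol(mask)
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0L])
  biggest <- which(sizes == max(sizes))
  if (length(biggest) > 1L) {
    # lexicographic (row, col) key of each tied component's smallest pixel
    key <- vapply(biggest, function(b) {
      px <- which(lab == b)
      r <- (px - 1L) %% h; cc <- (px - 1L) %/% h
      min(r * w + cc)
    }, numeric(1))
    biggest <- biggest[which.min(key)]
  }
  kept <- lab == biggest[1L]
  n_removed <- sum(mask) - sum(kept)

  # flood the border-connected background; the rest of the background is holes
  bg <- !kept
  reached <- matrix(FALSE, h, w)
  border <- which(bg & (row(bg) == 1L | row(bg) == h | col(bg) == 1L | col(bg) == w))
  reached[border] <- TRUE
  frontier <- border
  while (length(frontier)) {
    r <- (frontier - 1L) %% h + 1L
    up    <- frontier[r > 1L] - 1L
    down  <- frontier[r < h] + 1L
    left  <- frontier[frontier > h] - h
    right <- frontier[frontier <= h * (w - 1L)] + h
    nb <- c(up, down, left, right)
    nb <- unique(nb[!reached[nb] & bg[nb]])
    reached[nb] <- TRUE
    frontier <- nb
  }
  holes <- bg & !reached
  out <- kept | holes
  attr(out, "n_removed") <- n_removed
  attr(out, "n_filled") <- sum(holes)
  out
}

## -- boundary tracing --------------------------------------------------------

# Brute-force boundary set: foreground pixels with at least one 4-adjacent
# background pixel (pixels outside the image count as background).
boundary_pixels <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- mask
  core <- pad[2:(h + 1L), 2:(w + 1L)]
  nb_bg <- !pad[1:h, 2:(w + 1L)] | !pad[3:(h + 2L), 2:(w + 1L)] |
    !pad[2:(h + 1L), 1:w] | !pad[2:(h + 1L), 3:(w + 2L)]
  core & nb_bg
}

#' Trace the ordered outer boundary of a cleaned mask
#'
#' Orders the boundary pixels of a single 4-connected, hole-free foreground
#' component by walking the outer contour (Moore-neighbourhood walk with the
#' Jacob stopping criterion, in the spirit of Pavlidis' contour-following
#' procedure), starting from the topmost-then-leftmost boundary pixel.
#' Masks touching the image border are handled as if padded by a one-pixel
#' background ring. Pixels revisited by the walk (possible along one-pixel-wide
#' necks) are reported once, at their first visit.
#'
#' @param mask Cleaned logical matrix (see [clean_mask()]).
#' @return Tibble with 0-based `row`, `col` pixel coordinates, ordered along
#'   the contour; counterclockwise in the `(x = col, y = -row)` convention.
#'   A single-pixel mask yields one row and attribute `"degenerate" = TRUE`.
#' @export
trace_boundary <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  fg <- function(r, cc) r >= 1L && r <= h && cc >= 1L && cc <= w && mask[r, cc]
  start <- which(mask)
  if (!length(start)) stop("empty mask")
  r0 <- min((start - 1L) %% h + 1L)
  c0 <- min((start[(start - 1L) %% h + 1L == r0] - 1L) %/% h + 1L)
  if (sum(mask) == 1L) {
    out <- tibble::tibble(row = r0 - 1, col = c0 - 1)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  # clockwise Moore neighbourhood in (row, col) screen coordinates, i.e.
  # counterclockwise when y points up
  moore <- matrix(c(-1L, 0L, -1L, 1L, 0L, 1L, 1L, 1L, 1L, 0L, 1L, -1L, 0L, -1L, -1L, -1L),
                  ncol = 2L, byrow = TRUE)
  cur <- c(r0, c0)
  back <- c(r0, c0 - 1L)   # to the left of the start: background by choice of start
  first_state <- NULL
  rows <- integer(0); cols <- integer(0)
  max_iter <- 8L * sum(boundary_pixels(mask)) + 16L
  for (it in seq_len(max_iter)) {
    rows <- c(rows, cur[1]); cols <- c(cols, cur[2])
    # index of backtrack cell in the Moore ring around cur
    d <- back - cur
    k0 <- which(moore[, 1] == d[1] & moore[, 2] == d[2])
    nxt <- NULL
    for (s in 1:8) {
      k <- (k0 - 1L + s - 1L) %% 8L + 1L
      cand <- cur + moore[k, ]
      if (fg(cand[1], cand[2])) {
        nxt <- cand
        back <- cur + moore[(k - 2L) %% 8L + 1L, ]
        break
      }
    }
    if (is.null(nxt)) break # isolated pixel (cannot happen for size >= 2)
    state <- c(nxt, back)
    if (is.null(first_state)) {
      first_state <- state
    } else if (all(state == first_state)) {
      break
    }
    cur <- nxt
  }
  pts <- cbind(rows, cols)
  keep <- !duplicated(pts)
  pts <- pts[keep, , drop = FALSE]
  # restrict to true boundary pixels (the walk can step on interior pixels of
  # very thin masks only; for cleaned blobs this is a no-op)
  bp <- boundary_pixels(mask)
  on_b <- bp[cbind(pts[, 1], pts[, 2])]
  pts <- pts[on_b, , drop = FALSE]
  tibble::tibble(row = pts[, 1] - 1, col = pts[, 2] - 1)
}

## -- resampling and normalization --------------------------------------------

#' Resample a boundary trace to equally spaced reference points
#'
#' Places `n_points` reference points at equal arc-length intervals along the
#' closed piecewise-linear curve through the trace pixels, starting at the
#' first trace point. Reference points may fall between pixels (linear
#' interpolation).
#'
#' @param trace Data frame with `row`,`col` columns (from [trace_boundary()])
#'   or `x`,`y` columns (any ordered closed polygon).
#' @param n_points Number of reference points `L` (default 200).
#' @return Tibble with columns `x`, `y` in pixel units (`x = col`,
#'   `y = -row` so that the outline is in conventional orientation).
#' @export
resample_outline <- function(trace, n_points = 200L) {
  stopifnot(n_points >= 3L)
  if (all(c("x", "y") %in% names(trace))) {
    xy <- cbind(trace$x, trace$y)
  } else {
    xy <- cbind(trace$col, -trace$row)
  }
  if (nrow(xy) < 3L) stop("trace too short to resample (need >= 3 points)")
  closed <- rbind(xy, xy[1, ])
  seg <- sqrt(rowSums(diff(closed)^2))
  total <- sum(seg)
  if (total <= 0) stop("degenerate trace: zero total length")
  cum <- c(0, cumsum(seg))
  s <- (seq_len(n_points) - 1L) * total / n_points
  j <- findInterval(s, cum, rightmost.closed = TRUE)
  t <- (s - cum[j]) / seg[j]
  pts <- closed[j, , drop = FALSE] + t * (closed[j + 1L, , drop = FALSE] - closed[j, , drop = FALSE])
  tibble::tibble(x = pts[, 1], y = pts[, 2])
}

#' Normalize an outline for symmetry analysis
#'
#' Translates the outline so its centroid (arithmetic mean of the reference
#' points) sits at the origin and rescales so the greatest centroid-to-point
#' distance is exactly one. This makes the downstream symmetry measure scale-
#' and translation-free.
#'
#' @param outline Data frame with `x`, `y` columns.
#' @return Tibble with `x`, `y`; `max(sqrt(x^2 + y^2)) == 1`.
#' @export
normalize_outline <- function(outline) {
  x <- outline$x - mean(outline$x)
  y <- outline$y - mean(outline$y)
  r <- sqrt(max(x^2 + y^2))
  if (r <= 0) stop("degenerate outline: all points coincide")
  tibble::tibble(x = x / r, y = y / r)
}

#' Extract a normalized outline from an image in one call
#'
#' Chains [extract_mask()], [clean_mask()], [trace_boundary()] and
#' [resample_outline()].
#'
#' @inheritParams extract_mask
#' @inheritParams resample_outline
#' @return Tibble with `x`, `y` (pixel units) and attributes `threshold`,
#'   `n_removed`, `n_filled` describing the segmentation.
#' @export
extract_outline <- function(image, n_points = 200L, bins = 256L) {
  mask <- extract_mask(image, bins = bins)
  cleaned <- clean_mask(mask)
  tr <- trace_boundary(cleaned)
  if (isTRUE(attr(tr, "degenerate"))) stop("mask reduced to a single pixel")
  out <- resample_outline(tr, n_points = n_points)
  attr(out, "threshold") <- attr(mask, "threshold")
  attr(out, "n_removed") <- attr(cleaned, "n_removed")
  attr(out, "n_filled") <- attr(cleaned, "n_filled")
  out
}

#' Write / read outline reference points as CSV
#'
#' The plain-text format has a comment header carrying the number of reference
#' points and the mm-per-pixel calibration, then `index,x,y` rows in pixel
#' units.
#'
#' @param outline Data frame with `x`, `y`.
#' @param path Output file.
#' @param calibration mm per pixel (recorded in the header).
#' @return `path`, invisibly (write); tibble with `x`, `y` and a
#'   `"calibration"` attribute (read).
#' @export
write_outline_csv <- function(outline, path, calibration = NA_real_) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_points=%d mm_per_px=%s", nrow(outline),
                     format(calibration, digits = 17)), con)
  utils::write.csv(
    data.frame(index = seq_len(nrow(outline)) - 1L, x = outline$x, y = outline$y),
    con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_outline_csv
#' @export
read_outline_csv <- function(path) {
  header <- readLines(path, n = 1L)
  cal <- NA_real_
  m <- regmatches(header, regexec("mm_per_px=([-0-9.eNA]+)", header))[[1]]
  if (length(m) == 2L) cal <- suppressWarnings(as.numeric(m[2]))
  df <- utils::read.csv(path, comment.char = "#")
  out <- tibble::tibble(x = df$x, y = df$y)
  attr(out, "calibration") <- cal
  out
}
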