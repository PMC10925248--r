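#' Dark-pupil detection
#'
#' Under infrared illumination the pupil is the darkest region of the eye
#' image. Detection proceeds as: brightness thresholding (strict `<`),
#' a single 3x3 morphological opening to suppress salt noise, 8-connected
#' component analysis with min/max area filtering, then one of three
#' interchangeable localization methods:
#'
#' * `centroid` - arithmetic mean of component pixel coordinates; the
#'   reported ellipse degenerates to a circle of equivalent area;
#' * `convex_hull` - ellipse fitted to the convex hull of the component,
#'   robust to concave occlusions (eyelid notches);
#' * `ellipse_fit` - direct least-squares conic fit to the component's
#'   boundary pixels, constrained to an ellipse.
#'
#' @name pupil
NULL

#' Threshold dark pixels
#'
#' @param image 8-bit grayscale integer matrix
#' @param threshold brightness threshold in 0-255; pixels strictly below it
#'   are marked
#' @return logical matrix (`TRUE` = dark)
#' @export
binarize_dark <- function(image, threshold) {
  stopifnot(is.matrix(image), threshold >= 0, threshold <= 255)
  image < threshold
}

# 3x3 binary erosion/dilation via padded shifts (vectorized)
shift_stack <- function(mask, pad) {
  h <- nrow(mask); w <- ncol(mask)
  padded <- matrix(pad, h + 2, w + 2)
  padded[2:(h + 1), 2:(w + 1)] <- mask
  list(p = padded, h = h, w = w)
}

morph3 <- function(mask, op = c("erode", "dilate"), pad) {
  op <- match.arg(op)
  s <- shift_stack(mask, pad)
  acc <- NULL
  for (dy in 0:2) for (dx in 0:2) {
    win <- s$p[(1 + dy):(s$h + dy), (1 + dx):(s$w + dx)]
    acc <- if (is.null(acc)) win else if (op == "erode") acc & win else acc | win
  }
  acc
}

#' One iteration of 3x3 morphological opening
#' @param mask logical matrix
#' @return opened logical matrix
#' @export
morph_open3 <- function(mask) {
  morph3(morph3(mask, "erode", pad = TRUE), "dilate", pad = FALSE)
}

# separable k x k box erosion/dilation (k odd)
morph_box <- function(mask, op, k, pad) {
  r <- (k - 1L) %/% 2L
  comb <- if (op == "erode") `&` else `|`
  pass <- function(m, along) {
    h <- nrow(m); w <- ncol(m)
    if (along == "row") {
      padded <- matrix(pad, h, w + 2L * r)
      padded[, (r + 1L):(r + w)] <- m
      acc <- NULL
      for (d in 0:(2L * r)) {
        win <- padded[, (1L + d):(w + d), drop = FALSE]
        acc <- if (is.null(acc)) win else comb(acc, win)
      }
    } else {
      padded <- matrix(pad, h + 2L * r, w)
      padded[(r + 1L):(r + h), ] <- m
      acc <- NULL
      for (d in 0:(2L * r)) {
        win <- padded[(1L + d):(h + d), , drop = FALSE]
        acc <- if (is.null(acc)) win else comb(acc, win)
      }
    }
    acc
  }
  pass(pass(mask, "row"), "col")
}

# closing bridges the notch a bright glint cuts into the dark pupil mask;
# closing leaves convex shapes (the un-occluded pupil) unchanged
morph_close_box <- function(mask, k = 7L) {
  morph_box(morph_box(mask, "dilate", k, pad = FALSE), "erode", k, pad = TRUE)
}

# label connected components; returns list of components, each
# list(xs, ys (0-based), area, bbox = c(x0, x1, y0, y1) half-open)
find_components <- function(mask) {
  lab <- .cc_label8(mask)
  n <- attr(lab, "n")
  if (n == 0) return(list())
  idx <- which(lab > 0)
  labs <- lab[idx]
  ys <- (idx - 1L) %% nrow(mask)        # 0-based row = y
  xs <- (idx - 1L) %/% nrow(mask)       # 0-based col = x
  comps <- vector("list", n)
  split_i <- split(seq_along(idx), labs)
  for (k in seq_along(split_i)) {
    ii <- split_i[[k]]
    comps[[k]] <- list(xs = xs[ii], ys = ys[ii], area = length(ii),
                       bbox = c(min(xs[ii]), max(xs[ii]) + 1L,
                                min(ys[ii]), max(ys[ii]) + 1L))
  }
  comps
}

#' Select the pupil candidate component
#'
#' Returns the largest 8-connected component whose area lies within
#' `[min_size_px2, max_size_px2]`. Equal-area ties are broken in favour of
#' the component whose centroid is nearest the image centre.
#'
#' @param mask logical matrix from [binarize_dark()]
#' @param min_size_px2,max_size_px2 inclusive area bounds in pixels^2
#' @return a component (list with `xs`, `ys`, `area`, `bbox`) or `NULL`
#' @export
find_pupil_component <- function(mask, min_size_px2, max_size_px2) {
  comps <- find_components(mask)
  comps <- Filter(function(cc) cc$area >= min_size_px2 && cc$area <= max_size_px2,
                  comps)
  if (!length(comps)) return(NULL)
  areas <- vapply(comps, `[[`, numeric(1), "area")
  best <- which(areas == max(areas))
  if (length(best) > 1) {
    cx <- (ncol(mask) - 1) / 2; cy <- (nrow(mask) - 1) / 2
    d2 <- vapply(comps[best], function(cc) {
      (mean(cc$xs) - cx)^2 + (mean(cc$ys) - cy)^2
    }, numeric(1))
    best <- best[which.min(d2)]
  } else {
    best <- best[1]
  }
  comps[[best]]
}

#' Centroid of a component
#' @param component as returned by [find_pupil_component()]
#' @return numeric `(x, y)`, sub-pixel
#' @export
pupil_centroid <- function(component) {
  if (is.null(component) || component$area == 0) stopf("empty component")
  c(mean(component$xs), mean(component$ys))
}

# fill interior holes (e.g. a glint punched out of the pupil) so only the
# outer contour survives: background components not touching the matrix
# border are part of the blob
fill_holes <- function(m) {
  bg <- .cc_label8(!m)
  n <- attr(bg, "n")
  if (n == 0) return(m)
  border_labels <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  holes <- setdiff(seq_len(n), border_labels)
  if (length(holes)) m[bg %in% holes] <- TRUE
  m
}

# outer-boundary pixels of a component: members of the hole-filled mask
# with a 4-neighbour outside it
component_boundary <- function(component, mask_dim) {
  h <- mask_dim[1]; w <- mask_dim[2]
  m <- matrix(FALSE, h, w)
  m[cbind(component$ys + 1L, component$xs + 1L)] <- TRUE
  m <- fill_holes(m)
  inner <- morph3_cross(m)
  on_boundary <- m & !inner
  idx <- which(on_boundary)
  cbind(x = (idx - 1L) %/% h, y = (idx - 1L) %% h)
}

# 4-neighbour erosion (cross structuring element), border counts as outside
morph3_cross <- function(mask) {
  s <- shift_stack(mask, FALSE)
  offs <- list(c(0, 1), c(2, 1), c(1, 0), c(1, 2), c(1, 1))
  acc <- NULL
  for (o in offs) {
    win <- s$p[(1 + o[1]):(s$h + o[1]), (1 + o[2]):(s$w + o[2])]
    acc <- if (is.null(acc)) win else acc & win
  }
  acc
}

#' Direct least-squares ellipse fit
#'
#' Fits the conic `a x^2 + b x y + c y^2 + d x + e y + f = 0` to at least
#' five points under the ellipse constraint `4ac - b^2 = 1` (numerically
#' stable split form of the classic direct fit), and converts it to centre,
#' semi-axes and orientation.
#'
#' @param points two-column matrix (x, y) of at least 5 boundary points
#' @return a `vog_ellipse`
#' @export
fit_ellipse <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 5) stopf("ellipse fit needs >= 5 points, got %d", nrow(points))
  x <- points[, 1]; y <- points[, 2]
  # centre/scale for conditioning
  mx <- mean(x); my <- mean(y)
  sc <- mean(c(sd(x), sd(y)))
  if (!is.finite(sc) || sc == 0) stopf("degenerate point set for ellipse fit")
  xs <- (x - mx) / sc; ys <- (y - my) / sc
  D1 <- cbind(xs^2, xs * ys, ys^2)
  D2 <- cbind(xs, ys, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  T3 <- tryCatch(-solve(S3, t(S2)), error = function(e) NULL)
  if (is.null(T3)) stopf("degenerate conic (collinear or coincident points)")
  M <- S1 + S2 %*% T3
  # premultiply by inv(C1), C1 = [[0,0,2],[0,-1,0],[2,0,0]]
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  a1 <- NULL
  for (k in seq_len(3)) {
    v <- Re(ev$vectors[, k])
    cond <- 4 * v[1] * v[3] - v[2]^2
    if (is.finite(cond) && cond > 0) { a1 <- v; break }
  }
  if (is.null(a1)) stopf("no ellipse solution (degenerate conic)")
  a2 <- T3 %*% a1
  A <- a1[1]; B <- a1[2]; C <- a1[3]
  D <- a2[1]; E <- a2[2]; F0 <- a2[3]
  # undo normalization: substitute x -> (x - mx)/sc etc.
  A2 <- A / sc^2
  B2 <- B / sc^2
  C2 <- C / sc^2
  D2c <- D / sc - (2 * A * mx + B * my) / sc^2
  E2 <- E / sc - (2 * C * my + B * mx) / sc^2
  F2 <- F0 + (A * mx^2 + B * mx * my + C * my^2) / sc^2 - (D * mx + E * my) / sc
  conic_to_ellipse(A2, B2, C2, D2c, E2, F2)
}

conic_to_ellipse <- function(A, B, C, D, E, F0) {
  if (A < 0) {  # normalize sign so the quadratic form is positive definite
    A <- -A; B <- -B; C <- -C; D <- -D; E <- -E; F0 <- -F0
  }
  den <- 4 * A * C - B^2
  if (!is.finite(den) || den <= 0) stopf("conic is not an ellipse")
  cx <- (B * E - 2 * C * D) / den
  cy <- (B * D - 2 * A * E) / den
  # value of conic at centre
  Fc <- A * cx^2 + B * cx * cy + C * cy^2 + D * cx + E * cy + F0
  # eigenvalues of [[A, B/2], [B/2, C]]
  tr <- A + C
  disc <- sqrt(((A - C) / 2)^2 + (B / 2)^2)
  l1 <- tr / 2 - disc   # smaller -> major axis
  l2 <- tr / 2 + disc
  if (Fc >= 0 || l1 <= 0) stopf("conic is not a real ellipse")
  major <- sqrt(-Fc / l1)
  minor <- sqrt(-Fc / l2)
  # major-axis direction: eigenvector of smaller eigenvalue
  angle <- if (abs(B) < 1e-12 && A <= C) 0
           else if (abs(B) < 1e-12) 90
           else rad2deg(atan2(l1 - A, B / 2))
  new_ellipse(c(cx, cy), major, minor, angle)
}

#' Convex-hull pupil estimate
#'
#' Takes the convex hull of the component's pixels and fits an ellipse to
#' the hull vertices. Because the hull spans occluded (concave) regions,
#' this is less biased than the raw centroid when an eyelid clips the
#' pupil.
#'
#' @param component pupil component
#' @return list with `hull` (matrix of hull vertices, closed not repeated),
#'   `ellipse` (a `vog_ellipse` or `NULL`) and `found`
#' @export
pupil_convex_hull <- function(component) {
  pts <- cbind(component$xs, component$ys)
  hull_idx <- grDevices::chull(pts)
  hull <- pts[hull_idx, , drop = FALSE]
  if (nrow(hull) < 3) return(list(hull = hull, ellipse = NULL, found = FALSE))
  ell <- tryCatch(fit_ellipse(hull_resample(hull)),
                  error = function(e) NULL)
  list(hull = hull, ellipse = ell, found = !is.null(ell))
}

# resample hull edges so long edges (occlusion chords) do not dominate the
# fit less than their length warrants: points every ~2 px along the hull
hull_resample <- function(hull, spacing = 2) {
  n <- nrow(hull)
  out <- list()
  for (i in seq_len(n)) {
    a <- hull[i, ]; b <- hull[if (i == n) 1 else i + 1, ]
    len <- sqrt(sum((b - a)^2))
    k <- max(1L, ceiling(len / spacing))
    t <- (seq_len(k) - 1) / k
    out[[i]] <- cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
  }
  do.call(rbind, out)
}

#' Track the pupil in one image
#'
#' Composition binarize -> open -> component selection -> localization.
#'
#' @param image 8-bit grayscale integer matrix
#' @param settings a `vog_settings` (uses `pipeline.pupil_threshold`,
#'   `pipeline.min_size_px2`, `pipeline.max_size_px2`, `pipeline.roi`)
#' @param method `"ellipse_fit"` (default), `"convex_hull"` or `"centroid"`;
#'   `NULL` takes `pipeline.pupil_method` from settings
#' @return list with `found`, `ellipse` (`vog_ellipse` or `NULL`),
#'   `method`, and `component` (or `NULL`); also `mask` (the pupil's pixel
#'   mask) for downstream glint exclusion
#' @export
track_pupil <- function(image, settings = default_settings(), method = NULL) {
  p <- settings$pipeline
  if (is.null(method)) method <- p$pupil_method
  method <- match.arg(method, c("ellipse_fit", "convex_hull", "centroid"))
  roi <- parse_roi(p$roi)
  work <- image
  off <- c(0, 0)
  if (!is.null(roi)) {
    work <- crop_image(image, roi)
    off <- c(roi$x0, roi$y0)
  }
  mask <- morph_close_box(morph_open3(binarize_dark(work, p$pupil_threshold)))
  comp <- find_pupil_component(mask, p$min_size_px2, p$max_size_px2)
  none <- list(found = FALSE, ellipse = NULL, method = method,
               component = NULL, mask = NULL)
  if (is.null(comp)) return(none)
  ell <- switch(method,
    centroid = {
      ctr <- pupil_centroid(comp)
      r <- sqrt(comp$area / pi)
      new_ellipse(ctr + off, r, r, 0)
    },
    convex_hull = {
      h <- pupil_convex_hull(comp)
      if (!h$found) return(none)
      e <- h$ellipse
      new_ellipse(e$center + off, e$major, e$minor, e$angle_deg)
    },
    ellipse_fit = {
      bnd <- component_boundary(comp, dim(mask))
      e <- tryCatch(fit_ellipse(bnd), error = function(err) NULL)
      if (is.null(e)) return(none)
      new_ellipse(e$center + off, e$major, e$minor, e$angle_deg)
    })
  pupil_mask <- matrix(FALSE, nrow(image), ncol(image))
  pupil_mask[cbind(comp$ys + 1L + off[2], comp$xs + 1L + off[1])] <- TRUE
  list(found = TRUE, ellipse = ell, method = method, component = comp,
       mask = pupil_mask)
}
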