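#' Myocardial contour
#'
#' An ordered closed polygon in 0-based, pixel-centered image
#' coordinates (column = x, row = y). The polygon is stored without a
#' repeated end point and treated as closed.
#'
#' @param points numeric matrix with columns `x`, `y`, at least 8 rows;
#'   a duplicated final vertex is dropped.
#' @param label one of `"epicardial"`, `"endocardial"`, `"lv_roi"`, or
#'   any ROI name.
#' @return An object of class `roi_contour`.
#' @export
roi_contour <- function(points, label = "roi") {
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop("`points` must have two columns", call. = FALSE)
  colnames(points) <- c("x", "y")
  if (nrow(points) > 1L && all(points[1, ] == points[nrow(points), ]))
    points <- points[-nrow(points), , drop = FALSE]
  if (nrow(points) < 8L)
    stop("a contour needs at least 8 points", call. = FALSE)
  structure(list(points = points, label = as.character(label)),
            class = "roi_contour")
}

#' @export
print.roi_contour <- function(x, ...) {
  cat(sprintf("<roi_contour> '%s', %d points\n", x$label, nrow(x$points)))
  invisible(x)
}

# logical mask of pixels whose (0-based) centers lie inside the contour
contour_mask <- function(contour, grid) {
  nr <- grid[1]; nc <- grid[2]
  xs <- rep(0:(nc - 1), each = nr)
  ys <- rep(0:(nr - 1), times = nc)
  inside <- mgcv::in.out(rbind(contour$points, contour$points[1, ]),
                         cbind(xs, ys))
  matrix(inside, nr, nc)
}

# centroid of the endo/epi centerline (midpoints of paired vertices
# when point counts match, mean of the two centroids otherwise)
centerline_centroid <- function(epi, endo) {
  if (nrow(epi$points) == nrow(endo$points)) {
    colMeans((epi$points + endo$points) / 2)
  } else {
    (colMeans(epi$points) + colMeans(endo$points)) / 2
  }
}

#' Partition the myocardium into equal-angle sectors
#'
#' Every pixel of the annulus between the endocardial and epicardial
#' contours is assigned to exactly one sector by the angular position
#' of its center about the centerline centroid, relative to the
#' anterior RV insertion angle. Sectors span consecutive
#' `360/n_sectors` degree arcs counterclockwise from the insertion
#' point; with three sectors they are labelled `septal`,
#' `anterolateral` and `inferolateral` in that order.
#'
#' @param epi,endo epicardial and endocardial [roi_contour()]s; `endo`
#'   must lie strictly inside `epi`.
#' @param rv_insertion_angle_deg reference angle of the anterior RV
#'   insertion, degrees counterclockwise from the image +x axis.
#' @param n_sectors number of sectors (`>= 2`; labels beyond 3 are
#'   `sector4`, ...).
#' @param grid image dimensions `c(rows, cols)`.
#' @return An object of class `sector_masks`: list of logical `masks`
#'   (named, pairwise disjoint, union = annulus), the `annulus` mask,
#'   and `rv_insertion_angle_deg`.
#' @export
sector_partition <- function(epi, endo, rv_insertion_angle_deg, grid,
                             n_sectors = 3L) {
  stopifnot(inherits(epi, "roi_contour"), inherits(endo, "roi_contour"))
  if (n_sectors < 2L) stop("`n_sectors` must be >= 2", call. = FALSE)
  epi_mask <- contour_mask(epi, grid)
  endo_mask <- contour_mask(endo, grid)
  if (any(endo_mask & !epi_mask))
    stop("contours intersect: endocardium is not inside epicardium",
         call. = FALSE)
  annulus <- epi_mask & !endo_mask
  if (!any(annulus)) stop("empty annulus between contours", call. = FALSE)

  ctr <- centerline_centroid(epi, endo)
  nr <- grid[1]; nc <- grid[2]
  xs <- matrix(rep(0:(nc - 1), each = nr), nr)
  ys <- matrix(rep(0:(nr - 1), times = nc), nr)
  ang <- pixel_angle_deg(xs, ys, ctr[1], ctr[2])
  sec <- sector_of_angle(ang, rv_insertion_angle_deg, n_sectors)

  labels <- if (n_sectors == 3L) c("septal", "anterolateral", "inferolateral")
            else paste0("sector", seq_len(n_sectors))
  masks <- lapply(seq_len(n_sectors), function(s) annulus & (sec == s))
  names(masks) <- labels
  if (any(!vapply(masks, any, logical(1))))
    stop("a sector mask is empty; contours too coarse for this grid",
         call. = FALSE)
  structure(list(masks = masks, annulus = annulus,
                 rv_insertion_angle_deg = rv_insertion_angle_deg),
            class = "sector_masks")
}

#' @export
print.sector_masks <- function(x, ...) {
  cat(sprintf("<sector_masks> %d sectors from insertion %.0f deg: %s\n",
              length(x$masks), x$rv_insertion_angle_deg,
              paste(sprintf("%s (%d px)", names(x$masks),
                            vapply(x$masks, sum, integer(1))),
                    collapse = ", ")))
  invisible(x)
}

#' Extract the mean signal-intensity curve of an ROI
#'
#' @param series a [dynamic_series()].
#' @param mask logical pixel mask matching the series' spatial
#'   dimensions; must select at least one pixel.
#' @param label ROI label stored on the curve.
#' @return An [si_curve()]: per frame, the arithmetic mean of the
#'   (magnitude) signal over the mask.
#' @export
extract_curve <- function(series, mask, label = "roi") {
  stopifnot(inherits(series, "dynamic_series"))
  d <- dim(series$data)
  if (!identical(dim(mask), d[1:2]))
    stop("mask shape does not match the series frames", call. = FALSE)
  npx <- sum(mask)
  if (npx == 0L) stop("empty ROI mask", call. = FALSE)
  si <- vapply(seq_len(d[3]),
               function(k) mean(Mod(series$data[, , k][mask])),
               numeric(1))
  si_curve(series$frame_times_s, si, roi_label = label, n_pixels = npx)
}

#' Rigidly shift contours per frame
#'
#' Applies per-frame in-plane translations to a set of contours,
#' emulating scripted correction of respiratory displacement.
#'
#' @param contours list of [roi_contour()]s.
#' @param dx_px,dy_px numeric vectors of per-frame offsets in pixels
#'   (recycled to a common length).
#' @return A list of length `n_frames`; each element is the contour set
#'   translated by that frame's offset.
#' @export
shift_contours <- function(contours, dx_px, dy_px) {
  if (!all(is.finite(dx_px)) || !all(is.finite(dy_px)))
    stop("offsets must be finite", call. = FALSE)
  nf <- max(length(dx_px), length(dy_px))
  dx_px <- rep_len(dx_px, nf); dy_px <- rep_len(dy_px, nf)
  lapply(seq_len(nf), function(k) {
    lapply(contours, function(ct) {
      roi_contour(sweep(ct$points, 2, c(dx_px[k], dy_px[k]), "+"),
                  label = ct$label)
    })
  })
}

#' Read or write contours as JSON
#'
#' @param contours list of [roi_contour()]s.
#' @param path JSON file path.
#' @return `write_contours` returns `path` invisibly; `read_contours`
#'   returns a named list of [roi_contour()]s.
#' @export
write_contours <- function(contours, path) {
  payload <- lapply(contours, function(ct)
    list(label = ct$label, x = ct$points[, "x"], y = ct$points[, "y"]))
  names(payload) <- vapply(contours, function(ct) ct$label, character(1))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_contours
#' @export
read_contours <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(payload, function(p)
    roi_contour(cbind(x = p$x, y = p$y), label = p$label))
}

#' Write or read a set of SI curves as CSV
#'
#' Columns: `frame`, `t_s`, then one column per ROI label. Pixel counts
#' are not stored in the CSV, so `read_curves` restores curves with
#' `n_pixels = 1`.
#'
#' @param curves list of [si_curve()]s sharing a time grid.
#' @param path CSV file path.
#' @return `write_curves` returns `path` invisibly; `read_curves` a
#'   named list of [si_curve()]s.
#' @export
write_curves <- function(curves, path) {
  t_s <- curves[[1]]$t_s
  df <- data.frame(frame = seq_along(t_s), t_s = t_s)
  for (cv in curves) {
    if (!isTRUE(all.equal(cv$t_s, t_s)))
      stop("curves do not share a time grid", call. = FALSE)
    df[[cv$roi_label]] <- cv$si
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curves
#' @export
read_curves <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  labels <- setdiff(names(df), c("frame", "t_s"))
  out <- lapply(labels, function(lb) si_curve(df$t_s, df[[lb]], roi_label = lb))
  names(out) <- labels
  out
}
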