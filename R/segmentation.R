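#' Segment seed blobs in a reflectance cube
#'
#' Thresholds the band-averaged image (automatic threshold by Otsu's method)
#' and labels 4-connected foreground components, discarding components below
#' `min_area` pixels. Masks are returned sorted by their centroid (row, then
#' column) so blob order is reproducible.
#'
#' @param cube a reflectance-kind [hyper_cube()].
#' @param threshold `"auto"` (Otsu on the band-mean image) or a numeric
#'   reflectance threshold.
#' @param min_area minimum component area in pixels (default 50).
#' @return List of logical masks, one per retained component; empty (with a
#'   warning) when nothing is found.
#' @export
segment_seeds <- function(cube, threshold = "auto", min_area = 50) {
  stopifnot(inherits(cube, "hyper_cube"))
  if (cube$kind != "reflectance")
    abort("segmentation expects a reflectance cube",
          class = "spectraseed_config_error")
  m <- apply(cube$data, c(1, 2), mean)
  if (identical(threshold, "auto")) {
    rng <- range(m)
    if (diff(rng) <= 0) {
      warn("segment_seeds: flat image, no components found")
      return(list())
    }
    scaled <- (m - rng[1]) / diff(rng)
    thr <- rng[1] + EBImage::otsu(EBImage::Image(scaled)) * diff(rng)
  } else {
    thr <- as.numeric(threshold)
  }
  lab <- label_components_4(m > thr)
  n_comp <- max(lab)
  if (n_comp == 0) {
    warn("segment_seeds: no components above threshold")
    return(list())
  }
  masks <- list()
  cent <- NULL
  for (k in seq_len(n_comp)) {
    mk <- lab == k
    if (sum(mk) < min_area) next
    masks[[length(masks) + 1]] <- mk
    w <- which(mk, arr.ind = TRUE)
    cent <- rbind(cent, colMeans(w))
  }
  if (length(masks) == 0) {
    warn("segment_seeds: all components below min_area")
    return(list())
  }
  masks[order(cent[, 1], cent[, 2])]
}

#' Rectangular region of interest
#'
#' Pixel rectangles are 0-based and half-open: a pixel `(r, c)` belongs to
#' the ROI iff `row_start <= r < row_end` and `col_start <= c < col_end`.
#'
#' @param row_start,row_end,col_start,col_end rectangle bounds.
#' @param seed_id identifier.
#' @param label optional class id.
#' @export
roi <- function(row_start, row_end, col_start, col_end,
                seed_id = NA_character_, label = NA_integer_) {
  if (row_start >= row_end || col_start >= col_end)
    abort("ROI must have positive extent", class = "spectraseed_format_error")
  structure(list(row_start = as.integer(row_start), row_end = as.integer(row_end),
                 col_start = as.integer(col_start), col_end = as.integer(col_end),
                 seed_id = as.character(seed_id), label = as.integer(label)),
            class = "roi")
}

#' Largest axis-aligned rectangle inscribed in a binary mask
#'
#' The classic maximal-rectangle-in-a-binary-matrix algorithm: per matrix
#' row, maintain a histogram of consecutive foreground heights and solve the
#' largest-rectangle-in-histogram subproblem with a monotone stack. Runs in
#' O(rows * cols).
#'
#' @param mask logical matrix.
#' @param seed_id,label carried through to the returned [roi()].
#' @return A [roi()] covering the maximum-area rectangle fully inside the mask.
#' @export
largest_inscribed_rectangle <- function(mask, seed_id = NA_character_,
                                        label = NA_integer_) {
  mask <- as.matrix(mask)
  if (!any(mask)) abort("mask is empty", class = "spectraseed_config_error")
  nr <- nrow(mask); nc <- ncol(mask)
  heights <- integer(nc)
  best <- c(area = 0L, r0 = 0L, r1 = 0L, c0 = 0L, c1 = 0L)
  for (i in seq_len(nr)) {
    heights <- ifelse(mask[i, ], heights + 1L, 0L)
    # largest rectangle in histogram via monotone stack (sentinel at end)
    h <- c(heights, 0L)
    stack <- integer(0)
    for (j in seq_along(h)) {
      while (length(stack) > 0 && h[stack[length(stack)]] > h[j]) {
        top <- stack[length(stack)]
        stack <- stack[-length(stack)]
        left <- if (length(stack) == 0) 1L else stack[length(stack)] + 1L
        width <- j - left
        area <- h[top] * width
        if (area > best["area"]) {
          best <- c(area = area, r0 = i - h[top], r1 = i,
                    c0 = left - 1L, c1 = left - 1L + width)
        }
      }
      stack <- c(stack, j)
    }
  }
  roi(best["r0"], best["r1"], best["c0"], best["c1"],
      seed_id = seed_id, label = label)
}

#' Mean ROI spectra from a reflectance cube
#'
#' For each region of interest, averages the reflectance of all pixels inside
#' the rectangle at every band: the mean spectrum of that seed.
#'
#' @param cube a reflectance-kind [hyper_cube()].
#' @param rois a list of [roi()] objects, or a data frame with columns
#'   `seed_id`, `label`, `row_start`, `row_end`, `col_start`, `col_end`
#'   (0-based half-open, as written by [write_rois()]).
#' @param labels optional labels overriding those in `rois`.
#' @return A [spectra_tbl()] with one row per ROI.
#' @export
extract_mean_spectra <- function(cube, rois, labels = NULL) {
  stopifnot(inherits(cube, "hyper_cube"))
  if (is.data.frame(rois)) {
    rois <- lapply(seq_len(nrow(rois)), function(i)
      roi(rois$row_start[i], rois$row_end[i], rois$col_start[i],
          rois$col_end[i], seed_id = rois$seed_id[i], label = rois$label[i]))
  }
  d <- dim(cube$data)
  out <- matrix(0, length(rois), d[3])
  ids <- character(length(rois)); labs <- integer(length(rois))
  for (i in seq_along(rois)) {
    r <- rois[[i]]
    if (r$row_start < 0 || r$col_start < 0 || r$row_end > d[1] || r$col_end > d[2])
      abort(sprintf("ROI `%s` is out of cube bounds", r$seed_id),
            class = "spectraseed_format_error")
    block <- cube$data[(r$row_start + 1):r$row_end,
                       (r$col_start + 1):r$col_end, , drop = FALSE]
    out[i, ] <- apply(block, 3, mean)
    ids[i] <- if (is.na(r$seed_id)) sprintf("roi_%03d", i) else r$seed_id
    labs[i] <- r$label
  }
  if (!is.null(labels)) labs <- rep_len(as.integer(labels), length(rois))
  spectra_tbl(out, cube$wavelengths_nm, labels = labs, sample_ids = ids)
}

#' Read / write ROI sets as delimited text
#'
#' Columns: `seed_id`, `label`, `row_start`, `row_end`, `col_start`,
#' `col_end` (0-based, half-open).
#'
#' @param rois list of [roi()] objects.
#' @param path file path.
#' @export
write_rois <- function(rois, path) {
  df <- dplyr::bind_rows(lapply(rois, function(r)
    tibble::tibble(seed_id = r$seed_id, label = r$label,
                   row_start = r$row_start, row_end = r$row_end,
                   col_start = r$col_start, col_end = r$col_end)))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_rois
#' @export
read_rois <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i)
    roi(df$row_start[i], df$row_end[i], df$col_start[i], df$col_end[i],
        seed_id = df$seed_id[i], label = df$label[i]))
}
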