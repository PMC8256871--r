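# Plant segmentation and per-view feature extraction.
#
# Segmentation follows the classic chamber-imaging recipe: nearest-neighbour
# colour classification of ROI pixels against reference colours, speckle
# removal by erosion/dilation, small-component dropping, and composition of
# all surviving parts into a single object. NIR images are measured under the
# RGB-derived mask.

#' Segmentation parameters
#'
#' @param foreground_refs,background_refs matrices (n x 3) of reference RGB
#'   colours on the 0-255 scale; each ROI pixel is assigned the class of its
#'   nearest reference in RGB Euclidean distance.
#' @param roi `NULL` for the whole image, else `c(y0, y1, x0, x1)` pixel
#'   bounds (inclusive).
#' @param erosion_radius,dilation_radius disc radii in px (0 = skip).
#' @param min_component_area connected components smaller than this are
#'   dropped before composition.
#' @return a `pg_seg_params` list.
#' @export
seg_params <- function(foreground_refs = rbind(c(26, 179, 38)),
                       background_refs = rbind(c(242, 242, 242)),
                       roi = NULL,
                       erosion_radius = 0, dilation_radius = 0,
                       min_component_area = 0) {
  fg <- rbind(foreground_refs); bg <- rbind(background_refs)
  if (ncol(fg) != 3 || ncol(bg) != 3 || nrow(fg) < 1 || nrow(bg) < 1) {
    pg_stop("config", "seg_params: need >= 1 RGB triple per class")
  }
  if (erosion_radius < 0 || dilation_radius < 0) {
    pg_stop("config", "seg_params: radii must be >= 0")
  }
  structure(list(foreground_refs = fg, background_refs = bg, roi = roi,
                 erosion_radius = erosion_radius,
                 dilation_radius = dilation_radius,
                 min_component_area = min_component_area),
            class = "pg_seg_params")
}

disc_brush <- function(r) EBImage::makeBrush(2L * as.integer(r) + 1L, "disc")

#' Segment a plant from an RGB view image
#'
#' @param rgb h x w x 3 array; values in [0, 1] or 0-255 (auto-detected).
#' @param params a [seg_params()].
#' @return a `pg_mask`: list with `mask` (logical h x w matrix), `pixel_count`
#'   and `empty` (`TRUE` when no plant pixel survives post-processing; this is
#'   a missing-observation signal, not an error).
#' @export
segment_plant <- function(rgb, params = seg_params()) {
  stopifnot(length(dim(rgb)) == 3, dim(rgb)[3] >= 3)
  if (max(rgb) <= 1) rgb <- rgb * 255
  h <- dim(rgb)[1]; w <- dim(rgb)[2]
  roi <- if (is.null(params$roi)) c(1L, h, 1L, w) else as.integer(params$roi)
  ys <- roi[1]:roi[2]; xs <- roi[3]:roi[4]
  r <- rgb[ys, xs, 1]; g <- rgb[ys, xs, 2]; b <- rgb[ys, xs, 3]
  refs <- rbind(params$foreground_refs, params$background_refs)
  n_fg <- nrow(params$foreground_refs)
  d2 <- vapply(seq_len(nrow(refs)), function(i) {
    as.vector((r - refs[i, 1])^2 + (g - refs[i, 2])^2 + (b - refs[i, 3])^2)
  }, numeric(length(r)))
  cls <- max.col(-d2, ties.method = "first")
  m <- matrix(cls <= n_fg, length(ys), length(xs))

  if (params$erosion_radius > 0 && any(m)) {
    m <- EBImage::erode(EBImage::Image(m * 1), disc_brush(params$erosion_radius)) > 0.5
  }
  if (params$dilation_radius > 0 && any(m)) {
    m <- EBImage::dilate(EBImage::Image(m * 1), disc_brush(params$dilation_radius)) > 0.5
  }
  m <- matrix(as.logical(m), length(ys), length(xs))
  if (params$min_component_area > 0 && any(m)) {
    lab <- EBImage::bwlabel(EBImage::Image(m * 1))
    sizes <- tabulate(as.integer(lab))
    keep <- which(sizes >= params$min_component_area)
    m <- matrix(as.integer(lab) %in% keep & as.vector(m), length(ys), length(xs))
  }
  full <- matrix(FALSE, h, w)
  full[ys, xs] <- m
  structure(list(mask = full, pixel_count = sum(full), empty = !any(full),
                 roi = roi),
            class = "pg_mask")
}

mask_contour_perimeter <- function(mask) {
  oc <- EBImage::ocontour(EBImage::bwlabel(EBImage::Image(mask * 1)))
  sum(vapply(oc, function(pts) {
    if (nrow(pts) < 2) return(0)
    d <- sqrt(rowSums((pts - pts[c(2:nrow(pts), 1), , drop = FALSE])^2))
    sum(d)
  }, numeric(1)))
}

polygon_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Extract geometric features from a plant mask
#'
#' Computes the 14 registered geometric descriptors (see
#' [pg_feature_registry()]). Perimeter is the traced 8-connected contour
#' length; the convex hull is taken over pixel corner points so that
#' `area <= hull_area` always holds; compactness `4*pi*A/P^2` is clamped to
#' (0, 1].
#'
#' @param mask a `pg_mask` from [segment_plant()].
#' @return named list of the 14 features, all `NA` (with `empty = TRUE`
#'   attribute) for an empty mask.
#' @export
extract_geometric_features <- function(mask) {
  reg <- pg_feature_registry()
  if (mask$empty) {
    out <- as.list(rep(NA_real_, length(reg$geometric)))
    names(out) <- reg$geometric
    attr(out, "empty") <- TRUE
    return(out)
  }
  idx <- which(mask$mask, arr.ind = TRUE)
  y <- idx[, 1]; x <- idx[, 2]
  area <- nrow(idx)
  width <- diff(range(x)) + 1
  height <- diff(range(y)) + 1
  # hull over pixel corners: every pixel contributes its 4 unit-square corners
  cx <- c(x - 0.5, x + 0.5, x - 0.5, x + 0.5)
  cy <- c(y - 0.5, y - 0.5, y + 0.5, y + 0.5)
  hidx <- grDevices::chull(cx, cy)
  hx <- cx[hidx]; hy <- cy[hidx]
  hull_area <- polygon_area(hx, hy)
  hull_perimeter <- sum(sqrt(diff(c(hx, hx[1]))^2 + diff(c(hy, hy[1]))^2))
  caliper <- if (length(hx) > 1) {
    max(stats::dist(cbind(hx, hy)))
  } else 1
  perimeter <- max(mask_contour_perimeter(mask$mask), 4)
  compactness <- min(1, 4 * pi * area / perimeter^2)
  mu20 <- var(x) * (area - 1) / area
  mu02 <- var(y) * (area - 1) / area
  mu11 <- if (area > 1) cov(x, y) * (area - 1) / area else 0
  tr <- mu20 + mu02
  det_ <- mu20 * mu02 - mu11^2
  disc <- max(tr^2 / 4 - det_, 0)
  l1 <- tr / 2 + sqrt(disc); l2 <- tr / 2 - sqrt(disc)
  eccentricity <- if (l1 > 0) sqrt(max(0, 1 - l2 / l1)) else 0
  list(area = area,
       hull_area = max(hull_area, area),
       perimeter = perimeter,
       hull_perimeter = hull_perimeter,
       width = width,
       height = height,
       caliper = caliper,
       compactness = compactness,
       eccentricity = eccentricity,
       centroid_y = mean(y),
       solidity = min(1, area / max(hull_area, area)),
       aspect_ratio = width / height,
       extent = area / (width * height),
       eq_diameter = 2 * sqrt(area / pi))
}

#' Mean NIR gray value under a plant mask
#'
#' @param nir h x w matrix; values in [0, 1] are scaled to the 8-bit range,
#'   values above 1 are taken as already 8-bit.
#' @param mask a `pg_mask` (derived from the RGB view and overlaid on the
#'   aligned NIR image).
#' @return mean 8-bit gray of foreground pixels, `NA` for an empty mask.
#'   High values indicate low tissue water content.
#' @export
nir_mean_gray <- function(nir, mask) {
  if (mask$empty) return(NA_real_)
  stopifnot(all(dim(nir)[1:2] == dim(mask$mask)))
  v <- nir[mask$mask]
  if (max(nir) <= 1) v <- v * 255
  mean(v)
}

#' Assemble per-view features into a feature table
#'
#' @param records data.frame with columns `plant_id`, `day`, `view` (one of
#'   top/side0/side90) and one column per feature (the registry names,
#'   optionally including `mean_gray`). Missing views or empty-mask rows
#'   yield `NA` cells; the (plant_id, day) row is retained.
#' @return a [pg_features] table with `<feature>.<view>` columns.
#' @export
build_feature_table <- function(records) {
  reg <- pg_feature_registry()
  check_cols(records, c("plant_id", "day", "view"), "feature records")
  bad <- setdiff(unique(records$view), reg$views)
  if (length(bad)) {
    pg_stop("schema", "feature records: unknown view(s): ",
            paste(bad, collapse = ", "))
  }
  key <- paste(records$plant_id, records$day, records$view)
  if (anyDuplicated(key)) {
    pg_stop("integrity", "feature records: conflicting duplicate entry: ",
            key[duplicated(key)][1])
  }
  feats <- intersect(c(reg$geometric, reg$nir), names(records))
  base <- unique(records[, c("plant_id", "day")])
  base <- base[order(base$plant_id, base$day), ]
  for (v in reg$views) {
    sub <- records[records$view == v, c("plant_id", "day", feats)]
    names(sub)[-(1:2)] <- paste(feats, v, sep = ".")
    base <- merge(base, sub, by = c("plant_id", "day"), all.x = TRUE,
                  sort = FALSE)
  }
  base <- base[order(base$plant_id, base$day), ]
  rownames(base) <- NULL
  pg_features(base)
}

read_view_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        pg_stop("io", "reading TIFF requires the 'tiff' package")
      }
      tiff::readTIFF(path)
    },
    pg_stop("io", "unsupported image format: ", path))
  img
}

#' Extract features for a directory of view images
#'
#' Expects files named `<plant_id>_<day>_<view>.png` (or `.tif`) for RGB and
#' `<plant_id>_<day>_<view>_nir.png` for NIR.
#'
#' @param images_dir directory of images.
#' @param params a [seg_params()].
#' @return a [pg_features] table.
#' @export
extract_features_dir <- function(images_dir, params = seg_params()) {
  files <- list.files(images_dir, pattern = "\\.(png|tif|tiff)$",
                      full.names = TRUE)
  rgb_files <- files[!grepl("_nir\\.", files)]
  if (!length(rgb_files)) pg_stop("io", "no view images in ", images_dir)
  recs <- lapply(rgb_files, function(f) {
    stem <- tools::file_path_sans_ext(basename(f))
    parts <- strsplit(stem, "_")[[1]]
    if (length(parts) < 3) pg_stop("io", "unparseable image name: ", f)
    view <- parts[length(parts)]
    day <- as.integer(parts[length(parts) - 1])
    pid <- paste(parts[seq_len(length(parts) - 2)], collapse = "_")
    mask <- segment_plant(read_view_image(f), params)
    feats <- extract_geometric_features(mask)
    nf <- file.path(dirname(f), paste0(stem, "_nir.png"))
    feats$mean_gray <- if (file.exists(nf)) {
      nir_mean_gray(read_view_image(nf), mask)
    } else NA_real_
    cbind(data.frame(plant_id = pid, day = day, view = view,
                     stringsAsFactors = FALSE),
          as.data.frame(feats))
  })
  build_feature_table(do.call(rbind, recs))
}
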