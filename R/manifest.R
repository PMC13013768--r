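CLASS_LABELS <- c("AD", "HP")

#' Bounding box constructor
#'
#' Boxes use 0-based pixel indices and half-open extents: the box covers
#' columns `[x_min, x_min + width)` and rows `[y_min, y_min + height)`.
#'
#' @param x_min,y_min 0-based top-left corner.
#' @param width,height Positive pixel counts.
#' @return A `specaug_bbox` list.
#' @export
bounding_box <- function(x_min, y_min, width, height) {
  x_min <- as.integer(x_min); y_min <- as.integer(y_min)
  width <- as.integer(width); height <- as.integer(height)
  if (x_min < 0L || y_min < 0L) stop("bounding box corner must be >= 0")
  if (width < 1L || height < 1L) stop("bounding box extents must be positive")
  structure(list(x_min = x_min, y_min = y_min, width = width, height = height),
            class = "specaug_bbox")
}

validate_bbox_in_image <- function(bbox, img) {
  h <- dim(img)[1]; w <- dim(img)[2]
  if (bbox$x_min + bbox$width > w || bbox$y_min + bbox$height > h)
    stop(sprintf("bounding box [%d+%d, %d+%d) exceeds %dx%d image",
                 bbox$x_min, bbox$width, bbox$y_min, bbox$height, h, w))
  invisible(bbox)
}

MANIFEST_COLUMNS <- c("image_path", "label", "x_min", "y_min", "width", "height")

new_manifest <- function(df) {
  rownames(df) <- NULL
  structure(df, class = c("specaug_manifest", "data.frame"))
}

#' Build a dataset manifest from vectors
#'
#' @param image_path Character vector of unique image paths.
#' @param label Class label per image, `"AD"` or `"HP"`.
#' @param x_min,y_min,width,height Bounding box columns (0-based, half-open).
#' @param sr_mask_path Optional ground-truth SR mask path per image.
#' @param ... Additional covariate columns (e.g. location, size category)
#'   carried through for balance reporting.
#' @return A `specaug_manifest` data frame.
#' @export
manifest <- function(image_path, label, x_min, y_min, width, height,
                     sr_mask_path = NULL, ...) {
  df <- data.frame(image_path = as.character(image_path),
                   label = as.character(label),
                   x_min = as.integer(x_min), y_min = as.integer(y_min),
                   width = as.integer(width), height = as.integer(height),
                   stringsAsFactors = FALSE)
  if (!is.null(sr_mask_path)) df$sr_mask_path <- as.character(sr_mask_path)
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  validate_manifest(new_manifest(df))
}

validate_manifest <- function(m) {
  miss <- setdiff(MANIFEST_COLUMNS, names(m))
  if (length(miss)) stop("manifest is missing columns: ", paste(miss, collapse = ", "))
  bad <- which(!(m$label %in% CLASS_LABELS))
  if (length(bad))
    stop("unknown label(s) in manifest row(s) ", paste(bad, collapse = ", "),
         ": ", paste(unique(m$label[bad]), collapse = ", "))
  if (anyDuplicated(m$image_path))
    stop("duplicate image paths in manifest")
  if (any(m$width < 1L) || any(m$height < 1L) || any(m$x_min < 0L) || any(m$y_min < 0L))
    stop("invalid bounding box in manifest")
  m
}

#' Per-label sample counts of a manifest
#'
#' @param m A manifest.
#' @return Named integer vector with one entry per class label.
#' @export
manifest_counts <- function(m) {
  vapply(CLASS_LABELS, function(l) sum(m$label == l), integer(1))
}

# Strip a leading base-directory prefix from paths so files stored next to
# their manifest are referenced relatively; other paths are left untouched.
path_relative_to <- function(paths, base) {
  prefix <- paste0(sub("/+$", "", base), "/")
  ifelse(!is.na(paths) & startsWith(paths, prefix),
         substring(paths, nchar(prefix) + 1L), paths)
}

resolve_paths <- function(paths, base) {
  paths <- as.character(paths)
  ifelse(is.na(paths) | !nzchar(paths) | substr(paths, 1, 1) == "/",
         paths, file.path(base, paths))
}

#' Read a dataset manifest CSV
#'
#' The manifest is a UTF-8 comma-separated file with a header row and columns
#' `image_path,label,x_min,y_min,width,height` plus an optional
#' `sr_mask_path` and arbitrary covariate columns. Coordinates are 0-based;
#' boxes are half-open. Relative image/mask paths are interpreted relative
#' to the manifest's own directory, so dataset folders are relocatable.
#'
#' @param path CSV path.
#' @param check_images If `TRUE`, open every image and verify that its
#'   bounding box fits inside it (slower).
#' @return A validated `specaug_manifest`.
#' @export
read_manifest <- function(path, check_images = FALSE) {
  if (!file.exists(path)) stop("no such manifest: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  base <- dirname(path)
  df$image_path <- resolve_paths(df$image_path, base)
  if ("sr_mask_path" %in% names(df))
    df$sr_mask_path <- resolve_paths(df$sr_mask_path, base)
  m <- validate_manifest(new_manifest(df))
  if (check_images) {
    for (i in seq_len(nrow(m))) {
      img <- read_image(m$image_path[i])
      validate_bbox_in_image(manifest_bbox(m, i), img)
    }
  }
  m
}

#' Write a dataset manifest CSV
#'
#' Round-trips losslessly with [read_manifest()]: sample order, labels, boxes
#' and covariates are preserved exactly. With `relative = TRUE` (the
#' default) image and mask paths are stored relative to the manifest's
#' directory, which keeps dataset folders relocatable and their manifests
#' byte-reproducible.
#'
#' @param m A manifest.
#' @param path Destination CSV path.
#' @param relative Store image/mask paths relative to `dirname(path)`.
#' @return Invisibly, `path`.
#' @export
write_manifest <- function(m, path, relative = TRUE) {
  validate_manifest(m)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  df <- as.data.frame(m)
  if (relative) {
    base <- dirname(path)
    df$image_path <- path_relative_to(df$image_path, base)
    if ("sr_mask_path" %in% names(df))
      df$sr_mask_path <- path_relative_to(df$sr_mask_path, base)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Extract one sample's bounding box from a manifest
#'
#' @param m A manifest.
#' @param i Row index.
#' @return A `specaug_bbox`.
#' @export
manifest_bbox <- function(m, i) {
  bounding_box(m$x_min[i], m$y_min[i], m$width[i], m$height[i])
}
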