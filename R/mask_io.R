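# Reading, writing and converting images, label masks and RLE submissions.

#' Construct a label mask
#'
#' A label mask is an integer matrix in which 0 is background and each
#' positive integer identifies one nucleus instance. On construction the mask
#' is canonicalized: positive labels are relabeled to `1..n` in ascending
#' original-id order, so arbitrary ids and gaps are accepted on input but the
#' internal state is deterministic. A label's pixels are not required to be
#' spatially connected, and a mask with zero objects is valid.
#'
#' @param labels integer (or numeric) matrix of non-negative labels.
#' @param image_id identifier string.
#' @return An object of class `label_mask` with elements `image_id`, `labels`
#'   (canonical integer matrix) and `n_objects`.
#' @examples
#' m <- label_mask(matrix(c(0, 5, 5, 9), 2, 2))
#' m$n_objects       # 2
#' unique(as.vector(m$labels))  # 0, 1, 2
#' @export
label_mask <- function(labels, image_id = "image") {
  if (!is.matrix(labels)) stopf("labels must be a matrix")
  if (any(!is.finite(labels)) || any(labels < 0) || any(labels != round(labels))) {
    stopf("labels must be finite non-negative integers")
  }
  labels <- canonicalize_labels(matrix(as.integer(labels), nrow(labels), ncol(labels)))
  structure(
    list(image_id = as.character(image_id), labels = labels,
         n_objects = max(labels, 0L)),
    class = "label_mask"
  )
}

# Relabel positive values to 1..n in ascending original-id order. Idempotent.
canonicalize_labels <- function(labels) {
  ids <- sort(unique(labels[labels > 0L]))
  if (length(ids) == 0L) return(labels)
  if (identical(ids, seq_along(ids))) return(labels)
  lut <- integer(max(ids))
  lut[ids] <- seq_along(ids)
  pos <- labels > 0L
  labels[pos] <- lut[labels[pos]]
  labels
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("<label_mask '%s': %d x %d, %d object%s>\n", x$image_id,
              nrow(x$labels), ncol(x$labels), x$n_objects,
              if (x$n_objects == 1L) "" else "s"))
  invisible(x)
}

#' @export
dim.label_mask <- function(x) dim(x$labels)

#' Construct an image record
#'
#' Holds one 2D microscopy image with intensities normalized to `[0, 1]`,
#' either single-channel (H x W matrix) or 3-channel (H x W x 3 array).
#'
#' @param pixels numeric matrix or H x W x 3 array with values in `[0, 1]`.
#' @param image_id identifier string.
#' @param group optional visual group label (see [group_names()]) or
#'   `"unknown"`.
#' @return An object of class `image_record`.
#' @export
image_record <- function(pixels, image_id = "image", group = "unknown") {
  if (is.matrix(pixels)) {
    nch <- 1L
  } else if (is.array(pixels) && length(dim(pixels)) == 3L && dim(pixels)[3] %in% c(1L, 3L)) {
    if (dim(pixels)[3] == 1L) {
      pixels <- pixels[, , 1L, drop = TRUE]
      nch <- 1L
    } else nch <- 3L
  } else {
    stopf("pixels must be an H x W matrix or H x W x 3 array")
  }
  if (any(!is.finite(pixels)) || min(pixels) < 0 || max(pixels) > 1) {
    stopf("pixel intensities must be finite and within [0, 1]")
  }
  d <- dim(pixels)
  if (d[1] * d[2] <= 0) stopf("image must have positive size")
  if (!group %in% c(group_names(), "unknown")) stopf("unknown group label '%s'", group)
  structure(
    list(image_id = as.character(image_id), pixels = pixels,
         height = d[1], width = d[2], n_channels = nch, group = group),
    class = "image_record"
  )
}

#' @export
print.image_record <- function(x, ...) {
  cat(sprintf("<image_record '%s': %d x %d, %d channel%s, group %s>\n",
              x$image_id, x$height, x$width, x$n_channels,
              if (x$n_channels == 1L) "" else "s", x$group))
  invisible(x)
}

#' Read a PNG or TIFF image as an image record
#'
#' Intensities are rescaled to `[0, 1]` from the native bit depth (the png
#' and tiff readers already return normalized values); 4-channel (RGBA)
#' inputs are reduced to 3 channels by dropping alpha.
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @param image_id identifier; defaults to the file name without extension.
#' @param group optional group label.
#' @return An [image_record()].
#' @export
read_image <- function(path, image_id = NULL, group = "unknown") {
  if (!file.exists(path)) stopf("image file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = tryCatch(png::readPNG(path), error = function(e)
      stopf("cannot read PNG %s: %s", path, conditionMessage(e))),
    tif = ,
    tiff = tryCatch(tiff::readTIFF(path), error = function(e)
      stopf("cannot read TIFF %s: %s", path, conditionMessage(e))),
    stopf("unsupported image format '%s' for %s (PNG or TIFF expected)", ext, path)
  )
  if (length(dim(px)) == 3L) {
    nch <- dim(px)[3]
    if (nch == 4L) px <- px[, , 1:3, drop = FALSE]            # drop alpha
    else if (nch == 2L) px <- px[, , 1L, drop = TRUE]         # gray + alpha
    else if (!nch %in% c(1L, 3L)) stopf("unsupported channel count %d in %s", nch, path)
  }
  px[px < 0] <- 0; px[px > 1] <- 1
  if (is.null(image_id)) image_id <- tools::file_path_sans_ext(basename(path))
  image_record(px, image_id = image_id, group = group)
}

#' Write an image record to PNG
#'
#' @param img an [image_record()].
#' @param path output path ending in `.png`.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  stopifnot(inherits(img, "image_record"))
  png::writePNG(img$pixels, target = path)
  invisible(path)
}

#' Read a label-mask image
#'
#' Reads a PNG or TIFF whose pixel values are integer object labels.
#' Grayscale PNGs are rescaled by their native bit depth (8 or 16 bit);
#' 3-channel PNGs are interpreted as 24-bit packed labels
#' (`R*65536 + G*256 + B`, the format [write_label_mask()] emits beyond 255
#' objects); TIFFs are read as raw integers. Non-canonical label ids are
#' relabeled to `1..n`.
#'
#' @param path path to the mask image.
#' @param image_id identifier; defaults to the file name without extension.
#' @return A [label_mask()].
#' @export
read_label_mask <- function(path, image_id = NULL) {
  if (!file.exists(path)) stopf("mask file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    px <- png::readPNG(path, info = TRUE)
    depth <- attr(px, "info")$bit.depth
    if (length(dim(px)) == 3L && dim(px)[3] >= 3L) {
      scale <- 2^depth - 1
      px <- round(px[, , 1] * scale) * 65536 + round(px[, , 2] * scale) * 256 +
        round(px[, , 3] * scale)
    } else {
      if (length(dim(px)) == 3L) px <- px[, , 1L, drop = TRUE]
      px <- round(px * (2^depth - 1))
    }
  } else if (ext %in% c("tif", "tiff")) {
    px <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(px)) == 3L) px <- px[, , 1L, drop = TRUE]
  } else {
    stopf("unsupported mask format '%s' for %s", ext, path)
  }
  if (is.null(image_id)) image_id <- tools::file_path_sans_ext(basename(path))
  label_mask(matrix(as.integer(round(px)), nrow(px), ncol(px)), image_id = image_id)
}

#' Write a label mask as a PNG
#'
#' Masks with up to 255 objects are written as plain 8-bit grayscale PNGs
#' (pixel value = label, readable by any image tool); larger masks pack the
#' label into the three 8-bit color channels (`R*65536 + G*256 + B`). Both
#' forms round-trip exactly through [read_label_mask()].
#'
#' @param mask a [label_mask()].
#' @param path output path ending in `.png`.
#' @return `path`, invisibly.
#' @export
write_label_mask <- function(mask, path) {
  stopifnot(inherits(mask, "label_mask"))
  if (mask$n_objects <= 255L) {
    png::writePNG(mask$labels / 255, target = path)
  } else if (mask$n_objects <= 16777215L) {
    lab <- mask$labels
    png::writePNG(array(c(lab %/% 65536, (lab %/% 256) %% 256, lab %% 256) / 255,
                        dim = c(dim(lab), 3L)), target = path)
  } else {
    stopf("more than 16777215 objects cannot be stored as a packed PNG")
  }
  invisible(path)
}

#' Combine per-object binary masks into one label mask
#'
#' The BBBC038-style layout stores each annotated nucleus as its own binary
#' mask; this stacks them into a single label mask, assigning labels `1..k`
#' in input order.
#'
#' @param masks list of logical/0-1 matrices of one common shape.
#' @param policy `"error"` (default) fails on any overlapping foregrounds,
#'   reporting the first disputed pixel; `"first-wins"` keeps the earliest
#'   mask's label at disputed pixels.
#' @param shape integer `c(height, width)`, required when `masks` is empty.
#' @param image_id identifier for the result.
#' @return A [label_mask()] with `n_objects` equal to the number of input
#'   masks that retained at least one pixel.
#' @export
combine_binary_masks <- function(masks, policy = c("error", "first-wins"),
                                 shape = NULL, image_id = "image") {
  policy <- match.arg(policy)
  if (length(masks) == 0L) {
    if (is.null(shape)) stopf("shape must be given when masks is empty")
    return(label_mask(matrix(0L, shape[1], shape[2]), image_id = image_id))
  }
  d <- dim(masks[[1]])
  out <- matrix(0L, d[1], d[2])
  for (k in seq_along(masks)) {
    mk <- masks[[k]]
    if (!identical(dim(mk), d)) stopf("mask %d shape differs from mask 1", k)
    fg <- which(mk > 0)
    clash <- fg[out[fg] != 0L]
    if (length(clash) > 0L) {
      if (policy == "error") {
        rc <- arrayInd(clash[1], d)
        stopf("masks %d and %d overlap at pixel (row %d, col %d)",
              out[clash[1]], k, rc[1], rc[2])
      }
      fg <- setdiff(fg, clash)   # first-wins: earlier label keeps disputed pixels
    }
    out[fg] <- k
  }
  label_mask(out, image_id = image_id)
}

#' Read a BBBC038-style directory of per-object binary masks
#'
#' @param dir directory containing one binary PNG per object.
#' @param policy overlap policy passed to [combine_binary_masks()].
#' @param image_id identifier; defaults to the directory name.
#' @return A [label_mask()].
#' @export
read_binary_mask_dir <- function(dir, policy = "error", image_id = NULL) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (is.null(image_id)) image_id <- basename(normalizePath(dir, mustWork = FALSE))
  masks <- lapply(files, function(f) {
    px <- png::readPNG(f)
    if (length(dim(px)) == 3L) px <- px[, , 1L, drop = TRUE]
    px > 0.5
  })
  if (length(masks) == 0L) stopf("no PNG masks found in %s", dir)
  combine_binary_masks(masks, policy = policy, image_id = image_id)
}

#' Run-length encode a label mask
#'
#' Uses the archived challenge-submission dialect: pixels are numbered
#' 1-based in column-major order (top to bottom within a column, columns left
#' to right), and each object is a sorted list of `(start, length)` runs.
#' Objects are emitted in ascending label order.
#'
#' @param mask a [label_mask()].
#' @return A list of `rle_record` objects (one per object), each with
#'   `image_id` and a two-column `runs` matrix (`start`, `length`). An empty
#'   mask yields an empty list.
#' @export
rle_encode <- function(mask) {
  stopifnot(inherits(mask, "label_mask"))
  lapply(seq_len(mask$n_objects), function(k) {
    idx <- which(mask$labels == k)    # column-major, 1-based: the RLE order
    breaks <- which(diff(idx) != 1L)
    starts <- idx[c(1L, breaks + 1L)]
    ends <- idx[c(breaks, length(idx))]
    rle_record(cbind(start = starts, length = ends - starts + 1L), mask$image_id)
  })
}

rle_record <- function(runs, image_id) {
  structure(list(image_id = image_id,
                 runs = matrix(as.integer(runs), ncol = 2,
                               dimnames = list(NULL, c("start", "length")))),
            class = "rle_record")
}

#' Decode run-length records into a label mask
#'
#' Inverse of [rle_encode()]: records are assigned labels `1..k` in list
#' order.
#'
#' @param records list of `rle_record`s (or a single record).
#' @param height,width mask dimensions.
#' @param policy `"error"` fails if two records claim one pixel;
#'   `"first-wins"` keeps the earlier record's label.
#' @param image_id identifier; defaults to the records' shared image id.
#' @return A [label_mask()].
#' @export
rle_decode <- function(records, height, width, policy = c("error", "first-wins"),
                       image_id = NULL) {
  policy <- match.arg(policy)
  if (inherits(records, "rle_record")) records <- list(records)
  n <- as.integer(height) * as.integer(width)
  v <- integer(n)
  for (k in seq_along(records)) {
    runs <- records[[k]]$runs
    if (nrow(runs) == 0L) next
    if (any(runs[, 1] < 1L) || any(runs[, 2] < 1L) ||
        any(runs[, 1] + runs[, 2] - 1L > n)) {
      stopf("record %d has a run outside the %d x %d grid", k, height, width)
    }
    idx <- unlist(lapply(seq_len(nrow(runs)), function(r)
      seq.int(runs[r, 1], length.out = runs[r, 2])), use.names = FALSE)
    if (anyDuplicated(idx)) stopf("record %d has overlapping runs", k)
    clash <- idx[v[idx] != 0L]
    if (length(clash) > 0L) {
      if (policy == "error") stopf("records %d and %d overlap at pixel %d",
                                   v[clash[1]], k, clash[1])
      idx <- setdiff(idx, clash)
    }
    v[idx] <- k
  }
  if (is.null(image_id)) {
    image_id <- if (length(records) > 0L) records[[1]]$image_id else "image"
  }
  label_mask(matrix(v, height, width), image_id = image_id)
}

#' Read a challenge submission CSV into RLE records
#'
#' The format has header columns `ImageId,EncodedPixels`; `EncodedPixels` is
#' a space-separated sequence `start length start length ...`. A blank
#' `EncodedPixels` field marks an image that is present with zero predicted
#' objects.
#'
#' @param path CSV file path.
#' @return A named list: one element per image id, each a list of
#'   `rle_record`s (possibly empty).
#' @export
read_submission_csv <- function(path) {
  if (!file.exists(path)) stopf("submission file not found: %s", path)
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (!all(c("ImageId", "EncodedPixels") %in% names(df))) {
    stopf("submission CSV must have columns ImageId and EncodedPixels")
  }
  out <- list()
  for (i in seq_len(nrow(df))) {
    id <- df$ImageId[i]
    enc <- trimws(df$EncodedPixels[i])
    if (is.null(out[[id]])) out[[id]] <- list()
    if (!nzchar(enc)) next
    tok <- suppressWarnings(as.integer(strsplit(enc, "\\s+")[[1]]))
    if (length(tok) %% 2L != 0L || anyNA(tok)) {
      stopf("row %d (image %s): EncodedPixels must be pairs of integers", i, id)
    }
    runs <- matrix(tok, ncol = 2, byrow = TRUE)
    runs <- runs[order(runs[, 1]), , drop = FALSE]
    out[[id]] <- c(out[[id]], list(rle_record(runs, id)))
  }
  out
}

#' Write RLE records as a challenge submission CSV
#'
#' @param records either a flat list of `rle_record`s or a named list of
#'   per-image record lists as returned by [read_submission_csv()]. Images
#'   with zero objects are written as one row with a blank `EncodedPixels`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_submission_csv <- function(records, path) {
  if (length(records) > 0L && inherits(records[[1]], "rle_record")) {
    grouped <- split(records, vapply(records, function(r) r$image_id, ""))
  } else grouped <- records
  lines <- "ImageId,EncodedPixels"
  for (id in names(grouped)) {
    recs <- grouped[[id]]
    if (length(recs) == 0L) {
      lines <- c(lines, paste0(id, ","))
    } else {
      for (r in recs) {
        lines <- c(lines, paste0(id, ",", paste(t(r$runs), collapse = " ")))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}
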