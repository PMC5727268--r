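#' Quantify nerve incision extent from grayscale images
#'
#' Binarizes a baseline image of the exposed nerve and an image taken after
#' incision, then reports the percentage of white (nerve) pixels removed:
#' `100 * (W_baseline - W_incised) / W_baseline`. Binarization uses Otsu's
#' threshold per image unless an explicit `threshold` is given; an optional
#' rectangular region of interest confines the count to the nerve.
#'
#' @param image Incised image: numeric matrix in \[0, 1\] (or 0..255), or a
#'   path to an 8-bit grayscale PNG/TIFF.
#' @param baseline Baseline image, same pixel dimensions.
#' @param threshold Optional fixed binarization threshold (same scale as
#'   the image); default uses Otsu's method per image.
#' @param roi Optional `c(x0, y0, x1, y1)` (1-based, inclusive) analysis
#'   region; default the whole image.
#' @return Percent of nerve tissue removed, in \[0, 100\].
#' @export
quantify_incision <- function(image, baseline, threshold = NULL, roi = NULL) {
  img <- .as_gray_matrix(image)
  base <- .as_gray_matrix(baseline)
  if (!identical(dim(img), dim(base)))
    stop("image and baseline must have the same pixel dimensions")
  if (!is.null(roi)) {
    if (length(roi) != 4L) stop("roi must be c(x0, y0, x1, y1)")
    img <- img[roi[2L]:roi[4L], roi[1L]:roi[3L], drop = FALSE]
    base <- base[roi[2L]:roi[4L], roi[1L]:roi[3L], drop = FALSE]
  }
  w_base <- sum(.binarize(base, threshold))
  w_img <- sum(.binarize(img, threshold))
  if (w_base == 0)
    stop("baseline contains no white pixels after binarization")
  100 * (w_base - w_img) / w_base
}

# load a grayscale image as a numeric matrix scaled to [0, 1]
.as_gray_matrix <- function(x) {
  if (is.character(x)) {
    img <- EBImage::readImage(x)
    x <- EBImage::imageData(EBImage::channel(img, "gray"))
    if (length(dim(x)) > 2L) x <- x[, , 1L]
  }
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("image must be numeric")
  if (max(x) > 1) x <- x / 255
  x
}

.binarize <- function(x, threshold = NULL) {
  if (is.null(threshold)) {
    if (diff(range(x)) == 0) {
      threshold <- 0.5  # constant image: call it all-white or all-black
    } else {
      threshold <- EBImage::otsu(x, range = c(0, 1))
    }
  }
  x > threshold
}
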