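## Segmentation of multi-seed cabinet images. Seeds are dark objects on
## a controlled light background, photographed on a regular grid (12
## columns x 8 rows by default, i.e. 96 seeds per image).

#' Read a cabinet image as an 8-bit RGB array
#'
#' Reads a PNG or TIFF image and returns an H x W x 3 array of channel
#' values in `[0, 255]`. Grayscale images are replicated to three
#' channels; an alpha channel, if present, is dropped.
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @return numeric array H x W x 3 with values in `[0, 255]`.
#' @export
readSeedImage <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF requires the 'tiff' package")
    tiff::readTIFF(path)
  } else stop("unsupported image format: ", ext)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
  img * 255
}

# Per-pixel CIELAB lightness of an H x W x 3 array (values 0-255).
.pixelLightness <- function(image) {
  d <- dim(image)
  lab <- srgbToLab(matrix(image, ncol = 3))
  matrix(lab[, "L"], d[1], d[2])
}

# Merge 4-connected labels that touch diagonally so the final labelling
# is 8-connected.
.merge8 <- function(labels) {
  mx <- max(labels)
  if (mx < 2) return(labels)
  H <- nrow(labels); W <- ncol(labels)
  parent <- seq_len(mx)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union2 <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  pairUp <- function(a, b) {   # a, b: equally-shaped label blocks
    sel <- a > 0 & b > 0 & a != b
    if (any(sel)) {
      pr <- unique(cbind(a[sel], b[sel]))
      for (r in seq_len(nrow(pr))) union2(pr[r, 1], pr[r, 2])
    }
  }
  pairUp(labels[-H, -W], labels[-1, -1])   # down-right diagonal
  pairUp(labels[-H, -1], labels[-1, -W])   # down-left diagonal
  root <- vapply(seq_len(mx), find, integer(1))
  out <- labels
  out[out > 0] <- root[out[out > 0]]
  out
}

#' Segment a gridded seed image into per-seed regions
#'
#' Thresholds the CIELAB lightness channel (dark foreground on a light
#' background), labels 8-connected components, and assigns each region
#' to the grid cell containing its centroid on an evenly divided image.
#' Regions smaller than `minAreaPx` are dropped with a warning; two
#' regions whose centroids fall in the same cell raise an error naming
#' the cell.
#'
#' @param image H x W x 3 array (values 0-255) or an H x W lightness
#'   matrix.
#' @param gridRows,gridCols grid layout; the default 8 x 12 corresponds
#'   to 96 seeds per image.
#' @param minAreaPx smallest region (pixels) kept as a seed.
#' @param thresholdMode `"otsu"` (default) computes the lightness
#'   threshold with Otsu's method; `"fixed"` uses `threshold`.
#' @param threshold fixed L* threshold (foreground is L* below it),
#'   default 80.
#' @return A data.frame sorted row-major with columns `row`, `col`
#'   (grid cell), `area_px`, `centroid_x`, `centroid_y` (pixel units,
#'   x = image column, y = image row) and a list-column `pixels` of
#'   linear pixel indices into the H x W plane.
#' @examples
#' sim <- generateSeedImage(seedCohortSpec(), seed = 1)
#' regions <- segmentSeedGrid(sim$image)
#' nrow(regions)  # 96
#' @export
segmentSeedGrid <- function(image, gridRows = 8, gridCols = 12,
                            minAreaPx = 20,
                            thresholdMode = c("otsu", "fixed"),
                            threshold = 80) {
  thresholdMode <- match.arg(thresholdMode)
  L <- if (length(dim(image)) == 3) .pixelLightness(image) else image
  H <- nrow(L); W <- ncol(L)
  thr <- if (thresholdMode == "otsu") {
    100 * EBImage::otsu(EBImage::Image(L / 100), range = c(0, 1))
  } else threshold
  mask <- L < thr
  if (!any(mask)) return(.emptyRegions())
  labels <- .merge8(EBImage::bwlabel(EBImage::Image(mask * 1)))
  labels <- as.integer(labels)
  idx <- which(labels > 0)
  groups <- split(idx, labels[idx])
  areas <- lengths(groups)
  small <- areas < minAreaPx
  if (any(small)) {
    warning(sum(small), " region(s) below minAreaPx = ", minAreaPx,
            " dropped")
    groups <- groups[!small]
  }
  if (!length(groups)) return(.emptyRegions())
  rows <- vapply(groups, function(g) mean((g - 1) %% H + 1), numeric(1))
  cols <- vapply(groups, function(g) mean((g - 1) %/% H + 1), numeric(1))
  cellR <- pmin(pmax(ceiling(rows / (H / gridRows)), 1), gridRows)
  cellC <- pmin(pmax(ceiling(cols / (W / gridCols)), 1), gridCols)
  cellId <- paste0("r", cellR, "c", cellC)
  if (anyDuplicated(cellId)) {
    dup <- unique(cellId[duplicated(cellId)])
    stop("ambiguous segmentation: multiple regions map to grid cell(s) ",
         paste(dup, collapse = ", "))
  }
  ord <- order(cellR, cellC)
  out <- data.frame(row = cellR[ord], col = cellC[ord],
                    area_px = as.integer(areas[!small][ord]),
                    centroid_x = cols[ord], centroid_y = rows[ord])
  out$pixels <- unname(groups[ord])
  out
}

.emptyRegions <- function() {
  out <- data.frame(row = integer(), col = integer(),
                    area_px = integer(), centroid_x = numeric(),
                    centroid_y = numeric())
  out$pixels <- list()
  out
}

#' Summarize per-seed color in CIELAB
#'
#' Converts every masked pixel to CIELAB, averages arithmetically over
#' the mask, and derives chroma and hue from the averaged a*, b*.
#' Averaging is done in CIELAB (the measurement space), not in RGB.
#'
#' @param regions a region data.frame from [segmentSeedGrid()] (one or
#'   more rows).
#' @param image the H x W x 3 array the regions were segmented from.
#' @return A data.frame with columns `seed_row`, `seed_col`, `area_px`,
#'   `L`, `a`, `b`, `C_ab`, `h_ab`.
#' @export
summarizeSeedColors <- function(regions, image) {
  if (length(dim(image)) != 3) stop("image must be an H x W x 3 array")
  H <- dim(image)[1]; W <- dim(image)[2]
  npx <- as.integer(H) * as.integer(W)
  if (nrow(regions) == 0)
    return(data.frame(seed_row = integer(), seed_col = integer(),
                      area_px = integer(), L = numeric(), a = numeric(),
                      b = numeric(), C_ab = numeric(), h_ab = numeric()))
  res <- lapply(seq_len(nrow(regions)), function(i) {
    px <- regions$pixels[[i]]
    if (!length(px)) stop("empty pixel mask for region ", i)
    if (any(px < 1 | px > npx)) stop("region mask outside image bounds")
    rgb <- cbind(image[px], image[px + npx], image[px + 2 * npx])
    lab <- srgbToLab(rgb)
    colMeans(lab)
  })
  lab <- do.call(rbind, res)
  ch <- chromaHue(lab[, "a"], lab[, "b"])
  ch <- matrix(ch, ncol = 2, dimnames = list(NULL, c("C_ab", "h_ab")))
  data.frame(seed_row = regions$row, seed_col = regions$col,
             area_px = regions$area_px, L = lab[, "L"], a = lab[, "a"],
             b = lab[, "b"], C_ab = ch[, "C_ab"], h_ab = ch[, "h_ab"])
}
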