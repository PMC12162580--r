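# Readers and writers: YOLO-dialect box annotations, polygon annotations
# rasterized to label masks, 8-bit PNG images and masks, single-slice
# NIfTI, and JSON/CSV metric reports.  The category-id table lives in
# boxCategories() and is shared by every reader and writer.

#' Read a YOLO-dialect annotation file
#'
#' One record per line: \code{category_id cx cy w h} with normalized [0,1]
#' center-form coordinates and integer category id in [0,3] (see
#' \code{\link{boxCategories}}).
#'
#' @param path file path.
#' @return data.frame with columns \code{category, cx, cy, w, h}.
#' @export
readYolo <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(data.frame(category = character(), cx = numeric(), cy = numeric(),
                      w = numeric(), h = numeric()))
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) != 5L)
      stop("malformed YOLO record at line ", i, ": expected 5 fields")
    v <- suppressWarnings(as.numeric(f))
    if (anyNA(v)) stop("malformed YOLO record at line ", i, ": non-numeric field")
    id <- as.integer(v[1])
    if (id < 0L || id > 3L)
      stop("category id out of range [0,3] at line ", i)
    data.frame(category = .categoryName(id), cx = v[2], cy = v[3],
               w = v[4], h = v[5])
  })
  do.call(rbind, rows)
}

#' Read a YOLO-dialect detection file
#'
#' Like \code{\link{readYolo}} but each record may carry a sixth field, the
#' confidence score in [0,1]; records without one default to confidence 1.
#'
#' @param path file path.
#' @return data.frame with columns \code{category, cx, cy, w, h,
#'   confidence}.
#' @export
readDetections <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(data.frame(category = character(), cx = numeric(), cy = numeric(),
                      w = numeric(), h = numeric(), confidence = numeric()))
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (!length(f) %in% 5:6)
      stop("malformed detection record at line ", i, ": expected 5 or 6 fields")
    v <- suppressWarnings(as.numeric(f))
    if (anyNA(v)) stop("malformed detection record at line ", i,
                       ": non-numeric field")
    id <- as.integer(v[1])
    if (id < 0L || id > 3L)
      stop("category id out of range [0,3] at line ", i)
    data.frame(category = .categoryName(id), cx = v[2], cy = v[3],
               w = v[4], h = v[5],
               confidence = if (length(v) == 6L) v[6] else 1)
  })
  do.call(rbind, rows)
}

#' Write YOLO-dialect annotations
#'
#' Coordinates are formatted at 6 decimals; \code{write} then \code{read}
#' recovers the annotations up to that formatting.
#'
#' @param annotations data.frame with \code{category, cx, cy, w, h}.
#' @param path file path.
#' @return invisibly, the path.
#' @export
writeYolo <- function(annotations, path) {
  ids <- .categoryId(annotations$category)
  lines <- sprintf("%d %.6f %.6f %.6f %.6f", ids, annotations$cx,
                   annotations$cy, annotations$w, annotations$h)
  writeLines(lines, path)
  invisible(path)
}

# Even-odd (crossing-number) test of pixel centers against one polygon.
# px, py: vectors of pixel-center coordinates; polygon vertices in pixel
# coordinates, implicitly closed.  Pixel centers exactly on an edge are
# included (consistent half-open convention plus explicit on-edge test).
.pointsInPolygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- logical(length(px))
  onEdge <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- vx[i]; yi <- vy[i]; xj <- vx[j]; yj <- vy[j]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    # on-segment test: collinear and within the bounding interval
    cross <- (xj - xi) * (py - yi) - (yj - yi) * (px - xi)
    within <- px >= pmin(xi, xj) - 1e-9 & px <= pmax(xi, xj) + 1e-9 &
      py >= pmin(yi, yj) - 1e-9 & py <= pmax(yi, yj) + 1e-9
    onEdge <- onEdge | (abs(cross) < 1e-9 & within)
    j <- i
  }
  inside | onEdge
}

#' Rasterize labeled polygons to a label mask
#'
#' Even-odd rasterization over pixel centers (pixel (row, col) covers the
#' unit square with center (col-0.5, row-0.5) in 0-based image
#' coordinates); later polygons overwrite earlier ones on overlap (file
#' order).  Pixel centers exactly on an edge are included.
#'
#' @param polys list of polygons, each a list with \code{label} (one of
#'   \code{"OC"}, \code{"ICA"}, \code{"SS"}) and \code{vertices}, an n x 2
#'   matrix of (x, y) pixel coordinates with n >= 3.
#' @param shape integer length-2: rows, cols of the target mask.
#' @return integer label matrix (0 background, 1 OC, 2 ICA, 3 SS).
#' @export
polygonsToMask <- function(polys, shape) {
  labelCode <- c(OC = 1L, ICA = 2L, SS = 3L)
  mask <- matrix(0L, shape[1], shape[2])
  px <- rep(seq_len(shape[2]) - 0.5, each = shape[1])
  py <- rep(seq_len(shape[1]) - 0.5, times = shape[2])
  for (p in polys) {
    v <- p$vertices
    if (is.null(dim(v)) || nrow(v) < 3L)
      stop("degenerate polygon: need at least 3 vertices")
    if (!p$label %in% names(labelCode))
      stop("unknown polygon label: ", p$label)
    sel <- .pointsInPolygon(px, py, v[, 1], v[, 2])  # column-major order
    mask[sel] <- labelCode[[p$label]]
  }
  mask
}

#' Read a polygon-annotation JSON file
#'
#' A LabelMe-style dialect: top-level \code{shapes}, each with \code{label}
#' and \code{points} (list of [x, y] pixel coordinates), plus
#' \code{imageHeight}/\code{imageWidth}.
#'
#' @param path file path.
#' @return list with \code{polys} (as for \code{\link{polygonsToMask}}) and
#'   \code{shape}.
#' @export
readPolygons <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  polys <- lapply(j$shapes, function(s)
    list(label = s$label,
         vertices = do.call(rbind, lapply(s$points, unlist))))
  list(polys = polys, shape = c(j$imageHeight, j$imageWidth))
}

#' @rdname imageIO
#' @export
writeImage <- function(image, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    q <- floor(pmin(pmax(image, 0), 1) * 255 + 0.5) / 255  # round half up
    png::writePNG(q, path)
  } else if (ext %in% c("nii", "gz")) {
    RNifti::writeNifti(RNifti::asNifti(image), path)
  } else stop("unsupported image extension: ", ext)
  invisible(path)
}

#' Image and mask input/output
#'
#' 8-bit grayscale PNG (intensities quantized by round-half-up to 1/255
#' steps) or single-slice NIfTI for images; masks are stored as 8-bit PNGs
#' whose gray value is the integer class code, giving bit-identical round
#' trips.
#'
#' @param image numeric matrix in [0,1].
#' @param mask integer label matrix (codes 0-255).
#' @param path file path; extension selects the format (\code{.png},
#'   \code{.nii}/\code{.nii.gz}).
#' @return readers return the matrix; writers the path, invisibly.
#' @name imageIO
#' @export
readImage <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) img <- img[, , 1]
    img
  } else if (ext %in% c("nii", "gz")) {
    m <- as.array(RNifti::readNifti(path))
    matrix(m, dim(m)[1], dim(m)[2])
  } else stop("unsupported image extension: ", ext)
}

#' @rdname imageIO
#' @export
writeMask <- function(mask, path) {
  if (tolower(tools::file_ext(path)) != "png") stop("masks are written as PNG")
  png::writePNG(mask / 255, path)
  invisible(path)
}

#' @rdname imageIO
#' @export
readMask <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
}

#' Write a metrics report to JSON or CSV
#'
#' Reports carry the payload plus a config hash, the seed and the package
#' version.  \code{readReport} restores the JSON form.
#'
#' @param report a \linkS4class{SegReport}, data.frame or plain list.
#' @param path output path (\code{.json} or \code{.csv}).
#' @param config object hashed into the report for provenance.
#' @param seed integer recorded with the report.
#' @return invisibly, the path.
#' @export
writeReport <- function(report, path, config = NULL, seed = NA_integer_) {
  ext <- tolower(tools::file_ext(path))
  payload <- if (methods::is(report, "SegReport"))
    list(perClass = as.data.frame(report@perClass), mIoU = report@mIoU,
         mDice = report@mDice, includeBackground = report@includeBackground,
         k = report@k)
  else report
  if (ext == "json") {
    jsonlite::write_json(list(report = payload,
                              configHash = .hashConfig(config),
                              seed = seed,
                              version = as.character(packageVersion("apexseg"))),
                         path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else if (ext == "csv") {
    df <- if (is.data.frame(payload)) payload else
      if (!is.null(payload$perClass)) payload$perClass else as.data.frame(payload)
    write.csv(df, path, row.names = FALSE)
  } else stop("unsupported report extension: ", ext)
  invisible(path)
}

#' @rdname writeReport
#' @export
readReport <- function(path) jsonlite::fromJSON(path)

#' Write a phantom dataset to disk
#'
#' Emits, per slice, an 8-bit PNG image, a class-code mask PNG and a YOLO
#' box file, plus a JSON manifest listing file paths, per-slice seeds,
#' split membership and the category table.
#'
#' @param dataset list with \code{train}/\code{test} from
#'   \code{\link{generateDataset}}.
#' @param dir output directory (created).
#' @param config the \linkS4class{PhantomConfig} used (hashed into the
#'   manifest).
#' @return invisibly, the manifest path.
#' @export
writePhantomDataset <- function(dataset, dir, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(categories = boxCategories(),
                   configHash = .hashConfig(config), splits = list())
  for (split in c("train", "test")) {
    entries <- lapply(seq_along(dataset[[split]]), function(i) {
      sl <- dataset[[split]][[i]]
      stem <- sprintf("%s_%04d", split, i)
      writeImage(sl@image, file.path(dir, paste0(stem, ".png")))
      writeMask(sl@mask, file.path(dir, paste0(stem, "_mask.png")))
      writeYolo(sl@boxes, file.path(dir, paste0(stem, ".txt")))
      list(image = paste0(stem, ".png"), mask = paste0(stem, "_mask.png"),
           boxes = paste0(stem, ".txt"), seed = sl@seedUsed)
    })
    manifest$splits[[split]] <- entries
  }
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
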