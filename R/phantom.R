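# Synthetic orbital-apex phantom generator.
#
# A slice is built from closed-form geometry primitives, one triple per side:
# sphenoid-sinus ellipse (air, dark), internal-carotid-artery disc (contrast,
# bright) touching the sinus lateral border, optic-canal ring (bone) placed
# superior-lateral to the sinus.  A fracture lesion is a gap cut into the
# ring plus a displaced bone fragment.  All randomness is drawn under a
# derived seed, so slices are pure functions of (config, seed).

.pixelGrid <- function(S) {
  # pixel-center coordinates, 0-based, origin top-left, x right / y down
  list(X = matrix(rep(seq_len(S) - 0.5, each = S), S, S),
       Y = matrix(rep(seq_len(S) - 0.5, times = S), S, S))
}

.inEllipse <- function(X, Y, cx, cy, rx, ry)
  ((X - cx) / rx)^2 + ((Y - cy) / ry)^2 <= 1

.inDisc <- function(X, Y, cx, cy, r) (X - cx)^2 + (Y - cy)^2 <= r^2

.inRing <- function(X, Y, cx, cy, rOut, rIn) {
  d2 <- (X - cx)^2 + (Y - cy)^2
  d2 <= rOut^2 & d2 >= rIn^2
}

.inRect <- function(X, Y, cx, cy, hx, hy) abs(X - cx) <= hx & abs(Y - cy) <= hy

.angDist <- function(a, b) {
  d <- abs((a - b) %% (2 * pi))
  pmin(d, 2 * pi - d)
}

# Draw the three primitives of one side; returns the primitive parameters.
# Randomness: a fixed number of draws per side regardless of fracture outcome.
.sidePrimitives <- function(S, u, side, fractureProb) {
  sgn <- if (side == "R") -1 else 1   # lateral direction (radiological layout)
  cx0 <- S / 2 + sgn * 14 * u + runif(1, -u, u)
  sy <- S / 2 + 6 * u + runif(1, -u, u)
  rx <- 7 * u * runif(1, 0.85, 1.15)
  ry <- 9 * u * runif(1, 0.85, 1.15)
  ri <- 3.5 * u * runif(1, 0.9, 1.1)
  icx <- cx0 + sgn * (rx + 0.8 * ri)
  icy <- sy + runif(1, -u, u)
  ocx <- cx0 + sgn * 4 * u + runif(1, -u, u)
  ocy <- sy - ry - 5.5 * u + runif(1, -u, u)
  rOut <- 5.5 * u + runif(1, 0, u)
  rIn <- rOut - 2.5 * u
  fracture <- runif(1) < fractureProb
  gapAngle <- runif(1, 0, 2 * pi)
  rMid <- (rOut + rIn) / 2
  gapHalf <- max(1.25 / rMid, 0.35)   # arc >= ~2.5 px at the mid radius
  fragDist <- rOut + u + runif(1, 0, 0.5 * u)
  frag <- list(cx = ocx + fragDist * cos(gapAngle),
               cy = ocy + fragDist * sin(gapAngle),
               hx = 1.6 * u, hy = 0.9 * u)
  list(side = side,
       sinus = list(cx = cx0, cy = sy, rx = rx, ry = ry),
       ica = list(cx = icx, cy = icy, r = ri),
       canal = list(cx = ocx, cy = ocy, rOut = rOut, rIn = rIn,
                    fracture = fracture, gapAngle = gapAngle,
                    gapHalf = gapHalf,
                    fragment = if (fracture) frag else NULL))
}

.checkBounds <- function(prims, S, u) {
  lim <- function(x, r) x - r < 1 || x + r > S - 1
  fragReach <- 3.2 * u    # max fragment displacement + half-extent
  for (p in prims) {
    si <- p$sinus; ic <- p$ica; oc <- p$canal
    bad <- lim(si$cx, si$rx) || lim(si$cy, si$ry) ||
      lim(ic$cx, ic$r) || lim(ic$cy, ic$r) ||
      lim(oc$cx, oc$rOut + fragReach) || lim(oc$cy, oc$rOut + fragReach)
    if (bad)
      stop("imageSize too small to place all orbital-apex structures; ",
           "use at least 32 px")
  }
  invisible(TRUE)
}

# Rasterize one side's primitives onto class masks.  Returns logical layers.
.rasterizeSide <- function(p, grid) {
  X <- grid$X; Y <- grid$Y
  ss <- .inEllipse(X, Y, p$sinus$cx, p$sinus$cy, p$sinus$rx, p$sinus$ry)
  ica <- .inDisc(X, Y, p$ica$cx, p$ica$cy, p$ica$r)
  oc <- .inRing(X, Y, p$canal$cx, p$canal$cy, p$canal$rOut, p$canal$rIn)
  if (p$canal$fracture) {
    ang <- atan2(Y - p$canal$cy, X - p$canal$cx)
    oc <- oc & .angDist(ang, p$canal$gapAngle) > p$canal$gapHalf
    fr <- p$canal$fragment
    oc <- oc | .inRect(X, Y, fr$cx, fr$cy, fr$hx, fr$hy)
  }
  list(ss = ss, ica = ica, oc = oc)
}

.sideBox <- function(ocLayer, S, margin = 2L) {
  w <- which(ocLayer, arr.ind = TRUE)
  # half-open 0-based pixel extents [x0, x1) x [y0, y1)
  x0 <- max(0L, min(w[, 2]) - 1L - margin)
  x1 <- min(S, max(w[, 2]) + margin)
  y0 <- max(0L, min(w[, 1]) - 1L - margin)
  y1 <- min(S, max(w[, 1]) + margin)
  c(x0 = x0, y0 = y0, x1 = x1, y1 = y1)
}

#' Generate one synthetic orbital-apex slice
#'
#' Draws, per side and in order, a sphenoid-sinus ellipse, an adjacent
#' internal-carotid-artery disc touching the sinus lateral border, and a
#' small optic-canal ring superior-lateral to the sinus; with probability
#' \code{fractureProb*} a fracture (ring gap plus displaced fragment) is cut
#' into the canal and that side's box category becomes \code{Fracture},
#' otherwise \code{Non-fracture}.  The call is a pure function of
#' \code{(config, seed)}.
#'
#' @param config a \linkS4class{PhantomConfig}.
#' @param seed integer; defaults to the config's seed.
#' @return A \linkS4class{PhantomSlice}.
#' @export
#' @examples
#' sl <- generateSlice(phantomConfig(), seed = 7)
#' sl
generateSlice <- function(config, seed = config@seed) {
  validObject(config)
  S <- config@imageSize
  u <- S / 64
  lv <- config@intensityLevels
  .withSeed(.deriveSeed(seed, 0L), {
    prims <- list(R = .sidePrimitives(S, u, "R", config@fractureProbRight),
                  L = .sidePrimitives(S, u, "L", config@fractureProbLeft))
    .checkBounds(prims, S, u)
    grid <- .pixelGrid(S)
    mask <- matrix(0L, S, S)
    img <- matrix(lv[["background"]], S, S)
    ocSides <- list()
    for (side in c("R", "L")) {
      lay <- .rasterizeSide(prims[[side]], grid)
      # draw order: sinus, then artery, then canal (later overwrites earlier)
      mask[lay$ss] <- 3L; img[lay$ss] <- lv[["SS"]]
      mask[lay$ica] <- 2L; img[lay$ica] <- lv[["ICA"]]
      mask[lay$oc] <- 1L; img[lay$oc] <- lv[["OC"]]
      ocSides[[side]] <- lay$oc
    }
    # the artery or sinus of one side never overlaps the other side's canal,
    # but re-assert class consistency of the recorded canal layers
    for (side in c("R", "L")) ocSides[[side]] <- ocSides[[side]] & mask == 1L
    # class-specific texture gratings
    if (config@textureContrast > 0) {
      classes <- c(background = 0L, OC = 1L, ICA = 2L, SS = 3L)
      for (nm in names(config@textureFreq)) {
        f <- config@textureFreq[[nm]]
        phase <- runif(1, 0, 2 * pi)
        sel <- mask == classes[[nm]]
        img[sel] <- img[sel] + config@textureContrast * 0.5 *
          sin(2 * pi * (f[1] * grid$X[sel] + f[2] * grid$Y[sel]) + phase)
      }
    }
    if (config@noiseSd > 0)
      img <- img + matrix(rnorm(S * S, sd = config@noiseSd), S, S)
    img <- pmin(pmax(img, 0), 1)
    boxes <- do.call(rbind, lapply(c("R", "L"), function(side) {
      b <- .sideBox(ocSides[[side]], S)
      cat <- paste0(if (prims[[side]]$canal$fracture) "Fracture" else "Non-fracture",
                    "(", side, ")")
      data.frame(category = cat, x0 = b["x0"], y0 = b["y0"], x1 = b["x1"],
                 y1 = b["y1"],
                 cx = (b["x0"] + b["x1"]) / 2 / S, cy = (b["y0"] + b["y1"]) / 2 / S,
                 w = (b["x1"] - b["x0"]) / S, h = (b["y1"] - b["y0"]) / S,
                 stringsAsFactors = FALSE)
    }))
    rownames(boxes) <- NULL
    new("PhantomSlice", image = img, mask = mask, boxes = boxes,
        primitives = prims, seedUsed = as.integer(seed))
  })
}

#' Generate a seeded phantom dataset with a train/test split
#'
#' Slices get disjoint per-slice seeds derived from the master seed; split
#' membership is a seeded permutation.  The default split ratio is 8:2.
#'
#' @param n number of slices (>= 0).
#' @param config a \linkS4class{PhantomConfig}.
#' @param seed master seed.
#' @param splitRatio training fraction in (0,1); \code{|train| =
#'   round(n * splitRatio)}.
#' @return list with elements \code{train} and \code{test}, each a list of
#'   \linkS4class{PhantomSlice}.
#' @export
generateDataset <- function(n, config, seed = config@seed, splitRatio = 0.8) {
  stopifnot(n >= 0, splitRatio > 0, splitRatio < 1)
  if (n == 0) return(list(train = list(), test = list()))
  slices <- lapply(seq_len(n), function(i)
    generateSlice(config, seed = .deriveSeed(seed, i)))
  nTrain <- round(n * splitRatio)
  perm <- .withSeed(.deriveSeed(seed, n + 1L), sample.int(n))
  list(train = slices[perm[seq_len(nTrain)]],
       test = slices[perm[setdiff(seq_len(n), seq_len(nTrain))]])
}

.AUG_OPS <- c("resize", "flip", "normalize", "pad", "rotate", "crop",
              "intensity_shift", "noise")

.rot90cw <- function(m) t(m[nrow(m):1, , drop = FALSE])

.nnResize <- function(m, S2) {
  S <- nrow(m)
  idx <- pmin(S, floor((seq_len(S2) - 0.5) * S / S2) + 1L)
  m[idx, idx, drop = FALSE]
}

.nnRotate <- function(m, angle, fill) {
  S <- nrow(m)
  cx <- S / 2
  th <- angle * pi / 180
  g <- .pixelGrid(S)
  # inverse map: sample source at the back-rotated pixel center
  xs <- cos(-th) * (g$X - cx) - sin(-th) * (g$Y - cx) + cx
  ys <- sin(-th) * (g$X - cx) + cos(-th) * (g$Y - cx) + cx
  rs <- floor(ys) + 1L
  cs <- floor(xs) + 1L
  out <- matrix(fill, S, S)
  ok <- rs >= 1L & rs <= S & cs >= 1L & cs <= S
  out[ok] <- m[cbind(rs[ok], cs[ok])]
  out
}

#' Apply seeded augmentations to an image/mask pair
#'
#' Geometric ops (\code{resize}, \code{flip}, \code{pad}, \code{rotate},
#' \code{crop}) apply identically to image and mask (mask via nearest
#' neighbor); intensity ops (\code{normalize}, \code{intensity_shift},
#' \code{noise}) touch the image only.  The result is deterministic per
#' seed.  Rotations by multiples of 90 degrees are exact pixel permutations.
#'
#' @param image numeric matrix in [0,1].
#' @param mask integer matrix of identical shape.
#' @param ops character vector of op names, applied in order.
#' @param seed integer.
#' @param params optional list of fixed op parameters: \code{resize_size},
#'   \code{flip_axis} ("h"/"v"), \code{pad_px}, \code{rotate_angle} degrees,
#'   \code{crop_frac}, \code{shift}, \code{noise_sd}.  Unset parameters are
#'   sampled from the seeded stream.
#' @return list with elements \code{image} and \code{mask}.
#' @export
augment <- function(image, mask, ops, seed = 1L, params = list()) {
  stopifnot(identical(dim(image), dim(mask)))
  unknown <- setdiff(ops, .AUG_OPS)
  if (length(unknown))
    stop("unknown augmentation op(s): ", paste(unknown, collapse = ", "))
  .withSeed(.deriveSeed(seed, 101L), {
    for (op in ops) {
      S <- nrow(image)
      switch(op,
        resize = {
          S2 <- params$resize_size %||% round(S * runif(1, 0.75, 1.25))
          image <- .nnResize(image, S2)
          mask <- .nnResize(mask, S2)
        },
        flip = {
          ax <- params$flip_axis %||% sample(c("h", "v"), 1)
          if (ax == "h") { image <- image[, ncol(image):1]; mask <- mask[, ncol(mask):1] }
          else { image <- image[nrow(image):1, ]; mask <- mask[nrow(mask):1, ] }
        },
        normalize = {
          rg <- range(image)
          if (rg[2] > rg[1]) image <- (image - rg[1]) / (rg[2] - rg[1])
        },
        pad = {
          p <- params$pad_px %||% 4L
          im2 <- matrix(0, S + 2 * p, ncol(image) + 2 * p)
          mk2 <- matrix(0L, S + 2 * p, ncol(mask) + 2 * p)
          im2[p + seq_len(S), p + seq_len(ncol(image))] <- image
          mk2[p + seq_len(S), p + seq_len(ncol(mask))] <- mask
          image <- im2; mask <- mk2
        },
        rotate = {
          ang <- params$rotate_angle %||% sample(c(90, 180, 270), 1)
          if (ang %% 90 == 0) {
            k <- (ang / 90) %% 4
            for (i in seq_len(k)) { image <- .rot90cw(image); mask <- .rot90cw(mask) }
          } else {
            image <- .nnRotate(image, ang, fill = 0)
            mask <- .nnRotate(mask, ang, fill = 0L)
          }
        },
        crop = {
          fr <- params$crop_frac %||% 0.8
          S2 <- max(2L, round(S * fr))
          r0 <- sample.int(S - S2 + 1L, 1)
          c0 <- sample.int(ncol(image) - S2 + 1L, 1)
          image <- image[r0:(r0 + S2 - 1L), c0:(c0 + S2 - 1L)]
          mask <- mask[r0:(r0 + S2 - 1L), c0:(c0 + S2 - 1L)]
        },
        intensity_shift = {
          d <- params$shift %||% runif(1, -0.1, 0.1)
          image <- pmin(pmax(image + d, 0), 1)
        },
        noise = {
          sd <- params$noise_sd %||% 0.02
          image <- pmin(pmax(image + matrix(rnorm(length(image), sd = sd),
                                            nrow(image)), 0), 1)
        })
    }
    list(image = image, mask = mask)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Transform pixel-extent boxes under a flip or right-angle rotation
#'
#' Applies the same geometric transform \code{\link{augment}} applies to the
#' raster, to half-open pixel-extent boxes, so box/mask consistency can be
#' preserved (and checked) under geometric augmentation.
#'
#' @param boxes data.frame with columns \code{x0,y0,x1,y1} (and optionally
#'   the normalized forms, which are recomputed).
#' @param op \code{"flip"} or \code{"rotate"}.
#' @param size image side in pixels.
#' @param params list: \code{flip_axis} ("h"/"v") or \code{rotate_angle}
#'   (multiple of 90).
#' @return The transformed boxes data.frame.
#' @export
augmentBoxes <- function(boxes, op, size, params = list()) {
  b <- boxes
  if (op == "flip") {
    ax <- params$flip_axis %||% "h"
    if (ax == "h") { x0 <- size - b$x1; b$x1 <- size - b$x0; b$x0 <- x0 }
    else { y0 <- size - b$y1; b$y1 <- size - b$y0; b$y0 <- y0 }
  } else if (op == "rotate") {
    ang <- (params$rotate_angle %||% 90) %% 360
    stopifnot(ang %% 90 == 0)
    for (i in seq_len(ang / 90)) {
      # matches .rot90cw: (x, y) -> (size - y, x)
      x0 <- size - b$y1; x1 <- size - b$y0
      y0 <- b$x0; y1 <- b$x1
      b$x0 <- x0; b$x1 <- x1; b$y0 <- y0; b$y1 <- y1
    }
  } else stop("augmentBoxes supports flip and right-angle rotate only")
  b$cx <- (b$x0 + b$x1) / 2 / size; b$cy <- (b$y0 + b$y1) / 2 / size
  b$w <- (b$x1 - b$x0) / size; b$h <- (b$y1 - b$y0) / size
  b
}
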