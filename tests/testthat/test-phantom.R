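# Phantom generator: determinism, geometry/ground-truth consistency,
# dataset splitting and augmentation algebra.

test_that("slice generation is bit-reproducible under a fixed seed", {
  cfg <- phantomConfig()
  a <- generateSlice(cfg, seed = 7)
  b <- generateSlice(cfg, seed = 7)
  expect_identical(phantomImage(a), phantomImage(b))
  expect_identical(phantomMask(a), phantomMask(b))
  expect_identical(phantomBoxes(a), phantomBoxes(b))
  expect_false(identical(phantomImage(a),
                         phantomImage(generateSlice(cfg, seed = 8))))
})

test_that("zero fracture probability forces Non-fracture categories", {
  cfg <- phantomConfig(fractureProbLeft = 0, fractureProbRight = 0)
  for (s in c(1, 5, 9)) {
    bx <- phantomBoxes(generateSlice(cfg, seed = s))
    expect_true(all(grepl("^Non-fracture", bx$category)))
  }
  cfg1 <- phantomConfig(fractureProbLeft = 1, fractureProbRight = 1)
  bx <- phantomBoxes(generateSlice(cfg1, seed = 3))
  expect_true(all(grepl("^Fracture", bx$category)))
})

test_that("mask contains all three structures on both sides", {
  sl <- generateSlice(phantomConfig(), seed = 7)
  m <- phantomMask(sl)
  mid <- ncol(m) / 2
  for (half in list(seq_len(mid), mid + seq_len(mid))) {
    sub <- m[, half]
    expect_setequal(sort(unique(as.vector(sub))), 0:3)
  }
})

test_that("per-class pixel counts match independent re-rasterization of the primitives", {
  sl <- generateSlice(phantomConfig(), seed = 7)
  m <- phantomMask(sl)
  S <- nrow(m)
  # independent scalar rasterizer over the recorded primitives, honoring
  # the generator's draw order (sinus, artery, canal per side)
  ref <- matrix(0L, S, S)
  for (p in sl@primitives) {
    for (r in seq_len(S)) for (cc in seq_len(S)) {
      x <- cc - 0.5; y <- r - 0.5
      si <- p$sinus
      if (((x - si$cx) / si$rx)^2 + ((y - si$cy) / si$ry)^2 <= 1) ref[r, cc] <- 3L
      ic <- p$ica
      if ((x - ic$cx)^2 + (y - ic$cy)^2 <= ic$r^2) ref[r, cc] <- 2L
      oc <- p$canal
      d2 <- (x - oc$cx)^2 + (y - oc$cy)^2
      inRing <- d2 <= oc$rOut^2 && d2 >= oc$rIn^2
      if (inRing && oc$fracture) {
        ang <- atan2(y - oc$cy, x - oc$cx)
        dd <- abs((ang - oc$gapAngle) %% (2 * pi))
        if (min(dd, 2 * pi - dd) <= oc$gapHalf) inRing <- FALSE
      }
      if (oc$fracture) {
        fr <- oc$fragment
        if (abs(x - fr$cx) <= fr$hx && abs(y - fr$cy) <= fr$hy) inRing <- TRUE
      }
      if (inRing) ref[r, cc] <- 1L
    }
  }
  expect_identical(as.vector(table(factor(m, levels = 0:3))),
                   as.vector(table(factor(ref, levels = 0:3))))
  expect_identical(m, ref)
})

test_that("every optic-canal pixel lies inside its side's box", {
  for (s in c(2, 7, 19)) {
    sl <- generateSlice(phantomConfig(), seed = s)
    m <- phantomMask(sl)
    mid <- ncol(m) / 2
    for (r in seq_len(nrow(phantomBoxes(sl)))) {
      b <- phantomBoxes(sl)[r, ]
      side <- if (grepl("\\(R\\)", b$category)) "R" else "L"
      oc <- which(m == 1L, arr.ind = TRUE)
      oc <- oc[if (side == "R") oc[, 2] <= mid else oc[, 2] > mid, , drop = FALSE]
      x <- oc[, 2] - 0.5; y <- oc[, 1] - 0.5
      expect_true(all(x >= b$x0 & x <= b$x1 & y >= b$y0 & y <= b$y1))
    }
  }
})

test_that("an image too small for the anatomy raises a sizing error", {
  expect_error(phantomConfig(imageSize = 16L), "imageSize")
  cfg <- phantomConfig()
  cfg@imageSize <- 32L   # legal size; shrunken geometry must still fit
  expect_s4_class(generateSlice(cfg, 1), "PhantomSlice")
})

test_that("dataset split sizes follow the 8:2 default and n = 0 is empty", {
  cfg <- phantomConfig()
  ds0 <- generateDataset(0, cfg)
  expect_length(ds0$train, 0)
  expect_length(ds0$test, 0)
  ds <- generateDataset(10, cfg, seed = 4)
  expect_length(ds$train, 8)
  expect_length(ds$test, 2)
  ds2 <- generateDataset(7, cfg, seed = 4, splitRatio = 0.5)
  expect_length(ds2$train, 4)   # round(3.5) -> 4
  expect_length(ds2$test, 3)
})

test_that("different master seeds share no bit-identical slice", {
  cfg <- phantomConfig()
  a <- generateDataset(25, cfg, seed = 1)
  b <- generateDataset(25, cfg, seed = 2)
  ia <- c(a$train, a$test)
  ib <- c(b$train, b$test)
  for (x in ia) for (y in ib)
    expect_false(identical(phantomImage(x), phantomImage(y)))
})

test_that("all four box categories appear in a default 120-slice dataset", {
  ds <- generateDataset(120, phantomConfig(), seed = 5)
  cats <- unique(unlist(lapply(c(ds$train, ds$test),
                               function(s) phantomBoxes(s)$category)))
  expect_setequal(cats, boxCategories()$name)
})

test_that("augment: empty op list is the identity and unknown ops error", {
  sl <- generateSlice(phantomConfig(), seed = 3)
  out <- augment(phantomImage(sl), phantomMask(sl), character(), seed = 1)
  expect_identical(out$image, phantomImage(sl))
  expect_identical(out$mask, phantomMask(sl))
  expect_error(augment(phantomImage(sl), phantomMask(sl), "shear", seed = 1),
               "unknown augmentation")
})

test_that("double flip on a forced axis recovers the original", {
  sl <- generateSlice(phantomConfig(), seed = 3)
  for (ax in c("h", "v")) {
    out <- augment(phantomImage(sl), phantomMask(sl), c("flip", "flip"),
                   seed = 1, params = list(flip_axis = ax))
    expect_identical(out$image, phantomImage(sl))
    expect_identical(out$mask, phantomMask(sl))
  }
})

test_that("right-angle rotation preserves per-class pixel counts exactly", {
  sl <- generateSlice(phantomConfig(), seed = 9)
  out <- augment(phantomImage(sl), phantomMask(sl), "rotate", seed = 1,
                 params = list(rotate_angle = 90))
  expect_identical(table(factor(out$mask, levels = 0:3)),
                   table(factor(phantomMask(sl), levels = 0:3)))
  expect_equal(sum(out$image), sum(phantomImage(sl)))
})

test_that("augmentation is deterministic per seed and seed-sensitive", {
  sl <- generateSlice(phantomConfig(), seed = 3)
  a <- augment(phantomImage(sl), phantomMask(sl), c("rotate", "noise"), seed = 5)
  b <- augment(phantomImage(sl), phantomMask(sl), c("rotate", "noise"), seed = 5)
  expect_identical(a, b)
  c <- augment(phantomImage(sl), phantomMask(sl), c("rotate", "noise"), seed = 6)
  expect_false(identical(a$image, c$image))
})

test_that("intensity ops leave the mask untouched; geometric ops move it identically", {
  sl <- generateSlice(phantomConfig(), seed = 4)
  ii <- augment(phantomImage(sl), phantomMask(sl),
                c("normalize", "intensity_shift", "noise"), seed = 2)
  expect_identical(ii$mask, phantomMask(sl))
  gg <- augment(phantomImage(sl), phantomMask(sl), "crop", seed = 2)
  expect_identical(dim(gg$image), dim(gg$mask))
  expect_lt(nrow(gg$image), nrow(phantomImage(sl)))
})

test_that("canal pixels stay inside identically transformed boxes", {
  sl <- generateSlice(phantomConfig(), seed = 12)
  S <- nrow(phantomMask(sl))
  cases <- list(list(op = "flip", params = list(flip_axis = "h")),
                list(op = "flip", params = list(flip_axis = "v")),
                list(op = "rotate", params = list(rotate_angle = 90)),
                list(op = "rotate", params = list(rotate_angle = 180)),
                list(op = "rotate", params = list(rotate_angle = 270)))
  for (cs in cases) {
    out <- augment(phantomImage(sl), phantomMask(sl), cs$op, seed = 1,
                   params = cs$params)
    bx <- augmentBoxes(phantomBoxes(sl), cs$op, S, cs$params)
    oc <- which(out$mask == 1L, arr.ind = TRUE)
    x <- oc[, 2] - 0.5; y <- oc[, 1] - 0.5
    insideAny <- rep(FALSE, length(x))
    for (r in seq_len(nrow(bx)))
      insideAny <- insideAny |
        (x >= bx$x0[r] & x <= bx$x1[r] & y >= bx$y0[r] & y <= bx$y1[r])
    expect_true(all(insideAny))
  }
})
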