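#' @useDynLib apexseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats rnorm runif t.test
#' @importFrom utils packageVersion read.csv write.csv capture.output
NULL

# Four-category box scheme, fractures first (right/left by patient side).
# This table is the single id <-> name mapping used by every reader/writer.
.CATEGORIES <- c("Fracture(R)", "Fracture(L)", "Non-fracture(R)", "Non-fracture(L)")

#' Bounding-box category table
#'
#' Returns the fixed category-id to category-name mapping used by every
#' annotation reader and writer in the package: ids 0 to 3 name
#' \code{Fracture(R)}, \code{Fracture(L)}, \code{Non-fracture(R)},
#' \code{Non-fracture(L)}.
#'
#' @return A data.frame with columns \code{id} (integer, 0-based) and
#'   \code{name} (character).
#' @export
#' @examples
#' boxCategories()
boxCategories <- function() {
  data.frame(id = 0:3, name = .CATEGORIES, stringsAsFactors = FALSE)
}

.categoryId <- function(name) {
  id <- match(name, .CATEGORIES) - 1L
  if (anyNA(id)) stop("unknown box category: ", paste(name[is.na(id)], collapse = ", "))
  id
}

.categoryName <- function(id) {
  if (any(id < 0L | id > 3L)) stop("category id out of range [0,3]")
  .CATEGORIES[id + 1L]
}

.categorySide <- function(name) ifelse(grepl("\\(R\\)$", name), "R", "L")
.categoryIsFracture <- function(name) grepl("^Fracture", name)

# Deterministic child seeds kept below 2^31 (R integers are 32-bit).
.deriveSeed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + as.double(i) * 16807) %% 2147483629)
}

.hashConfig <- function(x) rlang::hash(x)

# Reusable im2col column buffers, keyed by layer id and shape.  Avoids
# re-allocating (and re-faulting) the large patch matrices on every batch;
# a buffer is only valid until the same layer's next forward pass, which
# matches the forward-then-backward call pattern of the training loop.
.bufPool <- new.env(parent = emptyenv())

.im2colBuf <- function(key, x, k) {
  if (is.null(key)) return(.im2col_nn(x, k))
  d <- dim(x)
  nr <- d[1] * d[2] * d[3]
  nc <- k * k * d[4]
  id <- paste0(key, "|", nr, "x", nc)
  buf <- .bufPool[[id]]
  if (is.null(buf)) {
    buf <- matrix(0, nr, nc)
    .bufPool[[id]] <- buf
  }
  .im2col_into_nn(buf, x, k)
}

# Stable local RNG scope: runs expr under a derived seed and restores the
# caller's RNG state afterwards.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
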