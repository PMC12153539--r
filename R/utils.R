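#' @importFrom rlang %||% abort
#' @importFrom stats runif rnorm rpois quantile setNames
#' @importFrom utils head tail
NULL

CLASS_LEVELS <- c("benign", "metastatic")

# numerically stable softmax
softmax <- function(x) {
  z <- exp(x - max(x))
  z / sum(z)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Area-average (block mean) downsampling of a matrix
#'
#' Averages non-overlapping `f` x `f` blocks. Trailing rows/columns that do
#' not fill a complete block are discarded, so the output has dimensions
#' `floor(dim/f)`.
#'
#' @param m numeric matrix.
#' @param f integer downsample factor (>= 1).
#' @return matrix of block means.
#' @keywords internal
block_mean <- function(m, f) {
  f <- as.integer(f)
  if (f < 1) abort("downsample factor must be >= 1")
  if (f == 1L) return(m)
  nr <- (nrow(m) %/% f) * f
  nc <- (ncol(m) %/% f) * f
  if (nr < f || nc < f) abort("matrix smaller than one block")
  m <- m[seq_len(nr), seq_len(nc), drop = FALSE]
  dim(m) <- c(f, nr %/% f, nc)
  a <- colMeans(m)                      # (nr/f) x nc
  a <- t(a)
  dim(a) <- c(f, nc %/% f, nr %/% f)
  t(colMeans(a))                        # (nr/f) x (nc/f)
}

# block mean applied to each channel of an H x W x 3 array
block_mean_rgb <- function(arr, f) {
  if (f == 1L) return(arr)
  ch <- lapply(1:3, function(k) block_mean(arr[, , k], f))
  out <- array(0, c(dim(ch[[1]]), 3))
  for (k in 1:3) out[, , k] <- ch[[k]]
  out
}

# vectorised HSV -> RGB (h, s, v in [0, 1]); returns list(r, g, b)
hsv_to_rgb_vec <- function(h, s, v) {
  h6 <- (h %% 1) * 6
  i <- floor(h6)
  f <- h6 - i
  p <- v * (1 - s)
  q <- v * (1 - s * f)
  t <- v * (1 - s * (1 - f))
  r <- g <- b <- numeric(length(h))
  idx <- i %% 6
  sel <- idx == 0; r[sel] <- v[sel]; g[sel] <- t[sel]; b[sel] <- p[sel]
  sel <- idx == 1; r[sel] <- q[sel]; g[sel] <- v[sel]; b[sel] <- p[sel]
  sel <- idx == 2; r[sel] <- p[sel]; g[sel] <- v[sel]; b[sel] <- t[sel]
  sel <- idx == 3; r[sel] <- p[sel]; g[sel] <- q[sel]; b[sel] <- v[sel]
  sel <- idx == 4; r[sel] <- t[sel]; g[sel] <- p[sel]; b[sel] <- v[sel]
  sel <- idx == 5; r[sel] <- v[sel]; g[sel] <- p[sel]; b[sel] <- q[sel]
  list(r = r, g = g, b = b)
}

# per-pixel HSV saturation of an H x W x 3 array in [0, 1]
saturation_of <- function(arr) {
  mx <- pmax(arr[, , 1], arr[, , 2], arr[, , 3])
  mn <- pmin(arr[, , 1], arr[, , 2], arr[, , 3])
  s <- ifelse(mx > 0, 1 - mn / mx, 0)
  matrix(s, nrow(arr[, , 1]), ncol(arr[, , 1]))
}

# validate a class-label vector, returning a character vector
check_labels <- function(x, arg = "labels") {
  x <- as.character(x)
  bad <- setdiff(unique(x), CLASS_LEVELS)
  if (length(bad) > 0) {
    abort(sprintf("%s must be in {%s}; found: %s", arg,
                  paste(CLASS_LEVELS, collapse = ", "),
                  paste(bad, collapse = ", ")))
  }
  x
}

# sample one element of a vector, safe against R's scalar-sample() surprise
sample_one <- function(x) if (length(x) == 1L) x else sample(x, 1L)

# derive a stream of independent sub-seeds from one master seed
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, n))
}
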