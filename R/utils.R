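`%||%` <- function(a, b) if (is.null(a)) b else a

# run code with a temporary RNG seed, restoring the caller's stream
local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483562L))
  force(code)
}

# derive a reproducible sub-seed below 2^31 from a base seed and stream index
sub_seed <- function(seed, index, stream = 0L) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 16807 +
                as.double(stream) * 69621) %% 2147483562)
}

clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

stopifnot_image <- function(a, b = NULL) {
  if (!is.matrix(a) || !is.numeric(a)) stop("expected a numeric matrix image")
  if (!is.null(b)) {
    if (!is.matrix(b) || !is.numeric(b)) stop("expected a numeric matrix image")
    if (!identical(dim(a), dim(b))) stop("image shape mismatch: ",
                                         paste(dim(a), collapse = "x"), " vs ",
                                         paste(dim(b), collapse = "x"))
  }
  invisible(TRUE)
}

# promote a matrix (H x W) or (H x W x C) array to the internal (H, W, C, N)
# batch layout
as_batch <- function(x) {
  if (is.matrix(x)) return(array(x, c(dim(x), 1L, 1L)))
  d <- dim(x)
  if (length(d) == 3L) return(array(x, c(d, 1L)))
  if (length(d) == 4L) return(x)
  stop("cannot interpret input of dimensionality ", length(d), " as a feature map")
}

batch_from_images <- function(imgs) {
  d <- dim(imgs[[1]])
  out <- array(0, c(d[1], d[2], 1L, length(imgs)))
  for (i in seq_along(imgs)) out[, , 1L, i] <- imgs[[i]]
  out
}
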