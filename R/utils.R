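# Internal array morphology helpers. All operate on logical 3-D (or 2-D)
# arrays, treating everything outside the grid as FALSE.

# shift a logical array by +1/-1 along one axis, filling with FALSE
shift_logical <- function(m, by, axis) {
  d <- dim(m)
  out <- array(FALSE, d)
  n <- d[axis]
  if (n <= 1L && abs(by) >= n) return(out)
  src <- lapply(d, seq_len)
  dst <- src
  if (by > 0) {
    dst[[axis]] <- seq.int(1L + by, n)
    src[[axis]] <- seq.int(1L, n - by)
  } else {
    dst[[axis]] <- seq.int(1L, n + by)
    src[[axis]] <- seq.int(1L - by, n)
  }
  out <- do.call(`[<-`, c(list(out), dst, list(do.call(`[`, c(list(m), src)))))
  out
}

# dilation by the 6-connected cross (digital ball, radius 1 voxel)
dilate_cross <- function(m) {
  out <- m
  for (ax in seq_along(dim(m))) {
    out <- out | shift_logical(m, 1L, ax) | shift_logical(m, -1L, ax)
  }
  out
}

# erosion by the same structuring element (outside the grid counts as FALSE)
erode_cross <- function(m) {
  out <- m
  for (ax in seq_along(dim(m))) {
    out <- out & shift_logical(m, 1L, ax) & shift_logical(m, -1L, ax)
  }
  out
}

# one binary closing pass (dilate then erode), radius-1 ball
binary_close <- function(m) erode_cross(dilate_cross(m))

# dilation by the full 3^k box = 26-connectivity neighbourhood in 3-D
# (separable: dilate along each axis in turn)
dilate_box <- function(m) {
  out <- m
  for (ax in seq_along(dim(m))) {
    out <- out | shift_logical(out, 1L, ax) | shift_logical(out, -1L, ax)
  }
  out
}

# geodesic region growing: connected component of `candidate` containing the
# seed voxel(s), under 26- (box) or 6- (cross) connectivity
grow_from_seed <- function(candidate, seed_index, connectivity = 26L) {
  stopifnot(connectivity %in% c(6L, 26L))
  dil <- if (connectivity == 26L) dilate_box else dilate_cross
  region <- array(FALSE, dim(candidate))
  region[matrix(seed_index, nrow = 1L)] <- TRUE
  if (!candidate[matrix(seed_index, nrow = 1L)]) return(region & FALSE)
  repeat {
    grown <- dil(region) & candidate
    if (sum(grown) == sum(region)) break
    region <- grown
  }
  region
}

# label all connected components of a logical array; returns a list of
# logical masks, largest first
label_components <- function(m, connectivity = 26L) {
  comps <- list()
  remaining <- m
  while (any(remaining)) {
    seed <- arrayInd(which(remaining)[1L], dim(m))
    comp <- grow_from_seed(remaining, as.integer(seed), connectivity)
    comps[[length(comps) + 1L]] <- comp
    remaining <- remaining & !comp
  }
  if (length(comps) > 1L)
    comps <- comps[order(vapply(comps, sum, numeric(1)), decreasing = TRUE)]
  comps
}

# crop a volume's candidate region to its bounding box (with margin) before
# region growing; returns list(sub, offset) where offset maps back
bounding_box <- function(mask, margin = 1L) {
  idx <- which(mask)
  if (length(idx) == 0L) return(NULL)
  ai <- arrayInd(idx, dim(mask))
  lo <- pmax(1L, apply(ai, 2, min) - margin)
  hi <- pmin(dim(mask), apply(ai, 2, max) + margin)
  list(lo = lo, hi = hi)
}

# run code with a temporary RNG seed, restoring the caller's RNG state
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

mm3_to_ml <- function(x) x / 1000
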