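# Internal helpers shared across modules.

# Evaluate expr with a locally seeded RNG, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Symmetric (half-sample) reflection padding by r pixels on every side.
.padReflect <- function(m, r) {
  stopifnot(r < nrow(m), r < ncol(m))
  idr <- c(seq(r, 1L), seq_len(nrow(m)), seq(nrow(m), nrow(m) - r + 1L))
  idc <- c(seq(r, 1L), seq_len(ncol(m)), seq(ncol(m), ncol(m) - r + 1L))
  m[idr, idc, drop = FALSE]
}

# Sliding w x w window sums via an integral image; returns a matrix of size
# (nrow(m) - w + 1) x (ncol(m) - w + 1).
.boxSum <- function(m, w) {
  S <- rbind(0, apply(m, 2L, cumsum))
  S <- cbind(0, t(apply(S, 1L, cumsum)))
  nr <- nrow(m); nc <- ncol(m)
  i2 <- (w + 1L):(nr + 1L); i1 <- 1L:(nr - w + 1L)
  j2 <- (w + 1L):(nc + 1L); j1 <- 1L:(nc - w + 1L)
  S[i2, j2] + S[i1, j1] - S[i1, j2] - S[i2, j1]
}

# Binary dilation of a logical matrix with a (2r+1)^2 square structuring
# element (zero padding at the border).
.dilateSquare <- function(mask, r) {
  if (r < 1L) return(mask)
  w <- 2L * r + 1L
  p <- matrix(0, nrow(mask) + 2L * r, ncol(mask) + 2L * r)
  p[(r + 1L):(r + nrow(mask)), (r + 1L):(r + ncol(mask))] <- mask
  .boxSum(p, w) > 0
}

# Binary erosion with the same square element (frame borders are preserved:
# only boundaries interior to the frame are eroded).
.erodeSquare <- function(mask, r) {
  if (r < 1L) return(mask)
  mask & !.dilateSquare(!mask, r)
}

# Connected-component labels of a logical 2-D or 3-D array under 4-/6-
# connectivity, via igraph components on the voxel adjacency graph.
.labelArray <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  idx <- which(mask)
  if (!length(idx)) return(lab)
  id <- integer(prod(d))
  id[idx] <- seq_along(idx)
  coords <- arrayInd(idx, d)
  strides <- cumprod(c(1L, d[-length(d)]))
  el <- list()
  for (k in seq_along(d)) {
    ok <- coords[, k] < d[k]
    nb <- idx[ok] + strides[k]
    keep <- mask[nb]
    if (any(keep))
      el[[length(el) + 1L]] <- cbind(id[idx[ok][keep]], id[nb[keep]])
  }
  if (length(el)) {
    g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
    g <- igraph::add_edges(g, t(do.call(rbind, el)))
    comp <- igraph::components(g)$membership
  } else {
    comp <- seq_along(idx)
  }
  lab[idx] <- as.integer(comp)
  lab
}
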