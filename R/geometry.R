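#' Minimum-image convention for displacements in an orthorhombic box
#'
#' Maps each displacement component into [-L/2, L/2) for box edge L, i.e.
#' replaces a displacement by the shortest equivalent displacement under
#' periodic boundary conditions.
#'
#' @param v displacement(s): numeric vector of length d, or an n x d matrix.
#' @param box box edge lengths in nm (length d, components > 0).
#' @return object of the same shape as \code{v}.
#' @export
minimum_image <- function(v, box) {
  box <- as.numeric(box)
  if (any(!is.finite(box)) || any(box <= 0))
    stop_ommtraj("box components must be positive and finite",
                 class = "ommtraj_domain_error")
  if (is.matrix(v)) {
    if (ncol(v) != length(box))
      stop_ommtraj("box dimension does not match displacement columns",
                   class = "ommtraj_domain_error")
    b <- matrix(box, nrow(v), ncol(v), byrow = TRUE)
    v - b * floor(v / b + 0.5)
  } else {
    v - box * floor(v / box + 0.5)
  }
}

## wrap absolute coordinates into [0, L)
wrap_coords <- function(x, box) {
  if (is.matrix(x)) {
    b <- matrix(box, nrow(x), ncol(x), byrow = TRUE)
    x - b * floor(x / b)
  } else {
    x - box * floor(x / box)
  }
}

#' All pairs of points within a cutoff under periodic boundary conditions
#'
#' Finds pairs (i from set a, j from set b) with minimum-image distance
#' strictly below \code{cutoff} in an orthorhombic box. The cell-list method
#' bins points into cells of at least the cutoff size and searches the 27
#' neighboring cells; it returns exactly the same pairs as the brute-force
#' all-pairs method and falls back to brute force when the box holds fewer
#' than three cells in any dimension.
#'
#' @param a,b n x 3 coordinate matrices (nm).
#' @param box box edge lengths (nm).
#' @param cutoff distance cutoff (nm).
#' @param method "cell" (default) or "brute".
#' @return data.frame with columns \code{i}, \code{j}, \code{d} (nm).
#' @export
pairs_within <- function(a, b, box, cutoff, method = c("cell", "brute")) {
  method <- match.arg(method)
  if (cutoff <= 0)
    stop_ommtraj("cutoff must be positive", class = "ommtraj_domain_error")
  a <- rbind(a); b <- rbind(b)
  if (nrow(a) == 0L || nrow(b) == 0L)
    return(data.frame(i = integer(), j = integer(), d = numeric()))
  ncell <- pmax(1L, floor(box / cutoff))
  if (method == "cell" && all(ncell >= 3L)) {
    pairs_within_cell(a, b, box, cutoff, ncell)
  } else {
    pairs_within_brute(a, b, box, cutoff)
  }
}

pairs_within_brute <- function(a, b, box, cutoff, chunk = 2e6) {
  na <- nrow(a); nb <- nrow(b)
  rows_per_chunk <- max(1L, floor(chunk / nb))
  out <- vector("list", ceiling(na / rows_per_chunk))
  k <- 0L
  for (start in seq(1L, na, by = rows_per_chunk)) {
    idx <- start:min(start + rows_per_chunk - 1L, na)
    d2 <- matrix(0, length(idx), nb)
    for (dim in 1:3) {
      dx <- outer(a[idx, dim], b[, dim], "-")
      dx <- dx - box[dim] * floor(dx / box[dim] + 0.5)
      d2 <- d2 + dx * dx
    }
    hit <- which(d2 < cutoff^2, arr.ind = TRUE)
    k <- k + 1L
    out[[k]] <- data.frame(i = idx[hit[, 1L]], j = hit[, 2L],
                           d = sqrt(d2[hit]))
  }
  res <- do.call(rbind, out[seq_len(k)])
  res[order(res$i, res$j), , drop = FALSE]
}

pairs_within_cell <- function(a, b, box, cutoff, ncell) {
  cw <- box / ncell                      # cell widths, all >= cutoff
  aw <- wrap_coords(a, box)
  bw <- wrap_coords(b, box)
  cell_idx <- function(x) {
    ix <- pmin(floor(x[, 1] / cw[1]), ncell[1] - 1L)
    iy <- pmin(floor(x[, 2] / cw[2]), ncell[2] - 1L)
    iz <- pmin(floor(x[, 3] / cw[3]), ncell[3] - 1L)
    cbind(ix, iy, iz)
  }
  ca <- cell_idx(aw); cb <- cell_idx(bw)
  key <- function(cx) (cx[, 1] * ncell[2] + cx[, 2]) * ncell[3] + cx[, 3]
  b_by_cell <- split(seq_len(nrow(b)), key(cb))
  offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  acc <- vector("list", nrow(offsets))
  for (o in seq_len(nrow(offsets))) {
    nc <- ca + matrix(offsets[o, ], nrow(ca), 3, byrow = TRUE)
    nc <- nc %% matrix(ncell, nrow(ca), 3, byrow = TRUE)
    hits <- b_by_cell[as.character(key(nc))]
    n_per <- lengths(hits)
    if (sum(n_per) == 0) next
    ii <- rep(seq_len(nrow(a)), n_per)
    jj <- unlist(hits, use.names = FALSE)
    dv <- minimum_image(a[ii, , drop = FALSE] - b[jj, , drop = FALSE], box)
    d2 <- rowSums(dv * dv)
    keep <- d2 < cutoff^2
    acc[[o]] <- data.frame(i = ii[keep], j = jj[keep], d = sqrt(d2[keep]))
  }
  res <- do.call(rbind, acc)
  if (is.null(res))
    return(data.frame(i = integer(), j = integer(), d = numeric()))
  res <- unique(res)                     # cells can repeat when ncell == 3
  res[order(res$i, res$j), , drop = FALSE]
}

## unit vectors, rows of a matrix
normalize_rows <- function(v) {
  n <- sqrt(rowSums(v * v))
  if (any(n == 0))
    stop_ommtraj("zero-length vector cannot be normalized",
                 class = "ommtraj_geometry_error")
  v / n
}
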