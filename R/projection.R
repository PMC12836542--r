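# Best-focus projection: collapse a Z-stack to a single 2D image by copying,
# per tile, the plane that maximizes a sharpness score.

#' Focus metric: variance of the discrete Laplacian
#'
#' Sharpness score of an image tile, computed as the sample variance of the
#' 4-neighbour discrete Laplacian (replicated borders). Zero for a constant
#' tile, invariant to additive intensity offsets, and strictly larger for a
#' sharp edge than for the same edge after Gaussian blur.
#'
#' @param tile non-empty numeric matrix.
#' @return non-negative scalar.
#' @examples
#' focus_metric(matrix(1, 8, 8)) # 0
#' @export
focus_metric <- function(tile) {
  if (!is.matrix(tile) || length(tile) == 0L) stop("tile must be a non-empty matrix")
  if (length(tile) == 1L) return(0)
  L <- .laplacian(tile)
  v <- var(as.vector(L))
  if (is.na(v)) 0 else v
}

# 4-neighbour Laplacian with replicated borders.
.laplacian <- function(m) {
  H <- nrow(m); W <- ncol(m)
  up    <- m[c(1, seq_len(H - 1)), , drop = FALSE]
  down  <- m[c(seq_len(H - 1) + 1, H), , drop = FALSE]
  left  <- m[, c(1, seq_len(W - 1)), drop = FALSE]
  right <- m[, c(seq_len(W - 1) + 1, W), drop = FALSE]
  up + down + left + right - 4 * m
}

# Tile index ranges covering 1..n with width ts (last tile may be short).
.tile_breaks <- function(n, ts) {
  starts <- seq(1L, n, by = ts)
  lapply(starts, function(s) s:min(s + ts - 1L, n))
}

#' Best-focus projection of a Z-stack
#'
#' Partitions the frame into square tiles and copies each output tile from
#' the plane with the highest [focus_metric()] for that tile (ties broken by
#' the lowest plane index). No blending is applied, so every output pixel
#' equals the corresponding pixel of exactly one source plane and the chosen
#' plane per tile is recorded as provenance.
#'
#' @param stack a [zstack()].
#' @param tile_size tile edge in px (>= 8). A tile size larger than the
#'   frame selects one best plane for the whole image.
#' @return an object of class \code{projected_image}: list with \code{image}
#'   (matrix), \code{provenance} (matrix of 0-based plane indices, one per
#'   tile), \code{tile_size}, \code{pixel_size}, \code{well_id}, \code{day}.
#' @export
best_focus_project <- function(stack, tile_size = 32L) {
  stopifnot(inherits(stack, "zstack"))
  tile_size <- as.integer(tile_size)
  if (tile_size < 8L) stop("tile_size must be >= 8 px")
  H <- nrow(stack$planes[[1]]); W <- ncol(stack$planes[[1]])
  n_planes <- length(stack$planes)
  rows <- .tile_breaks(H, tile_size)
  cols <- .tile_breaks(W, tile_size)
  out <- matrix(NA_real_, H, W)
  prov <- matrix(0L, length(rows), length(cols))
  for (i in seq_along(rows)) {
    for (j in seq_along(cols)) {
      if (n_planes == 1L) {
        best <- 1L
      } else {
        scores <- vapply(stack$planes,
                         function(p) focus_metric(p[rows[[i]], cols[[j]], drop = FALSE]),
                         numeric(1))
        best <- which.max(scores)  # which.max takes the first maximum: lowest plane wins ties
      }
      out[rows[[i]], cols[[j]]] <- stack$planes[[best]][rows[[i]], cols[[j]]]
      prov[i, j] <- best - 1L
    }
  }
  structure(list(image = out, provenance = prov, tile_size = tile_size,
                 pixel_size = stack$pixel_size, well_id = stack$well_id,
                 day = stack$day),
            class = "projected_image")
}

#' @export
print.projected_image <- function(x, ...) {
  cat(sprintf("projected_image: %d x %d px, tile %d px, planes used: %s\n",
              nrow(x$image), ncol(x$image), x$tile_size,
              paste(sort(unique(as.vector(x$provenance))), collapse = ",")))
  invisible(x)
}
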