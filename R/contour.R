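#' Extract the ordered contour of a binary mask
#'
#' The contour is the set of foreground pixels having at least one background
#' 4-neighbour (pixels on the image border count their out-of-image side as
#' background). Points are returned ordered by Moore boundary tracing of the
#' outer boundary, starting from the topmost-leftmost foreground pixel.
#' Interior hole boundaries are not traced; masks produced by this package are
#' hole-free single components.
#'
#' @param mask Binary matrix.
#' @return Integer matrix with columns `row`, `col`, one contour point per
#'   row, in boundary order.
#' @export
extract_contour <- function(mask) {
  m <- as_mask(mask)
  pts <- mask_points(m)
  if (nrow(pts) == 0L) abort("empty segmentation")
  if (nrow(pts) == 1L) {
    out <- pts
    colnames(out) <- c("row", "col")
    return(out)
  }
  H <- nrow(m); W <- ncol(m)
  is_fg <- function(r, c) r >= 1 && r <= H && c >= 1 && c <= W && m[r, c] == 1L

  # start: topmost, then leftmost foreground pixel
  start_r <- min(pts[, 1])
  start_c <- min(pts[pts[, 1] == start_r, 2])

  # Moore neighbourhood, clockwise starting from "west"
  nbr <- matrix(c(0, -1, -1, -1, -1, 0, -1, 1, 0, 1, 1, 1, 1, 0, 1, -1),
                ncol = 2, byrow = TRUE)
  trace <- matrix(NA_integer_, nrow = 8L * nrow(pts) + 8L, ncol = 2)
  cur <- c(start_r, start_c)
  trace[1, ] <- cur
  nt <- 1L
  enter <- 1L  # index in nbr of the backtrack direction (came from west)
  repeat {
    found <- FALSE
    for (k in 0:7) {
      idx <- ((enter - 1L + k) %% 8L) + 1L
      cand <- cur + nbr[idx, ]
      if (is_fg(cand[1], cand[2])) {
        # new backtrack: neighbour just before the found one
        enter <- ((idx - 2L) %% 8L) + 1L
        # re-point backtrack relative to the new current pixel
        back <- cur + nbr[enter, ] - cand
        enter <- which(nbr[, 1] == back[1] & nbr[, 2] == back[2])
        cur <- cand
        found <- TRUE
        break
      }
    }
    if (!found) break  # isolated pixel among >1 components
    nt <- nt + 1L
    if (nt > nrow(trace)) break
    trace[nt, ] <- cur
    if (cur[1] == start_r && cur[2] == start_c && nt > 2L) break
  }
  seq_pts <- trace[seq_len(nt), , drop = FALSE]
  seq_pts <- seq_pts[!duplicated(seq_pts), , drop = FALSE]

  # restrict to pixels with a background 4-neighbour, preserving trace order
  keep <- vapply(seq_len(nrow(seq_pts)), function(i) {
    r <- seq_pts[i, 1]; c <- seq_pts[i, 2]
    !is_fg(r - 1, c) || !is_fg(r + 1, c) || !is_fg(r, c - 1) || !is_fg(r, c + 1)
  }, logical(1))
  out <- seq_pts[keep, , drop = FALSE]
  # pixels the outer trace did not reach (other components, hole rims) are
  # appended in scan order so the full 4-boundary set is always returned
  all_b <- contour_points(m)
  seen <- paste(out[, 1], out[, 2])
  rest <- all_b[!paste(all_b[, 1], all_b[, 2]) %in% seen, , drop = FALSE]
  out <- rbind(out, rest)
  colnames(out) <- c("row", "col")
  out
}

# Unordered 4-boundary point set (fast path for metrics).
contour_points <- function(mask) {
  m <- as_mask(mask)
  if (!any(m == 1L)) abort("empty segmentation")
  H <- nrow(m); W <- ncol(m)
  up <- rbind(matrix(0L, 1, W), m[-H, , drop = FALSE])
  dn <- rbind(m[-1, , drop = FALSE], matrix(0L, 1, W))
  lf <- cbind(matrix(0L, H, 1), m[, -W, drop = FALSE])
  rt <- cbind(m[, -1, drop = FALSE], matrix(0L, H, 1))
  boundary <- m == 1L & (up == 0L | dn == 0L | lf == 0L | rt == 0L)
  pts <- which(boundary, arr.ind = TRUE)
  colnames(pts) <- c("row", "col")
  pts
}

# Number of maximal foreground runs in each column (contour crossing count of
# a vertical line is twice this).
column_run_counts <- function(mask) {
  m <- as_mask(mask)
  apply(m, 2, function(col) {
    d <- diff(c(0L, col))
    sum(d == 1L)
  })
}
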