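#' Oriented free-edge reference
#'
#' Represents the wound edge of a scratched monolayer or the sprouting front
#' of a vascular plexus as an oriented polyline. The `inward_side` flag
#' declares on which side of the polyline the free space (the wound, or the
#' avascular tissue ahead of the front) lies, which fixes the 0-degree
#' direction of all polarity angles: 0 degrees points into the free space.
#'
#' Walking the polyline vertex by vertex, `"left"` means the free space lies
#' to the left of the direction of travel (the left normal of a segment with
#' unit tangent `(tx, ty)` is `(-ty, tx)`).
#'
#' @param polyline numeric matrix or data.frame with two columns (x, y) in
#'   micrometres; at least two distinct vertices.
#' @param inward_side `"left"` or `"right"`: side of the polyline on which
#'   the free space lies.
#' @return An object of class `edge_reference`.
#' @examples
#' # vertical wound edge at x = 0, wound occupying x < 0
#' edge_reference(cbind(c(0, 0), c(0, 100)), inward_side = "left")
#' @export
edge_reference <- function(polyline, inward_side = c("left", "right")) {
  inward_side <- match.arg(inward_side)
  p <- as.matrix(polyline)
  if (ncol(p) != 2L || nrow(p) < 2L)
    stop("'polyline' needs >= 2 vertices with columns (x, y)", call. = FALSE)
  storage.mode(p) <- "double"
  keep <- c(TRUE, rowSums(abs(diff(p))) > 0)  # drop repeated vertices
  p <- p[keep, , drop = FALSE]
  if (nrow(p) < 2L)
    stop("'polyline' needs >= 2 distinct vertices", call. = FALSE)
  structure(list(polyline = p, inward_side = inward_side),
            class = "edge_reference")
}

#' @export
print.edge_reference <- function(x, ...) {
  cat(sprintf("<edge_reference> %d vertices, free space on the %s\n",
              nrow(x$polyline), x$inward_side))
  invisible(x)
}

# Project points onto the edge: for each point, the Euclidean distance to the
# nearest polyline segment and the inward (toward free space) unit normal of
# that segment. `points` is an n x 2 matrix in micrometres.
edge_project <- function(points, edge) {
  stopifnot(inherits(edge, "edge_reference"))
  pts <- matrix(as.numeric(points), ncol = 2)
  pl <- edge$polyline
  nseg <- nrow(pl) - 1L
  n <- nrow(pts)
  best_d2 <- rep(Inf, n)
  best_seg <- integer(n)
  for (s in seq_len(nseg)) {
    a <- pl[s, ]; b <- pl[s + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / len2
    t <- pmin(pmax(t, 0), 1)
    dx <- pts[, 1] - (a[1] + t * ab[1])
    dy <- pts[, 2] - (a[2] + t * ab[2])
    d2 <- dx * dx + dy * dy
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_seg[upd] <- s
  }
  tang <- pl[best_seg + 1L, , drop = FALSE] - pl[best_seg, , drop = FALSE]
  tl <- sqrt(rowSums(tang^2))
  tx <- tang[, 1] / tl; ty <- tang[, 2] / tl
  if (edge$inward_side == "left") {
    nx <- -ty; ny <- tx
  } else {
    nx <- ty; ny <- -tx
  }
  data.frame(distance_um = sqrt(best_d2), segment = best_seg,
             normal_x = nx, normal_y = ny)
}

#' Distance from points to the free edge
#'
#' @param points n x 2 matrix (or data.frame) of coordinates in micrometres.
#' @param edge an [edge_reference()].
#' @return Numeric vector of Euclidean distances (um) to the nearest
#'   polyline segment.
#' @export
distance_to_edge <- function(points, edge) {
  edge_project(points, edge)$distance_um
}
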