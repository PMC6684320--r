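#' Leader/follower row classification by adjacency peeling
#'
#' Assigns each cell a row index counted from the free edge: row 1 (leader
#' cells) are the cells whose neighbourhood region touches the free edge,
#' row k cells are adjacent to row k-1 after peeling. Edge contact is
#' decided by nearest-cell ownership of densely sampled edge points (the
#' cells owning a piece of the edge in the Voronoi sense), and adjacency is
#' the Gabriel-filtered Delaunay triangulation of the nucleus centroids with
#' implausibly long edges pruned.
#'
#' Disconnected cell clouds are handled per connected component (with a
#' warning): in a component nowhere adjacent to the edge, the cell closest
#' to the edge seeds the next row.
#'
#' @param centroids two-column matrix / data.frame of nucleus centroids (um).
#' @param edge an [edge_reference()].
#' @param prune_factor adjacency edges longer than `prune_factor` times the
#'   median adjacency-edge length are dropped (default 3), so genuinely
#'   separate cell clusters disconnect while a jittered confluent sheet
#'   stays whole.
#' @param edge_sample_um spacing of the edge sampling used for the row-1
#'   ownership test (default: half the median nearest-neighbour spacing).
#' @return Integer vector of row indices (1 = leader row).
#' @seealso [follower_set()] to extract follower cells (default rows 2-5).
#' @export
classify_rows <- function(centroids, edge, prune_factor = 3,
                          edge_sample_um = NULL) {
  pts <- matrix(as.numeric(as.matrix(centroids)), ncol = 2)
  n <- nrow(pts)
  if (n < 1L) stop("need at least one cell")
  if (n == 1L) return(1L)

  # median nearest-neighbour spacing sets the length scales
  D <- as.matrix(stats::dist(pts))
  diag(D) <- Inf
  nn <- apply(D, 1, min)
  spacing <- stats::median(nn)
  if (is.null(edge_sample_um)) edge_sample_um <- spacing / 2

  adj <- .adjacency(pts, D, prune_factor)

  # row 1: cells owning at least one sampled edge point (nearest cell)
  samp <- .sample_polyline(edge$polyline, edge_sample_um)
  d2 <- outer(samp[, 1], pts[, 1], "-")^2 + outer(samp[, 2], pts[, 2], "-")^2
  row1 <- sort(unique(max.col(-d2)))

  row <- rep(NA_integer_, n)
  row[row1] <- 1L
  frontier <- row1
  k <- 1L
  while (any(is.na(row))) {
    nxt <- setdiff(unique(unlist(adj[frontier])), which(!is.na(row)))
    if (length(nxt) == 0L) {
      # disconnected component: seed from its closest-to-edge cell
      warning("disconnected cell cloud: seeding next row from nearest cell")
      rem <- which(is.na(row))
      dist_edge <- distance_to_edge(pts[rem, , drop = FALSE], edge)
      nxt <- rem[which.min(dist_edge)]
    }
    k <- k + 1L
    row[nxt] <- k
    frontier <- nxt
  }
  row
}

# adjacency list: Gabriel-filtered Delaunay where possible, symmetric
# nearest-neighbour fallback for degenerate (e.g. collinear) configurations.
# The Gabriel filter (no third cell inside the circle with the edge as
# diameter) removes convex-hull shortcuts that would let peeling skip a row,
# while keeping the sheet connected (the Gabriel graph contains the EMST).
.adjacency <- function(pts, D, prune_factor) {
  n <- nrow(pts)
  del <- tryCatch(
    deldir::deldir(pts[, 1], pts[, 2], suppressMsge = TRUE),
    error = function(e) NULL)
  adj <- vector("list", n)
  if (!is.null(del)) {
    seg <- del$delsgs
    gabriel <- vapply(seq_len(nrow(seg)), function(i) {
      mx <- (seg$x1[i] + seg$x2[i]) / 2; my <- (seg$y1[i] + seg$y2[i]) / 2
      r2 <- ((seg$x1[i] - seg$x2[i])^2 + (seg$y1[i] - seg$y2[i])^2) / 4
      d2 <- (pts[, 1] - mx)^2 + (pts[, 2] - my)^2
      d2[seg$ind1[i]] <- Inf; d2[seg$ind2[i]] <- Inf
      min(d2) >= r2 - 1e-9
    }, logical(1))
    seg <- seg[gabriel, , drop = FALSE]
    len <- sqrt((seg$x1 - seg$x2)^2 + (seg$y1 - seg$y2)^2)
    seg <- seg[len <= prune_factor * stats::median(len), , drop = FALSE]
    for (i in seq_len(nrow(seg))) {
      a <- seg$ind1[i]; b <- seg$ind2[i]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  } else {
    nn <- apply(D, 1, min)
    max_len <- prune_factor * stats::median(nn)
    for (i in seq_len(n)) adj[[i]] <- which(D[i, ] <= max_len)
  }
  lapply(adj, unique)
}

# resample a polyline at roughly the requested spacing (keeps vertices)
.sample_polyline <- function(pl, spacing) {
  out <- list()
  for (s in seq_len(nrow(pl) - 1L)) {
    a <- pl[s, ]; b <- pl[s + 1L, ]
    len <- sqrt(sum((b - a)^2))
    t <- seq(0, 1, length.out = max(2L, ceiling(len / spacing) + 1L))
    out[[s]] <- cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
  }
  do.call(rbind, out)
}

#' Follower-cell selector
#'
#' Follower cells default to rows 2-5 behind the leader row; the narrower
#' rows 2-4 definition is available through `rows`.
#'
#' @param row_index integer vector from [classify_rows()].
#' @param rows which row indices count as followers (default `2:5`).
#' @return Logical vector marking follower cells.
#' @export
follower_set <- function(row_index, rows = 2:5) {
  row_index %in% rows
}
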