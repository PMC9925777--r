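#' Build the cubical sublevel-set filtration of a scalar field
#'
#' Enumerates all cells of the V-construction cubical complex of a 2D field:
#' 0-cubes are pixels, 1-cubes join orthogonally adjacent pixels, 2-cubes
#' fill 2x2 pixel blocks. A cell's filtration value is the maximum of its
#' vertices' values, so faces always enter no later than their cofaces.
#' Cells are returned in filtration order: value, then dimension, then
#' lexicographic anchor position.
#'
#' This explicit listing is meant for inspection and testing; the persistence
#' computation in [compute_persistence()] builds the same complex internally.
#'
#' @param field Numeric matrix (e.g. an SEDT field).
#' @return Data frame with columns `dim` (0/1/2), `value`, `row`, `col`
#'   (anchor = top-left incident pixel, 1-based) and `orient`
#'   (`"h"`/`"v"` for edges, `NA` otherwise), ordered by the filtration.
#'   Degenerate (all-infinite) fields give a zero-row frame with attribute
#'   `degenerate = TRUE`.
#' @export
build_filtration <- function(field) {
  stopifnot(is.matrix(field))
  if (isTRUE(attr(field, "degenerate")) || all(is.infinite(field))) {
    out <- data.frame(dim = integer(0), value = numeric(0), row = integer(0),
                      col = integer(0), orient = character(0))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  H <- nrow(field); W <- ncol(field)
  verts <- data.frame(dim = 0L, value = as.vector(t(field)),
                      row = rep(seq_len(H), each = W),
                      col = rep(seq_len(W), times = H), orient = NA_character_)
  cells <- list(verts)
  if (W >= 2L) {
    v <- pmax(field[, -W, drop = FALSE], field[, -1L, drop = FALSE])
    cells[[length(cells) + 1L]] <- data.frame(
      dim = 1L, value = as.vector(t(v)),
      row = rep(seq_len(H), each = W - 1L),
      col = rep(seq_len(W - 1L), times = H), orient = "h")
  }
  if (H >= 2L) {
    v <- pmax(field[-H, , drop = FALSE], field[-1L, , drop = FALSE])
    cells[[length(cells) + 1L]] <- data.frame(
      dim = 1L, value = as.vector(t(v)),
      row = rep(seq_len(H - 1L), each = W),
      col = rep(seq_len(W), times = H - 1L), orient = "v")
  }
  if (H >= 2L && W >= 2L) {
    v <- pmax(pmax(field[-H, -W, drop = FALSE], field[-H, -1L, drop = FALSE]),
              pmax(field[-1L, -W, drop = FALSE], field[-1L, -1L, drop = FALSE]))
    cells[[length(cells) + 1L]] <- data.frame(
      dim = 2L, value = as.vector(t(v)),
      row = rep(seq_len(H - 1L), each = W - 1L),
      col = rep(seq_len(W - 1L), times = H - 1L), orient = NA_character_)
  }
  out <- do.call(rbind, cells)
  out <- out[order(out$value, out$dim, out$row, out$col), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "degenerate") <- FALSE
  out
}

#' Persistent homology of a cubical sublevel-set filtration
#'
#' Computes the H0 and H1 persistence diagram of the V-construction cubical
#' filtration of a 2D scalar field (typically an SEDT field). H0 pairs come
#' from union-find over the edge order (elder rule); H1 pairs from the dual
#' construction (each cycle-creating edge is paired with the value at which
#' its bounded region fills in). Exactly one dimension-0 class never dies and
#' is reported with `death = Inf` and `essential = TRUE`; zero-persistence
#' pairs (birth equal to death) are discarded.
#'
#' @param field Numeric matrix; infinite sentinel fields (single-phase
#'   patches) give an empty diagram flagged `degenerate`.
#' @return A `persistence_diagram`: data frame with columns `dim`, `birth`,
#'   `death`, `birth_row`, `birth_col`, `essential`.
#' @export
compute_persistence <- function(field) {
  stopifnot(is.matrix(field))
  if (all(is.infinite(field))) {
    out <- data.frame(dim = integer(0), birth = numeric(0), death = numeric(0),
                      birth_row = integer(0), birth_col = integer(0),
                      essential = logical(0))
    attr(out, "degenerate") <- TRUE
    class(out) <- c("persistence_diagram", class(out))
    return(out)
  }
  out <- cubical_pairs_cpp(field)
  attr(out, "degenerate") <- FALSE
  class(out) <- c("persistence_diagram", class(out))
  out
}

#' @export
print.persistence_diagram <- function(x, ...) {
  cat("Persistence diagram: ", sum(x$dim == 0), " H0 point(s) (",
      sum(x$essential), " essential), ", sum(x$dim == 1), " H1 point(s)\n",
      sep = "")
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 10), ...)
  invisible(x)
}

#' Brute-force Betti curve of a sublevel filtration
#'
#' Independent oracle for [compute_persistence()]: for each threshold it
#' builds the sublevel cubical complex explicitly and counts beta0 as the
#' number of connected components of included vertices under included edges
#' (4-connectivity) and beta1 from the Euler formula
#' `beta1 = beta0 - V + E - F` of the 2-complex. Intended for small fields.
#'
#' @param field Numeric matrix (<= 20 x 20 advisable).
#' @param thresholds Numeric vector of filtration values `delta`.
#' @return Data frame with columns `threshold`, `beta0`, `beta1`.
#' @export
oracle_betti_curve <- function(field, thresholds) {
  stopifnot(is.matrix(field))
  H <- nrow(field); W <- ncol(field)
  vid <- function(i, j) (i - 1L) * W + j
  res <- lapply(thresholds, function(delta) {
    inc <- field <= delta
    V <- sum(inc)
    if (V == 0L) return(c(0L, 0L))
    # included edges: both endpoints included
    eh <- which(inc[, -W, drop = FALSE] & inc[, -1L, drop = FALSE], arr.ind = TRUE)
    ev <- which(inc[-H, , drop = FALSE] & inc[-1L, , drop = FALSE], arr.ind = TRUE)
    E <- nrow(eh) + nrow(ev)
    f4 <- if (H >= 2L && W >= 2L)
      inc[-H, -W, drop = FALSE] & inc[-H, -1L, drop = FALSE] &
      inc[-1L, -W, drop = FALSE] & inc[-1L, -1L, drop = FALSE]
    else matrix(FALSE, 0, 0)
    Fc <- sum(f4)
    # components via union-find on vertices
    parent <- seq_len(H * W)
    find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
    unite <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[rb] <<- ra }
    if (nrow(eh)) for (k in seq_len(nrow(eh)))
      unite(vid(eh[k, 1], eh[k, 2]), vid(eh[k, 1], eh[k, 2] + 1L))
    if (nrow(ev)) for (k in seq_len(nrow(ev)))
      unite(vid(ev[k, 1], ev[k, 2]), vid(ev[k, 1] + 1L, ev[k, 2]))
    roots <- vapply(which(as.vector(t(inc))), function(v) find(v), integer(1))
    b0 <- length(unique(roots))
    b1 <- b0 - V + E - Fc
    c(b0, b1)
  })
  res <- do.call(rbind, res)
  data.frame(threshold = thresholds, beta0 = res[, 1], beta1 = res[, 2])
}

#' Assign persistence points to diagram quadrants
#'
#' Under the SEDT filtration the quadrants of the persistence diagram
#' (labelled 1 to 4 from the top right, anti-clockwise) carry distinct
#' morphological meaning: H0 quadrant 2 (`birth < 0 < death`) holds
#' individual micro-holes (|birth| = largest inscribed radius, death = half
#' the distance to the nearest micro-hole); H0 quadrant 3 holds connected
#' micro-holes merged by `delta = 0`; H1 quadrant 1 holds loops of signal
#' between micro-holes; H1 quadrant 2 holds micro-hole loops. Boundary
#' conventions: Q1 is `birth >= 0, death > 0`; Q2 `birth < 0, death > 0`;
#' Q3 `birth < 0, death <= 0`. The essential class is assigned to Q2 and
#' stays flagged.
#'
#' @param diag A `persistence_diagram`.
#' @param check Validate the SEDT quadrant laws (no H0 in Q1, no H1 in Q3,
#'   Q4 empty, exactly one essential class) and error on violation. Set to
#'   `FALSE` for diagrams of arbitrary (non-SEDT) fields.
#' @return The diagram with an integer `quadrant` column.
#' @export
split_quadrants <- function(diag, check = TRUE) {
  q <- rep(NA_integer_, nrow(diag))
  b <- diag$birth; d <- diag$death
  q[b >= 0 & d > 0] <- 1L
  q[b < 0 & d > 0] <- 2L
  q[b < 0 & d <= 0] <- 3L
  q[b >= 0 & d <= 0] <- 4L
  diag$quadrant <- q
  if (check && nrow(diag)) {
    if (any(diag$dim == 0 & q == 1L))
      stop("internal consistency error: H0 point in quadrant 1")
    if (any(diag$dim == 1 & q == 3L))
      stop("internal consistency error: H1 point in quadrant 3")
    if (any(q == 4L))
      stop("internal consistency error: point in quadrant 4")
    if (sum(diag$essential) != 1L)
      stop("internal consistency error: expected exactly one essential class, found ",
           sum(diag$essential))
  }
  diag
}
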