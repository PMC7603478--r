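#' @importFrom Matrix sparseMatrix Diagonal
#' @importFrom stats rnorm runif rexp optim cor cor.test sd median ecdf
#' @importFrom utils write.csv
NULL

# Symmetric partition of a 1D interval structure [-x0, -xw, xw, x0] such
# that the wound lines +-xw (and 0) are always grid lines.
axis_lines <- function(x0, xw, h) {
  n_out <- max(1L, ceiling((x0 - xw) / h))
  n_in  <- max(1L, ceiling(xw / h))
  inner <- seq(-xw, xw, length.out = 2L * n_in + 1L)
  outer <- seq(xw, x0, length.out = n_out + 1L)
  sort(unique(c(-rev(outer), inner, outer)))
}

#' Build a structured, boundary-conforming triangulation of the skin domain
#'
#' The computational domain is the rectangle \eqn{(-x_0, x_0) \times
#' (-y_0, y_0)} with an inner rectangular wound \eqn{(-x_w, x_w) \times
#' (-y_w, y_w)}. The mesh is a structured triangulation whose grid lines
#' include the wound rectangle, so the wound interface is an exact mesh
#' polyline; diagonals are mirrored across both axes so the mesh is
#' symmetric under \eqn{x \to -x} and \eqn{y \to -y}.
#'
#' @param x0,y0 half-width and half-height of the domain (\eqn{\mu m}).
#' @param xw,yw half-lengths of the wound rectangle (\eqn{\mu m}).
#' @param target_edge requested grid spacing (\eqn{\mu m}); the actual
#'   spacing is adjusted per segment so domain and wound boundaries are
#'   resolved exactly.
#' @return an object of class `ws_mesh`: list with `nodes` (n x 2),
#'   `tri` (m x 3, counter-clockwise), `boundary_edges` (k x 2),
#'   `boundary_tag` (`"outer"` or `"wound_interface"`),
#'   `wound_node_ids` (ordered closed polygon on the wound interface) and
#'   `wound_elem` (logical per triangle, material wound region).
#' @export
build_rect_mesh <- function(x0, y0, xw, yw, target_edge) {
  if (!(x0 > 0 && y0 > 0 && xw > 0 && yw > 0 && target_edge > 0) ||
      !(xw < x0 && yw < y0)) {
    stop("invalid geometry: need 0 < xw < x0, 0 < yw < y0, target_edge > 0")
  }
  xs <- axis_lines(x0, xw, target_edge)
  ys <- axis_lines(y0, yw, target_edge)
  nx <- length(xs); ny <- length(ys)
  nodes <- cbind(rep(xs, times = ny), rep(ys, each = nx))

  # cell corners (i, j) -> node index
  nid <- function(i, j) (j - 1L) * nx + i
  ci <- rep(seq_len(nx - 1L), times = ny - 1L)
  cj <- rep(seq_len(ny - 1L), each = nx - 1L)
  n00 <- nid(ci, cj); n10 <- nid(ci + 1L, cj)
  n01 <- nid(ci, cj + 1L); n11 <- nid(ci + 1L, cj + 1L)
  cx <- (xs[ci] + xs[ci + 1L]) / 2
  cy <- (ys[cj] + ys[cj + 1L]) / 2
  # mirror-symmetric diagonal pattern
  diag1 <- (cx * cy) >= 0
  t1 <- ifelse(diag1, n00, n10); t2 <- ifelse(diag1, n10, n11)
  t3 <- ifelse(diag1, n11, n01)
  s1 <- ifelse(diag1, n00, n10); s2 <- ifelse(diag1, n11, n01)
  s3 <- ifelse(diag1, n01, n00)
  tri <- rbind(cbind(t1, t2, t3), cbind(s1, s2, s3))
  colnames(tri) <- NULL

  # enforce counter-clockwise orientation
  a <- signed_areas(nodes, tri)
  flip <- a < 0
  if (any(flip)) tri[flip, c(2, 3)] <- tri[flip, c(3, 2)]

  on_outer <- function(p) abs(abs(p[, 1]) - x0) < 1e-9 | abs(abs(p[, 2]) - y0) < 1e-9
  on_wound <- function(p) {
    (abs(abs(p[, 1]) - xw) < 1e-9 & abs(p[, 2]) <= yw + 1e-9) |
      (abs(abs(p[, 2]) - yw) < 1e-9 & abs(p[, 1]) <= xw + 1e-9)
  }

  edges <- all_edges(tri)
  emid <- (nodes[edges[, 1], , drop = FALSE] + nodes[edges[, 2], , drop = FALSE]) / 2
  outer_e <- on_outer(nodes[edges[, 1], , drop = FALSE]) &
    on_outer(nodes[edges[, 2], , drop = FALSE]) & on_outer(emid)
  wound_e <- on_wound(nodes[edges[, 1], , drop = FALSE]) &
    on_wound(nodes[edges[, 2], , drop = FALSE]) & on_wound(emid)
  boundary_edges <- rbind(edges[outer_e, , drop = FALSE], edges[wound_e, , drop = FALSE])
  boundary_tag <- c(rep("outer", sum(outer_e)), rep("wound_interface", sum(wound_e)))

  # ordered wound polygon (counter-clockwise, material node ids)
  wn <- which(on_wound(nodes))
  ang <- atan2(nodes[wn, 2], nodes[wn, 1])
  wound_node_ids <- wn[order(ang)]

  cent <- tri_centroids(nodes, tri)
  wound_elem <- abs(cent[, 1]) < xw & abs(cent[, 2]) < yw

  m <- structure(list(
    nodes = nodes, tri = tri,
    boundary_edges = boundary_edges, boundary_tag = boundary_tag,
    wound_node_ids = wound_node_ids, wound_elem = wound_elem,
    target_edge = target_edge,
    geom = c(x0 = x0, y0 = y0, xw = xw, yw = yw),
    cache = new.env(parent = emptyenv())
  ), class = "ws_mesh")
  m$adj <- tri_adjacency(m)
  m
}

# coordinate-dependent quantities are cached per mesh object; assembly
# patterns depend on connectivity only and are carried across
# displacements
get_geom <- function(mesh) {
  g <- mesh$cache$geom_p1
  if (is.null(g)) {
    g <- tri_geom(mesh)
    assign("geom_p1", g, envir = mesh$cache)
  }
  g
}

signed_areas <- function(nodes, tri) {
  p1 <- nodes[tri[, 1], , drop = FALSE]
  p2 <- nodes[tri[, 2], , drop = FALSE]
  p3 <- nodes[tri[, 3], , drop = FALSE]
  0.5 * ((p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
           (p3[, 1] - p1[, 1]) * (p2[, 2] - p1[, 2]))
}

tri_centroids <- function(nodes, tri) {
  (nodes[tri[, 1], , drop = FALSE] + nodes[tri[, 2], , drop = FALSE] +
     nodes[tri[, 3], , drop = FALSE]) / 3
}

all_edges <- function(tri) {
  e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

# element adjacency across shared edges: m x 3 matrix, adj[i, k] is the
# triangle sharing the edge opposite local vertex k (NA on the boundary)
tri_adjacency <- function(mesh) {
  tri <- mesh$tri
  m <- nrow(tri)
  n <- max(tri)
  # edge opposite local vertex k is (k+1, k+2); integer key
  ek <- function(k) {
    a <- tri[, (k %% 3) + 1L]; b <- tri[, ((k + 1L) %% 3) + 1L]
    pmin(a, b) * (n + 1) + pmax(a, b)
  }
  keys <- c(ek(1L), ek(2L), ek(3L))        # entry id e + (k-1)*m
  ord <- order(keys)
  ks <- keys[ord]
  adj <- matrix(NA_integer_, m, 3L)
  pair <- which(ks[-length(ks)] == ks[-1])
  a <- ord[pair]; b <- ord[pair + 1L]
  ea <- (a - 1L) %% m + 1L; ka <- (a - 1L) %/% m + 1L
  eb <- (b - 1L) %% m + 1L; kb <- (b - 1L) %/% m + 1L
  adj[cbind(ea, ka)] <- eb
  adj[cbind(eb, kb)] <- ea
  adj
}

#' Move mesh nodes by a displacement increment
#'
#' Connectivity, tags and material ids are unchanged; only coordinates
#' move. Any triangle whose signed area becomes non-positive aborts the
#' step (the model assumes small deformations and never remeshes).
#'
#' @param mesh a `ws_mesh`.
#' @param u n x 2 matrix of nodal displacements (\eqn{\mu m}).
#' @return the displaced `ws_mesh`.
#' @export
displace_mesh <- function(mesh, u) {
  stopifnot(inherits(mesh, "ws_mesh"))
  u <- as.matrix(u)
  if (!all(is.finite(u))) stop("non-finite displacement")
  if (nrow(u) != nrow(mesh$nodes) || ncol(u) != 2) stop("displacement shape mismatch")
  m2 <- mesh
  m2$nodes <- mesh$nodes + u
  if (any(signed_areas(m2$nodes, m2$tri) <= 0)) {
    stop("mesh tangling: a triangle inverted during the displacement step")
  }
  m2$cache <- new.env(parent = emptyenv())
  for (nm in c("scalar_asm", "vector_asm")) {   # connectivity-only caches
    if (!is.null(mesh$cache[[nm]])) assign(nm, mesh$cache[[nm]], envir = m2$cache)
  }
  m2
}

# per-element geometry: areas, P1 basis gradients g[elem, vertex, xy]
tri_geom <- function(mesh) {
  nodes <- mesh$nodes; tri <- mesh$tri
  p1 <- nodes[tri[, 1], , drop = FALSE]
  p2 <- nodes[tri[, 2], , drop = FALSE]
  p3 <- nodes[tri[, 3], , drop = FALSE]
  a2 <- (p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
    (p3[, 1] - p1[, 1]) * (p2[, 2] - p1[, 2])
  area <- a2 / 2
  g <- array(0, c(nrow(tri), 3, 2))
  g[, 1, 1] <- (p2[, 2] - p3[, 2]) / a2; g[, 1, 2] <- (p3[, 1] - p2[, 1]) / a2
  g[, 2, 1] <- (p3[, 2] - p1[, 2]) / a2; g[, 2, 2] <- (p1[, 1] - p3[, 1]) / a2
  g[, 3, 1] <- (p1[, 2] - p2[, 2]) / a2; g[, 3, 2] <- (p2[, 1] - p1[, 1]) / a2
  list(area = area, g = g, p1 = p1, p2 = p2, p3 = p3)
}

# lumped nodal areas (sum of adjacent element areas / 3)
lumped_areas <- function(mesh, geom = get_geom(mesh)) {
  n <- nrow(mesh$nodes)
  as.numeric(rowsum_vec(rep(geom$area / 3, 3), as.vector(mesh$tri), n))
}

# sum x by integer group into a length-n vector (no name coercion)
rowsum_vec <- function(x, group, n) {
  ord <- order(group)
  go <- group[ord]
  cs <- cumsum(x[ord])
  len <- length(go)
  if (len == 0L) return(numeric(n))
  ends <- c(which(go[-len] != go[-1]), len)
  out <- numeric(n)
  out[go[ends]] <- cs[ends] - c(0, cs[ends[-length(ends)]])
  out
}

# precomputed aggregator for a fixed group vector
make_agg <- function(group, n) {
  ord <- order(group)
  go <- group[ord]
  len <- length(go)
  ends <- c(which(go[-len] != go[-1]), len)
  list(ord = ord, ends = ends, targets = go[ends], n = n)
}

agg_apply <- function(agg, x) {
  cs <- cumsum(x[agg$ord])
  out <- numeric(agg$n)
  out[agg$targets] <- cs[agg$ends] - c(0, cs[agg$ends[-length(agg$ends)]])
  out
}

#' Locate points in the mesh
#'
#' Vectorised barycentric walk through element adjacency, with an
#' exhaustive fallback; points outside the mesh are snapped to the
#' nearest element (with a warning), matching the behaviour required for
#' Dirac loads whose carrier cell straddles the boundary.
#'
#' @param mesh a `ws_mesh`.
#' @param pts q x 2 matrix of coordinates.
#' @param guess optional integer vector of starting elements.
#' @return list with `elem` (integer q) and `bary` (q x 3 barycentric
#'   weights, clamped to the simplex for snapped points).
#' @export
locate_points <- function(mesh, pts, guess = NULL) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  q <- nrow(pts)
  if (q == 0L) return(list(elem = integer(0), bary = matrix(0, 0, 3)))
  geom <- get_geom(mesh)
  m <- nrow(mesh$tri)
  if (is.null(guess)) guess <- grid_guess(mesh, pts)
  elem <- pmin(pmax(as.integer(guess), 1L), m)
  bary <- matrix(0, q, 3)
  active <- rep(TRUE, q)
  tol <- -1e-12
  for (it in 1:80) {
    ia <- which(active)
    if (!length(ia)) break
    b <- bary_in(geom, elem[ia], pts[ia, , drop = FALSE])
    bary[ia, ] <- b
    worst <- max.col(-b)                     # most negative barycentric
    inside <- b[cbind(seq_along(ia), worst)] >= tol
    active[ia[inside]] <- FALSE
    ia <- ia[!inside]; worst <- worst[!inside]
    if (!length(ia)) break
    nxt <- mesh$adj[cbind(elem[ia], worst)]
    dead <- is.na(nxt)
    elem[ia[!dead]] <- nxt[!dead]
    active[ia[dead]] <- FALSE               # walked off the boundary
    if (any(dead)) {
      # snap: nearest element centroid, clamp barycentrics
      cent <- get_centroids(mesh)
      for (j in ia[dead]) {
        d2 <- (cent[, 1] - pts[j, 1])^2 + (cent[, 2] - pts[j, 2])^2
        elem[j] <- which.min(d2)
        bb <- bary_in(geom, elem[j], pts[j, , drop = FALSE])
        bb <- pmax(bb, 0); bary[j, ] <- bb / sum(bb)
      }
    }
  }
  if (any(active)) {   # walk did not converge: exhaustive fallback
    for (j in which(active)) {
      bb <- t(vapply(seq_len(m), function(e)
        bary_in(geom, e, pts[j, , drop = FALSE])[1, ], numeric(3)))
      ok <- which(apply(bb, 1, min) >= tol)
      if (length(ok)) {
        elem[j] <- ok[1]; bary[j, ] <- bb[ok[1], ]
      } else {
        e <- which.max(apply(bb, 1, min))
        elem[j] <- e
        b2 <- pmax(bb[e, ], 0); bary[j, ] <- b2 / sum(b2)
      }
    }
  }
  list(elem = elem, bary = bary)
}

bary_in <- function(geom, elem, pts) {
  p1 <- geom$p1[elem, , drop = FALSE]
  p2 <- geom$p2[elem, , drop = FALSE]
  p3 <- geom$p3[elem, , drop = FALSE]
  a <- geom$area[elem] * 2
  w1 <- ((p2[, 1] - pts[, 1]) * (p3[, 2] - pts[, 2]) -
           (p3[, 1] - pts[, 1]) * (p2[, 2] - pts[, 2])) / a
  w2 <- ((p3[, 1] - pts[, 1]) * (p1[, 2] - pts[, 2]) -
           (p1[, 1] - pts[, 1]) * (p3[, 2] - pts[, 2])) / a
  cbind(w1, w2, 1 - w1 - w2)
}

get_centroids <- function(mesh) {
  cc <- mesh$cache$centroids
  if (is.null(cc)) {
    cc <- tri_centroids(mesh$nodes, mesh$tri)
    assign("centroids", cc, envir = mesh$cache)
  }
  cc
}

# cheap starting guess: nearest binned centroid
grid_guess <- function(mesh, pts) {
  cent <- get_centroids(mesh)
  # coarse binning of centroids
  nb <- max(4L, floor(sqrt(nrow(cent) / 2)))
  rx <- range(mesh$nodes[, 1]); ry <- range(mesh$nodes[, 2])
  bx <- function(x) pmin(pmax(1L + floor((x - rx[1]) / diff(rx) * nb), 1L), nb)
  by <- function(y) pmin(pmax(1L + floor((y - ry[1]) / diff(ry) * nb), 1L), nb)
  key_c <- bx(cent[, 1]) + nb * (by(cent[, 2]) - 1L)
  first <- match(seq_len(nb * nb), key_c)
  key_p <- bx(pts[, 1]) + nb * (by(pts[, 2]) - 1L)
  g <- first[key_p]
  g[is.na(g)] <- 1L
  g
}

#' Ordered wound polygon in current coordinates
#'
#' The wound interface nodes are material points; their stored cyclic
#' order from the initial configuration is reused at every time.
#'
#' @param mesh a `ws_mesh`.
#' @return matrix of polygon vertices (closed implicitly).
#' @export
wound_polygon <- function(mesh) {
  mesh$nodes[mesh$wound_node_ids, , drop = FALSE]
}
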