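# Centerline extraction: Hessian-based vessel enhancement, segmentation,
# morphological thinning, skeleton-to-graph conversion, and nearest-edge
# selection from user clicks.

#' Multiscale Hessian vesselness (Frangi) filter
#'
#' Enhances curvilinear structures by eigenvalue analysis of the
#' scale-normalized Gaussian Hessian. At each scale the tubularity measure
#' combines the blobness ratio `Rb = l1/l2` (eigenvalues ordered by
#' magnitude) and the second-order structure strength
#' `S = sqrt(l1^2 + l2^2)`; pixels whose principal curvature has the wrong
#' sign for the requested polarity score zero. The response is maximized
#' over scales and normalized to `[0, 1]`.
#'
#' @param image Numeric matrix of finite intensities.
#' @param scales_px Gaussian scales (sd, pixels); typically spanning the
#'   expected vessel radii.
#' @param polarity `"bright"` for bright tubes on dark background (the
#'   plasma-labeled case) or `"dark"`.
#' @param beta Blobness sensitivity (default 0.5).
#' @param c_norm Structure sensitivity; default half the maximum `S` at
#'   each scale.
#' @return Matrix of vesselness values in `[0, 1]`.
#' @export
enhance_vessels <- function(image, scales_px = c(1, 2, 3, 4),
                            polarity = c("bright", "dark"), beta = 0.5,
                            c_norm = NULL) {
  polarity <- match.arg(polarity)
  if (!is.matrix(image) || !all(is.finite(image))) {
    stop("`image` must be a finite numeric matrix", call. = FALSE)
  }
  if (length(scales_px) < 1L) {
    stop("at least one scale is required", call. = FALSE)
  }
  if (any(scales_px <= 0)) stop("scales must be positive", call. = FALSE)
  img <- if (polarity == "dark") -image else image
  v <- matrix(0, nrow(image), ncol(image))
  for (sigma in scales_px) {
    h <- hessian_gauss(img, sigma)
    m <- (h$xx + h$yy) / 2
    delta <- sqrt(((h$xx - h$yy) / 2)^2 + h$xy^2)
    e1 <- m + delta; e2 <- m - delta
    big <- abs(e1) >= abs(e2)
    lam2 <- ifelse(big, e1, e2)   # larger magnitude
    lam1 <- ifelse(big, e2, e1)
    s2 <- lam1^2 + lam2^2
    cc <- if (is.null(c_norm)) 0.5 * sqrt(max(s2)) else c_norm
    # numerically structureless at this scale (e.g. constant image)
    if (cc <= 1e-8 * max(1, max(abs(img)))) next
    rb2 <- ifelse(lam2 != 0, (lam1 / lam2)^2, 0)
    resp <- exp(-rb2 / (2 * beta^2)) * (1 - exp(-s2 / (2 * cc^2)))
    resp[lam2 >= 0] <- 0  # bright tube: principal curvature negative
    v <- pmax(v, resp)
  }
  mx <- max(v)
  if (mx > 0) v <- v / mx
  v
}

# scale-normalized Gaussian Hessian via separable derivative kernels
hessian_gauss <- function(img, sigma) {
  r <- max(2L, ceiling(4 * sigma))
  x <- -r:r
  g <- exp(-x^2 / (2 * sigma^2)); g <- g / sum(g)
  g1 <- -x / sigma^2 * g
  g2 <- (x^2 - sigma^2) / sigma^4 * g
  g2 <- g2 - sum(g2) / length(g2)  # exact zero response to constants
  # kernel[i, j] operates on (y_i, x_j); filter2 correlates, kernels are
  # symmetric/antisymmetric so orientation is handled explicitly
  conv <- function(k) EBImage::filter2(img, k, boundary = "replicate")
  list(xx = sigma^2 * conv(outer(g, g2)),
       yy = sigma^2 * conv(outer(g2, g)),
       xy = sigma^2 * conv(outer(g1, g1)))
}

#' Threshold a vesselness map into a binary vessel mask
#'
#' @param vesselness Vesselness map (values in `[0, 1]`).
#' @param threshold Scalar in `[0, 1)`: the mask is
#'   `vesselness >= threshold`. `NULL` (default) selects the threshold
#'   automatically by Otsu's method on the vesselness histogram.
#' @return Logical matrix.
#' @export
segment_vessels <- function(vesselness, threshold = NULL) {
  stopifnot(is.matrix(vesselness))
  if (is.null(threshold)) {
    threshold <- EBImage::otsu(EBImage::Image(vesselness),
                               range = range(0, max(vesselness, 1)))
  }
  if (threshold < 0 || threshold >= 1) {
    stop("`threshold` must lie in [0, 1)", call. = FALSE)
  }
  vesselness >= threshold
}

# 8 neighbor shifts of a 0-padded integer matrix, Zhang-Suen order
# P2..P9 = N, NE, E, SE, S, SW, W, NW
neighbor_stack <- function(P) {
  H <- nrow(P); W <- ncol(P)
  core <- function(dy, dx) P[(2 + dy):(H - 1 + dy), (2 + dx):(W - 1 + dx)]
  list(core(-1, 0), core(-1, 1), core(0, 1), core(1, 1),
       core(1, 0), core(1, -1), core(0, -1), core(-1, -1))
}

#' Skeletonize a binary mask to 1-pixel-wide centerlines
#'
#' Morphological thinning (Zhang-Suen parallel thinning with a 2x2-block
#' cleanup pass). The skeleton is a subset of the mask, contains no 2x2
#' all-true block, and has the same number of 8-connected components as
#' the input.
#'
#' @param mask Logical matrix.
#' @return Logical matrix of the same size.
#' @export
skeletonize_mask <- function(mask) {
  stopifnot(is.matrix(mask))
  storage.mode(mask) <- "logical"
  if (!any(mask)) return(mask)
  H <- nrow(mask); W <- ncol(mask)
  P <- matrix(0L, H + 2, W + 2)
  P[2:(H + 1), 2:(W + 1)] <- as.integer(mask)

  thin_pass <- function(P, second) {
    nb <- neighbor_stack(P)
    B <- Reduce(`+`, nb)
    A <- matrix(0L, H, W)
    for (k in 1:8) {
      A <- A + as.integer(nb[[k]] == 0L & nb[[if (k == 8) 1 else k + 1]] == 1L)
    }
    cur <- P[2:(H + 1), 2:(W + 1)]
    if (!second) {
      cond <- nb[[1]] * nb[[3]] * nb[[5]] == 0L & nb[[3]] * nb[[5]] * nb[[7]] == 0L
    } else {
      cond <- nb[[1]] * nb[[3]] * nb[[7]] == 0L & nb[[1]] * nb[[5]] * nb[[7]] == 0L
    }
    del <- cur == 1L & B >= 2L & B <= 6L & A == 1L & cond
    P[2:(H + 1), 2:(W + 1)][del] <- 0L
    list(P = P, changed = any(del))
  }

  repeat {
    s1 <- thin_pass(P, second = FALSE); P <- s1$P
    s2 <- thin_pass(P, second = TRUE);  P <- s2$P
    if (!s1$changed && !s2$changed) break
  }

  skel <- P[2:(H + 1), 2:(W + 1)] == 1L

  # parallel thinning can erase a small component entirely; restore one
  # pixel per lost component
  lab <- label_components8(mask)
  surv <- unique(lab[skel])
  for (l in setdiff(unique(lab[mask]), surv)) {
    idx <- which(lab == l)
    skel[idx[ceiling(length(idx) / 2)]] <- TRUE
  }

  prune_staircases(remove_square_corners(skel))
}

# 8-connected component labeling by union-find (EBImage::bwlabel is
# 4-connected, which splits thin diagonal structures)
label_components8 <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  out <- matrix(0L, H, W)
  idx <- which(mask)
  if (!length(idx)) return(out)
  rank_of <- integer(H * W)
  rank_of[idx] <- seq_along(idx)
  parent <- seq_along(idx)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  x <- (idx - 1L) %/% H + 1L; y <- (idx - 1L) %% H + 1L
  for (d in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(-1L, 1L))) {
    ny <- y + d[1]; nx <- x + d[2]
    ok <- ny >= 1L & ny <= H & nx >= 1L & nx <= W
    nidx <- (nx[ok] - 1L) * H + ny[ok]
    inmask <- mask[nidx]
    a_list <- rank_of[idx[ok][inmask]]
    b_list <- rank_of[nidx[inmask]]
    for (k in seq_along(a_list)) {
      ra <- find(a_list[k]); rb <- find(b_list[k])
      if (ra != rb) parent[rb] <- ra
    }
  }
  roots <- vapply(seq_along(idx), find, integer(1))
  out[idx] <- match(roots, unique(roots))
  out
}

# ring positions P2..P9 = N, NE, E, SE, S, SW, W, NW as (dy, dx)
ring_dy <- c(-1, -1, 0, 1, 1, 1, 0, -1)
ring_dx <- c(0, 1, 1, 1, 0, -1, -1, -1)

# true 8-simple test: the occupied ring cells around p form one
# 8-connected component (so deleting p cannot disconnect anything locally)
is_simple8 <- function(ring) {
  occ <- which(ring)
  if (length(occ) <= 1L) return(length(occ) == 1L)
  comp <- seq_along(occ)
  for (a in seq_along(occ)) {
    for (b in seq_along(occ)) {
      if (a < b &&
          max(abs(ring_dy[occ[a]] - ring_dy[occ[b]]),
              abs(ring_dx[occ[a]] - ring_dx[occ[b]])) <= 1L) {
        comp[comp == comp[b]] <- comp[a]
      }
    }
  }
  length(unique(comp)) == 1L
}

# thinning staircases leave redundant pixels that are not true junctions:
# degree>=3 pixels that are 8-simple, and degree-2 "corner" pixels whose
# two neighbors touch each other (3-pixel cliques). Both are deleted
# sequentially; genuine branch points are not 8-simple and survive.
prune_staircases <- function(skel) {
  H <- nrow(skel); W <- ncol(skel)
  ring_of <- function(y, x) {
    ny <- y + ring_dy; nx <- x + ring_dx
    ok <- ny >= 1 & ny <= H & nx >= 1 & nx <= W
    r <- logical(8L)
    r[ok] <- skel[cbind(ny[ok], nx[ok])]
    r
  }
  repeat {
    P <- matrix(0L, H + 2, W + 2)
    P[2:(H + 1), 2:(W + 1)] <- as.integer(skel)
    deg <- Reduce(`+`, neighbor_stack(P))
    cand <- which(skel & deg >= 2L)
    changed <- FALSE
    for (idx in cand) {
      y <- (idx - 1L) %% H + 1L; x <- (idx - 1L) %/% H + 1L
      ring <- ring_of(y, x)
      n_occ <- sum(ring)
      del <- if (n_occ >= 3L) {
        is_simple8(ring)
      } else if (n_occ == 2L) {
        occ <- which(ring)
        max(abs(ring_dy[occ[1]] - ring_dy[occ[2]]),
            abs(ring_dx[occ[1]] - ring_dx[occ[2]])) <= 1L
      } else FALSE
      if (del) {
        skel[idx] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) return(skel)
  }
}

# delete simple pixels until no 2x2 all-true block remains
remove_square_corners <- function(skel) {
  H <- nrow(skel); W <- ncol(skel)
  repeat {
    P <- matrix(0L, H + 2, W + 2)
    P[2:(H + 1), 2:(W + 1)] <- as.integer(skel)
    nb <- neighbor_stack(P)
    sq <- skel & nb[[3]] == 1L & nb[[5]] == 1L & nb[[4]] == 1L  # top-left of 2x2
    if (!any(sq)) return(skel)
    A <- matrix(0L, H, W)
    for (k in 1:8) {
      A <- A + as.integer(nb[[k]] == 0L & nb[[if (k == 8) 1 else k + 1]] == 1L)
    }
    # corners of any 2x2 block that are simple (deletable without
    # breaking connectivity); delete the first one only, then recompute
    corner <- sq | (skel & nb[[7]] == 1L & nb[[5]] == 1L & nb[[6]] == 1L) |
      (skel & nb[[3]] == 1L & nb[[1]] == 1L & nb[[2]] == 1L) |
      (skel & nb[[7]] == 1L & nb[[1]] == 1L & nb[[8]] == 1L)
    cand <- which(corner & A == 1L)
    if (length(cand) == 0L) return(skel)  # nothing safely deletable
    skel[cand[1]] <- FALSE
  }
}

#' Convert a 1-pixel skeleton to a vessel graph
#'
#' Nodes are skeleton pixels with a number of 8-neighbors different from 2
#' (endpoints have 1, branch points 3 or more, isolated pixels 0); edges
#' are the maximal degree-2 pixel paths connecting them. Isolated closed
#' loops, which contain no natural node, are anchored at their
#' lowest-index pixel and represented as a self-edge.
#'
#' @param skeleton Logical matrix, 1 pixel wide (no 2x2 all-true block).
#' @return An object of class `vessel_graph`: list with `nodes` (data
#'   frame `id`, `x`, `y`) and `edges` (list of `id`, `node_a`, `node_b`,
#'   `path` n x 2 matrix of x, y pixel coordinates from node_a to node_b).
#' @export
skeleton_to_graph <- function(skeleton) {
  stopifnot(is.matrix(skeleton))
  storage.mode(skeleton) <- "logical"
  H <- nrow(skeleton); W <- ncol(skeleton)
  if (any(skeleton[-H, -W] & skeleton[-1, -W] & skeleton[-H, -1] & skeleton[-1, -1])) {
    stop("skeleton is not 1 pixel wide (contains a 2x2 block)", call. = FALSE)
  }
  P <- matrix(0L, H + 2, W + 2)
  P[2:(H + 1), 2:(W + 1)] <- as.integer(skeleton)
  deg <- Reduce(`+`, neighbor_stack(P))
  deg[!skeleton] <- -1L

  node_idx <- which(skeleton & deg != 2L)  # column-major order: deterministic
  is_node <- matrix(FALSE, H, W); is_node[node_idx] <- TRUE
  node_id <- matrix(NA_integer_, H, W); node_id[node_idx] <- seq_along(node_idx)

  xy <- function(idx) cbind(x = (idx - 1L) %/% H + 1L, y = (idx - 1L) %% H + 1L)
  # fixed 8-neighbor order for deterministic traversal
  nb_dx <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  nb_dy <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  neighbors_of <- function(idx) {
    x <- (idx - 1L) %/% H + 1L; y <- (idx - 1L) %% H + 1L
    nx <- x + nb_dx; ny <- y + nb_dy
    ok <- nx >= 1L & nx <= W & ny >= 1L & ny <= H
    cand <- (nx[ok] - 1L) * H + ny[ok]
    cand[skeleton[cand]]
  }

  visited <- matrix(FALSE, H, W)   # interior pixels consumed by an edge
  edges <- list()
  seen_direct <- character(0)

  ensure_node <- function(idx) {
    if (!is_node[idx]) {
      is_node[idx] <<- TRUE
      node_idx <<- c(node_idx, idx)
      node_id[idx] <<- length(node_idx)
    }
    node_id[idx]
  }
  add_edge <- function(path_idx) {
    a <- ensure_node(path_idx[1])
    b <- ensure_node(path_idx[length(path_idx)])
    edges[[length(edges) + 1L]] <<- list(id = length(edges) + 1L,
                                         node_a = a, node_b = b,
                                         path = xy(path_idx))
  }

  for (nidx in node_idx) {
    for (nb1 in neighbors_of(nidx)) {
      if (is_node[nb1]) {
        key <- paste(min(nidx, nb1), max(nidx, nb1), sep = "-")
        if (!(key %in% seen_direct)) {
          seen_direct <- c(seen_direct, key)
          add_edge(c(nidx, nb1))
        }
        next
      }
      if (visited[nb1]) next
      path <- c(nidx, nb1)
      visited[nb1] <- TRUE
      prev <- nidx; cur <- nb1
      repeat {
        nxt <- setdiff(neighbors_of(cur), prev)
        # on diagonal steps two pixels of the path can both touch `cur`
        nxt <- setdiff(nxt, path)
        if (length(nxt) == 0L) break  # lollipop closing onto its own path
        nxt <- nxt[1]
        path <- c(path, nxt)
        if (is_node[nxt]) break
        visited[nxt] <- TRUE
        prev <- cur; cur <- nxt
      }
      add_edge(path)
    }
  }

  # isolated cycles: remaining unvisited degree-2 pixels
  remaining <- which(skeleton & deg == 2L & !visited & !is_node)
  while (length(remaining) > 0L) {
    anchor <- remaining[1]
    is_node[anchor] <- TRUE
    node_idx <- c(node_idx, anchor)
    node_id[anchor] <- length(node_idx)
    path <- anchor
    visited[anchor] <- TRUE
    prev <- anchor
    cur <- neighbors_of(anchor)[1]
    while (cur != anchor) {
      path <- c(path, cur)
      visited[cur] <- TRUE
      nxt <- setdiff(neighbors_of(cur), c(prev, path))
      prev <- cur
      cur <- if (length(nxt) == 0L) anchor else nxt[1]
    }
    add_edge(c(path, anchor))
    remaining <- which(skeleton & deg == 2L & !visited & !is_node)
  }

  nodes <- if (length(node_idx)) {
    data.frame(id = seq_along(node_idx), xy(node_idx))
  } else {
    data.frame(id = integer(0), x = integer(0), y = integer(0))
  }
  structure(list(nodes = nodes, edges = edges), class = "vessel_graph")
}

#' @export
print.vessel_graph <- function(x, ...) {
  cat(sprintf("<vessel_graph> %d nodes, %d edges\n", nrow(x$nodes),
              length(x$edges)))
  invisible(x)
}

#' Select the centerline nearest a user click
#'
#' Returns, as a [centerline()], the path of the graph edge containing the
#' pixel closest (Euclidean) to the click. Ties on the minimal distance are
#' broken in favor of the lowest edge id.
#'
#' @param graph A [skeleton_to_graph()] result.
#' @param click Numeric `c(x, y)` pixel coordinates (1-based).
#' @param max_click_distance Maximum accepted click-to-vessel distance in
#'   pixels (default 20).
#' @param capillary_id Identifier attached to the returned centerline.
#' @return A [centerline()] whose points are the edge path.
#' @export
select_centerline <- function(graph, click, max_click_distance = 20,
                              capillary_id = NA_character_) {
  stopifnot(inherits(graph, "vessel_graph"), length(click) == 2L)
  if (length(graph$edges) == 0L) {
    stop("vessel graph has no edges", call. = FALSE)
  }
  d_best <- Inf; e_best <- NA_integer_
  for (e in graph$edges) {
    d <- min((e$path[, 1] - click[1])^2 + (e$path[, 2] - click[2])^2)
    if (d < d_best - 1e-12) {  # strict improvement: lowest id wins ties
      d_best <- d; e_best <- e$id
    }
  }
  if (sqrt(d_best) > max_click_distance) {
    stop(sprintf("no vessel within %g px of click (%g, %g); nearest is %.1f px away",
                 max_click_distance, click[1], click[2], sqrt(d_best)),
         call. = FALSE)
  }
  centerline(graph$edges[[e_best]]$path, capillary_id)
}

#' Exclude short centerlines
#'
#' Centerlines of 5 pixels or fewer carry too little intensity structure
#' for the frame-to-frame correlation to be meaningful and are excluded;
#' only centerlines of at least 6 points are retained.
#'
#' @param centerlines List of [centerline()] objects.
#' @return Filtered list.
#' @export
filter_short_centerlines <- function(centerlines) {
  Filter(function(cl) cl$length_px >= 6L, centerlines)
}
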