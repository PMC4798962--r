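# Binary lumen mask -> measured vessel graph.
#
# Skeletonization by Guo-Hall topological thinning (connectivity-preserving,
# 8-connected, one pixel wide), local radii from the Euclidean distance
# transform (maximum inscribed circle), then junction/endpoint detection and
# chain tracing into a vessel_graph. Mask-level morphometrics: vessel area
# fraction and branch-point density.

# Shifted copies of a padded logical matrix: neighbours P2..P9 clockwise
# from north (image rows increase downwards, so "north" = row - 1).
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  rs <- (1 + max(0, -dr)):(nr - max(0, dr))
  cs <- (1 + max(0, -dc)):(nc - max(0, dc))
  out[rs + dr, cs + dc] <- m[rs, cs]
  out
}

#' Skeletonize a binary mask
#'
#' Reduces the foreground to a one-pixel-wide, 8-connected centreline by
#' Guo-Hall thinning. The algorithm preserves the number of connected
#' components of the foreground.
#'
#' @param mask 2D binary matrix (nonzero = foreground), e.g. from
#'   [rasterize_mask()] or [read_mask()].
#' @return Logical matrix of skeleton pixels, same dimensions as `mask`.
#' @export
skeletonize_mask <- function(mask) {
  m <- mask > 0
  stop_if_not(is.matrix(m) && length(dim(m)) == 2, "mask must be a 2D matrix")
  if (!any(m)) stop("mask has empty foreground: nothing to skeletonize",
                    call. = FALSE)
  repeat {
    changed <- FALSE
    for (iter in 0:1) {
      p2 <- shift_mat(m, -1, 0);  p3 <- shift_mat(m, -1, +1)
      p4 <- shift_mat(m, 0, +1);  p5 <- shift_mat(m, +1, +1)
      p6 <- shift_mat(m, +1, 0);  p7 <- shift_mat(m, +1, -1)
      p8 <- shift_mat(m, 0, -1);  p9 <- shift_mat(m, -1, -1)
      C <- (!p2 & (p3 | p4)) + (!p4 & (p5 | p6)) +
        (!p6 & (p7 | p8)) + (!p8 & (p9 | p2))
      N1 <- (p9 | p2) + (p3 | p4) + (p5 | p6) + (p7 | p8)
      N2 <- (p2 | p3) + (p4 | p5) + (p6 | p7) + (p8 | p9)
      N <- pmin(N1, N2)
      m_cond <- if (iter == 0) ((p6 | p7 | !p9) & p8) else ((p2 | p3 | !p5) & p4)
      del <- m & (C == 1) & (N >= 2) & (N <= 3) & !m_cond
      if (any(del)) { m[del] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  m
}

#' Estimate local vessel radii along the skeleton
#'
#' The radius at each skeleton pixel is the maximum-inscribed-circle radius:
#' the Euclidean distance from the pixel centre to the nearest background
#' pixel, corrected by half a pixel for the boundary lying between pixel
#' centres, and scaled to micrometres.
#'
#' @param mask Binary matrix the skeleton was computed from.
#' @param skeleton Logical matrix of skeleton pixels.
#' @param pixel_size um per pixel.
#' @return Numeric matrix with radii (um) at skeleton pixels, NA elsewhere.
#' @export
estimate_local_radii <- function(mask, skeleton, pixel_size = 1) {
  m <- mask > 0
  stop_if_not(all(dim(m) == dim(skeleton)), "mask/skeleton dimension mismatch")
  if (any(skeleton & !m))
    stop("skeleton pixel lies on background: skeleton does not match mask",
         call. = FALSE)
  dm <- EBImage::distmap(matrix(as.numeric(m), nrow(m), ncol(m)))
  out <- matrix(NA_real_, nrow(m), ncol(m))
  out[skeleton] <- pmax(dm[skeleton] - 0.5, 0.5) * pixel_size
  out
}

# 8-neighbour offsets, fixed order for deterministic tracing.
NBR <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
             dc = c(-1, 0, 1, -1, 1, -1, 0, 1))

#' Build a vessel graph from a skeleton
#'
#' Nodes are skeleton pixels with a neighbour count other than 2 (junctions
#' and endpoints); 8-adjacent junction pixels are merged into single nodes
#' at their centroid. Edges trace maximal chains of 2-neighbour pixels
#' between nodes, carrying ordered centreline polylines and per-point radii
#' in micrometres. Isolated cycles become a single self-loop edge anchored
#' at their lexicographically smallest pixel.
#'
#' @param skeleton Logical matrix from [skeletonize_mask()].
#' @param radii Radius matrix from [estimate_local_radii()] (um).
#' @param pixel_size um per pixel.
#' @return A `vessel_graph` (all beds `unassigned`).
#' @export
build_vessel_graph <- function(skeleton, radii, pixel_size = 1) {
  sk <- which(skeleton, arr.ind = TRUE)
  stop_if_not(nrow(sk) > 0, "skeleton is empty")
  nr <- nrow(skeleton)
  key <- function(r, c) (c - 1) * nr + r
  sk_set <- new.env(hash = TRUE, size = nrow(sk))
  for (i in seq_len(nrow(sk)))
    assign(as.character(key(sk[i, 1], sk[i, 2])), i, envir = sk_set)
  lookup <- function(r, c) {
    if (r < 1 || c < 1 || r > nr || c > ncol(skeleton)) return(0L)
    v <- get0(as.character(key(r, c)), envir = sk_set)
    if (is.null(v)) 0L else v
  }
  nbrs <- lapply(seq_len(nrow(sk)), function(i) {
    hits <- integer(0)
    for (k in seq_len(8)) {
      j <- lookup(sk[i, 1] + NBR[k, 1], sk[i, 2] + NBR[k, 2])
      if (j > 0L) hits <- c(hits, j)
    }
    hits
  })
  ncount <- lengths(nbrs)
  is_nodepx <- ncount != 2L

  # cluster 8-adjacent junction pixels (count >= 3) into single nodes
  cluster <- integer(nrow(sk))          # 0 = not a node pixel
  ncl <- 0L
  ord <- order(sk[, 2], sk[, 1])        # lexicographic: by column, then row
  for (i in ord) {
    if (!is_nodepx[i] || cluster[i] != 0L) next
    ncl <- ncl + 1L
    if (ncount[i] >= 3L) {
      stack <- i
      while (length(stack)) {
        cur <- stack[length(stack)]; stack <- stack[-length(stack)]
        if (cluster[cur] != 0L) next
        cluster[cur] <- ncl
        for (j in nbrs[[cur]])
          if (is_nodepx[j] && ncount[j] >= 3L && cluster[j] == 0L)
            stack <- c(stack, j)
      }
    } else cluster[i] <- ncl            # endpoint or isolated pixel
  }

  px_um <- function(i) c((sk[i, 2] - 0.5) * pixel_size,
                         (sk[i, 1] - 0.5) * pixel_size)
  rad_um <- function(i) radii[sk[i, 1], sk[i, 2]]

  node_pos <- matrix(0, ncl, 2)
  node_rad <- numeric(ncl)
  for (cl in seq_len(ncl)) {
    members <- which(cluster == cl)
    pts <- t(vapply(members, px_um, numeric(2)))
    node_pos[cl, ] <- colMeans(pts)
    node_rad[cl] <- mean(vapply(members, rad_um, numeric(1)))
  }
  nodes <- data.frame(id = seq_len(ncl), x = node_pos[, 1], y = node_pos[, 2])

  edges <- list(); eid <- 0L
  add_traced_edge <- function(cl_a, cl_b, path) {
    eid <<- eid + 1L
    pl <- rbind(node_pos[cl_a, , drop = FALSE],
                if (length(path)) t(vapply(path, px_um, numeric(2))),
                node_pos[cl_b, , drop = FALSE])
    rr <- c(node_rad[cl_a],
            if (length(path)) vapply(path, rad_um, numeric(1)),
            node_rad[cl_b])
    edges[[eid]] <<- list(id = eid, node_a = cl_a, node_b = cl_b,
                          polyline = pl, radii = rr,
                          length = polyline_length(pl), bed = "unassigned")
  }

  visited <- logical(nrow(sk))          # chain pixels consumed by tracing
  # trace from every node pixel into each unvisited chain neighbour
  for (i in ord) {
    if (cluster[i] == 0L) next
    for (j in nbrs[[i]]) {
      if (cluster[j] != 0L) next        # node-node adjacency handled below
      if (visited[j]) next
      path <- integer(0)
      prev <- i; cur <- j
      repeat {
        if (cluster[cur] != 0L) break
        visited[cur] <- TRUE
        path <- c(path, cur)
        nxt <- setdiff(nbrs[[cur]], prev)
        if (length(nxt) == 0L) { cur <- NA_integer_; break }
        # staircase corners can briefly see 2 onward pixels; take the one
        # 4-connected to us for a deterministic, shortest continuation
        if (length(nxt) > 1L) {
          d4 <- abs(sk[nxt, 1] - sk[cur, 1]) + abs(sk[nxt, 2] - sk[cur, 2])
          nxt <- nxt[order(d4, nxt)][1]
        }
        prev <- cur; cur <- nxt
      }
      if (is.na(cur)) next              # dangling chain (shouldn't happen)
      add_traced_edge(cluster[i], cluster[cur], path)
    }
  }
  # direct node-node adjacencies (no chain pixels between them)
  seen_pair <- character(0)
  for (i in ord) {
    if (cluster[i] == 0L) next
    for (j in nbrs[[i]]) {
      if (cluster[j] == 0L || cluster[j] == cluster[i]) next
      kk <- paste(min(i, j), max(i, j))
      if (kk %in% seen_pair) next
      seen_pair <- c(seen_pair, kk)
      eid <- eid + 1L
      pl <- rbind(node_pos[cluster[i], ], px_um(i), px_um(j),
                  node_pos[cluster[j], ])
      rr <- c(node_rad[cluster[i]], rad_um(i), rad_um(j), node_rad[cluster[j]])
      keep <- c(TRUE, polyline_length(pl[1:2, , drop = FALSE]) > 1e-9,
                polyline_length(pl[3:4, , drop = FALSE]) > 1e-9, TRUE)
      edges[[eid]] <- list(id = eid, node_a = cluster[i], node_b = cluster[j],
                           polyline = pl[keep, , drop = FALSE],
                           radii = rr[keep],
                           length = polyline_length(pl[keep, , drop = FALSE]),
                           bed = "unassigned")
    }
  }
  # isolated cycles: every pixel has exactly 2 neighbours, none visited
  for (i in ord) {
    if (cluster[i] != 0L || visited[i]) next
    # open a node at the lexicographically smallest pixel of the cycle
    ncl <- ncl + 1L
    cluster[i] <- ncl
    node_pos <- rbind(node_pos, px_um(i))
    node_rad <- c(node_rad, rad_um(i))
    nodes <- rbind(nodes, data.frame(id = ncl, x = px_um(i)[1],
                                     y = px_um(i)[2]))
    path <- integer(0)
    prev <- i; cur <- nbrs[[i]][1]
    while (cluster[cur] == 0L) {
      visited[cur] <- TRUE
      path <- c(path, cur)
      nxt <- setdiff(nbrs[[cur]], prev)
      prev <- cur; cur <- nxt[1]
    }
    add_traced_edge(ncl, ncl, path)
  }
  vessel_graph(nodes, edges, validate = FALSE)
}

#' Prune short terminal spurs from a vessel graph
#'
#' Iteratively removes terminal edges (free endpoint of degree 1) shorter
#' than `min_length`, skipping edges labelled `sprouting_front` (true blind
#' sprouts), then splices edges across any node left with degree 2.
#' Idempotent at fixed `min_length`.
#'
#' @param g A `vessel_graph`.
#' @param min_length Spur threshold, um (default: twice the largest radius
#'   in the graph, which removes discretization whiskers).
#' @return Pruned `vessel_graph`.
#' @export
prune_spurs <- function(g, min_length = NULL) {
  if (is.null(min_length))
    min_length <- 2 * max(vapply(g$edges, function(e) max(e$radii), numeric(1)))
  stop_if_not(min_length >= 0, "min_length must be >= 0")
  repeat {
    deg <- node_degrees(g)
    drop <- vapply(g$edges, function(e) {
      if (e$bed == "sprouting_front" || e$length >= min_length) return(FALSE)
      da <- deg[[as.character(e$node_a)]]; db <- deg[[as.character(e$node_b)]]
      (da == 1L && db >= 2L) || (db == 1L && da >= 2L)
    }, logical(1))
    if (!any(drop)) break
    g$edges <- g$edges[!drop]
    g <- drop_orphan_nodes(g)
    g <- merge_degree2_nodes(g)
  }
  g
}

drop_orphan_nodes <- function(g) {
  used <- unique(unlist(lapply(g$edges, function(e) c(e$node_a, e$node_b))))
  g$nodes <- g$nodes[g$nodes$id %in% used, , drop = FALSE]
  if (!is.null(g$roots))
    g$roots <- Filter(function(id) id %in% used, g$roots)
  g
}

# Splice the two edges meeting at every degree-2 node into one.
merge_degree2_nodes <- function(g) {
  repeat {
    deg <- node_degrees(g)
    protected <- unlist(g$roots %||% list())
    cand <- setdiff(as.integer(names(deg)[deg == 2L]), protected)
    nid <- NA_integer_; inc <- integer(0)
    for (cd in cand) {
      hits <- which(vapply(g$edges, function(e)
        e$node_a == cd || e$node_b == cd, logical(1)))
      if (length(hits) == 2L) { nid <- cd; inc <- hits; break }
      # a single self-loop also gives degree 2: leave those nodes alone
    }
    if (is.na(nid)) break
    e1 <- g$edges[[inc[1]]]; e2 <- g$edges[[inc[2]]]
    # orient e1 to end at nid, e2 to start at nid
    if (e1$node_a == nid) {
      e1$polyline <- e1$polyline[nrow(e1$polyline):1, , drop = FALSE]
      e1$radii <- rev(e1$radii)
      e1[c("node_a", "node_b")] <- e1[c("node_b", "node_a")]
    }
    if (e2$node_b == nid) {
      e2$polyline <- e2$polyline[nrow(e2$polyline):1, , drop = FALSE]
      e2$radii <- rev(e2$radii)
      e2[c("node_a", "node_b")] <- e2[c("node_b", "node_a")]
    }
    merged <- list(id = min(e1$id, e2$id), node_a = e1$node_a,
                   node_b = e2$node_b,
                   polyline = rbind(e1$polyline,
                                    e2$polyline[-1, , drop = FALSE]),
                   radii = c(e1$radii, e2$radii[-1]),
                   length = e1$length + e2$length,
                   bed = if (e1$length >= e2$length) e1$bed else e2$bed)
    g$edges <- c(g$edges[-inc], list(merged))
    g$edges <- g$edges[order(vapply(g$edges, `[[`, integer(1), "id"))]
    g <- drop_orphan_nodes(g)
  }
  g
}

#' Consolidate split junctions
#'
#' Thinning can split one anatomical branch point into two nearby skeleton
#' junctions joined by a very short internal edge (typically where two
#' vessels cross at width). This contracts every edge whose endpoints both
#' have degree >= 3 and whose length is below the local vessel diameter
#' (or an explicit `tol`), merging the junction pair at its midpoint.
#'
#' @param g A `vessel_graph`.
#' @param tol Length threshold, um; `NULL` uses twice the mean of each
#'   edge's endpoint radii (the local diameter).
#' @return Consolidated `vessel_graph`.
#' @export
consolidate_junctions <- function(g, tol = NULL) {
  repeat {
    deg <- node_degrees(g)
    short <- Filter(function(e) {
      if (e$node_a == e$node_b) return(FALSE)
      if (deg[[as.character(e$node_a)]] < 3L ||
          deg[[as.character(e$node_b)]] < 3L) return(FALSE)
      lim <- tol %||% (2 * mean(c(e$radii[1], e$radii[length(e$radii)])))
      e$length < lim
    }, g$edges)
    if (!length(short)) break
    lens <- vapply(short, `[[`, numeric(1), "length")
    ids <- vapply(short, `[[`, integer(1), "id")
    e <- short[[order(lens, ids)[1]]]
    keep_id <- e$node_a; drop_id <- e$node_b
    pa <- unlist(g$nodes[g$nodes$id == keep_id, c("x", "y")])
    pb <- unlist(g$nodes[g$nodes$id == drop_id, c("x", "y")])
    newpos <- (pa + pb) / 2
    g$nodes[g$nodes$id == keep_id, c("x", "y")] <- as.list(newpos)
    g$nodes <- g$nodes[g$nodes$id != drop_id, , drop = FALSE]
    g$edges <- Filter(function(x) x$id != e$id, g$edges)
    g$edges <- lapply(g$edges, function(x) {
      if (x$node_a == drop_id) x$node_a <- keep_id
      if (x$node_b == drop_id) x$node_b <- keep_id
      if (x$node_a == keep_id) x$polyline[1, ] <- newpos
      if (x$node_b == keep_id) x$polyline[nrow(x$polyline), ] <- newpos
      x$length <- polyline_length(x$polyline)
      x
    })
    # contracting can create short self-loops; drop them
    g$edges <- Filter(function(x)
      !(x$node_a == x$node_b && x$length < 2 * max(x$radii)), g$edges)
    if (!is.null(g$roots))
      g$roots <- lapply(g$roots, function(id) if (id == drop_id) keep_id else id)
  }
  merge_degree2_nodes(g)
}

#' Extract a measured vessel graph from a binary mask
#'
#' Full extraction pipeline: skeletonize, estimate radii, build the graph,
#' prune spurs and consolidate split junctions.
#'
#' @param mask Binary matrix (nonzero = foreground).
#' @param pixel_size um per pixel.
#' @param min_spur_length Spur threshold passed to [prune_spurs()];
#'   default twice the largest estimated radius.
#' @param consolidate Logical; run [consolidate_junctions()] (default TRUE).
#' @param reference Optional `vessel_graph` carrying trusted bed labels
#'   (e.g. the generating graph, or one built from a label image); labels
#'   are transferred before pruning so that true sprouts are protected.
#' @return A `vessel_graph`.
#' @export
extract_network <- function(mask, pixel_size = 1, min_spur_length = NULL,
                            consolidate = TRUE, reference = NULL) {
  sk <- skeletonize_mask(mask)
  rad <- estimate_local_radii(mask, sk, pixel_size)
  g <- build_vessel_graph(sk, rad, pixel_size)
  if (!is.null(reference)) g <- transfer_bed_labels(g, reference)
  g <- prune_spurs(g, min_spur_length)
  if (consolidate) g <- consolidate_junctions(g)
  g
}

#' Vessel area fraction of a mask
#'
#' Foreground pixel count divided by the region-of-interest pixel count
#' (the whole image if no ROI is given): the standard vessel-density readout.
#'
#' @param mask Binary matrix.
#' @param roi Optional binary ROI matrix of the same size.
#' @return Fraction in \[0, 1\].
#' @export
vessel_area_fraction <- function(mask, roi = NULL) {
  m <- mask > 0
  if (is.null(roi)) return(sum(m) / length(m))
  r <- roi > 0
  stop_if_not(all(dim(r) == dim(m)), "roi/mask dimension mismatch")
  stop_if_not(any(r), "roi is empty")
  sum(m & r) / sum(r)
}

#' Branch-point density of a vessel graph
#'
#' Number of nodes with degree >= 3 divided by the analysed area.
#'
#' @param g A `vessel_graph`.
#' @param area_mm2 Area in mm^2 (> 0).
#' @return Branch points per mm^2.
#' @export
branchpoint_density <- function(g, area_mm2) {
  stop_if_not(is_scalar_num(area_mm2) && area_mm2 > 0, "area_mm2 must be > 0")
  sum(node_degrees(g) >= 3) / area_mm2
}
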