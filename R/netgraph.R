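# Conversion of the pixel skeleton (plus cisternae and puncta) into an
# attributed network graph: nodes at junctions, free ends, puncta and
# cisterna centroids; edges along each tubule carrying a property vector.

offs8 <- cbind(dy = rep(-1:1, 3), dx = rep(-1:1, each = 3))[-5, ]

# Core extraction: junction pixels have >= 3 skeleton neighbours
# (8-connectivity), free ends exactly 1; adjacent junction pixels are
# clustered into a single node at their centroid. Each edge stores its
# ordered pixel path.
extract_graph_once <- function(sk, pixel_size_nm, forced = NULL) {
  ny <- nrow(sk); nx <- ncol(sk)
  nc <- neighbour_count8(sk); nc[!sk] <- 0
  # branch count = number of 0->1 transitions around the pixel (crossing
  # number); raw neighbour counts over-call junctions on thinning staircases
  p2 <- mat_shift(sk, -1,  0, FALSE); p3 <- mat_shift(sk, -1,  1, FALSE)
  p4 <- mat_shift(sk,  0,  1, FALSE); p5 <- mat_shift(sk,  1,  1, FALSE)
  p6 <- mat_shift(sk,  1,  0, FALSE); p7 <- mat_shift(sk,  1, -1, FALSE)
  p8 <- mat_shift(sk,  0, -1, FALSE); p9 <- mat_shift(sk, -1, -1, FALSE)
  seqs <- list(p2, p3, p4, p5, p6, p7, p8, p9, p2)
  trans <- matrix(0L, ny, nx)
  for (i in 1:8) trans <- trans + (!seqs[[i]] & seqs[[i + 1]])
  node_px <- sk & (trans >= 3 | nc <= 1)
  if (!is.null(forced)) node_px <- node_px | (sk & forced)
  nodelab <- label8(node_px)
  n_node <- max(nodelab)
  pathpx <- sk & !node_px
  visited <- matrix(FALSE, ny, nx)
  node_pts <- vector("list", max(n_node, 1))
  if (n_node > 0) {
    w <- which(nodelab > 0, arr.ind = TRUE)
    lb <- nodelab[nodelab > 0]
    for (i in seq_len(n_node)) node_pts[[i]] <- w[lb == i, , drop = FALSE]
  }
  nbrs <- function(y, x) {
    yy <- y + offs8[, 1]; xx <- x + offs8[, 2]
    ok <- yy >= 1 & yy <= ny & xx >= 1 & xx <= nx
    cbind(yy[ok], xx[ok])
  }
  edges <- list(); paths <- list()
  add_edge <- function(from, to, path) {
    edges[[length(edges) + 1]] <<- c(from, to)
    paths[[length(paths) + 1]] <<- path
  }
  trace_path <- function(entry_cluster, sy, sx) {
    path <- matrix(c(sy, sx), 1)
    visited[sy, sx] <<- TRUE
    cur <- c(sy, sx)
    repeat {
      nb <- nbrs(cur[1], cur[2])
      labs <- nodelab[nb]
      is_node <- labs > 0
      term <- unique(labs[is_node])
      term_other <- setdiff(term, entry_cluster)
      if (length(term_other) > 0) return(list(to = term_other[1], path = path))
      if (entry_cluster %in% term && nrow(path) >= 3)
        return(list(to = entry_cluster, path = path))
      cand <- nb[pathpx[nb] & !visited[nb], , drop = FALSE]
      if (nrow(cand) == 0) {
        if (entry_cluster %in% term && nrow(path) >= 1)
          return(list(to = entry_cluster, path = path))
        return(list(to = NA_integer_, path = path))  # dangling: new free end
      }
      # prefer 4-connected continuation to avoid diagonal shortcuts
      d4 <- abs(cand[, 1] - cur[1]) + abs(cand[, 2] - cur[2]) == 1
      nxt <- if (any(d4)) cand[which(d4)[1], ] else cand[1, ]
      visited[nxt[1], nxt[2]] <<- TRUE
      path <- rbind(path, nxt)
      cur <- nxt
    }
  }
  direct_pairs <- character(0)
  extra_nodes <- list()
  for (cl in seq_len(n_node)) {
    for (i in seq_len(nrow(node_pts[[cl]]))) {
      p <- node_pts[[cl]][i, ]
      nb <- nbrs(p[1], p[2])
      # direct cluster-cluster adjacency (edge with no interior pixels)
      labs <- nodelab[nb]
      for (c2 in unique(labs[labs > 0 & labs > cl])) {
        key <- paste(cl, c2)
        if (!(key %in% direct_pairs)) {
          direct_pairs <- c(direct_pairs, key)
          add_edge(cl, c2, matrix(numeric(0), 0, 2))
        }
      }
      starts <- nb[pathpx[nb] & !visited[nb], , drop = FALSE]
      for (j in seq_len(nrow(starts))) {
        s <- starts[j, ]
        if (visited[s[1], s[2]]) next
        tr <- trace_path(cl, s[1], s[2])
        if (is.na(tr$to)) {
          # dangling path end: promote the last pixel to a node and register
          # it so traces arriving from the other side terminate on it
          endp <- tr$path[nrow(tr$path), , drop = FALSE]
          extra_nodes[[length(extra_nodes) + 1]] <- endp
          to_id <- n_node + length(extra_nodes)
          nodelab[endp[1, 1], endp[1, 2]] <- to_id
          pathpx[endp[1, 1], endp[1, 2]] <- FALSE
          if (nrow(tr$path) > 1)
            add_edge(cl, to_id, tr$path[-nrow(tr$path), , drop = FALSE])
          else add_edge(cl, to_id, matrix(numeric(0), 0, 2))
        } else add_edge(cl, tr$to, tr$path)
      }
    }
  }
  # pure cycles with no junction: promote one pixel to a node and trace
  leftover <- pathpx & !visited
  while (any(leftover)) {
    p <- which(leftover, arr.ind = TRUE)[1, , drop = FALSE]
    extra_nodes[[length(extra_nodes) + 1]] <- p
    new_id <- n_node + length(extra_nodes)
    pathpx[p[1], p[2]] <- FALSE
    nodelab[p[1], p[2]] <- new_id
    nb <- nbrs(p[1], p[2])
    starts <- nb[pathpx[nb] & !visited[nb], , drop = FALSE]
    if (nrow(starts) > 0) {
      tr <- trace_path(new_id, starts[1, 1], starts[1, 2])
      add_edge(new_id, if (is.na(tr$to)) new_id else tr$to, tr$path)
    }
    leftover <- pathpx & !visited
  }
  all_nodes <- c(lapply(seq_len(n_node), function(i) node_pts[[i]]), extra_nodes)
  pos <- t(vapply(all_nodes, function(m) colMeans(m[, 1:2, drop = FALSE]),
                  numeric(2)))
  nodes <- data.frame(id = seq_along(all_nodes),
                      y = pos[, 1], x = pos[, 2],
                      type = "junction", stringsAsFactors = FALSE)
  um <- pixel_size_nm / 1000
  ne <- length(edges)
  ed <- data.frame(id = seq_len(ne),
                   from = vapply(edges, `[`, numeric(1), 1),
                   to = vapply(edges, `[`, numeric(1), 2))
  ed$n_px <- vapply(paths, nrow, integer(1))
  ed$length_um <- vapply(seq_len(ne), function(i) {
    full <- rbind(pos[ed$from[i], ], paths[[i]], pos[ed$to[i], ])
    sum(sqrt(rowSums(diff(full)^2))) * um
  }, numeric(1))
  ed$is_cisterna_internal <- FALSE
  g <- structure(list(nodes = nodes, edges = ed, paths = paths,
                      node_pixels = all_nodes,
                      pixel_size_nm = pixel_size_nm),
                 class = "er_graph")
  update_node_types(g)
}

node_degrees <- function(g) {
  deg <- integer(nrow(g$nodes))
  if (nrow(g$edges)) {
    t1 <- table(factor(g$edges$from, levels = g$nodes$id))
    t2 <- table(factor(g$edges$to, levels = g$nodes$id))
    deg <- as.integer(t1 + t2)
  }
  deg
}

update_node_types <- function(g) {
  deg <- node_degrees(g)
  g$nodes$degree <- deg
  fixed <- g$nodes$type %in% c("cisterna", "punctum", "resolver")
  g$nodes$type[!fixed] <- ifelse(deg[!fixed] >= 3, "junction",
                          ifelse(deg[!fixed] == 1, "free_end",
                          ifelse(deg[!fixed] == 0, "punctum", "connector")))
  g
}

# Junction hygiene: skeletonisation splits what is physically one junction
# into clusters a few pixels apart, connected by sub-scale edges (and, for
# crossing tubules, by lens-shaped micro self-loops). Junction-junction
# edges shorter than `min_sep_px` are contracted to a single node and
# self-loops shorter than `2 * min_sep_px` dropped.
merge_close_junctions <- function(g, min_sep_px = 2.5) {
  if (!nrow(g$edges)) return(g)
  px <- g$pixel_size_nm
  repeat {
    g <- update_node_types(g)
    len_px <- g$edges$length_um * 1000 / px
    deg <- g$nodes$degree
    loops <- which(g$edges$from == g$edges$to & len_px < 2 * min_sep_px)
    if (length(loops)) {
      g$edges <- g$edges[-loops[1], ]
      g$paths <- g$paths[-loops[1]]
      next
    }
    tiny <- which(g$edges$from != g$edges$to & len_px < min_sep_px &
                    deg[g$edges$from] >= 3 & deg[g$edges$to] >= 3)
    if (!length(tiny)) break
    i <- tiny[1]
    a <- g$edges$from[i]; b <- g$edges$to[i]
    g$nodes$y[a] <- (g$nodes$y[a] + g$nodes$y[b]) / 2
    g$nodes$x[a] <- (g$nodes$x[a] + g$nodes$x[b]) / 2
    g$node_pixels[[a]] <- rbind(g$node_pixels[[a]], g$node_pixels[[b]])
    g$edges <- g$edges[-i, ]; g$paths <- g$paths[-i]
    g$edges$from[g$edges$from == b] <- a
    g$edges$to[g$edges$to == b] <- a
  }
  # compact node ids
  used <- sort(unique(c(g$edges$from, g$edges$to,
                        g$nodes$id[g$nodes$degree > 0 |
                                     g$nodes$type %in% c("punctum", "cisterna")])))
  if (!length(used)) used <- g$nodes$id
  remap <- match(g$nodes$id, used)
  keep <- !is.na(remap)
  g$nodes <- g$nodes[keep, , drop = FALSE]
  g$node_pixels <- g$node_pixels[keep]
  g$nodes$id <- remap[keep]
  ord <- order(g$nodes$id)
  g$nodes <- g$nodes[ord, , drop = FALSE]
  g$node_pixels <- g$node_pixels[ord]
  if (nrow(g$edges)) {
    g$edges$from <- match(g$edges$from, used)
    g$edges$to <- match(g$edges$to, used)
    g$edges$id <- seq_len(nrow(g$edges))
  }
  rownames(g$nodes) <- rownames(g$edges) <- NULL
  update_node_types(g)
}

#' Convert a pixel skeleton to a network graph
#'
#' Junction pixels (>= 3 skeleton neighbours, 8-connected) are clustered
#' into single nodes; free ends become degree-1 nodes; each tubule edge
#' carries its ordered pixel path and length (sum of 1 or sqrt(2) pixel
#' steps). Short free-end spurs (below `fwhm_min_px`) are pruned by default.
#'
#' @param skeleton An `er_skeleton` (or logical matrix).
#' @param pixel_size_nm Pixel size in nm.
#' @param prune_spurs Remove free-end edges shorter than `fwhm_min_px`.
#' @param fwhm_min_px Minimum tubule FWHM in px (spur-pruning scale).
#' @return An `er_graph`.
#' @export
skeleton_to_graph <- function(skeleton, pixel_size_nm, prune_spurs = TRUE,
                              fwhm_min_px = 5) {
  sk <- if (inherits(skeleton, "er_skeleton")) skeleton$pixels else skeleton
  if (!any(sk)) {
    return(structure(list(
      nodes = data.frame(id = integer(0), y = numeric(0), x = numeric(0),
                         type = character(0), degree = integer(0)),
      edges = data.frame(id = integer(0), from = integer(0), to = integer(0),
                         n_px = integer(0), length_um = numeric(0),
                         is_cisterna_internal = logical(0)),
      paths = list(), node_pixels = list(), pixel_size_nm = pixel_size_nm),
      class = "er_graph"))
  }
  g <- extract_stable(sk, pixel_size_nm, fwhm_min_px)
  if (prune_spurs && nrow(g$edges)) {
    deg <- node_degrees(g)
    spur <- g$edges$length_um * 1000 / pixel_size_nm < fwhm_min_px &
      (deg[g$edges$from] == 1 | deg[g$edges$to] == 1) &
      g$edges$from != g$edges$to
    if (any(spur)) {
      sk2 <- sk
      for (i in which(spur)) {
        if (nrow(g$paths[[i]]) > 0) sk2[g$paths[[i]]] <- FALSE
        for (nid in c(g$edges$from[i], g$edges$to[i])) {
          if (deg[nid] == 1) sk2[g$node_pixels[[nid]]] <- FALSE
        }
      }
      sk2 <- thin_connected(sk2)
      if (any(sk2)) g <- extract_stable(sk2, pixel_size_nm, fwhm_min_px)
    }
  }
  merge_close_junctions(g, min_sep_px = fwhm_min_px / 2)
}

# Extraction with junction-lens absorption: micro pixel-cycles at a
# junction (left by thinning when tubules cross slightly off-centre) show
# up as tiny self-loops; their pixels really belong to the junction, so
# they are forced into the node cluster and the graph re-extracted.
extract_stable <- function(sk, pixel_size_nm, fwhm_min_px) {
  forced <- NULL
  for (pass in 1:3) {
    g <- extract_graph_once(sk, pixel_size_nm, forced = forced)
    len_px <- g$edges$length_um * 1000 / pixel_size_nm
    tiny_loop <- which(g$edges$from == g$edges$to & len_px < fwhm_min_px)
    if (!length(tiny_loop)) break
    if (is.null(forced)) forced <- matrix(FALSE, nrow(sk), ncol(sk))
    for (i in tiny_loop) {
      if (nrow(g$paths[[i]])) forced[g$paths[[i]]] <- TRUE
      forced[g$node_pixels[[g$edges$from[i]]]] <- TRUE
    }
  }
  g
}

#' @export
print.er_graph <- function(x, ...) {
  cat(sprintf("ER network graph: %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  if (nrow(x$nodes)) {
    tb <- table(x$nodes$type)
    cat("  nodes:", paste(names(tb), tb, sep = " = ", collapse = ", "), "\n")
  }
  if (nrow(x$edges))
    cat(sprintf("  total tubule length %.2f um\n",
                sum(x$edges$length_um[!x$edges$is_cisterna_internal])))
  invisible(x)
}

#' Resolve duplicate edges and self-loops
#'
#' Parallel edges connecting the same two nodes are resolved by inserting a
#' degree-2 resolver node at the midpoint of one arm, repeated until the
#' graph is simple; resolver nodes are excluded from junction statistics.
#'
#' @param g An `er_graph`.
#' @return The resolved `er_graph`.
#' @export
resolve_duplicates <- function(g) {
  repeat {
    if (!nrow(g$edges)) break
    key <- paste(pmin(g$edges$from, g$edges$to), pmax(g$edges$from, g$edges$to))
    dup_idx <- which(duplicated(key) | g$edges$from == g$edges$to)
    if (!length(dup_idx)) break
    i <- dup_idx[1]
    path <- g$paths[[i]]
    new_id <- nrow(g$nodes) + 1L
    if (nrow(path) >= 2) {
      mid <- ceiling(nrow(path) / 2)
      pos <- path[mid, ]
      p1 <- path[seq_len(mid - 1), , drop = FALSE]
      p2 <- path[seq(mid + 1, nrow(path)), , drop = FALSE]
      if (mid == nrow(path)) p2 <- matrix(numeric(0), 0, 2)
    } else {
      pos <- (unlist(g$nodes[g$edges$from[i], c("y", "x")]) +
                unlist(g$nodes[g$edges$to[i], c("y", "x")])) / 2
      p1 <- p2 <- matrix(numeric(0), 0, 2)
    }
    g$nodes <- rbind(g$nodes, data.frame(id = new_id, y = pos[1], x = pos[2],
                                         type = "resolver", degree = 2L))
    g$node_pixels[[new_id]] <- matrix(round(pos), 1)
    um <- g$pixel_size_nm / 1000
    seg_len <- function(a, b, path) {
      full <- rbind(a, path, b)
      sum(sqrt(rowSums(diff(full)^2))) * um
    }
    from <- g$edges$from[i]; to <- g$edges$to[i]
    posf <- unlist(g$nodes[from, c("y", "x")])
    post <- unlist(g$nodes[to, c("y", "x")])
    tmpl <- g$edges[i, ]
    e1 <- tmpl; e1$id <- max(g$edges$id) + 1L; e1$from <- from; e1$to <- new_id
    e1$n_px <- nrow(p1); e1$length_um <- seg_len(posf, p1, pos)
    e2 <- tmpl; e2$id <- max(g$edges$id) + 2L; e2$from <- new_id; e2$to <- to
    e2$n_px <- nrow(p2); e2$length_um <- seg_len(pos, p2, post)
    g$edges <- rbind(g$edges[-i, ], e1, e2)
    g$paths <- c(g$paths[-i], list(p1), list(p2))
  }
  rownames(g$edges) <- NULL
  g$edges$id <- seq_len(nrow(g$edges))
  update_node_types(g)
}

#' Centre-weighted width of an edge
#'
#' Mean width over the edge's pixel path excluding pixels within an
#' exclusion distance of each endpoint node; the exclusion distance is the
#' maximum of the initial (whole-edge mean) widths of the tubules connected
#' to that node. Edges entirely within the exclusion zones fall back to the
#' unweighted mean and are flagged.
#'
#' @param g An `er_graph`.
#' @param widthmap An `er_widthmap`.
#' @param width_column Which width estimate to average (default the
#'   calibrated diameter `2 * calibrated_radius_nm`).
#' @return `g` with edge columns `mean_width_nm`, `centre_width_nm`,
#'   `centre_fallback`.
#' @export
centre_weighted_width <- function(g, widthmap,
                                  width_column = "calibrated_radius_nm") {
  wm <- matrix(NA_real_, max(widthmap$table$y, 1), max(widthmap$table$x, 1))
  wmat_idx <- cbind(widthmap$table$y, widthmap$table$x)
  wvals <- widthmap$table[[width_column]]
  if (width_column == "calibrated_radius_nm") wvals <- 2 * wvals
  wm[wmat_idx] <- wvals
  ne <- nrow(g$edges)
  path_w <- vector("list", ne)
  for (i in seq_len(ne)) {
    path <- g$paths[[i]]
    path_w[[i]] <- if (nrow(path))
      wm[cbind(pmin(path[, 1], nrow(wm)), pmin(path[, 2], ncol(wm)))]
    else numeric(0)
  }
  g$edges$mean_width_nm <- vapply(path_w, function(v)
    if (length(v) && any(is.finite(v))) mean(v, na.rm = TRUE) else NA_real_,
    numeric(1))
  excl_px <- numeric(nrow(g$nodes))
  for (n in g$nodes$id) {
    inc <- g$edges$mean_width_nm[g$edges$from == n | g$edges$to == n]
    inc <- inc[is.finite(inc)]
    excl_px[n] <- if (length(inc)) max(inc) / g$pixel_size_nm else 0
  }
  cw <- numeric(ne); fb <- logical(ne)
  for (i in seq_len(ne)) {
    path <- g$paths[[i]]
    if (!nrow(path)) { cw[i] <- g$edges$mean_width_nm[i]; fb[i] <- TRUE; next }
    pf <- unlist(g$nodes[g$edges$from[i], c("y", "x")])
    pt <- unlist(g$nodes[g$edges$to[i], c("y", "x")])
    df <- sqrt((path[, 1] - pf[1])^2 + (path[, 2] - pf[2])^2)
    dt <- sqrt((path[, 1] - pt[1])^2 + (path[, 2] - pt[2])^2)
    keep <- df > excl_px[g$edges$from[i]] & dt > excl_px[g$edges$to[i]]
    v <- path_w[[i]][keep]
    v <- v[is.finite(v)]
    if (length(v)) cw[i] <- mean(v)
    else { cw[i] <- g$edges$mean_width_nm[i]; fb[i] <- TRUE }
  }
  g$edges$centre_width_nm <- cw
  g$edges$centre_fallback <- fb
  g
}

circ_mean_deg <- function(deg) {
  rad <- deg * pi / 180
  s <- mean(sin(rad)); c <- mean(cos(rad))
  list(mean_deg = (atan2(s, c) * 180 / pi) %% 360,
       resultant = sqrt(s^2 + c^2))
}

#' Node branch angles, circular statistics and strength
#'
#' Branch angles are measured between chords drawn from the node to the
#' midpoint of each incident edge's pixel path; the angles reported are
#' those between circularly consecutive chords (summing to 360 degrees for
#' degree >= 2). Strength is the sum of the centre widths of the incident
#' edges. Circular summaries (mean direction, resultant length) follow the
#' standard conventions.
#'
#' @param g An `er_graph` (after [centre_weighted_width] for strength).
#' @return `g` with node columns `strength`, `mean_direction_deg`,
#'   `resultant_length` and a list column `branch_angles_deg`.
#' @export
node_properties <- function(g) {
  nn <- nrow(g$nodes)
  strength <- numeric(nn)
  mean_dir <- rep(NA_real_, nn); resl <- rep(NA_real_, nn)
  angles <- vector("list", nn)
  has_cw <- "centre_width_nm" %in% names(g$edges)
  for (n in seq_len(nn)) {
    inc <- which(g$edges$from == n | g$edges$to == n)
    if (!length(inc)) { angles[[n]] <- numeric(0); next }
    if (has_cw) {
      wsum <- g$edges$centre_width_nm[inc]
      strength[n] <- sum(wsum[is.finite(wsum)])
    }
    pos <- unlist(g$nodes[n, c("y", "x")])
    dirs <- numeric(0)
    for (i in inc) {
      path <- g$paths[[i]]
      mid <- if (nrow(path)) path[ceiling(nrow(path) / 2), ]
      else unlist(g$nodes[if (g$edges$from[i] == n) g$edges$to[i]
                          else g$edges$from[i], c("y", "x")])
      v <- c(mid[1] - pos[1], mid[2] - pos[2])
      if (all(v == 0)) next
      dirs <- c(dirs, (atan2(-v[1], v[2]) * 180 / pi) %% 360)
      if (g$edges$from[i] == n && g$edges$to[i] == n) {
        # self loop contributes a second chord (other half of the loop)
        q <- path[max(1, round(nrow(path) * 3 / 4)), ]
        v2 <- c(q[1] - pos[1], q[2] - pos[2])
        if (!all(v2 == 0)) dirs <- c(dirs, (atan2(-v2[1], v2[2]) * 180 / pi) %% 360)
      }
    }
    if (length(dirs) >= 2) {
      sd <- sort(dirs)
      angles[[n]] <- diff(c(sd, sd[1] + 360))
    } else angles[[n]] <- numeric(0)
    if (length(dirs)) {
      cs <- circ_mean_deg(dirs)
      mean_dir[n] <- cs$mean_deg; resl[n] <- cs$resultant
    }
  }
  g$nodes$strength <- strength
  g$nodes$mean_direction_deg <- mean_dir
  g$nodes$resultant_length <- resl
  g$nodes$branch_angles_deg <- I(angles)
  g
}

#' Attach cisternae to the graph
#'
#' Each cisterna becomes a single node at its intensity-weighted centroid,
#' connected to every graph node lying on (or just outside) the cisterna
#' boundary. Connector edges are flagged `is_cisterna_internal`, get the
#' global mean centre-width of all tubules and their Euclidean length; they
#' enter graph-theoretic metrics but are excluded from tubule statistics.
#' Tubule edges whose pixel path lies mostly inside a cisterna are flagged
#' likewise.
#'
#' @param g An `er_graph`.
#' @param cisternae An `er_cisternae`.
#' @param frame Intensity matrix for the intensity weighting.
#' @return The augmented `er_graph`; cisterna node ids are recorded in
#'   `cisterna_nodes` (named by cisterna id).
#' @export
attach_cisternae <- function(g, cisternae, frame) {
  if (is.null(cisternae) || nrow(cisternae$table) == 0) {
    g$cisterna_nodes <- integer(0)
    return(g)
  }
  um <- g$pixel_size_nm / 1000
  has_cw <- "centre_width_nm" %in% names(g$edges)
  mean_cw <- if (has_cw && nrow(g$edges))
    mean(g$edges$centre_width_nm[!g$edges$is_cisterna_internal], na.rm = TRUE)
  else NA_real_
  # flag tubule edges running inside cisternae
  if (nrow(g$edges)) {
    inside <- vapply(seq_len(nrow(g$edges)), function(i) {
      path <- g$paths[[i]]
      if (!nrow(path)) return(FALSE)
      mean(cisternae$labels[path] > 0) > 0.5
    }, logical(1))
    g$edges$is_cisterna_internal <- g$edges$is_cisterna_internal | inside
  }
  cis_nodes <- integer(nrow(cisternae$table))
  for (ci in seq_len(nrow(cisternae$table))) {
    id <- cisternae$table$id[ci]
    reg <- cisternae$labels == id
    pts <- which(reg, arr.ind = TRUE)
    wts <- frame[reg]
    if (sum(wts) <= 0) wts <- rep(1, length(wts))
    cy <- sum(pts[, 1] * wts) / sum(wts)
    cx <- sum(pts[, 2] * wts) / sum(wts)
    new_id <- nrow(g$nodes) + 1L
    newrow <- g$nodes[0, ]
    newrow[1, c("id", "y", "x")] <- list(new_id, cy, cx)
    newrow$type <- "cisterna"; newrow$degree <- 0L
    g$nodes <- rbind(g$nodes, newrow)
    g$node_pixels[[new_id]] <- matrix(round(c(cy, cx)), 1)
    cis_nodes[ci] <- new_id
    # connect to graph nodes on / near the boundary
    ring <- dilate_disc(reg, 2)
    near <- which(g$nodes$id != new_id &
                    g$nodes$type %in% c("junction", "free_end", "connector",
                                        "punctum") &
                    ring[cbind(pmax(1, pmin(nrow(ring), round(g$nodes$y))),
                               pmax(1, pmin(ncol(ring), round(g$nodes$x))))])
    for (n in near) {
      eid <- if (nrow(g$edges)) max(g$edges$id) + 1L else 1L
      erow <- g$edges[0, ]
      erow[1, c("id", "from", "to")] <- list(eid, new_id, g$nodes$id[n])
      erow$n_px <- 0L
      erow$length_um <- sqrt((cy - g$nodes$y[n])^2 + (cx - g$nodes$x[n])^2) * um
      erow$is_cisterna_internal <- TRUE
      if (has_cw) { erow$mean_width_nm <- mean_cw
                    erow$centre_width_nm <- mean_cw
                    erow$centre_fallback <- FALSE }
      g$edges <- rbind(g$edges, erow)
      g$paths <- c(g$paths, list(matrix(numeric(0), 0, 2)))
    }
  }
  names(cis_nodes) <- cisternae$table$id
  g$cisterna_nodes <- cis_nodes
  rownames(g$edges) <- NULL
  update_node_types(g)
}

#' Add puncta as graph nodes
#'
#' Each punctum (bright region below the cisterna area cut-off) is snapped
#' to the nearest existing skeleton node within `fwhm_min_px` (retyping it
#' as a punctum), or inserted as an isolated punctum node.
#'
#' @param g An `er_graph`.
#' @param puncta Data frame with `y`, `x` (px) from [segment_cisternae].
#' @param fwhm_min_px Snap radius in pixels.
#' @return The augmented `er_graph`.
#' @export
attach_puncta <- function(g, puncta, fwhm_min_px = 5) {
  if (is.null(puncta) || nrow(puncta) == 0) return(g)
  for (i in seq_len(nrow(puncta))) {
    if (nrow(g$nodes)) {
      d <- sqrt((g$nodes$y - puncta$y[i])^2 + (g$nodes$x - puncta$x[i])^2)
      d[!g$nodes$type %in% c("junction", "free_end", "connector")] <- Inf
      j <- which.min(d)
      if (length(j) && is.finite(d[j]) && d[j] <= fwhm_min_px) {
        g$nodes$type[j] <- "punctum"
        next
      }
    }
    new_id <- nrow(g$nodes) + 1L
    newrow <- g$nodes[0, ]
    newrow[1, c("id", "y", "x")] <- list(new_id, puncta$y[i], puncta$x[i])
    newrow$type <- "punctum"; newrow$degree <- 0L
    g$nodes <- rbind(g$nodes, newrow)
    g$node_pixels[[new_id]] <- matrix(round(c(puncta$y[i], puncta$x[i])), 1)
  }
  g
}

#' Convert an `er_graph` to an igraph object
#'
#' Node and edge attributes are carried over; list columns are collapsed to
#' comma-separated strings so the result can be serialised to GraphML.
#'
#' @param g An `er_graph`.
#' @return An [igraph::igraph] object.
#' @export
as_igraph <- function(g) {
  nd <- g$nodes
  for (cl in names(nd)) {
    if (is.list(nd[[cl]]))
      nd[[cl]] <- vapply(nd[[cl]], paste, character(1), collapse = ",")
  }
  nd$name <- as.character(nd$id)
  names(nd)[names(nd) == "id"] <- "node_id"   # igraph reserves 'id' in GraphML
  ed <- g$edges
  if (nrow(ed)) {
    ed$from <- as.character(ed$from); ed$to <- as.character(ed$to)
  }
  igraph::graph_from_data_frame(
    d = ed[, c("from", "to",
               setdiff(names(ed), c("from", "to"))), drop = FALSE],
    directed = FALSE,
    vertices = nd[, c("name", setdiff(names(nd), "name")), drop = FALSE])
}
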