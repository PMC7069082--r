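#' Topology-preserving 3D skeletonization
#'
#' Iterative ordered thinning: border voxels are peeled in six directional
#' subiterations, deleting only simple points (deletion preserves the
#' foreground 26-topology and background 6-topology) that are not curve
#' endpoints, until stable. The result is a one-voxel-wide medial set
#' homotopic to the mask.
#'
#' @param vessel_mask non-empty logical 3D array.
#' @return logical array of skeleton voxels.
#' @export
skeletonize_3d <- function(vessel_mask) {
  m <- as_array3(vessel_mask)
  if (!any(m)) stop("mask is empty")
  out <- cpp_thin3d(as.logical(m), dim(m))
  dim(out) <- dim(vessel_mask)
  out
}

#' Local vessel radius from the mask (Euclidean distance transform)
#'
#' Distance from each mask voxel to the nearest background voxel, in mm;
#' sampled along skeleton centerlines it estimates the local tube radius.
#'
#' @param mask logical array.
#' @param spacing_mm voxel spacing (mm).
#' @export
radius_map_from_mask <- function(mask, spacing_mm = 0.1) {
  distance_transform(mask, spacing_mm)
}

# 26-neighbor adjacency among skeleton voxels.
# Returns list(ids per voxel), voxel coords, and linear indices.
skeleton_adjacency <- function(sk) {
  d <- dim(sk)
  lin <- which(sk)
  n <- length(lin)
  id <- integer(prod(d)); id[lin] <- seq_len(n)
  co <- arrayInd(lin, d)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  from <- integer(0); to <- integer(0)
  for (r in seq_len(nrow(offs))) {
    nb <- cbind(co[, 1] + offs[r, 1], co[, 2] + offs[r, 2], co[, 3] + offs[r, 3])
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    nlin <- nb[ok, 1] + d[1] * (nb[ok, 2] - 1) + d[1] * d[2] * (nb[ok, 3] - 1)
    hit <- id[nlin] > 0
    from <- c(from, which(ok)[hit])
    to <- c(to, id[nlin[hit]])
  }
  adj <- split(to, factor(from, levels = seq_len(n)))
  list(adj = adj, coords = co, lin = lin, n = n)
}

#' Convert a skeleton into a vessel network graph
#'
#' Nodes are skeleton voxels whose 26-neighborhood degree differs from 2:
#' endpoints (degree <= 1) and junctions (degree >= 3); 26-adjacent junction
#' voxels are merged into a single node at their centroid. Edges are the
#' maximal degree-2 centerline paths between nodes. Per edge: length is the
#' summed Euclidean inter-voxel step length, chord the Euclidean distance
#' between the path endpoints, tortuosity = chord/length (1 = straight),
#' radius the mean of `radius_map` along the path. Node-free cycles get one
#' artificial node at their lowest-index voxel. Terminal spurs shorter than
#' `prune_spur_mm` are removed and pass-through nodes re-merged.
#'
#' @param skeleton logical array from [skeletonize_3d()].
#' @param radius_map numeric array of local radii (mm), e.g. from
#'   [radius_map_from_mask()]; `NULL` gives NA radii.
#' @param spacing_mm voxel spacing (mm), scalar or length 3.
#' @param prune_spur_mm terminal branches shorter than this are pruned
#'   (default two voxels; use 0 to disable).
#' @param consolidate merge sub-resolution junction clusters (see
#'   [consolidate_junctions()]); default TRUE.
#' @return object of class `vessel_graph`: `nodes` (data.frame id, x, y, z in
#'   voxel coords, degree), `edges` (data.frame from, to, length_mm,
#'   chord_mm, radius_mm, tortuosity, n_vox), `paths` (list of voxel-coord
#'   matrices), `spacing_mm`.
#' @export
skeleton_to_graph <- function(skeleton, radius_map = NULL, spacing_mm = 0.1,
                              prune_spur_mm = NULL, consolidate = TRUE) {
  sk <- as_array3(skeleton)
  if (length(spacing_mm) == 1) spacing_mm <- rep(spacing_mm, 3)
  if (is.null(prune_spur_mm)) prune_spur_mm <- 2 * min(spacing_mm)
  if (!any(sk))
    return(structure(list(nodes = data.frame(), edges = data.frame(),
                          paths = list(), spacing_mm = spacing_mm),
                     class = "vessel_graph"))
  A <- skeleton_adjacency(sk)
  deg <- vapply(A$adj, length, integer(1))
  is_node_vox <- deg != 2

  # node ids: junction clusters (26-adjacent deg >= 3 voxels) merged; each
  # endpoint voxel its own node
  node_of <- integer(A$n)
  next_node <- 0L
  junc <- which(deg >= 3)
  if (length(junc)) {
    in_junc <- logical(A$n); in_junc[junc] <- TRUE
    seen <- logical(A$n)
    for (j in junc) {
      if (seen[j]) next
      next_node <- next_node + 1L
      stack <- j; seen[j] <- TRUE
      while (length(stack)) {
        cur <- stack[length(stack)]; stack <- stack[-length(stack)]
        node_of[cur] <- next_node
        nb <- A$adj[[cur]]
        nb <- nb[in_junc[nb] & !seen[nb]]
        seen[nb] <- TRUE
        stack <- c(stack, nb)
      }
    }
  }
  for (v in which(deg <= 1)) {
    next_node <- next_node + 1L
    node_of[v] <- next_node
  }

  paths <- list()
  edges <- list()
  used_step <- new.env(hash = TRUE)  # directed steps already traced
  step_key <- function(a, b) paste0(a, "_", b)

  edge_metrics <- function(path_ids) {
    pc <- A$coords[path_ids, , drop = FALSE]
    pw <- sweep(pc, 2, spacing_mm, "*")
    len <- if (nrow(pw) > 1)
      sum(sqrt(rowSums((pw[-1, , drop = FALSE] -
                          pw[-nrow(pw), , drop = FALSE])^2))) else 0
    chord <- sqrt(sum((pw[nrow(pw), ] - pw[1, ])^2))
    rad <- if (!is.null(radius_map)) mean(radius_map[A$lin[path_ids]])
    else NA_real_
    list(coords = pc, length = len, chord = chord, radius = rad)
  }

  add_edge <- function(path_ids) {
    m <- edge_metrics(path_ids)
    edges[[length(edges) + 1]] <<- list(
      from = node_of[path_ids[1]], to = node_of[path_ids[length(path_ids)]],
      length_mm = m$length, chord_mm = m$chord, radius_mm = m$radius,
      n_vox = length(path_ids))
    paths[[length(paths) + 1]] <<- m$coords
  }

  trace_from <- function(v, u) {
    # walk from node voxel v through u until the next node voxel
    path <- c(v, u)
    prev <- v; cur <- u
    while (!is_node_vox[cur]) {
      nb <- A$adj[[cur]]
      nxt <- nb[nb != prev]
      if (!length(nxt)) break  # dead end (shouldn't happen: deg==2)
      prev <- cur; cur <- nxt[1]
      path <- c(path, cur)
      if (cur == v) break  # self-loop back to start
    }
    path
  }

  for (v in seq_len(A$n)) {
    if (!is_node_vox[v]) next
    for (u in A$adj[[v]]) {
      if (is_node_vox[u]) {
        # direct node-node adjacency
        if (node_of[u] == node_of[v]) next  # inside one junction cluster
        k <- paste0("nn_", step_key(min(v, u), max(v, u)))
        if (exists(k, envir = used_step)) next
        assign(k, TRUE, envir = used_step)
        add_edge(c(v, u))
      } else {
        k <- step_key(v, u)
        if (exists(k, envir = used_step)) next
        path <- trace_from(v, u)
        last <- path[length(path)]
        assign(k, TRUE, envir = used_step)
        assign(step_key(last, path[length(path) - 1]), TRUE, envir = used_step)
        add_edge(path)
      }
    }
  }

  # node-free cycles: remaining untraced degree-2 voxels
  traced <- logical(A$n)
  for (i in seq_along(paths)) {
    pc <- paths[[i]]
    linp <- pc[, 1] + dim(sk)[1] * (pc[, 2] - 1) +
      dim(sk)[1] * dim(sk)[2] * (pc[, 3] - 1)
    idmap <- match(linp, A$lin)
    traced[idmap] <- TRUE
  }
  leftover <- which(!traced & deg == 2 & node_of == 0)
  while (length(leftover)) {
    v <- leftover[1]
    next_node <- next_node + 1L
    node_of[v] <- next_node
    is_node_vox[v] <- TRUE
    u <- A$adj[[v]][1]
    path <- trace_from(v, u)
    add_edge(path)
    pc <- paths[[length(paths)]]
    linp <- pc[, 1] + dim(sk)[1] * (pc[, 2] - 1) +
      dim(sk)[1] * dim(sk)[2] * (pc[, 3] - 1)
    traced[match(linp, A$lin)] <- TRUE
    leftover <- which(!traced & deg == 2 & node_of == 0)
  }

  g <- build_graph_tables(edges, paths, node_of, A, spacing_mm)
  if (consolidate) g <- consolidate_junctions(g)
  if (prune_spur_mm > 0) g <- prune_spurs(g, prune_spur_mm)
  g
}

build_graph_tables <- function(edges, paths, node_of, A, spacing_mm) {
  used_nodes <- sort(unique(c(vapply(edges, function(e) e$from, numeric(1)),
                              vapply(edges, function(e) e$to, numeric(1)),
                              node_of[node_of > 0])))
  cent <- t(vapply(used_nodes, function(nid) {
    vox <- which(node_of == nid)
    colMeans(A$coords[vox, , drop = FALSE])
  }, numeric(3)))
  nodes <- data.frame(id = used_nodes, x = cent[, 1], y = cent[, 2],
                      z = cent[, 3], degree = 0L)
  ed <- if (length(edges)) data.frame(
    from = vapply(edges, function(e) e$from, numeric(1)),
    to = vapply(edges, function(e) e$to, numeric(1)),
    length_mm = vapply(edges, function(e) e$length_mm, numeric(1)),
    chord_mm = vapply(edges, function(e) e$chord_mm, numeric(1)),
    radius_mm = vapply(edges, function(e) e$radius_mm, numeric(1)),
    n_vox = vapply(edges, function(e) e$n_vox, numeric(1))
  ) else data.frame(from = numeric(), to = numeric(), length_mm = numeric(),
                    chord_mm = numeric(), radius_mm = numeric(),
                    n_vox = numeric())
  ed$tortuosity <- ifelse(ed$length_mm > 0, ed$chord_mm / ed$length_mm, NA)
  # the common inverse convention, kept as a clearly separate column
  ed$length_over_chord <- ifelse(ed$chord_mm > 0, ed$length_mm / ed$chord_mm,
                                 NA)
  if (nrow(ed))
    nodes$degree <- vapply(nodes$id, function(i)
      sum(ed$from == i) + sum(ed$to == i), numeric(1))
  structure(list(nodes = nodes, edges = ed, paths = paths,
                 spacing_mm = spacing_mm),
            class = "vessel_graph")
}

#' Prune short terminal spurs from a vessel graph
#'
#' Removes terminal edges (one endpoint of degree 1) shorter than
#' `min_length_mm`, then merges any node left with exactly two incident
#' edges by concatenating them into one edge (chord and tortuosity
#' recomputed from the merged path). Repeats until stable.
#'
#' @param graph a `vessel_graph`.
#' @param min_length_mm spur length threshold (mm).
#' @export
prune_spurs <- function(graph, min_length_mm) {
  ed <- graph$edges; paths <- graph$paths; nodes <- graph$nodes
  spacing <- graph$spacing_mm
  repeat {
    if (!nrow(ed)) break
    degv <- table(factor(c(ed$from, ed$to), levels = nodes$id))
    term <- as.numeric(names(degv))[degv == 1]
    drop <- which((ed$from %in% term | ed$to %in% term) &
                    ed$length_mm < min_length_mm &
                    nrow(ed) > 1)  # never drop the last edge
    if (!length(drop)) break
    # drop the shortest spur first, one at a time, then re-evaluate
    drop <- drop[which.min(ed$length_mm[drop])]
    ed <- ed[-drop, , drop = FALSE]
    paths <- paths[-drop]
    m <- merge_degree2(ed, paths, nodes, spacing)
    ed <- m$ed; paths <- m$paths
  }
  rebuild_graph(ed, paths, nodes, spacing)
}

# Merge pass-through nodes (exactly two incident edge slots belonging to two
# distinct edges) by concatenating their edges into one; chord and
# tortuosity recomputed from the merged path.
merge_degree2 <- function(ed, paths, nodes, spacing) {
  repeat {
    if (!nrow(ed)) break
    degv <- table(factor(c(ed$from, ed$to), levels = nodes$id))
    mid <- as.numeric(names(degv))[degv == 2]
    merged <- FALSE
    for (n2 in mid) {
      inc <- which(ed$from == n2 | ed$to == n2)
      if (length(inc) != 2) next  # self-loop at the node: keep
      e1 <- inc[1]; e2 <- inc[2]
      orient <- function(i, end_at) {
        p <- paths[[i]]
        if (ed$to[i] != end_at) p <- p[rev(seq_len(nrow(p))), , drop = FALSE]
        p
      }
      p1 <- orient(e1, n2)           # ends at n2
      p2 <- orient(e2, n2)
      p2 <- p2[rev(seq_len(nrow(p2))), , drop = FALSE]  # starts at n2
      gap <- sqrt(sum(((p1[nrow(p1), ] - p2[1, ]) * spacing)^2))
      newp <- rbind(p1, if (gap == 0) p2[-1, , drop = FALSE] else p2)
      pw <- sweep(newp, 2, spacing, "*")
      len <- sum(sqrt(rowSums((pw[-1, , drop = FALSE] -
                                 pw[-nrow(pw), , drop = FALSE])^2)))
      chord <- sqrt(sum((pw[nrow(pw), ] - pw[1, ])^2))
      w1 <- ed$n_vox[e1]; w2 <- ed$n_vox[e2]
      newe <- data.frame(
        from = if (ed$to[e1] == n2) ed$from[e1] else ed$to[e1],
        to = if (ed$to[e2] == n2) ed$from[e2] else ed$to[e2],
        length_mm = len, chord_mm = chord,
        radius_mm = (ed$radius_mm[e1] * w1 + ed$radius_mm[e2] * w2) /
          (w1 + w2),
        n_vox = nrow(newp))
      newe$tortuosity <- newe$chord_mm / newe$length_mm
      newe$length_over_chord <- if (newe$chord_mm > 0)
        newe$length_mm / newe$chord_mm else NA
      keep <- setdiff(seq_len(nrow(ed)), inc)
      ed <- rbind(ed[keep, , drop = FALSE], newe)
      paths <- c(paths[keep], list(newp))
      merged <- TRUE
      break
    }
    if (!merged) break
  }
  list(ed = ed, paths = paths)
}

rebuild_graph <- function(ed, paths, nodes, spacing) {
  if (nrow(ed)) {
    used <- unique(c(ed$from, ed$to))
    nodes <- nodes[nodes$id %in% used, , drop = FALSE]
    nodes$degree <- vapply(nodes$id, function(i)
      sum(ed$from == i) + sum(ed$to == i), numeric(1))
  }
  structure(list(nodes = nodes, edges = ed, paths = paths,
                 spacing_mm = spacing),
            class = "vessel_graph")
}

#' Consolidate junction clusters in a vessel graph
#'
#' Inside a junction region the medial axis of crossing tubes is not
#' resolvable below the local vessel diameter, so thinning can split one
#' anatomical junction into a small cluster of nearby graph nodes. This step
#' contracts junction-to-junction edges shorter than the local resolvable
#' scale (`2 x edge radius + 2 voxels`, or `3 voxels` when no radius is
#' available), removes the resulting sub-scale self-loops, and re-merges
#' pass-through nodes.
#'
#' @param graph a `vessel_graph`.
#' @param spacing_mm voxel spacing (mm); defaults to the graph's.
#' @export
consolidate_junctions <- function(graph, spacing_mm = NULL) {
  ed <- graph$edges; paths <- graph$paths; nodes <- graph$nodes
  spacing <- if (is.null(spacing_mm)) graph$spacing_mm else spacing_mm
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  vox <- min(spacing)
  scale_of <- function(i) {
    r <- ed$radius_mm[i]
    if (is.na(r)) 3 * vox else 2 * r + 2 * vox
  }
  repeat {
    if (!nrow(ed)) break
    degv <- table(factor(c(ed$from, ed$to), levels = nodes$id))
    juncs <- as.numeric(names(degv))[degv >= 3]
    cand <- which(ed$from != ed$to &
                    ed$from %in% juncs & ed$to %in% juncs &
                    ed$length_mm < vapply(seq_len(nrow(ed)), scale_of,
                                          numeric(1)))
    # drop sub-scale self-loops left by earlier contractions
    loops <- which(ed$from == ed$to &
                     ed$length_mm < 2 * vapply(seq_len(nrow(ed)), scale_of,
                                               numeric(1)))
    if (length(loops)) {
      ed <- ed[-loops, , drop = FALSE]
      paths <- paths[-loops]
      next
    }
    if (!length(cand)) break
    i <- cand[which.min(ed$length_mm[cand])]
    keep_id <- min(ed$from[i], ed$to[i])
    drop_id <- max(ed$from[i], ed$to[i])
    # merged node at the midpoint of the two centroids
    ki <- nodes$id == keep_id; di <- nodes$id == drop_id
    nodes[ki, c("x", "y", "z")] <-
      (nodes[ki, c("x", "y", "z")] + nodes[di, c("x", "y", "z")]) / 2
    ed <- ed[-i, , drop = FALSE]; paths <- paths[-i]
    ed$from[ed$from == drop_id] <- keep_id
    ed$to[ed$to == drop_id] <- keep_id
    m <- merge_degree2(ed, paths, nodes, spacing)
    ed <- m$ed; paths <- m$paths
  }
  m <- merge_degree2(ed, paths, nodes, spacing)
  rebuild_graph(m$ed, m$paths, nodes, spacing)
}

#' Summary morphometrics of a vessel network
#'
#' Mean/min/max edge length and radius, mean tortuosity (chord/length, 1 =
#' straight), node count, and vessel volume = mask voxel count x voxel
#' volume (mm^3). An empty graph yields an explicitly flagged empty record,
#' not zeros.
#'
#' @param graph a `vessel_graph`.
#' @param mask the vessel mask the graph came from (for the volume).
#' @param spacing_mm voxel spacing (mm).
#' @return list of metrics with logical `empty`.
#' @export
vessel_summary <- function(graph, mask = NULL, spacing_mm = 0.1) {
  if (length(spacing_mm) == 1) spacing_mm <- rep(spacing_mm, 3)
  vol <- if (!is.null(mask)) sum(mask) * prod(spacing_mm) else NA_real_
  ed <- graph$edges
  if (is.null(ed) || !nrow(ed)) {
    return(list(empty = TRUE, n_edges = 0L, n_nodes = nrow(graph$nodes),
                mean_length_mm = NA_real_, min_length_mm = NA_real_,
                max_length_mm = NA_real_, mean_radius_mm = NA_real_,
                min_radius_mm = NA_real_, max_radius_mm = NA_real_,
                mean_tortuosity = NA_real_, length_sd_mm = NA_real_,
                vessel_volume_mm3 = vol))
  }
  list(empty = FALSE, n_edges = nrow(ed), n_nodes = nrow(graph$nodes),
       mean_length_mm = mean(ed$length_mm),
       min_length_mm = min(ed$length_mm),
       max_length_mm = max(ed$length_mm),
       mean_radius_mm = mean(ed$radius_mm),
       min_radius_mm = min(ed$radius_mm),
       max_radius_mm = max(ed$radius_mm),
       mean_tortuosity = mean(ed$tortuosity, na.rm = TRUE),
       length_sd_mm = if (nrow(ed) > 1) stats::sd(ed$length_mm) else 0,
       vessel_volume_mm3 = vol)
}
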