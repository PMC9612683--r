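# endoscopy: intraluminal fly-through geometry. A centerline graph is
# traced through the mask (root at the largest inscribed sphere, branches
# to the geodesically farthest lumen points, paths pulled to the medial
# axis by a centrality-weighted metric), then resampled into camera
# waypoints.

#' Extract the lumen centerline graph
#'
#' Builds a voxel adjacency graph (26-connectivity) over the mask, roots
#' it at the voxel with the largest inscribed-sphere radius and
#' iteratively traces branches to the farthest unreached lumen voxel
#' using a centrality-weighted shortest path (steps near the wall are
#' penalised, so paths follow the medial axis). A candidate branch is
#' kept only when it extends beyond the inscribed sphere of its
#' attachment point by more than the spur-pruning length (3 mm, which
#' also absorbs the mild skeletal elongation of the flattened pelvis); a
#' sphere-like mask therefore yields a single node and no edges.
#'
#' @param mask a `segmentation_mask` (single connected component).
#' @param spur_mm branches shorter than the local radius plus this length
#'   are pruned.
#' @return an object of class `centerline_graph`: `nodes` (mm, one row
#'   per node), `edges` (index pairs), `roles` (root/branch/tip/internal),
#'   `graph` (igraph, edge weights = mm length).
#' @export
extract_centerline <- function(mask, spur_mm = 3) {
  m <- mask$mask
  d <- dim(m)
  idx <- which(m)
  if (length(idx) < 2) stop("degenerate lumen: too few voxels")
  lab <- label_components(m, 26L)
  if (max(lab) > 1) stop("mask must be one connected component")
  D <- distance_transform(m, mask$spacing)

  vid <- integer(length(m))
  vid[idx] <- seq_along(idx)
  ai <- arrayInd(idx, d)
  # 26-neighbourhood edge list in voxel index space
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  offs <- offs[offs[, 1] > 0 | (offs[, 1] == 0 & offs[, 2] > 0) |
                 (offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] > 0), ,
               drop = FALSE]  # half the directions: undirected edges once
  efrom <- integer(0); eto <- integer(0); elen <- numeric(0)
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ]
    nb <- cbind(ai[, 1] + o[1], ai[, 2] + o[2], ai[, 3] + o[3])
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    nbl <- nb[ok, 1] + (nb[ok, 2] - 1) * d[1] + (nb[ok, 3] - 1) * d[1] * d[2]
    hit <- m[nbl]
    efrom <- c(efrom, vid[idx[ok]][hit])
    eto <- c(eto, vid[nbl][hit])
    step <- sqrt(sum((o * mask$spacing)^2))
    elen <- c(elen, rep(step, sum(hit)))
  }
  g <- igraph::make_graph(rbind(efrom, eto), n = length(idx),
                          directed = FALSE)
  dv <- D[idx]
  # centrality-weighted metric: stepping near the wall is expensive
  wc <- elen / (0.25 + (dv[efrom] + dv[eto]) / 2)

  # root: centre of the maximal-inscribed-sphere plateau (plain which.max
  # would pick an arbitrary end of an elongated plateau, e.g. in a tube)
  plateau <- which(dv >= max(dv) - 0.5)
  wz <- ai[plateau, , drop = FALSE]
  ctr <- colMeans(wz)
  root <- plateau[which.min(rowSums(sweep(wz, 2, ctr)^2))]
  nv <- length(idx)
  skel <- root
  branch_paths <- list()
  repeat {
    # virtual source attached to the whole skeleton: one Dijkstra gives the
    # distance from every voxel to its nearest skeleton point
    g2 <- igraph::add_vertices(g, 1)
    g2 <- igraph::add_edges(g2, rbind(rep(nv + 1L, length(skel)), skel))
    w_plain <- c(elen, rep(1e-9, length(skel)))
    gd <- igraph::distances(g2, v = nv + 1L, weights = w_plain)[1, seq_len(nv)]
    if (!is.finite(max(gd))) stop("mask must be one connected component")
    # anchor the branch tip at the most central voxel of the far region
    # (end-face centre rather than an arbitrary rim corner)
    near_far <- which(gd >= max(gd) - 2.5)
    cand <- near_far[dv[near_far] >= max(dv[near_far]) - 0.25]
    cw <- ai[cand, , drop = FALSE]
    cc <- colMeans(cw)
    far <- cand[which.min(rowSums(sweep(cw, 2, cc)^2))]
    branch_len <- gd[far]
    w_central <- c(wc, rep(1e-9, length(skel)))
    path <- igraph::shortest_paths(g2, from = far, to = nv + 1L,
                                   weights = w_central,
                                   output = "vpath")$vpath[[1]]
    path <- as.integer(path)
    path <- path[path <= nv]
    attach_pt <- path[length(path)]
    if (branch_len < dv[attach_pt] + spur_mm) break
    branch_paths[[length(branch_paths) + 1]] <- path
    skel <- unique(c(skel, path))
  }

  world <- cbind(
    mask$origin[1] + (ai[, 1] - 1) * mask$spacing[1],
    mask$origin[2] + (ai[, 2] - 1) * mask$spacing[2],
    mask$origin[3] + (ai[, 3] - 1) * mask$spacing[3]
  )
  if (length(branch_paths) == 0) {
    nodes <- world[root, , drop = FALSE]
    return(structure(list(nodes = nodes, edges = matrix(0L, 0, 2),
                          roles = "root", root = 1L, radii = dv[root],
                          graph = igraph::make_empty_graph(1, FALSE),
                          voxel_ids = root),
                     class = "centerline_graph"))
  }
  skel_ids <- unique(c(root, unlist(branch_paths)))
  node_of <- function(v) match(v, skel_ids)
  edges <- NULL
  for (p in branch_paths) {
    pn <- node_of(p)
    edges <- rbind(edges, cbind(pn[-length(pn)], pn[-1]))
  }
  edges <- unique(edges)
  nodes <- world[skel_ids, , drop = FALSE]
  # de-zigzag: moving-average smoothing of each branch path (endpoints and
  # junction nodes fixed) so tangents follow the lumen axis
  shared <- table(unlist(lapply(branch_paths, unique)))
  fixed_vox <- c(root, as.integer(names(shared)[shared > 1]))
  smoothed <- nodes
  touched <- rep(FALSE, nrow(nodes))
  for (p in branch_paths) {
    pn <- node_of(p)
    if (length(pn) < 3) next
    pw <- nodes[pn, , drop = FALSE]
    sm <- smooth_path(pw, w = 5, passes = 2)
    keep <- (p %in% fixed_vox) | touched[pn]
    keep[c(1, length(pn))] <- TRUE
    sm[keep, ] <- smoothed[pn, , drop = FALSE][keep, ]
    smoothed[pn, ] <- sm
    touched[pn] <- TRUE
  }
  nodes <- smoothed
  elen2 <- sqrt(rowSums((nodes[edges[, 1], , drop = FALSE] -
                           nodes[edges[, 2], , drop = FALSE])^2))
  cg <- igraph::make_graph(t(edges), n = nrow(nodes), directed = FALSE)
  igraph::E(cg)$weight <- elen2
  deg <- igraph::degree(cg)
  roles <- ifelse(deg == 1, "tip", ifelse(deg > 2, "branch", "internal"))
  rootn <- node_of(root)
  roles[rootn] <- "root"
  structure(list(nodes = nodes, edges = edges, roles = roles,
                 root = rootn, radii = dv[skel_ids], graph = cg,
                 voxel_ids = skel_ids),
            class = "centerline_graph")
}

# endpoint-padded moving-average smoothing of an ordered point path
smooth_path <- function(pw, w = 5, passes = 2) {
  n <- nrow(pw)
  if (n < 3) return(pw)
  h <- w %/% 2
  for (pass in seq_len(passes)) {
    padded <- rbind(pw[rep(1, h), , drop = FALSE], pw,
                    pw[rep(n, h), , drop = FALSE])
    cs <- apply(padded, 2, cumsum)
    pw <- (cs[(w:(n + w - 1)), , drop = FALSE] -
             rbind(0, cs[seq_len(n - 1), , drop = FALSE])) / w
  }
  pw
}

#' @export
print.centerline_graph <- function(x, ...) {
  cat(sprintf("<centerline_graph> %d nodes, %d edges, %d tips\n",
              nrow(x$nodes), nrow(x$edges), sum(x$roles == "tip")))
  invisible(x)
}

#' Tip nodes of a centerline graph
#' @param graph a `centerline_graph`.
#' @return integer node ids with role "tip".
#' @export
centerline_tips <- function(graph) which(graph$roles == "tip")

#' Camera fly-through path to a calyx tip
#'
#' Waypoints along the root-to-tip centerline path, resampled at
#' `step_mm`, with the view direction equal to the local path tangent.
#'
#' @param graph a `centerline_graph`.
#' @param target_tip node id of a tip.
#' @param step_mm waypoint spacing in mm.
#' @param reverse start at the tip instead of the root.
#' @return data.frame with `z`, `y`, `x` (mm) and `dz`, `dy`, `dx`
#'   (unit view direction).
#' @export
flythrough_path <- function(graph, target_tip, step_mm = 1.0,
                            reverse = FALSE) {
  if (graph$roles[target_tip] != "tip") stop("target is not a tip")
  if (target_tip == graph$root) stop("target is the root")
  root <- graph$root
  vp <- igraph::shortest_paths(graph$graph, from = root, to = target_tip,
                               output = "vpath")$vpath[[1]]
  pts <- graph$nodes[as.integer(vp), , drop = FALSE]
  seg <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  svals <- seq(0, total, by = step_mm)
  if (svals[length(svals)] < total) svals <- c(svals, total)
  interp <- vapply(1:3, function(c_) {
    approx(s, pts[, c_], xout = svals, ties = "ordered")$y
  }, numeric(length(svals)))
  interp <- matrix(interp, ncol = 3)
  tang <- rbind(interp[2, ] - interp[1, ],
                (interp[-(1:2), , drop = FALSE] -
                   interp[seq_len(nrow(interp) - 2), , drop = FALSE]) / 2,
                interp[nrow(interp), ] - interp[nrow(interp) - 1, ])
  tang <- tang / pmax(sqrt(rowSums(tang^2)), 1e-12)
  if (reverse) {
    ord <- rev(seq_len(nrow(interp)))
    interp <- interp[ord, , drop = FALSE]
    tang <- -tang[ord, , drop = FALSE]
  }
  data.frame(z = interp[, 1], y = interp[, 2], x = interp[, 3],
             dz = tang[, 1], dy = tang[, 2], dx = tang[, 3])
}
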