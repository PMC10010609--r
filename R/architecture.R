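#' Root system architecture
#'
#' A rooted tree of axes: exactly one primary axis (order 0) carrying
#' first-order laterals (order 1). Axial positions are arc-length distances
#' to the tip of the axis that carries them, in meters; a lateral's
#' `insertion_position` is therefore its distance to the tip of the primary.
#'
#' @param axes data.frame with columns `axis_id`, `parent_axis` (NA for the
#'   primary), `insertion_position` (m from the parent's tip), `length` (m),
#'   `order` (0 or 1) and `diameter` (m).
#' @param provenance free-text description of where the architecture came
#'   from (file, reconstruction, generator ...).
#' @return an object of class `root_system`.
#' @export
root_system <- function(axes, provenance = "") {
  req <- c("axis_id", "parent_axis", "insertion_position", "length", "order",
           "diameter")
  missing_cols <- setdiff(req, names(axes))
  if (length(missing_cols) > 0) {
    stop("axes table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  axes <- as.data.frame(axes)[req]
  axes$axis_id <- as.character(axes$axis_id)
  axes$parent_axis <- as.character(axes$parent_axis)
  if (anyDuplicated(axes$axis_id)) stop("duplicated axis_id", call. = FALSE)
  primary <- axes$order == 0L
  if (sum(primary) != 1L) {
    stop("a root system must have exactly one primary (order 0) axis",
         call. = FALSE)
  }
  if (!all(axes$order %in% c(0L, 1L))) {
    stop("only orders 0 (primary) and 1 (first laterals) are supported",
         call. = FALSE)
  }
  if (any(axes$length <= 0)) stop("axis lengths must be positive", call. = FALSE)
  if (any(axes$diameter <= 0)) stop("axis diameters must be positive", call. = FALSE)
  if (!is.na(axes$parent_axis[primary])) {
    stop("the primary axis cannot have a parent", call. = FALSE)
  }
  lat <- axes[!primary, , drop = FALSE]
  if (nrow(lat) > 0) {
    if (anyNA(lat$parent_axis)) {
      stop("lateral without parent axis (orphan)", call. = FALSE)
    }
    if (!all(lat$parent_axis %in% axes$axis_id[primary])) {
      stop("lateral parent does not exist or is not the primary axis",
           call. = FALSE)
    }
    L0 <- axes$length[primary]
    bad <- lat$insertion_position < 0 | lat$insertion_position > L0
    if (any(bad)) {
      stop("insertion_position outside [0, parent length] for axis ",
           paste(lat$axis_id[bad], collapse = ", "), call. = FALSE)
    }
  }
  rownames(axes) <- NULL
  structure(list(axes = axes, provenance = provenance), class = "root_system")
}

#' @export
print.root_system <- function(x, ...) {
  a <- x$axes
  L0 <- a$length[a$order == 0L]
  cat(sprintf("Root system: primary %.3f m, %d lateral(s), total length %.3f m\n",
              L0, sum(a$order == 1L), sum(a$length)))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

# mean root diameters (m) measured on seedling panels, by growth condition
.default_diameters <- function(condition = c("CTR", "PEG")) {
  condition <- match.arg(condition)
  switch(condition,
         CTR = c(primary = 1.05e-3, lateral = 0.36e-3),
         PEG = c(primary = 1.03e-3, lateral = 0.39e-3))
}

#' Read a digitized root architecture
#'
#' Reads per-axis records in the style of SmartRoot CSV exports. Expected
#' columns: `axis_id`, `parent_axis`, `insertion_position_m`, `length_m`,
#' `order`, and optionally `diameter_m`. Missing diameters are filled with
#' growth-condition defaults (primary 1.05 mm / laterals 0.36 mm for roots
#' grown in control solution, 1.03 mm / 0.39 mm for PEG-grown roots).
#'
#' @param x path to a CSV file, or a data.frame with the columns above.
#' @param condition growth condition used for default diameters, `"CTR"` or
#'   `"PEG"`.
#' @return a [root_system].
#' @export
read_architecture <- function(x, condition = c("CTR", "PEG")) {
  condition <- match.arg(condition)
  tab <- if (is.character(x)) {
    utils::read.csv(x, stringsAsFactors = FALSE)
  } else {
    as.data.frame(x)
  }
  # accept both unit-suffixed file headers and bare internal names
  ren <- c(insertion_position_m = "insertion_position", length_m = "length",
           diameter_m = "diameter")
  for (from in names(ren)) {
    if (from %in% names(tab)) names(tab)[names(tab) == from] <- ren[[from]]
  }
  req <- c("axis_id", "parent_axis", "insertion_position", "length", "order")
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols) > 0) {
    stop("architecture table lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  defaults <- .default_diameters(condition)
  if (!"diameter" %in% names(tab)) tab$diameter <- NA_real_
  fill <- is.na(tab$diameter)
  tab$diameter[fill] <- ifelse(tab$order[fill] == 0L,
                               defaults[["primary"]], defaults[["lateral"]])
  src <- if (is.character(x)) x else "data.frame"
  root_system(tab, provenance = paste0("read_architecture(", src,
                                       ", condition = ", condition, ")"))
}

#' Write a root architecture to CSV
#'
#' Counterpart of [read_architecture()]; writes unit-suffixed headers.
#'
#' @param rs a [root_system].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_architecture <- function(rs, path) {
  stopifnot(inherits(rs, "root_system"))
  a <- rs$axes
  out <- data.frame(axis_id = a$axis_id, parent_axis = a$parent_axis,
                    insertion_position_m = a$insertion_position,
                    length_m = a$length, order = a$order,
                    diameter_m = a$diameter)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Reconstruct a whole root system from digitized cut segments
#'
#' In a cut-and-flow experiment the intact root is never scanned; it is
#' rebuilt by pasting the digitized segments released at each cut back onto
#' the remaining basal root system, starting from the last (most basal) cut.
#' Each cut set must contain exactly one primary segment; lateral positions
#' recorded within a segment (distance to that segment's distal end) are
#' re-offset by the cumulative length of the more distal segments.
#'
#' @param cut_sets list ordered from the first (most distal) to the last cut.
#'   Each element is a list with `primary_length` (m) and optionally
#'   `laterals`, a data.frame with columns `insertion_position` (m from the
#'   distal end of this primary segment), `length` and optionally `diameter`.
#' @param basal_remainder a [root_system] describing the basal part remaining
#'   after the last cut (its laterals' insertion positions are distances to
#'   its own distal end).
#' @param condition growth condition for default lateral diameters.
#' @return the reconstructed [root_system].
#' @export
reconstruct_from_cuts <- function(cut_sets, basal_remainder,
                                  condition = c("CTR", "PEG")) {
  condition <- match.arg(condition)
  stopifnot(inherits(basal_remainder, "root_system"))
  defaults <- .default_diameters(condition)
  lens <- vapply(cut_sets, function(s) {
    if (is.null(s$primary_length) || !is.numeric(s$primary_length) ||
        s$primary_length <= 0) {
      stop("cut set without a primary segment", call. = FALSE)
    }
    s$primary_length
  }, numeric(1))
  offsets <- cumsum(c(0, lens))          # distal length pasted below each set
  rem <- basal_remainder$axes
  prim_row <- rem[rem$order == 0L, ]
  total_primary <- sum(lens) + prim_row$length

  lat_list <- list()
  for (i in seq_along(cut_sets)) {
    lat <- cut_sets[[i]]$laterals
    if (is.null(lat) || nrow(lat) == 0) next
    d <- if ("diameter" %in% names(lat)) lat$diameter else NA_real_
    d[is.na(d)] <- defaults[["lateral"]]
    lat_list[[length(lat_list) + 1L]] <- data.frame(
      insertion_position = lat$insertion_position + offsets[i],
      length = lat$length, diameter = d)
  }
  rem_lat <- rem[rem$order == 1L, , drop = FALSE]
  if (nrow(rem_lat) > 0) {
    lat_list[[length(lat_list) + 1L]] <- data.frame(
      insertion_position = rem_lat$insertion_position + offsets[length(offsets)],
      length = rem_lat$length, diameter = rem_lat$diameter)
  }
  lat_all <- if (length(lat_list) > 0) do.call(rbind, lat_list) else
    data.frame(insertion_position = numeric(0), length = numeric(0),
               diameter = numeric(0))

  n_lat <- nrow(lat_all)
  axes <- data.frame(
    axis_id = c("P", if (n_lat > 0) paste0("L", seq_len(n_lat))),
    parent_axis = c(NA_character_, rep("P", n_lat)),
    insertion_position = c(NA_real_, lat_all$insertion_position),
    length = c(total_primary, lat_all$length),
    order = c(0L, rep(1L, n_lat)),
    diameter = c(prim_row$diameter, lat_all$diameter))
  axes$insertion_position[1] <- 0
  root_system(axes, provenance = sprintf(
    "reconstruct_from_cuts(%d cut sets + basal remainder)", length(cut_sets)))
}

#' Discretize a root system into representative elementary volumes
#'
#' Each axis is split into `ceiling(length / l_target)` cylindrical REVs of
#' equal length (so total length is conserved exactly and no degenerate short
#' element is created). REV distance-to-tip is assigned at element centers
#' along the REV's own axis. A lateral's basal REV becomes a child of the
#' primary REV whose span contains its insertion point; junctions carry no
#' extra resistance.
#'
#' @param rs a [root_system].
#' @param l_target target REV length, m (default 1 mm, of the order of the
#'   primary root diameter).
#' @return an object of class `rev_graph`: a list with a `nodes` data.frame
#'   (`rev_id`, `parent`, `axis_id`, `order`, `length`, `diameter`,
#'   `dist_tip`, `surface`, `is_cut_face`), the originating `axes` table,
#'   the basal REV id and a post-order traversal (children before parents).
#' @export
discretize <- function(rs, l_target = 1e-3) {
  stopifnot(inherits(rs, "root_system"), l_target > 0)
  a <- rs$axes
  prim <- a[a$order == 0L, ]
  L0 <- prim$length
  n0 <- ceiling(L0 / l_target - 1e-12)
  l0 <- L0 / n0
  idx <- seq_len(n0)
  nodes <- data.frame(
    rev_id = idx,
    parent = c(NA_integer_, idx[-n0]),
    axis_id = prim$axis_id,
    order = 0L,
    length = l0,
    diameter = prim$diameter,
    dist_tip = L0 - (idx - 0.5) * l0,
    is_cut_face = FALSE)

  lats <- a[a$order == 1L, , drop = FALSE]
  next_id <- n0
  if (nrow(lats) > 0) {
    for (i in seq_len(nrow(lats))) {
      Ll <- lats$length[i]
      nl <- ceiling(Ll / l_target - 1e-12)
      ll <- Ll / nl
      # primary REV containing the insertion point (base-to-tip index)
      s <- L0 - lats$insertion_position[i]     # arc length from primary base
      j <- min(max(ceiling(s / l0 - 1e-12), 1L), n0)
      idl <- next_id + seq_len(nl)
      nodes <- rbind(nodes, data.frame(
        rev_id = idl,
        parent = c(j, idl[-nl]),
        axis_id = lats$axis_id[i],
        order = 1L,
        length = ll,
        diameter = lats$diameter[i],
        dist_tip = Ll - (seq_len(nl) - 0.5) * ll,
        is_cut_face = FALSE))
      next_id <- next_id + nl
    }
  }
  nodes$surface <- pi * nodes$diameter * nodes$length
  rownames(nodes) <- NULL
  g <- structure(list(nodes = nodes, axes = a, basal = 1L,
                      l_target = l_target),
                 class = "rev_graph")
  g$post_order <- .post_order(g)
  g
}

# children-before-parents traversal (reverse BFS from the basal REV)
.post_order <- function(g) {
  nodes <- g$nodes
  n <- nrow(nodes)
  id <- nodes$rev_id
  pos <- integer(max(id)); pos[id] <- seq_len(n)   # rev_id -> row
  parent_row <- ifelse(is.na(nodes$parent), NA_integer_, pos[nodes$parent])
  kids <- split(seq_len(n), factor(parent_row, levels = seq_len(n)))
  bfs <- integer(n)
  bfs[1] <- pos[g$basal]
  head <- 1L; tail <- 1L
  while (head <= tail) {
    cur <- bfs[head]
    ch <- kids[[cur]]
    if (length(ch) > 0) {
      bfs[(tail + 1L):(tail + length(ch))] <- ch
      tail <- tail + length(ch)
    }
    head <- head + 1L
  }
  if (tail != n) stop("REV graph is not connected", call. = FALSE)
  rev(bfs)
}

#' @export
print.rev_graph <- function(x, ...) {
  n <- x$nodes
  cat(sprintf(
    "REV graph: %d REVs (%d primary, %d lateral), total length %.3f m, surface %.3e m^2\n",
    nrow(n), sum(n$order == 0L), sum(n$order == 1L), sum(n$length),
    sum(n$surface)))
  if (any(n$is_cut_face)) {
    cat(sprintf("  %d open cut face(s)\n", sum(n$is_cut_face)))
  }
  invisible(x)
}

#' Cut a discretized root at a blade position
#'
#' Simulates one razor-blade stroke of a cut-and-flow experiment. The blade
#' position `x_blade` is the distance to the primary tip (the graph's
#' distance-to-tip coordinate, which is kept in original-tip units across
#' successive cuts). Every primary REV with center distance-to-tip below the
#' blade is removed and the new distal primary REV is flagged as an open cut
#' face.
#'
#' During the experiment the laterals are stretched and aligned tipward along
#' the primary before cutting, so a lateral attached at primary distance `p`
#' with length `L` spans primary coordinates `[p - L, p]`: it is removed
#' entirely when `p <= x_blade`, keeps its basal `p - x_blade` when the blade
#' falls inside its span (new distal REV flagged as cut face), and is left
#' untouched when `p - L >= x_blade`. The alternative convention (cut a
#' lateral where its own distance-to-tip passes the blade) is available via
#' `lateral_rule = "own_distance"`.
#'
#' @param g a `rev_graph`.
#' @param x_blade blade distance to the primary tip, m.
#' @param lateral_rule `"stretched"` (default) or `"own_distance"`.
#' @return the cut `rev_graph` (REV ids and distance-to-tip coordinates are
#'   preserved).
#' @export
cut_at_distance <- function(g, x_blade,
                            lateral_rule = c("stretched", "own_distance")) {
  stopifnot(inherits(g, "rev_graph"))
  lateral_rule <- match.arg(lateral_rule)
  nodes <- g$nodes
  L0 <- g$axes$length[g$axes$order == 0L]
  if (x_blade <= 0 || x_blade >= L0) {
    stop("x_blade must lie strictly inside the remaining primary axis",
         call. = FALSE)
  }
  keep <- rep(TRUE, nrow(nodes))
  new_face <- rep(FALSE, nrow(nodes))

  prim <- nodes$order == 0L
  keep[prim] <- nodes$dist_tip[prim] >= x_blade
  if (!any(keep[prim])) {
    stop("x_blade removes the whole primary axis", call. = FALSE)
  }
  kept_prim <- which(prim & keep)
  if (any(prim & !keep)) {
    distal <- kept_prim[which.min(nodes$dist_tip[kept_prim])]
    new_face[distal] <- TRUE
  }

  lat_axes <- g$axes[g$axes$order == 1L, , drop = FALSE]
  for (i in seq_len(nrow(lat_axes))) {
    ax <- lat_axes$axis_id[i]
    rows <- which(nodes$axis_id == ax)
    if (length(rows) == 0) next
    p <- lat_axes$insertion_position[i]
    Ll <- lat_axes$length[i]
    if (lateral_rule == "stretched") {
      if (p <= x_blade) {              # attachment at or below the blade
        keep[rows] <- FALSE
        next
      }
      t_min <- Ll - (p - x_blade)      # own-axis dtt below this is removed
      if (t_min <= 0) next             # whole lateral basal of the blade
    } else {
      t_min <- x_blade
    }
    drop <- nodes$dist_tip[rows] < t_min
    if (all(drop)) {
      keep[rows] <- FALSE
    } else if (any(drop)) {
      keep[rows[drop]] <- FALSE
      kept <- rows[!drop]
      new_face[kept[which.min(nodes$dist_tip[kept])]] <- TRUE
    }
  }

  nodes$is_cut_face <- (nodes$is_cut_face | new_face) & keep
  nodes <- nodes[keep, , drop = FALSE]
  # a pre-existing cut face that survives stays open only if still distal
  rownames(nodes) <- NULL
  g2 <- g
  g2$nodes <- nodes
  g2$post_order <- NULL
  g2$post_order <- .post_order(g2)
  g2
}

#' Generate a synthetic root system architecture
#'
#' Produces reproducible seedling-like architectures for simulation studies:
#' one primary axis carrying first-order laterals placed by a Poisson (or
#' fixed-count uniform) process outside an apical unbranched zone, with
#' normally distributed lateral lengths (truncated at 5 mm).
#'
#' @param primary_length primary axis length, m.
#' @param lateral_density expected laterals per meter of branchable primary.
#' @param lateral_length_mean,lateral_length_sd lateral length law, m.
#' @param apical_zone apical unbranched zone (no laterals within this
#'   distance of the primary tip), m.
#' @param seed integer seed for reproducibility (the caller's RNG state is
#'   left untouched).
#' @param condition growth condition for default diameters.
#' @param placement `"poisson"` (Poisson count) or `"uniform"` (fixed count
#'   `round(density * branchable length)`).
#' @return a [root_system].
#' @export
generate_synthetic_rsa <- function(primary_length = 0.35,
                                   lateral_density = 60,
                                   lateral_length_mean = 0.04,
                                   lateral_length_sd = 0.015,
                                   apical_zone = 0.02,
                                   seed = NULL,
                                   condition = c("CTR", "PEG"),
                                   placement = c("poisson", "uniform")) {
  stopifnot(primary_length > 0, lateral_density >= 0,
            lateral_length_mean > 0, lateral_length_sd >= 0,
            apical_zone >= 0, apical_zone < primary_length)
  condition <- match.arg(condition)
  placement <- match.arg(placement)
  if (!is.null(seed)) withr::local_seed(seed)
  defaults <- .default_diameters(condition)
  branchable <- primary_length - apical_zone
  n_lat <- if (placement == "poisson") {
    stats::rpois(1, lateral_density * branchable)
  } else {
    round(lateral_density * branchable)
  }
  pos <- sort(stats::runif(n_lat, min = apical_zone, max = primary_length))
  len <- pmax(stats::rnorm(n_lat, lateral_length_mean, lateral_length_sd),
              0.005)
  axes <- data.frame(
    axis_id = c("P", if (n_lat > 0) paste0("L", seq_len(n_lat))),
    parent_axis = c(NA_character_, rep("P", n_lat)),
    insertion_position = c(0, pos),
    length = c(primary_length, len),
    order = c(0L, rep(1L, n_lat)),
    diameter = c(defaults[["primary"]], rep(defaults[["lateral"]], n_lat)))
  root_system(axes, provenance = sprintf(
    "generate_synthetic_rsa(seed = %s, condition = %s)",
    if (is.null(seed)) "NULL" else seed, condition))
}

#' Default cut-and-flow blade schedule
#'
#' Blade positions (distance to the original primary tip, m) mimicking the
#' experimental protocol: a first cut of 8.3 cm, subsequent cuts of 4.3 cm,
#' stopping so that at least 5.2 cm of root system remains.
#'
#' @param primary_length primary axis length, m.
#' @param first_cut,later_cut,final_remainder protocol lengths, m.
#' @return increasing numeric vector of blade distances to the original tip.
#' @export
default_cut_schedule <- function(primary_length, first_cut = 0.083,
                                 later_cut = 0.043, final_remainder = 0.052) {
  stopifnot(primary_length > first_cut + final_remainder)
  cuts <- first_cut
  while (primary_length - (cuts[length(cuts)] + later_cut) >=
         final_remainder - 1e-9) {
    cuts <- c(cuts, cuts[length(cuts)] + later_cut)
  }
  cuts
}
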