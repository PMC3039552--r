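#' Area adjacency graph
#'
#' An `area_graph` holds the neighbourhood structure that the intrinsic CAR
#' prior needs: ordered area labels, planar centroids, and a symmetric 0/1
#' adjacency encoded as per-area neighbour index sets.
#'
#' @param area_ids Character vector of unique area labels (order defines the
#'   area index used throughout the package).
#' @param centroids Data frame with columns `area_id`, `x`, `y` giving a planar
#'   centroid per area (arbitrary, consistent distance units). May be `NULL`
#'   when the graph was read from a weights file without geometry; operations
#'   that need distances (isolate repair by nearest centroid, Tango's MEET)
#'   then refuse to run.
#' @param neighbours List, one integer vector per area, of neighbouring area
#'   indices. Must be symmetric and free of self-loops.
#'
#' @return An object of class `area_graph`.
#' @export
area_graph <- function(area_ids, centroids = NULL, neighbours) {
  area_ids <- as.character(area_ids)
  if (anyDuplicated(area_ids)) {
    stop("duplicate area labels: ", paste(unique(area_ids[duplicated(area_ids)]), collapse = ", "))
  }
  n <- length(area_ids)
  if (n == 0L) stop("empty area set")
  if (length(neighbours) != n) stop("`neighbours` must have one entry per area")
  neighbours <- lapply(neighbours, function(v) sort(unique(as.integer(v))))
  for (i in seq_len(n)) {
    nb <- neighbours[[i]]
    if (length(nb) && (min(nb) < 1L || max(nb) > n)) {
      stop("neighbour index out of range for area ", area_ids[i])
    }
    if (i %in% nb) stop("self-loop at area ", area_ids[i])
    for (j in nb) {
      if (!(i %in% neighbours[[j]])) {
        stop("asymmetric adjacency: ", area_ids[j], " is a neighbour of ",
             area_ids[i], " but not vice versa")
      }
    }
  }
  if (!is.null(centroids)) {
    centroids <- tibble::as_tibble(centroids)[, c("area_id", "x", "y")]
    centroids <- centroids[match(area_ids, centroids$area_id), ]
    if (anyNA(centroids$x) || anyNA(centroids$y)) {
      stop("centroids missing for some areas")
    }
  }
  structure(
    list(area_ids = area_ids, centroids = centroids,
         neighbours = neighbours, n_areas = n),
    class = "area_graph"
  )
}

#' @export
print.area_graph <- function(x, ...) {
  deg <- lengths(x$neighbours)
  cat("<area_graph> ", x$n_areas, " areas, ",
      sum(deg) %/% 2L, " links, ", sum(deg == 0L), " isolates\n", sep = "")
  invisible(x)
}

#' Number of isolated (neighbourless) areas
#' @param graph An `area_graph`.
#' @return Integer vector of area indices with no neighbours.
#' @export
isolates <- function(graph) which(lengths(graph$neighbours) == 0L)

#' Edge list of an area graph
#'
#' @param graph An `area_graph`.
#' @return A tibble with one row per unordered adjacent pair, columns
#'   `from`, `to` (area indices, `from < to`).
#' @export
graph_edges <- function(graph) {
  rows <- purrr::imap(graph$neighbours, function(nb, i) {
    keep <- nb[nb > i]
    if (length(keep)) tibble::tibble(from = i, to = keep) else NULL
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) out <- tibble::tibble(from = integer(), to = integer())
  out
}

#' Number of connected components of an area graph
#' @param graph An `area_graph`.
#' @return Integer count (isolated areas each count as a component).
#' @export
graph_components <- function(graph) {
  n <- graph$n_areas
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] == 0L) {
      cur <- cur + 1L
      stack <- s
      while (length(stack)) {
        i <- stack[length(stack)]
        stack <- stack[-length(stack)]
        if (comp[i] == 0L) {
          comp[i] <- cur
          stack <- c(stack, graph$neighbours[[i]][comp[graph$neighbours[[i]]] == 0L])
        }
      }
    }
  }
  cur
}

# ---- queen contiguity from polygons ------------------------------------

# cross product of (b-a) x (c-a)
.cross <- function(ax, ay, bx, by, cx, cy) (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)

# does segment (p,q) touch/cross segment (r,s)? endpoints count.
.seg_touch <- function(px, py, qx, qy, rx, ry, sx, sy, eps) {
  d1 <- .cross(rx, ry, sx, sy, px, py)
  d2 <- .cross(rx, ry, sx, sy, qx, qy)
  d3 <- .cross(px, py, qx, qy, rx, ry)
  d4 <- .cross(px, py, qx, qy, sx, sy)
  if (((d1 > eps && d2 < -eps) || (d1 < -eps && d2 > eps)) &&
      ((d3 > eps && d4 < -eps) || (d3 < -eps && d4 > eps))) return(TRUE)
  on_seg <- function(ax, ay, bx, by, cx, cy) {
    # c collinear with (a,b); is it within the bounding box?
    cx >= min(ax, bx) - eps && cx <= max(ax, bx) + eps &&
      cy >= min(ay, by) - eps && cy <= max(ay, by) + eps
  }
  if (abs(d1) <= eps && on_seg(rx, ry, sx, sy, px, py)) return(TRUE)
  if (abs(d2) <= eps && on_seg(rx, ry, sx, sy, qx, qy)) return(TRUE)
  if (abs(d3) <= eps && on_seg(px, py, qx, qy, rx, ry)) return(TRUE)
  if (abs(d4) <= eps && on_seg(px, py, qx, qy, sx, sy)) return(TRUE)
  FALSE
}

# boundary segments of one area's polygon parts: matrix (x0, y0, x1, y1)
.area_segments <- function(df) {
  parts <- split(df, df$part)
  segs <- lapply(parts, function(p) {
    x <- p$x; y <- p$y
    # close the ring if needed
    if (x[1] != x[length(x)] || y[1] != y[length(y)]) {
      x <- c(x, x[1]); y <- c(y, y[1])
    }
    cbind(x0 = x[-length(x)], y0 = y[-length(y)], x1 = x[-1], y1 = y[-1])
  })
  do.call(rbind, segs)
}

.polys_touch <- function(seg_a, seg_b, eps) {
  for (a in seq_len(nrow(seg_a))) {
    for (b in seq_len(nrow(seg_b))) {
      if (.seg_touch(seg_a[a, 1], seg_a[a, 2], seg_a[a, 3], seg_a[a, 4],
                     seg_b[b, 1], seg_b[b, 2], seg_b[b, 3], seg_b[b, 4], eps)) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Build first-order queen contiguity from labelled polygons
#'
#' Two areas are neighbours if their boundaries share at least one point —
#' a full edge or a single corner (the "Queen" rule, named after the chess
#' move). Isolated areas (e.g. islands) are retained with empty neighbour
#' sets; see [repair_isolates()].
#'
#' @param polygons A tidy coordinate table with columns `area_id`, `part`
#'   (ring identifier within an area, for multipolygons), `x`, `y`. Rings
#'   need not repeat their first vertex. See [read_geojson_areas()].
#' @param eps Coordinate tolerance for point/segment contact.
#' @return An [area_graph()] whose centroids are the vertex means of each
#'   area's rings.
#' @export
build_queen_adjacency <- function(polygons, eps = 1e-9) {
  polygons <- tibble::as_tibble(polygons)
  req <- c("area_id", "part", "x", "y")
  if (!all(req %in% names(polygons))) {
    stop("`polygons` needs columns ", paste(req, collapse = ", "))
  }
  if (nrow(polygons) == 0L) stop("empty polygon set")
  runs <- rle(paste(polygons$area_id, polygons$part))$values
  if (anyDuplicated(runs)) {
    stop("duplicate labels: ring coordinates for the same area_id/part appear ",
         "in non-contiguous blocks")
  }
  ids <- unique(polygons$area_id)
  by_area <- split(polygons, factor(polygons$area_id, levels = ids))
  segs <- lapply(by_area, .area_segments)
  bbox <- t(vapply(by_area, function(d) {
    c(min(d$x), max(d$x), min(d$y), max(d$y))
  }, numeric(4)))
  n <- length(ids)
  nb <- vector("list", n)
  for (i in seq_len(n)) nb[[i]] <- integer()
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      if (bbox[i, 1] > bbox[j, 2] + eps || bbox[j, 1] > bbox[i, 2] + eps ||
          bbox[i, 3] > bbox[j, 4] + eps || bbox[j, 3] > bbox[i, 4] + eps) next
      if (.polys_touch(segs[[i]], segs[[j]], eps)) {
        nb[[i]] <- c(nb[[i]], j)
        nb[[j]] <- c(nb[[j]], i)
      }
    }
  }
  cent <- dplyr::summarise(dplyr::group_by(polygons, .data$area_id),
                           x = mean(.data$x), y = mean(.data$y), .groups = "drop")
  area_graph(ids, centroids = cent, neighbours = nb)
}

# ---- isolate repair -----------------------------------------------------

#' Link isolated areas into the graph
#'
#' Manual links (e.g. grouping offshore islands with chosen mainland areas)
#' are applied first, in both directions. Any remaining neighbourless area is
#' then linked to the area with the nearest centroid; ties break to the area
#' earlier in `area_ids` order. The CAR prior cannot smooth an area with no
#' neighbours, so fitted models require a repaired graph.
#'
#' @param graph An [area_graph()].
#' @param manual_links Optional two-column data frame (or matrix) of area ids
#'   to join; unknown ids are an error.
#' @return The repaired `area_graph`, with a tibble of added links (columns
#'   `from`, `to`, `how`) attached as element `repair_log`.
#' @export
repair_isolates <- function(graph, manual_links = NULL) {
  nb <- graph$neighbours
  ids <- graph$area_ids
  log_rows <- list()
  if (!is.null(manual_links)) {
    ml <- as.data.frame(manual_links)
    if (ncol(ml) < 2) stop("`manual_links` needs two columns of area ids")
    for (r in seq_len(nrow(ml))) {
      a <- match(as.character(ml[r, 1]), ids)
      b <- match(as.character(ml[r, 2]), ids)
      if (is.na(a) || is.na(b)) {
        stop("manual link names unknown area: ", ml[r, 1], " - ", ml[r, 2])
      }
      if (a != b && !(b %in% nb[[a]])) {
        nb[[a]] <- sort(c(nb[[a]], b))
        nb[[b]] <- sort(c(nb[[b]], a))
        log_rows[[length(log_rows) + 1L]] <-
          tibble::tibble(from = ids[a], to = ids[b], how = "manual")
      }
    }
  }
  iso <- which(lengths(nb) == 0L)
  if (length(iso)) {
    if (is.null(graph$centroids)) {
      stop("graph has isolates but no centroids; supply manual_links or centroids")
    }
    cx <- graph$centroids$x
    cy <- graph$centroids$y
    for (i in iso) {
      if (length(nb[[i]])) next  # may have been linked by an earlier isolate
      d <- sqrt((cx - cx[i])^2 + (cy - cy[i])^2)
      d[i] <- Inf
      j <- which(d <= min(d))[1L]  # tie -> earliest area_id order
      nb[[i]] <- sort(c(nb[[i]], j))
      nb[[j]] <- sort(c(nb[[j]], i))
      log_rows[[length(log_rows) + 1L]] <-
        tibble::tibble(from = ids[i], to = ids[j], how = "nearest_centroid")
    }
  }
  out <- area_graph(ids, centroids = graph$centroids, neighbours = nb)
  out$repair_log <- if (length(log_rows)) dplyr::bind_rows(log_rows) else
    tibble::tibble(from = character(), to = character(), how = character())
  out
}

# ---- GAL serialization --------------------------------------------------

#' Read / write GAL spatial weights
#'
#' The GAL dialect used here has a header line with the area count, then for
#' each area a line `id n` followed by a line listing its `n` neighbour ids.
#' Reading rejects neighbour ids absent from the file's own area set and
#' asymmetric neighbour structures.
#'
#' @param text Character scalar (whole file) or character vector of lines; a
#'   path to an existing file is also accepted.
#' @param centroids Optional centroid table (`area_id`, `x`, `y`) to attach.
#' @return `read_gal()` returns an [area_graph()]; `write_gal()` returns the
#'   file text invisibly (and writes it when `path` is given).
#' @export
read_gal <- function(text, centroids = NULL) {
  if (length(text) == 1L && file.exists(text)) {
    lines <- readLines(text)
  } else if (length(text) == 1L) {
    lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  } else {
    lines <- text
  }
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GAL input")
  n <- as.integer(strsplit(lines[1], "\\s+")[[1]][1])
  if (is.na(n) || n < 1L) stop("bad GAL header")
  ids <- character(n)
  raw_nb <- vector("list", n)
  cursor <- 2L
  for (k in seq_len(n)) {
    hdr <- strsplit(lines[cursor], "\\s+")[[1]]
    if (length(hdr) < 2) stop("malformed GAL area header: ", lines[cursor])
    ids[k] <- hdr[1]
    cnt <- as.integer(hdr[2])
    if (is.na(cnt) || cnt < 0) stop("bad neighbour count for area ", hdr[1])
    if (cnt > 0L) {
      raw_nb[[k]] <- strsplit(lines[cursor + 1L], "\\s+")[[1]]
      if (length(raw_nb[[k]]) != cnt) {
        stop("area ", hdr[1], " declares ", cnt, " neighbours but lists ",
             length(raw_nb[[k]]))
      }
      cursor <- cursor + 2L
    } else {
      raw_nb[[k]] <- character()
      cursor <- cursor + 1L
    }
  }
  nb <- lapply(raw_nb, function(v) {
    idx <- match(v, ids)
    if (anyNA(idx)) stop("neighbour id not in area set: ",
                         paste(v[is.na(idx)], collapse = ", "))
    idx
  })
  area_graph(ids, centroids = centroids, neighbours = nb)  # validates symmetry
}

#' @param graph An [area_graph()].
#' @param path Optional output file path.
#' @rdname read_gal
#' @export
write_gal <- function(graph, path = NULL) {
  lines <- as.character(graph$n_areas)
  for (i in seq_len(graph$n_areas)) {
    nb <- graph$neighbours[[i]]
    lines <- c(lines, paste(graph$area_ids[i], length(nb)))
    if (length(nb)) lines <- c(lines, paste(graph$area_ids[nb], collapse = " "))
  }
  text <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) writeLines(lines, path)
  invisible(text)
}
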