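# Small graphs and datasets built in code, shared across test files.

# n-area path graph 1-2-...-n with centroids on the x axis
path_graph <- function(n = 3) {
  nb <- lapply(seq_len(n), function(i) {
    c(if (i > 1) i - 1L, if (i < n) i + 1L)
  })
  area_graph(sprintf("P%02d", seq_len(n)),
             centroids = data.frame(area_id = sprintf("P%02d", seq_len(n)),
                                    x = seq_len(n), y = 0),
             neighbours = nb)
}

# square lattice with queen (8-neighbour) adjacency, built by row/col
# arithmetic -- independent of the polygon-based construction
lattice_graph <- function(n_rows, n_cols) {
  ids <- sprintf("L%03d", seq_len(n_rows * n_cols))
  rc <- expand.grid(col = seq_len(n_cols), row = seq_len(n_rows))
  nb <- lapply(seq_len(n_rows * n_cols), function(k) {
    dr <- abs(rc$row - rc$row[k])
    dc <- abs(rc$col - rc$col[k])
    which(dr <= 1 & dc <= 1 & !(dr == 0 & dc == 0))
  })
  area_graph(ids,
             centroids = data.frame(area_id = ids, x = rc$col, y = rc$row),
             neighbours = nb)
}

# unit square polygon rows for hand-built geometries
square_poly <- function(id, x0, y0, size = 1) {
  tibble::tibble(area_id = id, part = 1L,
                 x = c(x0, x0 + size, x0 + size, x0),
                 y = c(y0, y0, y0 + size, y0 + size))
}

# Moran's I of x on a graph (binary weights), straight-line implementation
morans_i <- function(x, graph) {
  ed <- graph_edges(graph)
  w2 <- 2 * nrow(ed)  # symmetric weight total
  z <- x - mean(x)
  num <- 2 * sum(z[ed$from] * z[ed$to])
  length(x) / w2 * num / sum(z^2)
}

# minimal fabricated fits for summary-level tests
fake_bym_fit <- function(theta, graph, e = rep(1, graph$n_areas),
                         y = rep(1, graph$n_areas)) {
  colnames(theta) <- graph$area_ids
  structure(list(
    theta = theta,
    draws = list(alpha = rep(0, nrow(theta)),
                 u = theta * 0, v = theta * 0),
    data = tibble::tibble(area_id = graph$area_ids, y = y, e = e),
    graph = graph, n_draws = nrow(theta)),
    class = c("bym_fit", "atlas_fit"))
}
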