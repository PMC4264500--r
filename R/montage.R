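#' Standard 32-channel fronto-centro-parietal montage
#'
#' Channel labels and 10-10 grid coordinates for the default 32-electrode
#' montage over frontal, central and parietal cortex.  Columns follow the
#' 10-10 convention (z = 0; odd labels left, even right; 1/2 = +/-1,
#' 3/4 = +/-2, 5/6 = +/-3 grid steps) and rows run anterior to posterior
#' (F, FC, C, CP, P, PO).  Only this grid topology matters downstream:
#' orthogonal neighbours are the channels one grid step away.
#'
#' @return A data.frame with columns `label`, `row`, `col`.
#' @export
channel_grid <- function() {
  mk <- function(row_name, row, cols) {
    side <- function(k)
      if (k == 0) "z" else as.character(if (k < 0) -2 * k - 1 else 2 * k)
    data.frame(label = paste0(row_name, vapply(cols, side, "")),
               row = row, col = cols, stringsAsFactors = FALSE)
  }
  rbind(mk("F",  0, -2:2),
        mk("FC", 1, -2:2),
        mk("C",  2, -3:3),
        mk("CP", 3, -2:2),
        mk("P",  4, -2:2),
        mk("PO", 5, -2:2))
}

#' Orthogonal Laplacian montage
#'
#' Builds a Hjorth-style Laplacian montage: each derivable channel is
#' re-referenced to the mean of its orthogonal nearest neighbours (up to
#' four: one grid step anterior/posterior/left/right).  Edge channels with
#' fewer than `min_neighbors` orthogonal neighbours are excluded from the
#' Laplacian set.
#'
#' @param labels channels present in the data; defaults to the full
#'   [channel_grid()] montage.
#' @param grid a data.frame like [channel_grid()] giving each label a
#'   `row`/`col` position.
#' @param min_neighbors minimum neighbour count for a derivable channel
#'   (default 2).
#' @return A `laplacian_montage`: named list mapping each derivable centre
#'   label to its character vector of neighbour labels.
#' @examples
#' m <- laplacian_montage()
#' m$Cz   # FCz, CPz, C1, C2
#' @export
laplacian_montage <- function(labels = channel_grid()$label,
                              grid = channel_grid(), min_neighbors = 2) {
  grid <- grid[grid$label %in% labels, , drop = FALSE]
  miss <- setdiff(labels, grid$label)
  if (length(miss))
    stopf("no grid position for: %s", paste(miss, collapse = ", "))
  out <- list()
  for (i in seq_len(nrow(grid))) {
    dr <- grid$row - grid$row[i]
    dc <- grid$col - grid$col[i]
    nb <- grid$label[(abs(dr) + abs(dc)) == 1]
    if (length(nb) >= min_neighbors) out[[grid$label[i]]] <- nb
  }
  structure(out, class = "laplacian_montage")
}

#' @export
print.laplacian_montage <- function(x, ...) {
  cat(sprintf("<laplacian_montage> %d derivable channels\n", length(x)))
  invisible(x)
}

#' Apply an orthogonal Laplacian derivation
#'
#' For each montage centre c, derived(c) = x(c) - mean(x(neighbours of c)).
#' The derivation is linear and removes activity common to the local
#' neighbourhood, sharpening focal sources.  Channels not in the montage
#' are dropped (they have no defined derivation).
#'
#' @param x an `eeg_recording` or `epoch_set`.
#' @param montage a [laplacian_montage()].
#' @return Same class as `x`, restricted to the derivable channels.
#' @export
laplacian_derive <- function(x, montage) {
  stopifnot(inherits(montage, "laplacian_montage"))
  centers <- names(montage)
  need <- unique(c(centers, unlist(montage)))
  miss <- setdiff(need, x$labels)
  if (length(miss))
    stopf("montage channels missing from data: %s", paste(miss, collapse = ", "))
  # weight matrix: derived = W %*% signal  (rows = centers)
  W <- matrix(0, length(centers), length(x$labels),
              dimnames = list(centers, x$labels))
  for (c in centers) {
    W[c, c] <- 1
    W[c, montage[[c]]] <- -1 / length(montage[[c]])
  }
  if (inherits(x, "eeg_recording")) {
    x$signal <- W %*% x$signal
  } else if (inherits(x, "epoch_set")) {
    d <- dim(x$data)
    out <- array(NA_real_, c(d[1], length(centers), d[3]),
                 dimnames = list(NULL, centers, NULL))
    for (t in seq_len(d[1]))
      out[t, , ] <- W %*% x$data[t, , ]
    x$data <- out
  } else stopf("unsupported class")
  x$labels <- centers
  x
}

#' Serialize a Laplacian montage to / from JSON
#' @param montage a [laplacian_montage()].
#' @param path JSON file path.
#' @export
write_montage <- function(montage, path) {
  jsonlite::write_json(unclass(montage), path, pretty = TRUE)
  invisible(path)
}

#' @rdname write_montage
#' @export
read_montage <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(as.list(m), class = "laplacian_montage")
}
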