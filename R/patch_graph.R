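#' Tile masked tissue into non-overlapping patches
#'
#' Lays a regular grid anchored at (0, 0) with stride `patch_size` over
#' the mask (computed at the x5 working magnification) and keeps every
#' patch whose in-mask pixel fraction is at least `tissue_fraction`.
#' Patches extending beyond the image count out-of-bounds pixels as
#' non-tissue. Patches are ordered row-major.
#'
#' @param mask a [compute_tissue_mask()] result, or a logical matrix.
#' @param tissue_fraction minimum in-mask fraction (default 0.5).
#' @param patch_size patch side in pixels at the mask magnification.
#' @param slide_id identifier stored on the patch set.
#' @return An object of class `patch_set` with `coords` (N x 2 integer
#'   matrix of patch top-left corners, columns `x`, `y`, 0-based pixels at
#'   the mask magnification), `patch_size` and `magnification`.
#' @export
tile_patches <- function(mask, tissue_fraction = 0.5, patch_size = 256L,
                         slide_id = "slide") {
  mag <- 5
  if (inherits(mask, "tissue_mask")) {
    mag <- mask$magnification
    mask <- mask$mask
  }
  stopifnot(is.matrix(mask), patch_size >= 1)
  nx <- ceiling(ncol(mask) / patch_size)
  ny <- ceiling(nrow(mask) / patch_size)
  m <- mask * 1
  coords <- NULL
  for (gy in seq_len(ny) - 1L) {          # row-major: y outer, x inner
    rows <- (gy * patch_size + 1L):min((gy + 1L) * patch_size, nrow(mask))
    for (gx in seq_len(nx) - 1L) {
      cols <- (gx * patch_size + 1L):min((gx + 1L) * patch_size, ncol(mask))
      frac <- sum(m[rows, cols]) / (patch_size^2)
      if (frac >= tissue_fraction) {
        coords <- rbind(coords, c(gx * patch_size, gy * patch_size))
      }
    }
  }
  if (is.null(coords)) {
    gs_error("no patches meet the tissue fraction threshold (empty slide)",
             "empty_slide_error")
  }
  colnames(coords) <- c("x", "y")
  structure(list(slide_id = slide_id, coords = coords,
                 patch_size = as.integer(patch_size), magnification = mag),
            class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("<patch_set> %s: %d patches of %dpx at x%g\n", x$slide_id,
              nrow(x$coords), x$patch_size, x$magnification))
  invisible(x)
}

#' Deterministic histogram patch encoder
#'
#' A self-contained stand-in for a pretrained histopathology foundation
#' encoder with the same interface contract: a deterministic map from
#' patch pixels to a 512-dimensional feature vector. It concatenates
#' per-channel intensity histograms (`bins` bins, as proportions) with
#' per-channel mean and standard deviation, then projects to `dim`
#' dimensions with a fixed, seeded random Gaussian matrix. Identical
#' pixels always give identical features. An adapter for an external
#' pretrained encoder can implement the same interface (`name`, `dim`,
#' `encode`).
#'
#' @param dim output feature dimension (default 512).
#' @param bins histogram bins per channel.
#' @param seed seed of the fixed projection matrix.
#' @return An object of class `patch_encoder` with fields `name`, `dim`
#'   and `encode(pixels)`.
#' @export
histogram_encoder <- function(dim = 512L, bins = 64L, seed = 20260101L) {
  in_dim <- 3L * bins + 6L
  proj <- with_preserved_seed(seed, {
    matrix(rnorm(in_dim * dim) / sqrt(in_dim), in_dim, dim)
  })
  encode <- function(pixels) {
    if (inherits(pixels, "raster_image")) pixels <- pixels$pixels
    v <- numeric(in_dim)
    for (ch in 1:3) {
      x <- as.vector(pixels[, , ch])
      h <- tabulate(pmin(bins, x %/% (256L / bins) + 1L), nbins = bins)
      v[((ch - 1L) * bins + 1L):(ch * bins)] <- h / length(x)
      v[3L * bins + 2L * ch - 1L] <- mean(x) / 255
      v[3L * bins + 2L * ch] <- if (length(x) > 1) sd(x) / 255 else 0
    }
    drop(v %*% proj)
  }
  structure(list(name = sprintf("histogram-%d", bins), dim = as.integer(dim),
                 encode = encode), class = "patch_encoder")
}

# run code under a fixed seed without disturbing the caller's RNG stream
with_preserved_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Encode tissue patches to feature vectors
#'
#' Reads each patch of a [tile_patches()] result from the slide at the
#' patch magnification and applies the encoder row-wise. Rows are checked
#' to be finite; an encoder failure aborts with the offending patch index.
#'
#' @param slide a [open_slide()] handle.
#' @param patches a [tile_patches()] result.
#' @param encoder a `patch_encoder` (default [histogram_encoder()]).
#' @return N x `encoder$dim` numeric matrix, rows in patch order.
#' @export
encode_patches <- function(slide, patches, encoder = histogram_encoder()) {
  stopifnot(inherits(patches, "patch_set"), inherits(encoder, "patch_encoder"))
  scale <- slide$base_magnification / patches$magnification
  n <- nrow(patches$coords)
  feats <- matrix(NA_real_, n, encoder$dim)
  for (i in seq_len(n)) {
    bbox <- c(patches$coords[i, 1] * scale, patches$coords[i, 2] * scale,
              patches$patch_size * scale, patches$patch_size * scale)
    row <- tryCatch(encoder$encode(read_region(slide, patches$magnification, bbox)),
                    error = function(e) e)
    if (inherits(row, "error") || length(row) != encoder$dim || !all(is.finite(row))) {
      gs_error(sprintf("encoder failed on patch %d: %s", i,
                       if (inherits(row, "error")) conditionMessage(row)
                       else "non-finite or wrong-length output"),
               "encoder_error")
    }
    feats[i, ] <- row
  }
  feats
}

#' Build the spatial k-nearest-neighbour patch graph
#'
#' Each node is a patch; directed k-NN edges are computed on Euclidean
#' distance between patch-centre coordinates (k capped at N - 1; distance
#' ties broken by lower node index), then symmetrised by union into an
#' undirected, deduplicated edge list sorted lexicographically. Union
#' symmetrisation guarantees every node keeps at least k neighbours when
#' N > k, so message passing never degenerates on isolated nodes.
#'
#' @param features N x d numeric feature matrix (rows follow `coords`).
#' @param coords N x 2 numeric matrix of patch centres.
#' @param k neighbours per node (default 8).
#' @param slide_id identifier stored on the graph.
#' @return An object of class `slide_graph` with `features`, `coords`,
#'   `edges` (E x 2 integer matrix, 1-based, `edges[,1] < edges[,2]`) and `k`.
#' @export
build_knn_graph <- function(features, coords, k = 8L, slide_id = "slide") {
  coords <- as.matrix(coords)
  features <- as.matrix(features)
  n <- nrow(coords)
  stopifnot(n >= 1, nrow(features) == n, ncol(coords) == 2)
  kk <- min(k, n - 1L)
  if (kk >= 1) {
    d <- as.matrix(stats::dist(coords))
    pairs <- NULL
    for (i in seq_len(n)) {
      di <- d[i, ]; di[i] <- Inf
      nb <- order(di, seq_len(n))[seq_len(kk)]   # ties: lower index wins
      pairs <- rbind(pairs, cbind(pmin(i, nb), pmax(i, nb)))
    }
    edges <- unique(pairs)
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  } else {
    edges <- matrix(integer(0), 0, 2)
  }
  storage.mode(edges) <- "integer"
  colnames(edges) <- c("from", "to")
  structure(list(slide_id = slide_id, features = features, coords = coords,
                 edges = edges, k = as.integer(k)),
            class = "slide_graph")
}

#' @export
print.slide_graph <- function(x, ...) {
  cat(sprintf("<slide_graph> %s: %d nodes (%d-dim), %d undirected edges (k=%d)\n",
              x$slide_id, nrow(x$features), ncol(x$features), nrow(x$edges), x$k))
  invisible(x)
}

#' Build a slide graph directly from a slide file
#'
#' Convenience wrapper chaining [read_region()] at the working
#' magnification, [compute_tissue_mask()], [tile_patches()],
#' [encode_patches()] and [build_knn_graph()] (node coordinates are patch
#' centres at the working magnification).
#'
#' @param slide a [open_slide()] handle.
#' @param magnification working magnification (default 5).
#' @param k,patch_size,tissue_fraction see the respective stages.
#' @param encoder a `patch_encoder`.
#' @param params a [mask_params()] bundle.
#' @return A `slide_graph`.
#' @export
slide_to_graph <- function(slide, magnification = 5, k = 8L, patch_size = 256L,
                           tissue_fraction = 0.5, encoder = histogram_encoder(),
                           params = mask_params()) {
  W <- slide$levels$width[1]; H <- slide$levels$height[1]
  low <- read_region(slide, magnification, c(0, 0, W, H))
  mask <- compute_tissue_mask(low, params,
                              scale_to_level0 = slide$base_magnification / magnification)
  patches <- tile_patches(mask, tissue_fraction, patch_size,
                          slide_id = basename(slide$path))
  feats <- encode_patches(slide, patches, encoder)
  centers <- patches$coords + patches$patch_size / 2
  build_knn_graph(feats, centers, k = k, slide_id = patches$slide_id)
}

#' Save / load a slide graph as a plain-text archive
#'
#' A graph is stored as a directory of CSV files (`features.csv`,
#' `coords.csv`, `edges.csv`) with a JSON sidecar (`graph.json`: slide id,
#' k, magnification of the coordinate frame).
#'
#' @param graph a `slide_graph`.
#' @param dir archive directory (created if missing).
#' @return `dir` (`save_slide_graph`) or a `slide_graph`
#'   (`load_slide_graph`).
#' @export
save_slide_graph <- function(graph, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(graph$features, file.path(dir, "features.csv"), row.names = FALSE)
  write.csv(graph$coords, file.path(dir, "coords.csv"), row.names = FALSE)
  write.csv(graph$edges, file.path(dir, "edges.csv"), row.names = FALSE)
  jsonlite::write_json(list(slide_id = graph$slide_id, k = graph$k,
                            magnification = 5),
                       file.path(dir, "graph.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname save_slide_graph
#' @export
load_slide_graph <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "graph.json"))
  edges <- as.matrix(read.csv(file.path(dir, "edges.csv")))
  if (nrow(edges) == 0) edges <- matrix(integer(0), 0, 2,
                                        dimnames = list(NULL, c("from", "to")))
  storage.mode(edges) <- "integer"
  structure(list(slide_id = meta$slide_id,
                 features = as.matrix(read.csv(file.path(dir, "features.csv"))),
                 coords = as.matrix(read.csv(file.path(dir, "coords.csv"))),
                 edges = edges, k = as.integer(meta$k)),
            class = "slide_graph")
}
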