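#' Node-importance explanation of a risk prediction
#'
#' Learns a sigmoid-parameterised soft mask over the graph's edges by
#' gradient descent on a fidelity-plus-sparsity objective,
#' `|risk(masked graph) - risk(full graph)| + sparsity_weight * mean(mask)
#' + entropy_weight * mean(binary entropy(mask))`,
#' in the spirit of mask-learning explainers for graph networks. The
#' mask multiplies the per-edge messages with the aggregation
#' normalisation held fixed (normalised-adjacency entries for graph
#' convolution, softmax attention coefficients for graph attention), so
#' a fully masked edge really removes its message. The mask starts low:
#' the fidelity term must actively recover the edges the prediction
#' needs, while the sparsity and entropy terms keep unneeded edges
#' suppressed. Node importance is the maximum mask weight over incident
#' edges, normalised to `[0, 1]` with maximum 1. Deterministic given the
#' seed.
#'
#' @param model a fitted [gnnsurv()] model.
#' @param graph a `slide_graph`.
#' @param steps gradient steps (default 200).
#' @param sparsity_weight weight of the mean-mask sparsity term.
#' @param entropy_weight weight of the element-entropy term that pushes
#'   mask values away from 0.5.
#' @param lr learning rate of the plain gradient descent on the mask
#'   logits. Plain (unnormalised) descent is deliberate: the step size of
#'   each edge tracks the magnitude of its influence on the risk, so
#'   edges the prediction does not need barely move from their low start
#'   while influential edges are recovered.
#' @param seed RNG seed for the logit initialisation.
#' @return An object of class `explanation_map` with `slide_id`,
#'   `node_importance` (length N in `[0,1]`, max 1), `coords` (patch
#'   top-left corners when derivable, else node coordinates), `patch_size`,
#'   `edge_mask` and the objective trajectory.
#' @export
explain_graph <- function(model, graph, steps = 200L, sparsity_weight = 0.005,
                          entropy_weight = 0.1, lr = 1, seed = 1L) {
  stopifnot(inherits(model, "gnnsurv"), inherits(graph, "slide_graph"))
  gp <- prep_graph(graph)
  n <- gp$n
  ne <- nrow(gp$edges)
  if (n == 1 || ne == 0) {
    return(new_explanation(graph, rep(1, n), numeric(0), numeric(0)))
  }
  full <- model_forward(model$params, model$backbone, gp)$risk
  logits <- with_preserved_seed(seed, rnorm(ne, mean = -2, sd = 0.1))
  obj <- numeric(steps)
  for (s in seq_len(steps)) {
    w <- 1 / (1 + exp(-logits))
    fw <- model_forward(model$params, model$backbone, gp, edge_weights = w)
    diff <- fw$risk - full
    ent <- -(w * log(pmax(w, 1e-12)) + (1 - w) * log(pmax(1 - w, 1e-12)))
    obj[s] <- abs(diff) + sparsity_weight * mean(w) + entropy_weight * mean(ent)
    bk <- model_backward(model$params, model$backbone, gp, fw, sign(diff),
                         want_edge_grad = TRUE, edge_weights = w)
    dw <- bk$edge + sparsity_weight / ne +
      entropy_weight * (-log(w / pmax(1 - w, 1e-12))) / ne
    logits <- logits - lr * dw * w * (1 - w)
  }
  w <- 1 / (1 + exp(-logits))
  imp <- numeric(n)
  for (i in seq_len(n)) {
    inc <- gp$edges[, 1] == i | gp$edges[, 2] == i
    imp[i] <- if (any(inc)) max(w[inc]) else 0
  }
  if (max(imp) > 0) imp <- imp / max(imp)
  new_explanation(graph, imp, w, obj)
}

new_explanation <- function(graph, importance, edge_mask, objective) {
  structure(list(slide_id = graph$slide_id, node_importance = importance,
                 coords = graph$coords, patch_size = 256L,
                 edge_mask = edge_mask, objective = objective),
            class = "explanation_map")
}

#' @export
print.explanation_map <- function(x, ...) {
  cat(sprintf("<explanation_map> %s: %d nodes, importance in [%.3f, %.3f]\n",
              x$slide_id, length(x$node_importance),
              min(x$node_importance), max(x$node_importance)))
  invisible(x)
}

#' Render a node-importance heatmap over the slide
#'
#' Downsamples the slide to the requested magnification and alpha-blends
#' (0.5) a blue-to-red colormap over each patch footprint: red marks
#' patches with high contribution to the risk prediction, blue low
#' contribution. Regions outside any patch are left unshaded.
#'
#' @param expl an [explain_graph()] result (coords are patch centres at
#'   the x5 working magnification).
#' @param slide a [open_slide()] handle.
#' @param magnification rendering magnification (default 1.25).
#' @param alpha overlay opacity.
#' @return A [raster_image()].
#' @export
render_heatmap <- function(expl, slide, magnification = 1.25, alpha = 0.5) {
  W <- slide$levels$width[1]; H <- slide$levels$height[1]
  img <- read_region(slide, magnification, c(0, 0, W, H))
  px <- img$pixels * 1.0
  ramp <- colorRamp(c("blue", "red"))
  scale <- magnification / 5      # coords live at x5
  half <- expl$patch_size / 2
  for (i in seq_along(expl$node_importance)) {
    col <- ramp(expl$node_importance[i])
    x0 <- floor((expl$coords[i, 1] - half) * scale)
    y0 <- floor((expl$coords[i, 2] - half) * scale)
    x1 <- min(ceiling(x0 + expl$patch_size * scale), ncol(px))
    y1 <- min(ceiling(y0 + expl$patch_size * scale), nrow(px))
    rows <- max(y0 + 1, 1):y1; cols <- max(x0 + 1, 1):x1
    for (ch in 1:3) {
      px[rows, cols, ch] <- (1 - alpha) * px[rows, cols, ch] + alpha * col[ch]
    }
  }
  raster_image(array(as.integer(round(px)), dim(px)), magnification)
}
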