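#' Proportional retention and kernel parameters
#'
#' All post-processing thresholds are adaptive ratios of the eyebrow height
#' `h`, keeping the measurement scale-invariant across subjects and
#' timepoints: centroid-distance threshold `tau_dist = 0.50 h`, minimum
#' secondary-component area `tau_area = 0.01 h^2` (1% of the bounding square
#' on `h`), opening kernel diameter `0.05 h` and dilation kernel diameter
#' `0.07 h` (each rounded to the nearest odd integer >= 1 so the elliptical
#' structuring element is centered).
#'
#' @param h eyebrow height (px, > 0).
#' @return object of class `retention_params`.
#' @export
retention_params <- function(h) {
  if (h <= 0) stop("eyebrow height must be > 0")
  structure(list(
    h = h,
    tau_dist = 0.50 * h,
    tau_area = 0.01 * h^2,
    kernel_open = odd_size(0.05 * h),
    kernel_dilate = odd_size(0.07 * h)
  ), class = "retention_params")
}

#' Binarize an 8-bit probability map
#'
#' High-sensitivity low-intensity threshold: foreground where the grayscale
#' value is strictly greater than `tau` (default 1 on the 0-255 scale),
#' preserving fine hair strands.
#'
#' @param gray8 matrix of 8-bit grayscale values (0-255).
#' @param tau threshold in [0, 255].
#' @return binary `{0, 1}` matrix.
#' @export
binarize <- function(gray8, tau = 1) {
  if (tau < 0 || tau > 255) stop("tau must be in [0, 255]")
  (gray8 > tau) * 1
}

ebi_opening <- function(mask, size) {
  if (size < 2) return(mask)
  brush <- EBImage::makeBrush(odd_size(size), shape = "disc")
  EBImage::imageData(EBImage::opening(EBImage::Image(t(mask)), brush)) |> t()
}

#' Morphological refinement of the binary hair mask
#'
#' Opening with an elliptical kernel (diameter `kernel_open`) suppresses
#' high-frequency salt noise; a following dilation (diameter
#' `kernel_dilate`) consolidates fragmented strands and restores structural
#' connectivity of the primary hair component.
#'
#' @param mask binary `{0, 1}` matrix.
#' @param params [retention_params()].
#' @return refined binary matrix.
#' @export
refine_morphology <- function(mask, params) {
  opened <- ebi_opening(mask, params$kernel_open)
  dilated <- ebi_dilate(opened, params$kernel_dilate)
  (dilated > 0) * 1
}

#' 8-connected component analysis
#'
#' Labels maximal 8-connected foreground regions (diagonal neighbors are
#' connected). Labels are assigned deterministically in row-major order of
#' each component's first pixel. Areas and centroids are reported per
#' component.
#'
#' @param mask binary `{0, 1}` matrix.
#' @return list with `labels` (integer matrix, 0 = background) and `table`
#'   (data frame: `label`, `area`, `centroid_x`, `centroid_y`).
#' @export
connected_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  fg <- which(mask > 0)
  labels <- matrix(0L, h, w)
  empty <- data.frame(label = integer(0), area = numeric(0),
                      centroid_x = numeric(0), centroid_y = numeric(0))
  if (length(fg) == 0) return(list(labels = labels, table = empty))
  idmap <- integer(h * w); idmap[fg] <- seq_along(fg)
  row <- ((fg - 1) %% h) + 1
  col <- ((fg - 1) %/% h) + 1
  # adjacency to E, S, SE, NE neighbors covers all 8-connected pairs once
  edges <- list()
  for (off in list(c(0, 1), c(1, 0), c(1, 1), c(-1, 1))) {
    nr <- row + off[1]; nc <- col + off[2]
    ok <- nr >= 1 & nr <= h & nc >= 1 & nc <= w
    nidx <- (nc[ok] - 1) * h + nr[ok]
    hit <- idmap[nidx] > 0
    edges[[length(edges) + 1]] <-
      cbind(idmap[fg[ok]][hit], idmap[nidx][hit])
  }
  edges <- do.call(rbind, edges)
  g <- igraph::graph_from_edgelist(
    rbind(edges, cbind(seq_along(fg), seq_along(fg))), directed = FALSE)
  comp <- igraph::components(g)$membership[seq_along(fg)]
  # deterministic relabel: row-major (scan rows top-to-bottom) first pixel
  scan_order <- order(row, col)
  first_seen <- !duplicated(comp[scan_order])
  relabel <- integer(max(comp))
  relabel[comp[scan_order][first_seen]] <- seq_len(sum(first_seen))
  lab <- relabel[comp]
  labels[fg] <- lab
  x <- col - 1; y <- row - 1  # 0-based point coords
  tab <- data.frame(
    label = sort(unique(lab)),
    area = as.numeric(tapply(rep(1, length(lab)), lab, sum)),
    centroid_x = as.numeric(tapply(x, lab, mean)),
    centroid_y = as.numeric(tapply(y, lab, mean))
  )
  list(labels = labels, table = tab)
}

#' Retention filtering of connected components
#'
#' The primary hair component `C_main` is the component of maximal area
#' (ties broken by lowest label) and is always kept. A secondary component
#' is retained only if its centroid lies strictly within `tau_dist` of the
#' main component's centroid AND its area is strictly greater than
#' `tau_area`; everything else is discarded as background noise. The
#' optimized mask is the union of retained components.
#'
#' @param cc output of [connected_components()].
#' @param params [retention_params()].
#' @return list with `mask` (binary matrix `M_opt`) and `table` (component
#'   table with a logical `retained` column). An empty component list yields
#'   an empty mask.
#' @export
retain_components <- function(cc, params) {
  tab <- cc$table
  if (nrow(tab) == 0)
    return(list(mask = (cc$labels > 0) * 1, table = cbind(tab, retained = logical(0))))
  main <- tab$label[order(-tab$area, tab$label)][1]
  mu_main <- c(tab$centroid_x[tab$label == main], tab$centroid_y[tab$label == main])
  d <- sqrt((tab$centroid_x - mu_main[1])^2 + (tab$centroid_y - mu_main[2])^2)
  tab$retained <- tab$label == main |
    (d < params$tau_dist & tab$area > params$tau_area)
  keep <- tab$label[tab$retained]
  mask <- matrix(0, nrow(cc$labels), ncol(cc$labels))
  mask[cc$labels %in% keep] <- 1
  list(mask = mask, table = tab)
}

#' Full post-processing chain: probability map to optimized hair mask
#'
#' Thresholding, proportional morphological opening + dilation, 8-connected
#' component analysis, and retention filtering.
#'
#' @param gray8 8-bit grayscale probability map (see [prob_to_gray8()]).
#' @param params [retention_params()].
#' @param tau binarization threshold (default 1).
#' @return list with `mask` (`M_opt`), `table` (component table with
#'   retention flags), and the intermediate `binary` and `refined` masks.
#' @export
postprocess_mask <- function(gray8, params, tau = 1) {
  b <- binarize(gray8, tau)
  refined <- refine_morphology(b, params)
  cc <- connected_components(refined)
  kept <- retain_components(cc, params)
  list(mask = kept$mask, table = kept$table, binary = b, refined = refined)
}

#' Write component table as CSV
#'
#' @param table component table from [retain_components()].
#' @param path CSV path.
#' @export
write_component_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Threshold sensitivity of total foreground area
#'
#' Reports the percent change in total foreground pixels of the optimized
#' mask between two binarization thresholds (the robustness experiment
#' design: `tau = 1` vs `tau = 10`). The value is data-dependent.
#'
#' @param gray8 8-bit grayscale probability map.
#' @param params [retention_params()].
#' @param tau_low,tau_high the two thresholds to compare.
#' @return list with the two areas and `percent_change` (% of the low-tau
#'   area).
#' @export
tau_sensitivity <- function(gray8, params, tau_low = 1, tau_high = 10) {
  a_low <- sum(postprocess_mask(gray8, params, tau_low)$mask)
  a_high <- sum(postprocess_mask(gray8, params, tau_high)$mask)
  list(area_low = a_low, area_high = a_high,
       percent_change = if (a_low > 0) 100 * (a_low - a_high) / a_low else NA_real_)
}
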