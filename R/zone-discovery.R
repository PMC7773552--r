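#' Session-long correlation matrix of ROI traces
#'
#' Symmetric Pearson correlation matrix over ROIs ordered from lateral to
#' medial (descending mediolateral coordinate), the representation on which
#' parasagittal zones appear as blocks.
#'
#' @param traces frames x ROIs matrix (dF/F or raw fluorescence; columns
#'   follow `roi_table` rows).
#' @param roi_table data.frame with `roi_id` and `ml_um`; rows match trace
#'   columns. When `NULL` the existing column order is kept.
#' @return list with `corr` (ROIs x ROIs matrix, unit diagonal), `order`
#'   (permutation applied), `roi_table` (reordered).
#' @export
correlation_matrix <- function(traces, roi_table = NULL) {
  traces <- as.matrix(traces)
  if (ncol(traces) < 2) stop("need at least 2 ROIs", call. = FALSE)
  sds <- apply(traces, 2, sd)
  if (any(sds == 0)) {
    stop(sprintf("constant trace: correlation undefined for ROI %d",
                 which(sds == 0)[1]), call. = FALSE)
  }
  ord <- seq_len(ncol(traces))
  if (!is.null(roi_table)) {
    stopifnot(nrow(roi_table) == ncol(traces))
    ord <- order(-roi_table$ml_um)
    roi_table <- roi_table[ord, , drop = FALSE]
    rownames(roi_table) <- NULL
  }
  cc <- cor(traces[, ord, drop = FALSE])
  diag(cc) <- 1
  list(corr = cc, order = ord, roi_table = roi_table)
}

# mean within-children minus mean between-children correlation of a split
split_separability <- function(cc, a, b) {
  wvals <- c(cc[a, a][upper.tri(diag(length(a)))],
             cc[b, b][upper.tri(diag(length(b)))])
  if (length(wvals) == 0) return(-Inf)
  mean(wvals) - mean(cc[a, b])
}

#' Discover zones by sequential binary k-means on a correlation matrix
#'
#' Recursively applies 2-means clustering (each ROI described by its row of
#' the current correlation submatrix, `nstart` seeded restarts) and accepts
#' a split only when both children contain at least `min_zone_size` ROIs
#' and the separability (mean within-child correlation minus mean
#' between-children correlation) reaches `sep_threshold`. The recursion
#' formalises the stopping judgment "no separable components remain";
#' accepted leaves become zones. With a coordinate column available, zones
#' are numbered 1..K from lateral to medial by median ROI coordinate.
#'
#' @param corr square symmetric correlation matrix (ROIs x ROIs).
#' @param roi_table optional data.frame with `ml_um` (rows match `corr`),
#'   used for lateral-to-medial numbering and [zone_geometry()].
#' @param min_zone_size minimum ROIs per zone (default 10).
#' @param sep_threshold separability gap required to accept a split
#'   (default 0.05: comfortably above the sampling noise of a homogeneous
#'   block, yet below the diluted gap of the first split of a many-zone
#'   field, where within-child correlation is averaged over several
#'   blocks).
#' @param nstart random restarts per 2-means run.
#' @param seed RNG seed for the k-means restarts.
#' @return object of class `zone_partition`: list with `assignment`
#'   (integer zone per ROI), `n_zones`, `separability` (per accepted
#'   split), `params`.
#' @export
sequential_kmeans <- function(corr, roi_table = NULL, min_zone_size = 10,
                              sep_threshold = 0.05, nstart = 20, seed = 1L) {
  stopifnot(is.matrix(corr), nrow(corr) == ncol(corr),
            isTRUE(all.equal(corr, t(corr), tolerance = 1e-8)))
  n <- nrow(corr)
  set.seed(seed)
  assignment <- rep(1L, n)
  seps <- numeric(0)

  recurse <- function(members) {
    if (length(members) < max(2, 2 * min_zone_size)) return(list(members))
    feats <- corr[members, members, drop = FALSE]
    km <- tryCatch(
      kmeans(feats, centers = 2, nstart = nstart, iter.max = 50),
      error = function(e) NULL)
    if (is.null(km) || length(unique(km$cluster)) < 2) return(list(members))
    a <- members[km$cluster == 1]
    b <- members[km$cluster == 2]
    if (min(length(a), length(b)) < min_zone_size) return(list(members))
    sep <- split_separability(corr, a, b)
    if (!is.finite(sep) || sep < sep_threshold) return(list(members))
    seps <<- c(seps, sep)
    c(recurse(a), recurse(b))
  }

  leaves <- recurse(seq_len(n))
  for (k in seq_along(leaves)) assignment[leaves[[k]]] <- k

  if (!is.null(roi_table)) {
    stopifnot(nrow(roi_table) == n)
    med <- tapply(roi_table$ml_um, assignment, median)
    relabel <- match(seq_along(med), order(-med))
    assignment <- relabel[assignment]
  }

  structure(list(
    assignment = as.integer(assignment),
    n_zones = length(unique(assignment)),
    separability = seps,
    params = list(min_zone_size = min_zone_size,
                  sep_threshold = sep_threshold, nstart = nstart,
                  seed = seed)
  ), class = "zone_partition")
}

#' @export
print.zone_partition <- function(x, ...) {
  cat(sprintf("<zone_partition> %d zones over %d ROIs (sizes: %s)\n",
              x$n_zones, length(x$assignment),
              paste(table(x$assignment), collapse = ", ")))
  invisible(x)
}

#' Zone widths and lateral-to-medial ordering
#'
#' The width of a zone is the mediolateral span (max minus min centroid
#' coordinate) of its member ROIs; zones are renumbered 1..K from lateral
#' to medial by median coordinate. Single-ROI zones have width 0 and are
#' flagged.
#'
#' @param partition a [sequential_kmeans()] result (or any list with an
#'   integer `assignment`).
#' @param roi_table data.frame with `ml_um`, rows matching the assignment.
#' @return data.frame with zone, n_rois, median_ml_um, width_um,
#'   degenerate (single-ROI flag), ordered zone 1 first.
#' @export
zone_geometry <- function(partition, roi_table) {
  asg <- partition$assignment
  stopifnot(length(asg) == nrow(roi_table),
            all(is.finite(roi_table$ml_um)))
  zs <- sort(unique(asg))
  geo <- do.call(rbind, lapply(zs, function(z) {
    x <- roi_table$ml_um[asg == z]
    data.frame(zone_raw = z, n_rois = length(x), median_ml_um = median(x),
               width_um = max(x) - min(x), degenerate = length(x) == 1)
  }))
  geo <- geo[order(-geo$median_ml_um), , drop = FALSE]
  geo$zone <- seq_len(nrow(geo))
  rownames(geo) <- NULL
  geo[, c("zone", "zone_raw", "n_rois", "median_ml_um", "width_um",
          "degenerate")]
}
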