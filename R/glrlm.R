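#' The 13 run directions (same set as [glcm_offsets()])
#' @return a 13 x 3 integer matrix.
#' @export
glrlm_directions <- function() glcm_offsets()

#' Gray-level run-length matrix of a quantized ROI
#'
#' A run is a maximal sequence of collinear in-mask voxels with equal gray
#' level along a direction; runs are truncated at the mask boundary and
#' accumulated over all directions. Row `i` of `counts` holds level `i-1`
#' (0-based levels), column `j` holds runs of length `j`.
#'
#' @param roi a [quantize()]d ROI.
#' @param directions integer matrix of unit displacement rows.
#' @return a `glrlm` list: `counts` (n_levels x max_run), `directions`,
#'   `n_voxels` (in-mask count), `n_directions`.
#' @export
compute_glrlm <- function(roi, directions = glrlm_directions()) {
  stopifnot(inherits(roi, "quantized_roi"))
  storage.mode(directions) <- "integer"
  max_run <- max(dim(roi$levels))
  counts <- glrlm_accumulate(as.integer(roi$levels),
                             as.integer(dim(roi$levels)),
                             directions, roi$n_levels, max_run)
  last <- max(which(colSums(counts) > 0))
  counts <- counts[, seq_len(last), drop = FALSE]
  structure(list(counts = counts, directions = directions,
                 n_voxels = sum(roi$mask), n_directions = nrow(directions)),
            class = "glrlm")
}

#' The 11 run-length texture statistics
#'
#' Short/long run emphasis (SRE, LRE), gray-level and run-length
#' non-uniformity (GLN, RLN), run percentage (RP), low/high gray-level run
#' emphasis (LGRE, HGRE) and the four joint emphases (SRLGE, SRHGE, LRLGE,
#' LRHGE). Gray levels are indexed from 1 for the low/high weighting; RP is
#' the run count divided by in-mask voxels times the number of directions.
#'
#' @param glrlm a [compute_glrlm()] result.
#' @param n_voxels in-mask voxel count (defaults to the value recorded in
#'   `glrlm`).
#' @param n_directions number of accumulated directions.
#' @return named numeric vector of length 11.
#' @export
glrlm_features <- function(glrlm, n_voxels = glrlm$n_voxels,
                           n_directions = glrlm$n_directions) {
  r <- glrlm$counts
  R <- sum(r)
  if (R <= 0) stop("GLRLM total must be positive")
  gl <- seq_len(nrow(r))          # gray level index from 1
  rl <- seq_len(ncol(r))          # run length
  ri <- rowSums(r); rj <- colSums(r)
  c(sre = sum(rj / rl^2) / R,
    lre = sum(rj * rl^2) / R,
    gln = sum(ri^2) / R,
    rln = sum(rj^2) / R,
    rp = R / (n_voxels * n_directions),
    lgre = sum(ri / gl^2) / R,
    hgre = sum(ri * gl^2) / R,
    srlge = sum(r / outer(gl^2, rl^2)) / R,
    srhge = sum(r * outer(gl^2, 1 / rl^2)) / R,
    lrlge = sum(r * outer(1 / gl^2, rl^2)) / R,
    lrhge = sum(r * outer(gl^2, rl^2)) / R)
}
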