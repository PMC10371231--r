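#' @include AllGenerics.R preprocess.R
NULL

#' Define a two-group voxel-wise study
#'
#' @param groupA,groupB lists of aligned 3D speed-map arrays or
#'   \linkS4class{SpeedMap} objects (>= 2 per group).
#' @param grid an \linkS4class{ImageGrid}; taken from the first SpeedMap if
#'   omitted.
#' @param mask logical analysis mask (defaults to the grid's brain mask,
#'   else the whole domain).
#' @param fwhm smoothing FWHM in mm applied to every map before statistics
#'   (default 0.4).
#' @param alpha significance level (default 0.05).
#' @return a \linkS4class{GroupStudy}.
#' @export
groupStudy <- function(groupA, groupB, grid = NULL, mask = NULL, fwhm = 0.4,
                       alpha = 0.05) {
  toArr <- function(x) if (is(x, "SpeedMap")) x@map else x
  if (is.null(grid)) {
    first <- c(groupA, groupB)[[1]]
    grid <- if (is(first, "SpeedMap")) first@grid
            else imageGrid3D(dim(first), 0.3)
  }
  if (is.null(mask))
    mask <- if ("brain" %in% names(grid@masks)) grid@masks$brain
            else array(TRUE, grid@dims)
  new("GroupStudy", groupA = lapply(groupA, toArr),
      groupB = lapply(groupB, toArr), mask = mask * 1 > 0,
      fwhm = fwhm, alpha = alpha, grid = grid)
}

smoothedGroups <- function(study) {
  sm <- function(m) gaussianSmooth(m, study@fwhm, study@grid@voxelSize)
  list(A = lapply(study@groupA, sm), B = lapply(study@groupB, sm))
}

#' Smoothed group-average speed maps
#'
#' Each subject map is smoothed at the study FWHM, then averaged voxel-wise
#' within each group.
#'
#' @param study a \code{\link{groupStudy}}.
#' @return list with 3D arrays \code{meanA} and \code{meanB}.
#' @export
smoothAndAverage <- function(study) {
  stopifnot(is(study, "GroupStudy"))
  g <- smoothedGroups(study)
  list(meanA = Reduce(`+`, g$A) / length(g$A),
       meanB = Reduce(`+`, g$B) / length(g$B))
}

#' Voxel-wise independent two-sample t map
#'
#' Pooled-variance (Student) t per in-mask voxel, with one-sided p values
#' in both directions (A greater than B, and the reverse), mirroring paired
#' group contrasts. Tested voxels must have nonzero smoothed coverage in
#' every subject; voxels with zero pooled variance are excluded and
#' counted. No multiple-testing adjustment is applied by default; an FDR
#' (Benjamini-Hochberg) option is available as a labeled extension.
#'
#' @param study a \code{\link{groupStudy}}.
#' @param welch use the Welch (unequal-variance) statistic instead of the
#'   pooled Student t.
#' @param fdr also threshold at Benjamini-Hochberg-adjusted p (stored in
#'   the provenance attribute, not in the significance masks).
#' @return a \linkS4class{StatMap}.
#' @export
ttestMap <- function(study, welch = FALSE, fdr = FALSE) {
  stopifnot(is(study, "GroupStudy"))
  g <- smoothedGroups(study)
  nA <- length(g$A); nB <- length(g$B)
  if (nA < 2L || nB < 2L) stop("need >= 2 subjects per group", call. = FALSE)
  dims <- dim(g$A[[1]])
  A <- matrix(unlist(g$A, use.names = FALSE), ncol = nA)
  B <- matrix(unlist(g$B, use.names = FALSE), ncol = nB)
  mask <- as.logical(study@mask)
  covered <- rowSums(A > 0) == nA & rowSums(B > 0) == nB
  included <- mask & covered
  mA <- rowMeans(A); mB <- rowMeans(B)
  vA <- rowSums((A - mA)^2) / (nA - 1)
  vB <- rowSums((B - mB)^2) / (nB - 1)
  if (welch) {
    se2 <- vA / nA + vB / nB
    df <- se2^2 / ((vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1))
    dfOut <- NA_real_
  } else {
    sp2 <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
    se2 <- sp2 * (1 / nA + 1 / nB)
    df <- rep(nA + nB - 2, length(se2))
    dfOut <- nA + nB - 2
  }
  zeroVar <- se2 <= 0
  included <- included & !zeroVar
  tstat <- rep(NA_real_, length(mA))
  tstat[included] <- (mA[included] - mB[included]) / sqrt(se2[included])
  pAB <- array(NA_real_, dims); pBA <- array(NA_real_, dims)
  pAB[included] <- pt(tstat[included], df[included], lower.tail = FALSE)
  pBA[included] <- pt(tstat[included], df[included], lower.tail = TRUE)
  sigAB <- array(FALSE, dims); sigBA <- array(FALSE, dims)
  sigAB[included] <- pAB[included] < study@alpha
  sigBA[included] <- pBA[included] < study@alpha
  out <- new("StatMap", t = array(tstat, dims), pAgtB = pAB, pBgtA = pBA,
             meanA = array(mA, dims), meanB = array(mB, dims),
             df = if (welch) NA_real_ else dfOut,
             sigAgtB = sigAB, sigBgtA = sigBA,
             included = array(included, dims), alpha = study@alpha)
  if (fdr) {
    attr(out, "fdr") <- list(
      qAgtB = stats::p.adjust(pAB[included], method = "BH"),
      qBgtA = stats::p.adjust(pBA[included], method = "BH"),
      note = "Benjamini-Hochberg extension; default analysis is unadjusted")
  }
  out
}
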