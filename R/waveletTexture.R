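## Single-level 2-D orthonormal Haar decomposition and subband texture
## statistics. The orthonormal filter pair (h = [1, 1]/sqrt(2),
## g = [1, -1]/sqrt(2)) is used so that the decomposition conserves energy
## exactly (Parseval), which is the invariant the test suite leans on.
## Subband naming: LH = row-lowpass / column-highpass (horizontal detail),
## HL its transpose (vertical detail), HH diagonal detail, LL approximation.

# One non-overlapping orthonormal Haar pass along matrix columns:
# returns low = (x[2k-1,] + x[2k,])/sqrt(2), high = (x[2k-1,] - x[2k,])/sqrt(2)
haarPassRows <- function(x) {
  m <- nrow(x)
  odd <- seq(1L, m, by = 2L)
  list(low  = (x[odd, , drop = FALSE] + x[odd + 1L, , drop = FALSE]) / sqrt(2),
       high = (x[odd, , drop = FALSE] - x[odd + 1L, , drop = FALSE]) / sqrt(2))
}

#' Single-level 2-D orthonormal Haar decomposition
#'
#' Decomposes a patch into the approximation subband `LL` and the three
#' detail subbands `LH` (horizontal detail: row-lowpass, column-highpass),
#' `HL` (vertical detail) and `HH` (diagonal detail). With even input
#' dimensions the transform is orthonormal, so the total sum of squares is
#' conserved across the four subbands. Odd dimensions are first padded to
#' even size by symmetric (half-sample) replication of the last row/column;
#' energy conservation then holds with respect to the padded patch.
#'
#' @param patch a numeric matrix, at least 2 x 2.
#' @return a list with matrices `LL`, `LH`, `HL`, `HH`, each
#'   `ceiling(M/2) x ceiling(N/2)`.
#' @examples
#' haarDwt2(matrix(0.5, 2, 2))$LL   # [[1]]
#' @export
haarDwt2 <- function(patch) {
  if (!is.matrix(patch) || nrow(patch) < 2L || ncol(patch) < 2L)
    stop("patch must be a matrix of at least 2 x 2 pixels")
  if (nrow(patch) %% 2L == 1L) patch <- rbind(patch, patch[nrow(patch), ])
  if (ncol(patch) %% 2L == 1L) patch <- cbind(patch, patch[, ncol(patch)])

  rows <- haarPassRows(patch)                # vertical filtering
  colsL <- haarPassRows(t(rows$low))         # horizontal filtering of lows
  colsH <- haarPassRows(t(rows$high))
  list(LL = t(colsL$low),   # low rows, low cols
       LH = t(colsL$high),  # row-lowpass, column-highpass: horizontal detail
       HL = t(colsH$low),   # row-highpass, column-lowpass: vertical detail
       HH = t(colsH$high))
}

#' Subband texture statistics
#'
#' The four statistics of one subband, each averaged over all `M x N`
#' coefficients:
#' \itemize{
#'   \item `Mea`: mean coefficient.
#'   \item `Var`: population variance (divisor `MN`).
#'   \item `Ene`: mean squared coefficient.
#'   \item `Ent`: `-(1/MN) * sum(q * log2(q))` with `q = |coefficient|` and
#'     the convention `0 * log2(0) = 0`. The absolute value makes the
#'     entropy measure well-defined on detail subbands, whose coefficients
#'     are signed and frequently zero.
#' }
#'
#' @param subband a numeric matrix (or vector) of coefficients.
#' @return a named numeric vector `c(Mea, Var, Ene, Ent)`.
#' @examples
#' subbandStats(matrix(c(1, 5, 3, 7), 2, 2))  # Mea 4, Var 5, Ene 21
#' @export
subbandStats <- function(subband) {
  if (length(subband) == 0L) stop("empty subband")
  v <- as.numeric(subband)
  mea <- mean(v)
  varp <- mean((v - mea)^2)
  ene <- mean(v^2)
  q <- abs(v)
  ql <- ifelse(q > 0, q * log2(q), 0)
  ent <- -mean(ql)
  c(Mea = mea, Var = varp, Ene = ene, Ent = ent)
}

#' The 64 wavelet texture features of one sample
#'
#' Decomposes each of the four band patches with [haarDwt2()] and computes
#' the four [subbandStats()] per subband, giving 4 bands x 4 subbands x 4
#' statistics = 64 features named `"{Subband}_{Band}_{Stat}"`, e.g.
#' `LL_Red_Mea` or `HH_Red-edge_Ent`.
#'
#' @param patches named list of four equal-sized band matrices (keys
#'   `green`, `red`, `red_edge`, `nir`).
#' @return a named numeric vector of length 64.
#' @export
computeWtFeatures <- function(patches) {
  missing <- setdiff(bandNames(), names(patches))
  if (length(missing))
    stop("missing band(s): ", paste(missing, collapse = ", "))
  dims <- lapply(patches[bandNames()], dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("band patches must share dimensions")
  labels <- bandLabels()
  out <- numeric(0)
  for (b in bandNames()) {
    sb <- haarDwt2(patches[[b]])
    for (s in subbandNames()) {
      st <- subbandStats(sb[[s]])
      names(st) <- paste(s, labels[[b]], statNames(), sep = "_")
      out <- c(out, st)
    }
  }
  out
}

#' Canonical names of the 64 wavelet texture features
#'
#' @return character vector of length 64 in the order produced by
#'   [computeWtFeatures()].
#' @export
wtFeatureNames <- function() {
  labels <- unname(bandLabels())
  as.vector(vapply(labels, function(b)
    vapply(subbandNames(), function(s)
      paste(s, b, statNames(), sep = "_"), character(4)), character(16)))
}
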