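#' Alignment parameters
#'
#' Scoring scheme for global pairwise protein alignment: substitution
#' matrix (BLOSUM62 by default, taken from Biostrings' built-in data), an
#' affine gap model where a gap of length L costs
#' `gapOpen + L * gapExtend`, and an end-gap policy. With
#' `endGaps = FALSE` (the default, matching the common reference tool's
#' default) leading and trailing gaps cost nothing but still appear in the
#' alignment and count toward its length.
#'
#' @param matrix substitution matrix name ("BLOSUM62", "BLOSUM50",
#'   "PAM250", ...) or a square numeric matrix covering the residues used.
#' @param gapOpen gap opening penalty (>= 0, default 10).
#' @param gapExtend gap extension penalty (>= 0, default 0.5).
#' @param endGaps logical; penalize end gaps (default FALSE).
#' @return list of validated parameters with the resolved matrix.
#' @export
alignmentParams <- function(matrix = "BLOSUM62", gapOpen = 10,
                            gapExtend = 0.5, endGaps = FALSE) {
  if (gapOpen < 0 || gapExtend < 0) stop("gap penalties must be >= 0")
  if (is.character(matrix)) {
    e <- new.env()
    utils::data(list = matrix, package = "Biostrings", envir = e)
    matrix <- get(matrix, envir = e)
  }
  if (!is.matrix(matrix) || !identical(rownames(matrix), colnames(matrix)))
    stop("substitution matrix must be square with matching dimnames")
  list(matrix = matrix, gapOpen = gapOpen, gapExtend = gapExtend,
       endGaps = isTRUE(endGaps))
}

#' AlignmentReport: global pairwise alignment result
#'
#' @slot alignedA,alignedB aligned sequences with `-` gap characters;
#'   removing the gaps recovers the inputs.
#' @slot score optimal alignment score under the scoring scheme.
#' @slot identity percent identical columns over the full alignment length
#'   (gap columns included in the denominator).
#' @slot similarity percent columns with a positive substitution score.
#' @slot gaps number of gap columns.
#' @slot params the [alignmentParams()] used (matrix stored by name when
#'   available).
#' @export
setClass("AlignmentReport",
  representation(alignedA = "character", alignedB = "character",
                 score = "numeric", identity = "numeric",
                 similarity = "numeric", gaps = "integer",
                 params = "list"))

setMethod("show", "AlignmentReport", function(object) {
  n <- nchar(object@alignedA)
  cat(sprintf("AlignmentReport: length %d, score %.1f\n", n, object@score))
  cat(sprintf("  identity  %.1f%%   similarity %.1f%%   gaps %d\n",
              object@identity, object@similarity, object@gaps))
  width <- 60L
  for (i in seq(1L, n, by = width)) {
    j <- min(i + width - 1L, n)
    a <- substr(object@alignedA, i, j)
    b <- substr(object@alignedB, i, j)
    mid <- paste(ifelse(strsplit(a, "")[[1]] == strsplit(b, "")[[1]] &
                          strsplit(a, "")[[1]] != "-", "|", " "),
                 collapse = "")
    cat(a, "\n", mid, "\n", b, "\n\n", sep = "")
  }
  invisible(object)
})

#' Global pairwise protein alignment with affine gaps
#'
#' Needleman-Wunsch/Gotoh dynamic programming over the full lengths of two
#' protein sequences, with an affine gap model and an optional free-end-gap
#' policy. Traceback ties are broken deterministically preferring
#' diagonal over a gap in the second sequence ("up") over a gap in the
#' first ("left"). The full alignment is returned, including unpenalized
#' end gaps, so percent identity uses the reference convention
#' (identical columns / total alignment length).
#'
#' @param a,b protein sequences (character scalars, named character, or
#'   [Biostrings::AAString]/single-record FASTA file path); X is permitted
#'   when covered by the substitution matrix.
#' @param params scoring scheme from [alignmentParams()].
#' @return An [AlignmentReport-class].
#' @examples
#' globalAlign("HEAGAWGHEE", "PAWHEAE")
#' @export
globalAlign <- function(a, b, params = alignmentParams()) {
  a <- .loadSingleSequence(a)
  b <- .loadSingleSequence(b)
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  sub <- params$matrix
  ra <- strsplit(a, "")[[1L]]
  rb <- strsplit(b, "")[[1L]]
  bad <- setdiff(unique(c(ra, rb)), rownames(sub))
  if (length(bad))
    stop("residue(s) not covered by the substitution matrix: ",
         paste(bad, collapse = ", "))
  go <- params$gapOpen; ge <- params$gapExtend
  n <- length(ra); m <- length(rb)
  NEG <- -1e18
  ## three-state Gotoh: M (diagonal), X (gap in b: consume a, "up"),
  ## Y (gap in a: consume b, "left"). A gap of length L costs go + L*ge.
  M <- matrix(NEG, n + 1L, m + 1L)
  X <- matrix(NEG, n + 1L, m + 1L)
  Y <- matrix(NEG, n + 1L, m + 1L)
  ## traceback: state matrices store predecessor state 1=M, 2=X, 3=Y
  tbM <- matrix(0L, n + 1L, m + 1L)
  tbX <- matrix(0L, n + 1L, m + 1L)
  tbY <- matrix(0L, n + 1L, m + 1L)
  M[1L, 1L] <- 0
  endo <- if (params$endGaps) go else 0
  ende <- if (params$endGaps) ge else 0
  if (n >= 1L) {
    X[2:(n + 1L), 1L] <- -(endo + ende * (1:n))
    tbX[2L, 1L] <- 1L
    if (n >= 2L) tbX[3:(n + 1L), 1L] <- 2L
  }
  if (m >= 1L) {
    Y[1L, 2:(m + 1L)] <- -(endo + ende * (1:m))
    tbY[1L, 2L] <- 1L
    if (m >= 2L) tbY[1L, 3:(m + 1L)] <- 3L
  }
  smat <- sub[ra, rb, drop = FALSE]
  for (i in 2L:(n + 1L)) {
    for (j in 2L:(m + 1L)) {
      s <- smat[i - 1L, j - 1L]
      ## M: diagonal from best of three states (tie: M > X > Y)
      cand <- c(M[i - 1L, j - 1L], X[i - 1L, j - 1L], Y[i - 1L, j - 1L])
      k <- which.max(cand)
      M[i, j] <- cand[k] + s
      tbM[i, j] <- k
      ## X: gap in b (consume a[i-1]); trailing-gap discount handled at end
      openX <- c(M[i - 1L, j] - go - ge, X[i - 1L, j] - ge,
                 Y[i - 1L, j] - go - ge)
      k <- which.max(openX)
      X[i, j] <- openX[k]
      tbX[i, j] <- k
      openY <- c(M[i, j - 1L] - go - ge, X[i, j - 1L] - go - ge,
                 Y[i, j - 1L] - ge)
      k <- which.max(openY)
      Y[i, j] <- openY[k]
      tbY[i, j] <- k
    }
  }
  if (!params$endGaps) {
    ## free end gaps: rebuild X/Y along the last column/row so trailing
    ## gaps cost nothing -- equivalent to taking the best score over the
    ## last row/column and padding with gaps. Done via a final sweep.
    best <- M[n + 1L, m + 1L]; endState <- 1L; endI <- n + 1L; endJ <- m + 1L
    for (i in 1L:(n + 1L)) {
      cand <- c(M[i, m + 1L], X[i, m + 1L], Y[i, m + 1L])
      k <- which.max(cand)
      if (cand[k] > best) { best <- cand[k]; endState <- k; endI <- i; endJ <- m + 1L }
    }
    for (j in 1L:(m + 1L)) {
      cand <- c(M[n + 1L, j], X[n + 1L, j], Y[n + 1L, j])
      k <- which.max(cand)
      if (cand[k] > best) { best <- cand[k]; endState <- k; endI <- n + 1L; endJ <- j }
    }
  } else {
    cand <- c(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
    endState <- which.max(cand)
    best <- cand[endState]
    endI <- n + 1L; endJ <- m + 1L
  }
  ## traceback from (endI, endJ, endState) to (1, 1)
  outA <- character(0L); outB <- character(0L)
  ## trailing free gaps
  if (endI <= n) { outA <- ra[n:endI]; outB <- rep("-", n - endI + 1L) }
  if (endJ <= m) { outA <- rep("-", m - endJ + 1L); outB <- rb[m:endJ] }
  i <- endI; j <- endJ; st <- endState
  while (i > 1L || j > 1L) {
    if (st == 1L) {
      outA <- c(outA, ra[i - 1L]); outB <- c(outB, rb[j - 1L])
      st <- tbM[i, j]; i <- i - 1L; j <- j - 1L
    } else if (st == 2L) {
      outA <- c(outA, ra[i - 1L]); outB <- c(outB, "-")
      st <- tbX[i, j]; i <- i - 1L
    } else {
      outA <- c(outA, "-"); outB <- c(outB, rb[j - 1L])
      st <- tbY[i, j]; j <- j - 1L
    }
  }
  alnA <- paste(rev(outA), collapse = "")
  alnB <- paste(rev(outB), collapse = "")
  .alignmentReport(alnA, alnB, best, params)
}

.alignmentReport <- function(alnA, alnB, score, params) {
  ca <- strsplit(alnA, "")[[1L]]
  cb <- strsplit(alnB, "")[[1L]]
  len <- length(ca)
  ident <- sum(ca == cb & ca != "-")
  gapcols <- sum(ca == "-" | cb == "-")
  both <- ca != "-" & cb != "-"
  simil <- if (any(both))
    sum(params$matrix[cbind(ca[both], cb[both])] > 0) else 0L
  new("AlignmentReport", alignedA = alnA, alignedB = alnB,
      score = score,
      identity = 100 * ident / len,
      similarity = 100 * simil / len,
      gaps = as.integer(gapcols),
      params = params[c("gapOpen", "gapExtend", "endGaps")])
}

.loadSingleSequence <- function(x) {
  if (is(x, "AAString") || is(x, "AAStringSet")) x <- as.character(x)
  if (is.character(x) && length(x) == 1L && file.exists(x) &&
      grepl("\\.(fa|fasta|faa)$", x, ignore.case = TRUE)) {
    x <- as.character(Biostrings::readAAStringSet(x))[1L]
  }
  if (!is.character(x) || length(x) != 1L)
    stop("expected a single protein sequence")
  toupper(unname(x))
}

#' Percent identity of an alignment
#'
#' Identical columns divided by the total alignment length (gap columns
#' included in the denominator -- the reference tool's convention; note
#' that dividing by the shorter sequence length instead would change the
#' number), times 100.
#'
#' @param result an [AlignmentReport-class].
#' @param digits rounding for display (default 1 decimal).
#' @return Numeric percentage in \[0, 100\].
#' @examples
#' percentIdentity(globalAlign("ACD", "ACD"))
#' @export
percentIdentity <- function(result, digits = 1) {
  stopifnot(is(result, "AlignmentReport"))
  round(result@identity, digits)
}

#' Align two receptor orthologs from FASTA files
#'
#' Convenience wrapper reproducing the cross-kingdom receptor comparison:
#' global alignment of two cargo-receptor protein sequences (e.g. human
#' Surf4 vs yeast Erv29p) under default parameters, reporting percent
#' identity. Sequences are supplied by the user as FASTA files (e.g.
#' downloaded from NCBI accessions NP_149351.1 and NP_011800.3); no remote
#' fetching is performed.
#'
#' @param fastaA,fastaB FASTA file paths (first record used) or sequences.
#' @param params scoring scheme from [alignmentParams()].
#' @return An [AlignmentReport-class].
#' @export
alignReceptorOrthologs <- function(fastaA, fastaB,
                                   params = alignmentParams()) {
  globalAlign(fastaA, fastaB, params)
}
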