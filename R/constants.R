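#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

## 20 standard amino acids, alphabetical single-letter order used throughout
.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "W", "V", "Y")

.NONSTANDARD <- c("B", "J", "O", "U", "X", "Z", "*")

#' Hydrophobic residue set of the ER-ESCAPE consensus
#'
#' The hydrophobic set \eqn{\Phi} used by the
#' hydrophobic--proline--hydrophobic (\eqn{\Phi}-P-\eqn{\Phi}) consensus.
#' Membership is restricted to residues experimentally shown to support
#' receptor-enhanced trafficking when flanking the position-2 proline
#' (A, I, L, M, F, V, Y). Tryptophan is untested and deliberately excluded.
#'
#' @return Character vector of single-letter residue codes.
#' @examples
#' phiSet()
#' @export
phiSet <- function() c("A", "I", "L", "M", "F", "V", "Y")

## Acidic residues triggering the hard nonbinding rule when two or more occur
.ACIDIC <- c("D", "E")

#' The 60-tripeptide growth-hormone reporter panel
#'
#' The panel of sixty amino-terminal tripeptides used to map motif
#' composition against steady-state levels of a growth-hormone reporter
#' cargo. It spans the hydrophobic-proline-hydrophobic consensus, arginine
#' and lysine substitutions, serine/threonine variants, single and double
#' acidic residues, and glutamine-containing nonbinders.
#'
#' @return Character vector of 60 tripeptides (includes the reference
#'   motif "IPV").
#' @examples
#' length(ghPanel())
#' @export
ghPanel <- function() {
  c("APV", "DYP", "EEE", "EEI", "EET", "EGT", "EPA", "EPT", "EPV", "EST",
    "FGT", "FLT", "FPE", "FPR", "FPT", "FPV", "FQV", "FSM", "FST", "FTV",
    "FVN", "GPV", "HSV", "IEV", "IGV", "ILV", "INV", "IPA", "IPD", "IPE",
    "IPP", "IPS", "IPV", "IRV", "ISH", "ISP", "ISQ", "ISR", "ISV", "ITV",
    "KAV", "KGV", "KSV", "KVH", "NPV", "QPV", "QQV", "QSV", "RGV", "RLV",
    "RPK", "RPV", "RRR", "RSV", "SLT", "SPT", "SPV", "SRT", "SST", "YPY")
}

## Split tripeptides into a 3-column matrix of residues, validating the
## alphabet. Errors name the offending character and position.
.splitTripeptides <- function(x) {
  if (!is.character(x) || length(x) == 0L)
    stop("tripeptides must be a non-empty character vector")
  x <- toupper(x)
  bad_len <- nchar(x) != 3L
  if (any(bad_len))
    stop("tripeptide must have exactly 3 residues: ",
         paste(sQuote(x[bad_len]), collapse = ", "))
  m <- matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
              ncol = 3L, byrow = TRUE)
  ok <- m %in% .AA20
  if (!all(ok)) {
    idx <- which(!matrix(ok, ncol = 3L), arr.ind = TRUE)[1L, ]
    stop(sprintf("invalid residue '%s' at position %d of tripeptide '%s'",
                 m[idx[1L], idx[2L]], idx[2L], x[idx[1L]]))
  }
  rownames(m) <- x
  m
}
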