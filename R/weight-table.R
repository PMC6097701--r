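#' PositionWeightTable: per-position amino-acid contributions to the
#' ER-ESCAPE motif
#'
#' Holds, for each of the three positions of the amino-terminal tripeptide
#' and each of the 20 standard amino acids, an ordinal contribution class
#' (\code{"favorable"}, \code{"neutral"}, \code{"unfavorable"}), a numeric
#' weight whose sign agrees with the class, and a provenance tag recording
#' whether the entry is directly supported by trafficking experiments
#' (\code{"paper-stated"}), inferred from the reporter panel
#' (\code{"paper-implied"}), or an untested default
#' (\code{"default-neutral"}).
#'
#' Validity enforces: exactly 3 x 20 entries; sign/class agreement
#' (favorable > 0, neutral = 0, unfavorable < 0); and the core biology of
#' the motif model: D and E unfavorable at every position, Q unfavorable at
#' positions 1 and 2, P favorable at position 2 but unfavorable at 3, R
#' favorable everywhere, and the hydrophobic set [phiSet()] favorable at
#' positions 1 and 3.
#'
#' @slot weights numeric 3 x 20 matrix (rows = positions, columns =
#'   residues in alphabetical single-letter order).
#' @slot classes character 3 x 20 matrix of contribution classes.
#' @slot provenance character 3 x 20 matrix of provenance tags.
#'
#' @seealso [defaultWeightTable()], [weightAt()], [readWeightTable()]
#' @export
setClass("PositionWeightTable",
  representation(weights = "matrix", classes = "matrix",
                 provenance = "matrix"))

.PWT_CLASSES <- c("favorable", "neutral", "unfavorable")
.PWT_PROVENANCE <- c("paper-stated", "paper-implied", "default-neutral")

setValidity("PositionWeightTable", function(object) {
  w <- object@weights; k <- object@classes; p <- object@provenance
  msg <- character()
  dims_ok <- identical(dim(w), c(3L, 20L))
  if (!dims_ok ||
      !identical(colnames(w), .AA20) ||
      !identical(dim(k), dim(w)) || !identical(dim(p), dim(w)))
    return("weights, classes and provenance must be 3 x 20 matrices with the 20 standard residues as columns")
  if (!all(k %in% .PWT_CLASSES))
    msg <- c(msg, "classes must be favorable/neutral/unfavorable")
  if (!all(p %in% .PWT_PROVENANCE))
    msg <- c(msg, "provenance must be paper-stated/paper-implied/default-neutral")
  sign_ok <- (k == "favorable" & w > 0) |
             (k == "neutral" & w == 0) |
             (k == "unfavorable" & w < 0)
  if (!all(sign_ok))
    msg <- c(msg, "weight sign must agree with class (favorable > 0, neutral = 0, unfavorable < 0)")
  ## motif-model hard constraints
  if (!all(k[, c("D", "E")] == "unfavorable"))
    msg <- c(msg, "D and E must be unfavorable at all positions")
  if (!all(k[1:2, "Q"] == "unfavorable"))
    msg <- c(msg, "Q must be unfavorable at positions 1 and 2")
  if (k[2L, "P"] != "favorable" || k[3L, "P"] != "unfavorable")
    msg <- c(msg, "P must be favorable at position 2 and unfavorable at position 3")
  if (!all(k[, "R"] == "favorable"))
    msg <- c(msg, "R must be favorable at all positions")
  if (!all(k[c(1L, 3L), phiSet()] == "favorable"))
    msg <- c(msg, "hydrophobic-set residues must be favorable at positions 1 and 3")
  if (length(msg)) msg else TRUE
})

.classFromWeight <- function(w) {
  ifelse(w > 0, "favorable", ifelse(w < 0, "unfavorable", "neutral"))
}

.makePWT <- function(weights, provenance) {
  dimnames(weights) <- list(as.character(1:3), .AA20)
  classes <- .classFromWeight(weights)
  dimnames(provenance) <- dimnames(weights)
  new("PositionWeightTable", weights = weights, classes = classes,
      provenance = provenance)
}

#' Default per-position contribution table
#'
#' Encodes the ordinal contribution of each amino acid at each tripeptide
#' position with the numeric scale favorable = +1, neutral = 0,
#' unfavorable = -1 (lysine is weakly favorable, +0.5, strictly below
#' arginine). The assignments:
#' \itemize{
#'   \item hydrophobic set A, I, L, M, F, V, Y: favorable at positions 1
#'     and 3, neutral at position 2;
#'   \item P: favorable at position 2, unfavorable at 3, neutral at 1;
#'   \item S, T: favorable at position 1, neutral at 2 and 3;
#'   \item R: favorable everywhere; K: weakly favorable everywhere (+0.5);
#'   \item N: neutral everywhere; Q: unfavorable at positions 1 and 2,
#'     neutral at 3; D, E: unfavorable everywhere;
#'   \item untested residues C, G, H, W: neutral, tagged
#'     \code{"default-neutral"}.
#' }
#'
#' @return A [PositionWeightTable-class] object.
#' @examples
#' tab <- defaultWeightTable()
#' weightAt(tab, 2, "P")
#' contributionClass(tab, 3, "P")
#' @export
defaultWeightTable <- function() {
  w <- matrix(0, nrow = 3L, ncol = 20L, dimnames = list(1:3, .AA20))
  pv <- matrix("default-neutral", 3L, 20L)
  dimnames(pv) <- dimnames(w)
  phi <- phiSet()
  w[c(1L, 3L), phi] <- 1;      pv[c(1L, 3L), phi] <- "paper-stated"
  pv[2L, phi] <- "paper-stated"           # "not good in position 2"
  w[2L, "P"] <- 1;  w[3L, "P"] <- -1
  pv[2:3, "P"] <- "paper-stated"; pv[1L, "P"] <- "paper-implied"
  w[1L, c("S", "T")] <- 1;      pv[1L, c("S", "T")] <- "paper-stated"
  pv[2L, c("S", "T")] <- "paper-implied"  # Phi-S-Phi is modest, not strong
  pv[3L, c("S", "T")] <- "paper-implied"
  w[, "R"] <- 1;                pv[, "R"] <- "paper-stated"
  w[, "K"] <- 0.5;              pv[, "K"] <- "paper-implied"
  pv[, "N"] <- "paper-implied"            # NPV low, INV modest
  w[1:2, "Q"] <- -1;            pv[1:2, "Q"] <- "paper-stated"
  pv[3L, "Q"] <- "paper-implied"
  w[, c("D", "E")] <- -1;       pv[, c("D", "E")] <- "paper-stated"
  .makePWT(w, pv)
}

#' Build a PositionWeightTable from weights
#'
#' Constructs a table from a 3 x 20 weight matrix (classes are derived from
#' the weight signs). Provenance defaults to \code{"paper-implied"} for all
#' entries unless supplied.
#'
#' @param weights numeric 3 x 20 matrix with residues as columns (any
#'   column order covering the 20 standard residues).
#' @param provenance optional character 3 x 20 matrix of provenance tags.
#' @return A [PositionWeightTable-class] object.
#' @export
positionWeightTable <- function(weights, provenance = NULL) {
  if (!is.matrix(weights) || !identical(dim(weights), c(3L, 20L)))
    stop("weights must be a 3 x 20 matrix")
  if (is.null(colnames(weights)) || !setequal(colnames(weights), .AA20))
    stop("weights columns must name the 20 standard residues")
  weights <- weights[, .AA20, drop = FALSE]
  if (is.null(provenance)) {
    provenance <- matrix("paper-implied", 3L, 20L)
  } else {
    provenance <- provenance[, .AA20, drop = FALSE]
  }
  .makePWT(weights, provenance)
}

#' @describeIn weightAt contribution class lookup
#' @export
contributionClass <- function(table, position, residue) {
  .checkLookup(table, position, residue)
  table@classes[cbind(position, match(toupper(residue), .AA20))]
}

.checkLookup <- function(table, position, residue) {
  stopifnot(is(table, "PositionWeightTable"))
  if (!all(position %in% 1:3))
    stop("position must be 1, 2 or 3")
  bad <- !(toupper(residue) %in% .AA20)
  if (any(bad))
    stop("unknown residue: ", paste(sQuote(residue[bad]), collapse = ", "))
  invisible(TRUE)
}

#' Look up entries of a PositionWeightTable
#'
#' @param table a [PositionWeightTable-class].
#' @param position integer position(s) in 1..3.
#' @param residue single-letter residue code(s).
#' @return `weightAt` returns numeric weights; `contributionClass` returns
#'   the ordinal class; `provenanceAt` the provenance tag. All are
#'   vectorized over `position`/`residue` in parallel.
#' @examples
#' weightAt(defaultWeightTable(), 1, "E")
#' @export
weightAt <- function(table, position, residue) {
  .checkLookup(table, position, residue)
  table@weights[cbind(position, match(toupper(residue), .AA20))]
}

#' @describeIn weightAt provenance tag lookup
#' @export
provenanceAt <- function(table, position, residue) {
  .checkLookup(table, position, residue)
  table@provenance[cbind(position, match(toupper(residue), .AA20))]
}

#' @describeIn weightAt the full 3 x 20 weight matrix
#' @export
weightMatrix <- function(table) {
  stopifnot(is(table, "PositionWeightTable"))
  table@weights
}

setMethod("show", "PositionWeightTable", function(object) {
  cat("PositionWeightTable (3 positions x 20 residues)\n")
  cat("  favorable:  ", sum(object@classes == "favorable"), "entries\n")
  cat("  neutral:    ", sum(object@classes == "neutral"), "entries\n")
  cat("  unfavorable:", sum(object@classes == "unfavorable"), "entries\n")
  print(object@weights)
  invisible(object)
})

#' Read/write a PositionWeightTable as TSV
#'
#' The on-disk format is a 60-row tab-delimited table with columns
#' `position`, `residue`, `class`, `weight`, `provenance`, so users can
#' supply alternative contribution tables.
#'
#' @param file path to a TSV file.
#' @return `readWeightTable` returns a [PositionWeightTable-class];
#'   `writeWeightTable` invisibly returns `file`.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeWeightTable(defaultWeightTable(), f)
#' identical(weightMatrix(readWeightTable(f)),
#'           weightMatrix(defaultWeightTable()))
#' @export
readWeightTable <- function(file) {
  d <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("position", "residue", "weight", "provenance")
  if (!all(need %in% names(d)))
    stop("weight table file must have columns position, residue, weight, provenance")
  if (nrow(d) != 60L)
    stop("weight table must have exactly 60 rows (3 positions x 20 residues)")
  w <- matrix(NA_real_, 3L, 20L, dimnames = list(1:3, .AA20))
  pv <- matrix(NA_character_, 3L, 20L, dimnames = list(1:3, .AA20))
  w[cbind(d$position, match(d$residue, .AA20))] <- d$weight
  pv[cbind(d$position, match(d$residue, .AA20))] <- d$provenance
  if (anyNA(w))
    stop("weight table must cover every residue at every position")
  .makePWT(w, pv)
}

#' @rdname readWeightTable
#' @param table a [PositionWeightTable-class] to serialize.
#' @export
writeWeightTable <- function(table, file) {
  stopifnot(is(table, "PositionWeightTable"))
  d <- data.frame(
    position = rep(1:3, each = 20L),
    residue = rep(.AA20, times = 3L),
    class = as.vector(t(table@classes)),
    weight = as.vector(t(table@weights)),
    provenance = as.vector(t(table@provenance)),
    stringsAsFactors = FALSE)
  utils::write.table(d, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
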