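#' Additive ER-ESCAPE motif score
#'
#' Scores one or more amino-terminal tripeptides by summing the three
#' per-position residue weights of a [PositionWeightTable-class]. The score
#' is the pure additive model; documented exceptions are applied only at
#' classification time (see [classifyTripeptides()]).
#'
#' @param tripeptides character vector of 3-letter tripeptides (standard
#'   amino-acid alphabet; ambiguity codes such as B, X, Z are errors).
#' @param table a [PositionWeightTable-class]; defaults to
#'   [defaultWeightTable()].
#' @return Named numeric vector of scores.
#' @examples
#' scoreTripeptide(c("IPV", "ISV", "EET"))
#' @export
scoreTripeptide <- function(tripeptides, table = defaultWeightTable()) {
  stopifnot(is(table, "PositionWeightTable"))
  m <- .splitTripeptides(tripeptides)
  cols <- match(m, .AA20)
  w <- table@weights[cbind(rep(1:3, each = nrow(m)), cols)]
  out <- rowSums(matrix(w, ncol = 3L))
  names(out) <- rownames(m)
  out
}

#' Is a tripeptide a hydrophobic-proline-hydrophobic consensus motif?
#'
#' Tests the \eqn{\Phi}-P-\eqn{\Phi} consensus: position 1 and position 3
#' in the hydrophobic set, proline at position 2.
#'
#' @param tripeptides character vector of tripeptides.
#' @param phi hydrophobic residue set (default [phiSet()]).
#' @return Logical vector.
#' @examples
#' isPhiPPhi(c("APV", "APT", "IPV"))
#' @export
isPhiPPhi <- function(tripeptides, phi = phiSet()) {
  m <- .splitTripeptides(tripeptides)
  out <- m[, 1L] %in% phi & m[, 2L] == "P" & m[, 3L] %in% phi
  names(out) <- rownames(m)
  out
}

#' Default classification thresholds
#'
#' Score cutoffs partitioning tripeptides into predicted receptor-affinity
#' classes: \code{strong} iff score >= \code{strong}; \code{nonbinding} iff
#' score <= \code{nonbinding}; \code{modest} otherwise. Boundary scores take
#' the higher class (inclusive comparisons). The defaults (+2.5 / -1 on the
#' +1/0/-1 weight scale) reproduce the experimental partition of the
#' reporter panel: all-favorable motifs (and their lysine variants at +2.5)
#' are strong, while two-favorable motifs such as FSM, ISV, ITV or FPT
#' (+2) are modest.
#'
#' @return Named numeric vector with elements `strong` and `nonbinding`.
#' @export
defaultThresholds <- function() c(strong = 2.5, nonbinding = -1)

#' Documented exception rules
#'
#' Tripeptides whose measured behaviour departs from the additive model and
#' are therefore overridden after scoring. Each rule carries a citation
#' note describing the supporting observation:
#' \itemize{
#'   \item FPV: a consensus \eqn{\Phi}-P-\eqn{\Phi} motif, yet the reporter
#'     accumulated to modest (not low) steady-state levels -- possibly two
#'     of the largest hydrophobics flanking proline destabilize the binding
#'     pocket; forced to \code{modest}.
#'   \item KVH: lacks proline/serine at position 2, yet the reporter showed
#'     a positive, if modest, trafficking benefit (the yeast protease A
#'     starting tripeptide); forced to \code{modest}.
#' }
#'
#' @return data.frame with columns `rule_id`, `pattern`, `forced_class`,
#'   `note`.
#' @export
defaultExceptionRules <- function() {
  data.frame(
    rule_id = c("FPV-modest", "KVH-modest"),
    pattern = c("FPV", "KVH"),
    forced_class = c("modest", "modest"),
    note = c(
      "consensus motif with higher-than-predicted steady-state level; forced modest",
      "no position-2 proline/serine yet a positive, modest trafficking benefit; forced modest"),
    stringsAsFactors = FALSE)
}

#' Read/write exception rules as TSV
#'
#' Exception lists are plain tab-delimited tables with columns `rule_id`,
#' `pattern`, `forced_class`, `note`, so users can supply alternatives to
#' [defaultExceptionRules()]. Every rule must carry a non-empty note
#' documenting its supporting observation.
#'
#' @param file path to a TSV file.
#' @return `readExceptionRules` returns a validated data.frame;
#'   `writeExceptionRules` invisibly returns `file`.
#' @export
readExceptionRules <- function(file) {
  d <- utils::read.delim(file, stringsAsFactors = FALSE)
  .validateExceptionRules(d)
}

#' @rdname readExceptionRules
#' @param rules an exception-rule data.frame.
#' @export
writeExceptionRules <- function(rules, file) {
  .validateExceptionRules(rules)
  utils::write.table(rules, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

.validateExceptionRules <- function(d) {
  need <- c("rule_id", "pattern", "forced_class", "note")
  if (!all(need %in% names(d)))
    stop("exception rules need columns: ", paste(need, collapse = ", "))
  if (nrow(d)) {
    .splitTripeptides(d$pattern)
    if (!all(d$forced_class %in% c("strong", "modest", "nonbinding")))
      stop("forced_class must be strong, modest or nonbinding")
    if (any(is.na(d$note) | !nzchar(d$note)))
      stop("every exception rule must carry a citation note")
  }
  d
}

#' Classify tripeptides into predicted receptor-affinity classes
#'
#' Computes the additive score, applies the threshold partition
#' (strong / modest / nonbinding), then two kinds of overrides:
#' \enumerate{
#'   \item the hard rule that two or more acidic residues (D/E) force
#'     \code{nonbinding} regardless of score;
#'   \item the documented per-tripeptide exception list
#'     ([defaultExceptionRules()]).
#' }
#' The result is a deterministic function of (tripeptide, table,
#' thresholds, exceptions).
#'
#' @inheritParams scoreTripeptide
#' @param thresholds named numeric vector as from [defaultThresholds()].
#' @param exceptions exception rule data.frame as from
#'   [defaultExceptionRules()]; use `NULL` (or a 0-row frame) for pure
#'   additive classification.
#' @return A [S4Vectors::DataFrame] with columns `tripeptide`, `score`,
#'   `klass` (factor strong/modest/nonbinding), `exception_applied`
#'   (logical) and `rule_id`.
#' @examples
#' classifyTripeptides(c("IPV", "FSM", "EET", "FPV"))
#' @export
classifyTripeptides <- function(tripeptides,
                                table = defaultWeightTable(),
                                thresholds = defaultThresholds(),
                                exceptions = defaultExceptionRules()) {
  if (!all(c("strong", "nonbinding") %in% names(thresholds)))
    stop("thresholds must name 'strong' and 'nonbinding'")
  if (thresholds[["nonbinding"]] >= thresholds[["strong"]])
    stop("nonbinding threshold must lie below the strong threshold")
  m <- .splitTripeptides(tripeptides)
  sc <- scoreTripeptide(rownames(m), table)
  klass <- ifelse(sc >= thresholds[["strong"]], "strong",
           ifelse(sc <= thresholds[["nonbinding"]], "nonbinding", "modest"))
  ## hard rule: >= 2 acidic residues is always nonbinding
  nAcid <- rowSums(matrix(m %in% .ACIDIC, ncol = 3L))
  klass[nAcid >= 2L] <- "nonbinding"
  exception_applied <- rep(FALSE, length(sc))
  rule_id <- rep(NA_character_, length(sc))
  if (!is.null(exceptions) && nrow(exceptions)) {
    hit <- match(rownames(m), exceptions$pattern)
    sel <- !is.na(hit)
    klass[sel] <- exceptions$forced_class[hit[sel]]
    exception_applied[sel] <- TRUE
    rule_id[sel] <- exceptions$rule_id[hit[sel]]
  }
  DataFrame(
    tripeptide = rownames(m),
    score = unname(sc),
    klass = factor(klass, levels = c("strong", "modest", "nonbinding")),
    exception_applied = exception_applied,
    rule_id = rule_id)
}
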