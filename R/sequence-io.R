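#' Read mature-protein records from FASTA plus cleavage annotations
#'
#' Pairs protein sequences with 1-based mature-start positions (the first
#' residue left after signal-peptide cleavage, as predicted upstream by
#' e.g. SignalP or Phobius, or known experimentally) and extracts the
#' amino-terminal tripeptide of each mature protein.
#'
#' FASTA ids are taken as the description line up to the first whitespace;
#' wrapped and unwrapped sequences are both accepted; `*` stop characters
#' are stripped with a warning. Coordinates are 1-based inclusive: a record
#' with `mature_start = 17` reads its tripeptide from residues 17..19.
#' FASTA records without an annotation are skipped with a warning.
#' Out-of-range positions and tripeptides containing non-standard residues
#' are collected per record in the `problems` attribute rather than
#' aborting the whole batch; duplicated annotation ids are an error.
#'
#' @param fasta path to a protein FASTA file, or a named
#'   [Biostrings::AAStringSet] / named character vector of sequences.
#' @param annotations path to a tab-delimited file with columns `id` and
#'   `mature_start`, or a data.frame with those columns.
#' @return A [S4Vectors::DataFrame] with columns `id`, `sequence`,
#'   `mature_start`, `tripeptide`; records that failed extraction are
#'   excluded and reported in `attr(, "problems")` (a data.frame with
#'   columns `id`, `problem`).
#' @examples
#' seqs <- c(rec1 = "MKWVTFISLLAPVSSAYS")
#' ann <- data.frame(id = "rec1", mature_start = 11)
#' readMatureRecords(seqs, ann)
#' @export
readMatureRecords <- function(fasta, annotations) {
  seqs <- .loadProteinSequences(fasta)
  ann <- .loadAnnotations(annotations)
  if (anyDuplicated(ann$id))
    stop("duplicate ids in annotations: ",
         paste(unique(ann$id[duplicated(ann$id)]), collapse = ", "))
  unknown <- setdiff(ann$id, names(seqs))
  if (length(unknown))
    stop("annotation ids absent from FASTA: ", paste(unknown, collapse = ", "))
  skipped <- setdiff(names(seqs), ann$id)
  if (length(skipped))
    warning(length(skipped), " FASTA record(s) without annotation skipped: ",
            paste(utils::head(skipped, 5L), collapse = ", "),
            if (length(skipped) > 5L) ", ..." else "")
  seq <- unname(seqs[ann$id])
  n <- nchar(seq)
  problems <- character(nrow(ann))
  bad_pos <- is.na(ann$mature_start) | ann$mature_start < 1L |
    ann$mature_start > n - 2L
  problems[bad_pos] <- "mature_start out of range"
  tri <- rep(NA_character_, nrow(ann))
  tri[!bad_pos] <- substr(seq[!bad_pos], ann$mature_start[!bad_pos],
                          ann$mature_start[!bad_pos] + 2L)
  bad_tri <- !bad_pos & !grepl(paste0("^[", paste(.AA20, collapse = ""), "]{3}$"), tri)
  problems[bad_tri] <- "non-standard residue in tripeptide window"
  ok <- problems == ""
  out <- DataFrame(id = ann$id[ok], sequence = seq[ok],
                   mature_start = as.integer(ann$mature_start[ok]),
                   tripeptide = tri[ok])
  attr(out, "problems") <- data.frame(id = ann$id[!ok],
                                      problem = problems[!ok],
                                      stringsAsFactors = FALSE)
  out
}

.loadProteinSequences <- function(fasta) {
  if (is.character(fasta) && length(fasta) == 1L && file.exists(fasta)) {
    seqs <- as.character(Biostrings::readAAStringSet(fasta))
    names(seqs) <- sub("\\s.*$", "", names(seqs))
  } else if (is(fasta, "AAStringSet")) {
    seqs <- as.character(fasta)
  } else if (is.character(fasta)) {
    seqs <- fasta
  } else {
    stop("fasta must be a file path, AAStringSet or named character vector")
  }
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    stop("protein sequences must be named")
  if (anyDuplicated(names(seqs)))
    stop("duplicate FASTA ids: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  seqs <- toupper(seqs)
  if (any(grepl("*", seqs, fixed = TRUE))) {
    warning("stripping '*' stop characters from sequences")
    seqs <- gsub("*", "", seqs, fixed = TRUE)
  }
  seqs
}

.loadAnnotations <- function(annotations) {
  if (is.character(annotations) && length(annotations) == 1L) {
    ann <- utils::read.delim(annotations, stringsAsFactors = FALSE)
  } else {
    ann <- as.data.frame(annotations)
  }
  if (!all(c("id", "mature_start") %in% names(ann)))
    stop("annotations must have columns 'id' and 'mature_start'")
  ann$mature_start <- as.integer(ann$mature_start)
  ann
}

#' Heuristic mature-start guess (unvalidated)
#'
#' A tiny fallback for sequences lacking upstream cleavage annotations: the
#' mature start is placed directly after the most C-terminal A-X-A pattern
#' (the classical small-residue signal-peptidase preference) found within
#' the first 40 residues. This heuristic is \strong{not validated} against
#' real signal-peptidase predictions and exists only so the pipeline can
#' run end-to-end on unannotated input; use SignalP/Phobius annotations for
#' any real analysis.
#'
#' @param sequences named character vector or [Biostrings::AAStringSet].
#' @param window number of N-terminal residues to search (default 40).
#' @return Integer vector of guessed 1-based mature starts (NA when no
#'   pattern is found).
#' @export
guessMatureStart <- function(sequences, window = 40L) {
  seqs <- .loadProteinSequences(sequences)
  vapply(seqs, function(s) {
    head_seq <- substr(s, 1L, min(window, nchar(s)))
    hits <- gregexpr("A.A", head_seq)[[1L]]
    if (hits[1L] == -1L) return(NA_integer_)
    as.integer(max(hits) + 3L)
  }, integer(1L))
}

## ---- survey tables -------------------------------------------------------

.SURVEY_COLS <- c("gene", "taxon", "species", "accession", "tripeptide", "count")

.validateSurveyTable <- function(table) {
  if (!all(.SURVEY_COLS %in% names(table)))
    stop("survey table must have columns: ", paste(.SURVEY_COLS, collapse = ", "))
  if (nrow(table)) {
    cnt <- table$count
    if (any(is.na(cnt)) || any(cnt < 1L) || any(cnt != round(cnt)))
      stop("survey counts must be positive integers")
    bad <- which(!grepl(paste0("^[", paste(.AA20, collapse = ""), "]{3}$"),
                        toupper(table$tripeptide)))
    if (length(bad))
      stop("invalid tripeptide in survey row ", bad[1L], ": ",
           sQuote(table$tripeptide[bad[1L]]))
  }
  invisible(table)
}

#' Read/write tripeptide survey tables
#'
#' Tab-delimited tables of starting tripeptides observed across genes and
#' taxa, with columns `gene`, `taxon`, `species`, `accession`,
#' `tripeptide`, `count` (count >= 1; a count row can stand for several
#' species sharing a tripeptide). A reconstructed survey of mating-factor
#' alpha-1 starting tripeptides across budding yeasts ships with the
#' package:
#' `system.file("extdata", "mfa1_tripeptide_survey.tsv", package = "erescape")`.
#'
#' @param file path to a TSV file.
#' @return `readSurveyTable` returns a validated data.frame;
#'   `writeSurveyTable` invisibly returns `file`.
#' @export
readSurveyTable <- function(file) {
  d <- utils::read.delim(file, stringsAsFactors = FALSE)
  d$tripeptide <- toupper(d$tripeptide)
  .validateSurveyTable(d)
}

#' @rdname readSurveyTable
#' @param table a survey data.frame.
#' @export
writeSurveyTable <- function(table, file) {
  .validateSurveyTable(table)
  utils::write.table(table, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Tally survey counts matching a tripeptide predicate
#'
#' Sums the `count` column over rows whose tripeptide satisfies a pure
#' predicate function, e.g. [isPhiPPhi()] to count consensus
#' hydrophobic-proline-hydrophobic starts.
#'
#' @param table a survey data.frame (see [readSurveyTable()]).
#' @param predicate function mapping a character vector of tripeptides to
#'   a logical vector.
#' @return Integer total count.
#' @examples
#' f <- system.file("extdata", "mfa1_tripeptide_survey.tsv", package = "erescape")
#' tallySurvey(readSurveyTable(f), isPhiPPhi)
#' @export
tallySurvey <- function(table, predicate) {
  .validateSurveyTable(table)
  if (!nrow(table)) return(0L)
  keep <- predicate(toupper(table$tripeptide))
  if (!is.logical(keep) || length(keep) != nrow(table))
    stop("predicate must return one logical per row")
  as.integer(sum(table$count[keep]))
}

#' Annotate a survey table with motif-model calls
#'
#' Appends the additive score, affinity class and exception flag from
#' [classifyTripeptides()] to every survey row.
#'
#' @inheritParams tallySurvey
#' @inheritParams classifyTripeptides
#' @return The survey data.frame with extra columns `score`, `klass`,
#'   `exception_applied`, `rule_id`.
#' @export
surveyClassify <- function(table,
                           weightTable = defaultWeightTable(),
                           thresholds = defaultThresholds(),
                           exceptions = defaultExceptionRules()) {
  .validateSurveyTable(table)
  calls <- classifyTripeptides(toupper(table$tripeptide), weightTable,
                               thresholds, exceptions)
  table$score <- calls$score
  table$klass <- as.character(calls$klass)
  table$exception_applied <- calls$exception_applied
  table$rule_id <- calls$rule_id
  table
}
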