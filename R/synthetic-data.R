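#' Seeded synthetic proteome with known mature starts
#'
#' Generates secreted-protein-like records: each sequence is a random
#' signal peptide (starting with M, ending with the A-X-A small-residue
#' signal-peptidase preference) followed by a mature region whose first
#' three residues are drawn from a supplied tripeptide spectrum. Emits the
#' FASTA-ready sequences, the mature-start annotation table and a
#' ground-truth key. Identical seeds reproduce identical output.
#'
#' @param n number of records (>= 1).
#' @param seed mandatory integer seed.
#' @param spectrum named numeric vector of tripeptide probabilities
#'   (normalized internally; default: uniform over [ghPanel()]).
#' @param spLength integer range of signal-peptide lengths (default
#'   c(15, 30)).
#' @param matureLength integer range of mature-region lengths (>= 3,
#'   default c(50, 150)).
#' @return list with `sequences` (named character), `annotation`
#'   (data.frame id/mature_start) and `truth` (data.frame
#'   id/mature_start/tripeptide).
#' @examples
#' p <- genProteome(5, seed = 1, spectrum = c(IPV = 1))
#' readMatureRecords(p$sequences, p$annotation)$tripeptide
#' @export
genProteome <- function(n, seed, spectrum = NULL,
                        spLength = c(15L, 30L),
                        matureLength = c(50L, 150L)) {
  if (n < 1L) stop("n must be >= 1")
  if (missing(seed)) stop("seed is mandatory")
  if (is.null(spectrum)) {
    spectrum <- stats::setNames(rep(1, 60L), ghPanel())
  }
  if (is.null(names(spectrum)) || any(spectrum < 0) || sum(spectrum) <= 0)
    stop("spectrum must be a named non-negative vector with positive sum")
  .splitTripeptides(names(spectrum))   # validates
  spectrum <- spectrum / sum(spectrum)
  withr::with_seed(seed, {
    ids <- sprintf("synthetic_prot_%03d", seq_len(n))
    spl <- sample(spLength[1L]:spLength[2L], n, replace = TRUE)
    mal <- sample(matureLength[1L]:matureLength[2L], n, replace = TRUE)
    tri <- sample(names(spectrum), n, replace = TRUE, prob = spectrum)
    ## signal peptide: M + random core + A-X-A cleavage cassette
    randAA <- function(k) paste(sample(.AA20, k, replace = TRUE),
                                collapse = "")
    seqs <- vapply(seq_len(n), function(i) {
      core <- randAA(spl[i] - 4L)
      axa <- paste0("A", sample(.AA20, 1L), "A")
      tail_seq <- randAA(mal[i] - 3L)
      paste0("M", core, axa, tri[i], tail_seq)
    }, character(1L))
    names(seqs) <- ids
    ann <- data.frame(id = ids, mature_start = spl + 1L,
                      stringsAsFactors = FALSE)
    list(sequences = seqs, annotation = ann,
         truth = data.frame(id = ids, mature_start = spl + 1L,
                            tripeptide = tri, stringsAsFactors = FALSE))
  })
}

#' Synthetic steady-state reporter table
#'
#' Emulates the structure of a reporter-cargo steady-state experiment:
#' tripeptides are split across experiment groups (each group always
#' containing the reference motif "IPV"), replicate raw levels are drawn
#' as `link(score) * experiment scale * lognormal noise`, and the
#' ground-truth link is attached. The default link is
#' `exp(lambda * (3 - score))` with lambda = 0.45, a monotone decreasing
#' map placing the strongest motifs (score 3) at level 1 and diacidic
#' nonbinders (score -2) about 9.5-fold higher, in line with the observed
#' dynamic range of such reporters. Noise is multiplicative lognormal
#' (abundance-type measurements are positive).
#'
#' @param tripeptides character vector of tripeptides (default the
#'   60-motif panel [ghPanel()]); must contain "IPV" (it is added with a
#'   warning if absent).
#' @param seed mandatory integer seed.
#' @param groups number of experiment groups (default 4).
#' @param replicates replicates per tripeptide (default 3).
#' @param noiseSd lognormal sdlog of the multiplicative noise
#'   (default 0.25).
#' @param link monotone decreasing function score -> expected level.
#' @param table weight table used to score tripeptides for the link.
#' @return data.frame with columns `experiment`, `tripeptide`, `value`;
#'   `attr(, "truth")` holds the per-tripeptide expected levels.
#' @export
genSteadyStateTable <- function(tripeptides = ghPanel(), seed,
                                groups = 4L, replicates = 3L,
                                noiseSd = 0.25,
                                link = function(s) exp(0.45 * (3 - s)),
                                table = defaultWeightTable()) {
  if (missing(seed)) stop("seed is mandatory")
  tripeptides <- unique(toupper(tripeptides))
  if (!"IPV" %in% tripeptides)
    stop("tripeptide list must contain the reference motif IPV")
  sc <- scoreTripeptide(tripeptides, table)
  expected <- link(sc)
  if (length(unique(sc)) > 1L &&
      stats::cor(sc, expected, method = "spearman") > 0)
    stop("link must be monotone non-increasing in score")
  withr::with_seed(seed, {
    others <- setdiff(tripeptides, "IPV")
    grp <- rep(seq_len(groups), length.out = length(others))
    grp <- sample(grp)
    assign_tbl <- rbind(
      data.frame(experiment = seq_len(groups), tripeptide = "IPV",
                 stringsAsFactors = FALSE),
      data.frame(experiment = grp, tripeptide = others,
                 stringsAsFactors = FALSE))
    ## per-experiment multiplicative scale (normalization removes it)
    scale <- stats::setNames(exp(stats::rnorm(groups, 0, 0.3)),
                             seq_len(groups))
    rows <- assign_tbl[rep(seq_len(nrow(assign_tbl)), each = replicates), ]
    mu <- expected[match(rows$tripeptide, tripeptides)] *
      scale[as.character(rows$experiment)]
    rows$value <- mu * exp(stats::rnorm(nrow(rows), 0, noiseSd))
    rownames(rows) <- NULL
    attr(rows, "truth") <- data.frame(tripeptide = tripeptides,
                                      score = unname(sc),
                                      expected_level = unname(expected),
                                      stringsAsFactors = FALSE)
    rows
  })
}

#' Synthetic saturation binding titration
#'
#' Draws replicate binding signals from the single-site model
#' `b0 + bmax * c / (kdTrue + c)` at the standard six-concentration
#' titration design (0, 100, 200, 300, 400, 800 nM), with multiplicative
#' lognormal noise scaled so that `noiseSd` is the approximate relative
#' error (a fraction of the local mean; an additive Gaussian floor of
#' `noiseSd * bmax / 10` keeps the zero-concentration point noisy too).
#' `bmax = 0` produces a flat, background-only (nonbinder) dataset.
#'
#' @param bmax true maximal specific binding (signal units).
#' @param kdTrue true half-maximal concentration (nM).
#' @param b0 background signal.
#' @param concentrations design concentrations (nM).
#' @param replicates replicates per concentration (default 3).
#' @param noiseSd relative noise level (default 0.05, i.e. 5% of signal);
#'   0 gives noiseless data.
#' @param seed mandatory integer seed.
#' @return data.frame with columns `concentration`, `signal`, `replicate`;
#'   `attr(, "truth")` holds the generating parameters.
#' @export
genBindingData <- function(bmax = 100, kdTrue = 250, b0 = 5,
                           concentrations = c(0, 100, 200, 300, 400, 800),
                           replicates = 3L, noiseSd = 0.05, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (bmax < 0 || kdTrue <= 0 || b0 < 0) stop("invalid true parameters")
  conc <- rep(concentrations, each = replicates)
  mu <- b0 + bmax * conc / (kdTrue + conc)
  withr::with_seed(seed, {
    if (noiseSd > 0) {
      sig <- mu * exp(stats::rnorm(length(mu), 0, noiseSd)) +
        stats::rnorm(length(mu), 0, noiseSd * max(bmax, b0) / 10)
      sig <- pmax(sig, 0)
    } else {
      sig <- mu
    }
    out <- data.frame(concentration = conc, signal = sig,
                      replicate = rep(seq_len(replicates),
                                      times = length(concentrations)))
    attr(out, "truth") <- list(bmax = bmax, kd = kdTrue, b0 = b0,
                               noiseSd = noiseSd)
    out
  })
}

#' Library of named trafficking scenarios
#'
#' Ready-made [CargoSystem-class] configurations mirroring the key
#' receptor-limitation experiments, each with its expected qualitative
#' outcome attached:
#' \describe{
#'   \item{receptor-excess-coexpression}{a strong binder plus a nonbinder
#'     under abundant receptor capacity; coexpression should leave the
#'     strong cargo's steady state essentially unchanged (< 1%).}
#'   \item{knockdown-grid}{a strong and a modest binder with equal
#'     synthesis rates plus the factor grid
#'     c(1, 0.5, 0.2, 0.1, 0.05); both steady-state levels rise as
#'     receptor capacity falls while the strong cargo retains the larger
#'     receptor flux share, and the modest:strong concentration ratio
#'     relaxes toward the bulk-only limit of 1.}
#'   \item{surf4-null}{an aggregation-prone, high-affinity cargo (low
#'     aggregation threshold, low kd); with receptor present it stays
#'     below threshold, with receptor capacity zero it aggregates.}
#' }
#' All units are abstract (nondimensionalized).
#'
#' @return Named list; each element has `system` (a
#'   [CargoSystem-class]), optional extra fields (e.g. `factors`,
#'   `system_null`) and an `expectation` string.
#' @export
genScenarios <- function() {
  strong <- data.frame(name = "strong", synthesis = 1, kd = 0.05,
                       c_agg = Inf)
  nonbinder <- data.frame(name = "nonbinder", synthesis = 1, kd = Inf,
                          c_agg = Inf)
  modest <- data.frame(name = "modest", synthesis = 1, kd = 1,
                       c_agg = Inf)
  aggprone <- data.frame(name = "aggprone", synthesis = 1, kd = 0.05,
                         c_agg = 5)
  list(
    `receptor-excess-coexpression` = list(
      strong = strong, other = nonbinder, kBulk = 0.1, vr = 50,
      expectation = "relative change of the strong cargo's steady state under coexpression < 1%"),
    `knockdown-grid` = list(
      strong = strong, modest = modest, kBulk = 0.1, vr = 2,
      factors = c(1, 0.5, 0.2, 0.1, 0.05),
      expectation = "both levels non-decreasing as receptor capacity falls; modest:strong concentration ratio relaxes monotonically toward the bulk-only limit 1"),
    `surf4-null` = list(
      system = cargoSystem(aggprone, kBulk = 0.1, vr = 2),
      system_null = cargoSystem(aggprone, kBulk = 0.1, vr = 0),
      expectation = "aggregation flag off with receptor, on with receptor capacity zero"))
}

#' Synthetic diverged ortholog pair
#'
#' Generates an ancestor protein and two independently diverged
#' descendants (per-site substitutions plus occasional short indels), a
#' stand-in for a real cross-kingdom receptor ortholog pair when the real
#' sequences are not at hand. Clearly synthetic: no claim of biological
#' realism beyond length and divergence scale.
#'
#' @param length ancestor length (default 280 residues).
#' @param pSub per-site substitution probability per lineage
#'   (default 0.45).
#' @param pIndel per-site indel initiation probability per lineage
#'   (default 0.02; indel lengths 1-4).
#' @param seed mandatory integer seed.
#' @return Named character vector of two sequences (`orthologA`,
#'   `orthologB`).
#' @export
genDivergedPair <- function(length = 280L, pSub = 0.45, pIndel = 0.02,
                            seed) {
  if (missing(seed)) stop("seed is mandatory")
  withr::with_seed(seed, {
    anc <- sample(.AA20, length, replace = TRUE)
    evolve <- function(x) {
      sub <- stats::runif(base::length(x)) < pSub
      x[sub] <- sample(.AA20, sum(sub), replace = TRUE)
      out <- character(0L)
      i <- 1L
      while (i <= base::length(x)) {
        r <- stats::runif(1L)
        if (r < pIndel / 2) {            # deletion
          i <- i + sample(1:4, 1L)
        } else if (r < pIndel) {         # insertion
          out <- c(out, sample(.AA20, sample(1:4, 1L), replace = TRUE),
                   x[i])
          i <- i + 1L
        } else {
          out <- c(out, x[i])
          i <- i + 1L
        }
      }
      paste(out, collapse = "")
    }
    c(orthologA = evolve(anc), orthologB = evolve(anc))
  })
}
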