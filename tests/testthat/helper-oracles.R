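## Independent oracles used by the test suite. These deliberately avoid the
## package's own code paths (different algorithms, naive implementations).

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "W", "V", "Y")

allTripeptides <- function() {
  as.vector(outer(as.vector(outer(AA20, AA20, paste0)), AA20, paste0))
}

## naive pool-adjacent-violators (non-decreasing): repeatedly merge the first
## violating adjacent block pair until none remain
pavOracle <- function(y, w = rep(1, length(y))) {
  blocks <- lapply(seq_along(y), function(i) list(v = y[i], w = w[i], n = 1L))
  repeat {
    vals <- vapply(blocks, function(b) b$v, numeric(1))
    viol <- which(diff(vals) < 0)
    if (!length(viol)) break
    i <- viol[1L]
    a <- blocks[[i]]; b <- blocks[[i + 1L]]
    merged <- list(v = (a$v * a$w + b$v * b$w) / (a$w + b$w),
                   w = a$w + b$w, n = a$n + b$n)
    blocks <- c(blocks[seq_len(i - 1L)], list(merged),
                blocks[seq_along(blocks) > i + 1L])
  }
  unlist(lapply(blocks, function(b) rep(b$v, b$n)))
}

## exhaustive enumeration of all global alignments of two short sequences,
## scored with affine gaps (gap of length L costs open + L*extend), end gaps
## free unless endGaps; returns the maximal score
bruteAlignScore <- function(a, b, sub, gapOpen = 10, gapExtend = 0.5,
                            endGaps = FALSE) {
  ra <- strsplit(a, "")[[1L]]
  rb <- strsplit(b, "")[[1L]]
  n <- length(ra); m <- length(rb)
  best <- -Inf
  scoreCols <- function(colsA, colsB) {
    s <- 0
    match_idx <- colsA != "-" & colsB != "-"
    if (any(match_idx))
      s <- s + sum(sub[cbind(colsA[match_idx], colsB[match_idx])])
    for (v in list(colsA, colsB)) {
      r <- rle(v == "-")
      if (!length(r$lengths)) next
      starts <- cumsum(c(1L, r$lengths))[seq_along(r$lengths)]
      for (k in seq_along(r$lengths)) {
        if (!r$values[k]) next
        atStart <- starts[k] == 1L
        atEnd <- starts[k] + r$lengths[k] - 1L == length(v)
        if (!endGaps && (atStart || atEnd)) next
        s <- s - (gapOpen + gapExtend * r$lengths[k])
      }
    }
    s
  }
  rec <- function(i, j, colsA, colsB) {
    if (i > n && j > m) {
      sc <- scoreCols(colsA, colsB)
      if (sc > best) best <<- sc
      return(invisible(NULL))
    }
    if (i <= n && j <= m)
      rec(i + 1L, j + 1L, c(colsA, ra[i]), c(colsB, rb[j]))
    if (i <= n)
      rec(i + 1L, j, c(colsA, ra[i]), c(colsB, "-"))
    if (j <= m)
      rec(i, j + 1L, c(colsA, "-"), c(colsB, rb[j]))
  }
  rec(1L, 1L, character(0L), character(0L))
  best
}

## dense two-stage grid-search fit of the single-site binding model
gridSearchBindingFit <- function(conc, signal) {
  sse <- function(bmax, kdv, b0) {
    pred <- b0 + bmax * conc / (kdv + conc)
    sum((signal - pred)^2)
  }
  span <- max(signal) - min(signal)
  bmaxGrid <- seq(0.5 * span, 2 * span, length.out = 40L)
  kdGrid <- seq(10, 1500, length.out = 150L)
  b0Grid <- seq(0, max(min(signal) * 2, 1), length.out = 20L)
  bestVal <- Inf; bestPar <- c(NA, NA, NA)
  for (b0v in b0Grid) for (bm in bmaxGrid) {
    vals <- vapply(kdGrid, function(k) sse(bm, k, b0v), numeric(1))
    i <- which.min(vals)
    if (vals[i] < bestVal) { bestVal <- vals[i]; bestPar <- c(bm, kdGrid[i], b0v) }
  }
  ## refine around the coarse optimum
  bm0 <- bestPar[1]; kd0 <- bestPar[2]; b00 <- bestPar[3]
  bmaxGrid <- seq(0.9 * bm0, 1.1 * bm0, length.out = 40L)
  kdGrid <- seq(max(1, kd0 - 60), kd0 + 60, length.out = 121L)
  b0Grid <- seq(max(0, b00 - 3), b00 + 3, length.out = 25L)
  for (b0v in b0Grid) for (bm in bmaxGrid) {
    vals <- vapply(kdGrid, function(k) sse(bm, k, b0v), numeric(1))
    i <- which.min(vals)
    if (vals[i] < bestVal) { bestVal <- vals[i]; bestPar <- c(bm, kdGrid[i], b0v) }
  }
  list(bmax = bestPar[1], kd = bestPar[2], b0 = bestPar[3])
}

## long-time ODE integration of the cargo balance equations (deSolve),
## written independently of the package's Newton solver
odeSteadyState <- function(synthesis, kdv, kBulk, vr, tEnd = 5000) {
  deriv <- function(t, C, parms) {
    x <- ifelse(is.finite(kdv), C / kdv, 0)
    occ <- 1 + sum(x)
    list(synthesis - kBulk * C - vr * x / occ)
  }
  out <- deSolve::ode(y = rep(0, length(synthesis)), times = c(0, tEnd),
                      func = deriv, parms = NULL,
                      rtol = 1e-10, atol = 1e-12)
  as.numeric(out[nrow(out), -1L])
}

blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
}
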