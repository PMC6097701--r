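test_that("default weight table satisfies its structural invariants", {
  tab <- defaultWeightTable()
  w <- weightMatrix(tab)
  expect_identical(dim(w), c(3L, 20L))
  expect_setequal(colnames(w), AA20)
  ## stated residue-level constraints
  expect_true(all(w[, c("D", "E")] < 0))
  expect_true(all(w[1:2, "Q"] < 0))
  expect_gt(w[2, "P"], 0)
  expect_lt(w[3, "P"], 0)
  expect_true(all(w[, "R"] > 0))
  expect_true(all(w[c(1, 3), phiSet()] > 0))
  ## K weakly favorable, strictly below R
  expect_true(all(w[, "K"] > 0 & w[, "K"] < w[, "R"]))
  ## untested residues default-neutral with matching provenance
  for (res in c("C", "G", "H", "W")) {
    expect_true(all(w[, res] == 0))
    expect_true(all(provenanceAt(tab, 1:3, rep(res, 3)) == "default-neutral"))
  }
  ## class lookups from the stated examples
  expect_identical(contributionClass(tab, 2, "P"), "favorable")
  expect_identical(contributionClass(tab, 3, "P"), "unfavorable")
  expect_identical(contributionClass(tab, 1, "E"), "unfavorable")
})

test_that("weight table round-trips through its TSV serialization", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeWeightTable(defaultWeightTable(), f)
  back <- readWeightTable(f)
  expect_identical(weightMatrix(back), weightMatrix(defaultWeightTable()))
  expect_identical(back@provenance, defaultWeightTable()@provenance)
})

test_that("invalid weight tables are rejected", {
  w <- weightMatrix(defaultWeightTable())
  w[1, "E"] <- 1  # acidic residues must stay unfavorable
  expect_error(positionWeightTable(w), "unfavorable")
  expect_error(weightAt(defaultWeightTable(), 4, "A"), "position")
  expect_error(weightAt(defaultWeightTable(), 1, "B"), "unknown residue")
})

test_that("additive scores reproduce the reported ordering and reject bad residues", {
  expect_gt(scoreTripeptide("IPV"), scoreTripeptide("ISV"))
  ## E weight is position-independent and T is identical at positions 2/3,
  ## so the two-E permutations score equally
  expect_equal(unname(scoreTripeptide("EET")), unname(scoreTripeptide("ETE")))
  expect_error(scoreTripeptide("IPX"), "invalid residue 'X' at position 3")
  expect_error(scoreTripeptide("BPV"), "invalid residue 'B' at position 1")
  expect_error(scoreTripeptide("IP"), "exactly 3")
})

test_that("the global score maximum over all 8000 tripeptides is attained by a consensus motif", {
  all8k <- allTripeptides()
  sc <- scoreTripeptide(all8k)
  top <- names(sc)[sc == max(sc)]
  expect_true(any(isPhiPPhi(top)))
  ## every maximal tripeptide is consensus-like: favorable at each position
  w <- weightMatrix(defaultWeightTable())
  expect_equal(max(sc), sum(apply(w, 1, max)))
})

test_that("phi-P-phi detection matches enumeration", {
  expect_true(isPhiPPhi("APV"))
  expect_false(isPhiPPhi("APT"))
  n_phi <- sum(isPhiPPhi(allTripeptides()))
  expect_identical(n_phi, as.integer(length(phiSet())^2))  # 49 with the 7-member set
})

test_that("classification reproduces the experimental panel, including exceptions", {
  trafficked <- c("IPV", "SPV", "TPV", "APV", "RPV", "IPR", "MPL", "YPY", "NPV")
  retained <- c("IPD", "ISV", "ITV", "EPL", "EPV", "EET", "EEE",
                "QQV", "QPV", "QSV", "FQV")
  calls_t <- classifyTripeptides(trafficked)
  expect_true(all(as.character(calls_t$klass) %in% c("strong", "modest")))
  calls_r <- classifyTripeptides(retained)
  expect_true(all(as.character(calls_r$klass) %in% c("modest", "nonbinding")))
  ## per-tripeptide calls stated directly
  one <- function(t) as.character(classifyTripeptides(t)$klass)
  expect_identical(one("IPV"), "strong")
  expect_identical(one("EET"), "nonbinding")
  expect_identical(one("FSM"), "modest")
  expect_identical(one("QQV"), "nonbinding")
  ## exceptions override the additive model
  fpv <- classifyTripeptides("FPV")
  expect_identical(as.character(fpv$klass), "modest")
  expect_true(fpv$exception_applied)
  expect_identical(fpv$rule_id, "FPV-modest")
  kvh <- classifyTripeptides("KVH")
  expect_identical(as.character(kvh$klass), "modest")
  expect_true(kvh$exception_applied)
})

test_that("two or more acidic residues force nonbinding regardless of score", {
  diacidic <- c("EET", "EEE", "DED", "EDR", "RDE", "DPE")
  calls <- classifyTripeptides(diacidic)
  expect_true(all(as.character(calls$klass) == "nonbinding"))
  ## property over all tripeptides
  all8k <- allTripeptides()
  m <- matrix(unlist(strsplit(all8k, "")), ncol = 3, byrow = TRUE)
  nacid <- rowSums(matrix(m %in% c("D", "E"), ncol = 3))
  calls_all <- classifyTripeptides(all8k)
  expect_true(all(as.character(calls_all$klass)[nacid >= 2] == "nonbinding"))
})

test_that("removing the exception list reproduces pure additive classification", {
  all8k <- allTripeptides()
  with_exc <- classifyTripeptides(all8k)
  without <- classifyTripeptides(all8k, exceptions = NULL)
  expect_false(any(without$exception_applied))
  differing <- which(as.character(with_exc$klass) != as.character(without$klass))
  ## every divergence is due to a listed exception; FPV genuinely changes
  ## class (KVH is modest under the additive model already)
  expect_true(all(with_exc$tripeptide[differing] %in%
                    defaultExceptionRules()$pattern))
  expect_true("FPV" %in% with_exc$tripeptide[differing])
  ## scores are untouched by exceptions
  expect_identical(with_exc$score, without$score)
})

test_that("single D/E substitution of a favorable residue never increases the score", {
  set.seed(42)
  tri <- sample(allTripeptides(), 400)
  w <- weightMatrix(defaultWeightTable())
  sc <- scoreTripeptide(tri)
  for (pos in 1:3) {
    res <- substr(tri, pos, pos)
    favorable <- w[cbind(pos, match(res, colnames(w)))] > 0
    for (acid in c("D", "E")) {
      mut <- tri
      substr(mut, pos, pos) <- acid
      expect_true(all(scoreTripeptide(mut)[favorable] <= sc[favorable]))
    }
  }
})

test_that("identical inputs give byte-identical serialized calls", {
  a <- classifyTripeptides(ghPanel())
  b <- classifyTripeptides(ghPanel())
  expect_identical(serialize(as.data.frame(a), NULL),
                   serialize(as.data.frame(b), NULL))
})

test_that("exception rules round-trip through TSV and are validated", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeExceptionRules(defaultExceptionRules(), f)
  back <- readExceptionRules(f)
  expect_identical(back, defaultExceptionRules())
  ## a user-supplied rule changes classification
  custom <- rbind(back, data.frame(rule_id = "NPV-strong", pattern = "NPV",
                                   forced_class = "strong",
                                   note = "user override"))
  expect_identical(
    as.character(classifyTripeptides("NPV", exceptions = custom)$klass),
    "strong")
  bad <- back; bad$note[1] <- ""
  expect_error(writeExceptionRules(bad, f), "citation note")
  bad2 <- back; bad2$forced_class[1] <- "superb"
  g <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(bad2, g, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readExceptionRules(g), "forced_class")
})

test_that("threshold boundaries take the higher class and thresholds are configurable", {
  ## KPV scores exactly at the default strong threshold (K + P + V = 2.5)
  expect_equal(unname(scoreTripeptide("KPV")), defaultThresholds()[["strong"]])
  expect_identical(as.character(classifyTripeptides("KPV")$klass), "strong")
  ## QQV sits exactly on the nonbinding boundary (-1)
  expect_identical(as.character(classifyTripeptides("QQV")$klass), "nonbinding")
  ## custom thresholds move the partition
  lax <- classifyTripeptides("FSM", thresholds = c(strong = 2, nonbinding = -1))
  expect_identical(as.character(lax$klass), "strong")
  expect_error(classifyTripeptides("IPV", thresholds = c(strong = -2, nonbinding = 0)),
               "below")
})
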