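panel_rows <- read.delim(tspo_panel_path(), stringsAsFactors = FALSE)

test_that("predictor outputs binarize under the published thresholds", {
  expect_equal(binarize_call("SIFT", 0.03), "damaging")
  expect_equal(binarize_call("SIFT", 0.2), "benign")
  # SNPs&GO rule is strictly 'greater than 0.5'
  expect_equal(binarize_call("SNPsGO", 0.5), "benign")
  expect_equal(binarize_call("SNPsGO", 0.51), "damaging")
  expect_equal(binarize_call("PolyPhen2", 0.9), "damaging")
  expect_equal(binarize_call("PolyPhen2", 0.5), "benign")
  expect_equal(binarize_call("IMutant3", -0.7), "damaging")
  expect_equal(binarize_call("IMutant3", 0.2), "benign")
  expect_equal(binarize_call("IMutant3", 0.9), "benign")
  expect_equal(binarize_call("PROVEAN", "Deleterious"), "damaging")
  expect_error(binarize_call("SIFT", "frobnicated"), "unrecognized")
  expect_error(binarize_call("nosuchtool", "x"), "unknown predictor")
})

test_that("binarization is total over fixture categories, fuzzed by wording", {
  for (tool in c("provean", "sift", "polyphen2", "phdsnp", "snap2",
                 "snpsgo", "fathmm", "imutant3")) {
    cats <- unique(panel_rows[[tool]])
    fuzzed <- c(cats, toupper(cats), tolower(cats),
                sub(" in stability", " of stability", cats, fixed = TRUE))
    for (cat in fuzzed)
      expect_true(binarize_call(tool, cat) %in% c("damaging", "benign"),
                  info = paste(tool, cat))
  }
})

test_that("'possibly damaging' must be a benign vote to explain the panel", {
  # brute force over both assignments: score every row under each and
  # compare re-derived labels to the printed ones
  concord <- function(possibly_damaging) {
    rules <- binarization_rules()
    if (possibly_damaging) {
      rules$polyphen2$damaging <- c(rules$polyphen2$damaging,
                                    "possibly damaging")
      rules$polyphen2$benign <- "benign"
    }
    got <- classify_table(panel_rows, rules)
    got$concordance$n_match
  }
  expect_gt(concord(FALSE), concord(TRUE))
  expect_equal(concord(FALSE), 51)
})

test_that("consensus vote follows the >= 5 damaging rule", {
  mk <- function(n_damaging) {
    calls <- rep("benign", 8)
    calls[seq_len(n_damaging)] <- "damaging"
    setNames(calls, c("provean", "sift", "polyphen2", "phdsnp", "snap2",
                      "snpsgo", "fathmm", "imutant3"))
  }
  expect_equal(consensus_classify(mk(0))$label, "N")
  expect_equal(consensus_classify(mk(4))$label, "N")
  expect_equal(consensus_classify(mk(5))$label, "D")
  expect_equal(consensus_classify(mk(8))$label, "D")
  # monotone: adding a damaging call never flips D -> N
  for (k in 0:7) {
    lo <- consensus_classify(mk(k))
    hi <- consensus_classify(mk(k + 1))
    expect_false(lo$label == "D" && hi$label == "N")
    expect_equal(hi$votes, lo$votes + 1)
  }
  expect_error(consensus_classify(mk(3)[1:7]), "8 tools")
  dup <- mk(2); names(dup)[2] <- "provean"
  expect_error(consensus_classify(dup), "duplicated")
})

test_that("the published A147T and A147M rows classify as printed", {
  r147t <- panel_rows[panel_rows$mutation == "A147T", ]
  got <- classify_table(r147t)
  expect_equal(got$results$votes, 5L)
  expect_equal(got$results$label, "D")
  r147m <- panel_rows[panel_rows$mutation == "A147M", ]
  got <- classify_table(r147m)
  expect_equal(got$results$votes, 4L)
  expect_equal(got$results$label, "N")
})

test_that("full panel re-derivation is concordant except the known G63S row", {
  got <- classify_table(panel_rows)
  expect_equal(nrow(got$results), 52)
  expect_equal(sum(got$results$printed_label == "D"), 21)
  expect_equal(got$concordance$n_match, 51)
  expect_equal(got$concordance$mismatches$mutation, "G63S")
  expect_equal(got$concordance$mismatches$votes, 4L)
  # order independence
  shuffled <- panel_rows[sample(nrow(panel_rows)), ]
  got2 <- classify_table(shuffled)
  m <- match(got$results$mutation, got2$results$mutation)
  expect_equal(got2$results$label[m], got$results$label)
  expect_error(classify_table(panel_rows[0, ]), "empty")
})

test_that("synthetic panels with planted vote counts classify exactly", {
  g <- gen_predictor_panels(500, seed = 9)
  got <- classify_table(g$panels)
  expect_equal(got$results$votes, g$truth$votes)
  expect_equal(got$results$label, g$truth$labels)
  expect_null(got$concordance)
})

test_that("region enrichment counts deleterious variants over residue ranges", {
  got <- classify_table(panel_rows)
  tmd <- rbind(c(44, 65), c(133, 150))
  enr <- region_enrichment(got$results, tmd, use_printed = TRUE)
  expect_equal(enr$per_range$count, c(4, 5))
  expect_equal(enr$total, 9)
  expect_setequal(strsplit(enr$per_range$mutations[1], ",")[[1]],
                  c("P44L", "G63S", "G63D", "Y65F"))
  expect_setequal(strsplit(enr$per_range$mutations[2], ",")[[1]],
                  c("A133T", "P139T", "P139S", "A147T", "L150F"))
  # empty range list and whole-protein range
  expect_equal(region_enrichment(got$results, matrix(numeric(0), 0, 2))$total,
               0L)
  full <- region_enrichment(got$results, rbind(c(1, 169)),
                            use_printed = TRUE)
  expect_equal(full$total, sum(got$results$printed_label == "D"))
  # union semantics: overlapping ranges count a variant once
  overlap <- region_enrichment(got$results, rbind(c(44, 65), c(60, 70)),
                               use_printed = TRUE)
  expect_equal(overlap$total, 4)
  expect_error(region_enrichment(got$results, rbind(c(65, 44))), "start")
})

test_that("conservation overlay intersects the deleterious set", {
  got <- classify_table(panel_rows)
  all_low <- rep(1L, 169)
  ov <- conservation_overlay(got$results, all_low, min_score = 9)
  expect_equal(nrow(ov$subset), 0)
  # planted high-score positions are recovered exactly
  track <- rep(1L, 169)
  planted <- c(44, 63, 147)
  track[planted] <- 9L
  ov2 <- conservation_overlay(got$results, track, min_score = 8,
                              use_printed = TRUE)
  pos <- map_protein_variants(ov2$subset$mutation)$position
  expect_true(all(pos %in% planted))
  dpos <- map_protein_variants(
    got$results$mutation[got$results$printed_label == "D"])$position
  expect_equal(ov2$n_conserved, sum(dpos %in% planted))
  # monotone in min_score
  sizes <- vapply(1:9, function(s)
    conservation_overlay(got$results, track, s)$n_conserved, 0L)
  expect_true(all(diff(sizes) <= 0))
  expect_error(conservation_overlay(got$results, rep(1L, 10)), "shorter")
  expect_error(conservation_overlay(got$results, rep(0L, 169)), "1..9")
})
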