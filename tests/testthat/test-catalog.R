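test_that("variant tables parse cleanly and collect malformed rows", {
  d <- data.frame(id = c("rs1", "rs2", "rs3"),
                  region_class = c("intronic", "coding_nonsynonymous", "utr"),
                  protein_change = c(NA, "A147T", NA),
                  maf = c(0.01, 0.30, NA))
  got <- load_variant_table(write_tmp_tsv(d))
  expect_equal(nrow(got$variants), 3)
  expect_equal(nrow(got$rejects), 0)
  expect_equal(got$variants$protein_change[2], "A147T")

  bad <- rbind(d, data.frame(id = "rs4", region_class = NA,
                             protein_change = NA, maf = 0.1))
  got2 <- load_variant_table(write_tmp_tsv(bad))
  expect_equal(nrow(got2$variants), 3)
  expect_equal(got2$rejects$row, 4)
  expect_match(got2$rejects$reason, "neither position nor region_class")

  empty <- d[0, ]
  expect_error(load_variant_table(write_tmp_tsv(empty)), "empty")
  expect_error(load_variant_table(write_tmp_tsv(d), dialect = c(maf = "MAF")),
               "not in file")
})

test_that("dialect remapping resolves nonstandard column names", {
  d <- data.frame(rsid = "rs1", klass = "intronic", freq = 0.2)
  got <- load_variant_table(write_tmp_tsv(d),
                            dialect = c(id = "rsid", region_class = "klass",
                                        maf = "freq"))
  expect_equal(got$variants$id, "rs1")
  expect_equal(got$variants$region_class, "intronic")
  expect_equal(got$variants$maf, 0.2)
})

test_that("region classification matches planted ground truth", {
  gm <- gen_gene_model(n_codons = 60, seed = 42)
  got <- vapply(seq_len(nrow(gm$positions)), function(i) {
    p <- gm$positions[i, ]
    classify_region(p$position, gm$annotation, gm$cds_sequence,
                    ref = if (is.na(p$ref)) NULL else p$ref,
                    alt = if (is.na(p$alt)) NULL else p$alt)
  }, "")
  expect_equal(got, gm$positions$truth_class)
  expect_gte(nrow(gm$positions), 200)
  # idempotent / order independent: shuffled evaluation gives same classes
  ord <- sample(nrow(gm$positions))
  got2 <- vapply(ord, function(i) {
    p <- gm$positions[i, ]
    classify_region(p$position, gm$annotation, gm$cds_sequence,
                    ref = if (is.na(p$ref)) NULL else p$ref,
                    alt = if (is.na(p$alt)) NULL else p$alt)
  }, "")
  expect_equal(got2, gm$positions$truth_class[ord])
  # outside all intervals -> annotation-gap error
  expect_error(classify_region(10^7, gm$annotation, gm$cds_sequence),
               "outside")
})

test_that("distribution summaries reproduce printed catalog percentages", {
  s <- summarize_distribution(c(intronic = 674, utr = 52,
                                coding_nonsynonymous = 52,
                                coding_synonymous = 40))
  expect_equal(s$count, c(674, 52, 52, 40))
  expect_equal(s$percent[s$class == "intronic"], 82.4)
  expect_equal(s$percent[s$class == "coding_nonsynonymous"], 6.4)
  expect_equal(s$percent[s$class == "utr"], 6.4)
  # 100*40/818 = 4.889...; half-up one-decimal rounding gives 4.9
  expect_equal(s$percent[s$class == "coding_synonymous"], 4.9)
  expect_lt(abs(sum(s$percent) - 100), 0.2)

  one <- summarize_distribution(data.frame(region_class = rep("intronic", 7)))
  expect_equal(one$percent[one$class == "intronic"], 100.0)
  expect_error(summarize_distribution(data.frame(region_class = character(0))),
               "empty")
})

test_that("sampled catalogs land near their generator fractions", {
  fr <- c(intronic = 0.8, utr = 0.1, coding_nonsynonymous = 0.06,
          coding_synonymous = 0.04)
  g <- gen_variant_catalog(1000, fractions = fr, seed = 7)
  s <- summarize_distribution(g$variants)
  for (cl in names(fr)) {
    tol <- 3 * sqrt(fr[[cl]] * (1 - fr[[cl]]) / 1000) * 100
    expect_lt(abs(s$percent[s$class == cl] - 100 * fr[[cl]]), tol)
  }
  expect_lt(abs(sum(s$percent) - 100), 0.2)
})

test_that("protein-change tokens parse and round-trip", {
  pv <- map_protein_variants("A147T")
  expect_equal(pv$ref_aa, "A")
  expect_equal(pv$position, 147L)
  expect_equal(pv$alt_aa, "T")
  # formatting a parsed token reproduces it
  toks <- c("G63S", "R162H", "E169V", "W5R")
  pv2 <- map_protein_variants(toks)
  expect_equal(paste0(pv2$ref_aa, pv2$position, pv2$alt_aa), toks)
  expect_error(map_protein_variants("A0T"), "position")
  expect_error(map_protein_variants("X9Z"), "unknown amino-acid")
  expect_error(map_protein_variants("A147"), "malformed")
  expect_error(map_protein_variants("A147A"), "identical")
})

test_that("multiallelic residues are recovered exactly", {
  pv <- map_protein_variants(c("A1T", "G2S", "G2D", "L3F"))
  multi <- multiallelic_residues(pv)
  expect_equal(names(multi), "2")
  expect_equal(sort(multi[["2"]]$alt_aa), c("D", "S"))
  expect_equal(multiallelic_residues(map_protein_variants(c("A1T", "G2S"))),
               list())
  # planted duplicates in a synthetic catalog
  g <- gen_variant_catalog(400, n_duplicate_positions = 6, seed = 3)
  pvs <- map_protein_variants(g$variants)
  expect_equal(as.integer(names(multiallelic_residues(pvs))),
               g$truth$duplicate_positions)
})

test_that("MAF partition matches a brute-force split and is exhaustive", {
  set.seed(11)
  v <- data.frame(id = sprintf("v%d", 1:50),
                  maf = c(runif(40, 0, 0.01), rep(NA, 5), runif(5, 0.1, 0.5)))
  parts <- filter_by_maf(v, 0.003)
  brute_ret <- v$id[!is.na(v$maf) & v$maf >= 0.003]
  brute_rare <- v$id[!is.na(v$maf) & v$maf < 0.003]
  expect_setequal(parts$retained$id, brute_ret)
  expect_setequal(parts$rare$id, brute_rare)
  expect_equal(nrow(parts$retained) + nrow(parts$rare) + nrow(parts$unknown),
               nrow(v))
  # a common allele at MAF 0.30 is retained at the 0.003 cutoff
  common <- filter_by_maf(data.frame(id = "rs6971", maf = 0.30), 0.003)
  expect_equal(common$retained$id, "rs6971")
  allzero <- filter_by_maf(data.frame(id = "a", maf = 0), 0.003)
  expect_equal(nrow(allzero$rare), 1)
})
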