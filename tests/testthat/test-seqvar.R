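test_that("Wu-Kabat matches direct counts on worked columns", {
  expect_equal(wu_kabat(rep("A", 10)), 1)
  expect_equal(wu_kabat(c(rep("A", 5), "C", "C", "D", "D", "E")), 8)
  expect_equal(wu_kabat(c("A", "C")), 4)
  expect_equal(wu_kabat(c("A", "A", "-", "-")), 1)  # gaps excluded
  expect_error(wu_kabat(c("-", "-")), "all gaps")
})

test_that("Wu-Kabat equals a brute-force counter on 1000 random columns", {
  set.seed(7)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY-", "")[[1]]
  for (i in 1:1000) {
    col <- sample(aa, sample(2:30, 1), replace = TRUE)
    if (all(col == "-")) next
    expect_equal(wu_kabat(col), oracle_wu_kabat(col))
  }
})

test_that("variability profile classifies columns and skips reference gaps", {
  # 10 records; column 2 hypervariable (all different), rest conserved
  base <- "MKLVG"
  seqs <- vapply(1:10, function(i) {
    s <- strsplit(base, "")[[1]]
    s[2] <- strsplit("ACDEFGHIKL", "")[[1]][i]
    paste(s, collapse = "")
  }, character(1))
  m <- msa(paste0("s", 1:10), seqs, "s1")
  prof <- variability_profile(m)
  expect_equal(nrow(prof), 5L)
  expect_equal(prof$V[1], 1)
  expect_equal(prof$V[2], 10 * 10 / 1)
  expect_equal(as.character(prof$class[2]), "high")
  expect_equal(as.character(prof$class[1]), "intermediate")  # viv = 1
  # row order invariance
  m2 <- msa(paste0("s", 10:1), rev(seqs), "s1")
  expect_equal(variability_profile(m2)$V, prof$V)
  # degenerate single-sequence alignment
  expect_error(variability_profile(msa("a", "MKLVG", "a")), ">= 2")
})

test_that("a fully conserved alignment has V = viv = 1 everywhere", {
  m <- msa(paste0("s", 1:5), rep("MSWQAYV", 5), "s1")
  prof <- variability_profile(m)
  expect_true(all(prof$V == 1))
  expect_true(all(prof$viv == 1))
  expect_true(all(prof$class == "intermediate"))
})

test_that("region variants recover planted frequencies with exact suffixes", {
  tmpl <- "MSWQAYVDDHLMGQAMIMGIYD"
  gen <- make_msa(tmpl, data.frame(id = "9A7", start = 13, end = 22),
                  data.frame(region = "9A7",
                             seq = c("GQAMIMGIYD", "GQALVFGIYE",
                                     "GQALVCGIYE"),
                             freq = c(70, 20, 10)), n = 10, seed = 4)
  v <- extract_region_variants(gen$msa, list(id = "9A7", start = 13,
                                             end = 22), "seq1")
  expect_equal(v$label, c("9A7-0", "9A7-1", "9A7-2"))
  expect_equal(v$variant[1], "GQAMIMGIYD")   # template gets suffix 0
  expect_equal(v$count, c(7L, 2L, 1L))
  expect_equal(v$freq, c(70, 20, 10))
  expect_equal(sum(v$freq), 100, tolerance = 0.01)
})

test_that("identical sequences collapse to one variant at 100%", {
  m <- msa(paste0("s", 1:6), rep("MSWQAYV", 6), "s3")
  v <- extract_region_variants(m, list(id = "10A4", start = 1, end = 7),
                               "s3")
  expect_equal(nrow(v), 1L)
  expect_equal(v$freq, 100)
  expect_equal(v$suffix, 0L)
})

test_that("indel variants keep inserted residues and X records are excluded", {
  gen <- make_msa("MSWQAYVDDH", data.frame(id = "A1", start = 3, end = 8),
                  data.frame(region = "A1",
                             seq = c("WQAYVD", "WQAYVDG"),
                             freq = c(80, 20)), n = 10, seed = 9)
  v <- extract_region_variants(gen$msa, list(id = "A1", start = 3, end = 8),
                               "seq1")
  expect_setequal(v$variant, c("WQAYVD", "WQAYVDG"))
  expect_equal(v$count[v$variant == "WQAYVDG"], 2L)
  # plant an X in one record's region
  m <- gen$msa
  idx <- which(m$ids != "seq1")[1]
  substr(m$seqs[idx], 4, 4) <- "X"
  m2 <- msa(m$ids, m$seqs, "seq1")
  v2 <- extract_region_variants(m2, list(id = "A1", start = 3, end = 8),
                                "seq1")
  expect_equal(attr(v2, "n_included"), 9L)
  expect_equal(attr(v2, "excluded"), m$ids[idx])
  expect_equal(sum(v2$freq), 100, tolerance = 0.01)
  expect_error(extract_region_variants(m2, list(id = "A1", start = 3,
                                                end = 99), "seq1"),
               "invalid region span")
})

test_that("anchor analysis classifies frequency bands and shared/specific", {
  groups <- data.frame(seq_id = paste0("s", 1:50),
                       group = rep(paste0("g", 1:5), each = 10))
  # anchor 'L70' in 8/10 of every group -> high, shared
  calls <- data.frame(seq_id = unlist(lapply(0:4, function(g) {
    paste0("s", g * 10 + 1:8)
  })), anchor = "L70")
  # anchor 'I53' only in group 1 at 90% -> specific
  calls <- rbind(calls, data.frame(seq_id = paste0("s", 1:9),
                                   anchor = "I53"))
  # anchor 'V29' at 50% in group 2 -> intermediate
  calls <- rbind(calls, data.frame(seq_id = paste0("s", 11:15),
                                   anchor = "V29"))
  am <- anchor_analysis(calls, groups)
  l70 <- am[am$anchor == "L70", ]
  expect_true(all(l70$class == "high"))
  expect_true(all(l70$shared))
  i53 <- am[am$anchor == "I53", ]
  expect_true(all(i53$specific))
  expect_equal(i53$class[i53$group == "g1"], "high")
  expect_true(all(i53$class[i53$group != "g1"] == "absent"))
  v29 <- am[am$anchor == "V29" & am$group == "g2", ]
  expect_equal(v29$freq, 50)
  expect_equal(v29$class, "intermediate")
  expect_error(anchor_analysis(calls, rbind(groups, groups[1, ])),
               "exactly one group")
})
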