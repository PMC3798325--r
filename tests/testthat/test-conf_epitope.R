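# exposure table stub: keys A|i| over a toy structure
fake_exposure <- function(resno, rel) {
  data.frame(key = residue_key("A", resno, ""), chain = "A", resno = resno,
             icode = "", resname = "GLY", abs_sasa = rel, ref_sasa = 100,
             rel_sasa = rel, stringsAsFactors = FALSE)
}

line_structure <- function(resno, step = 3.8) {
  n <- length(resno)
  pdbstruct(data.frame(chain = "A", resno = resno, icode = "",
                       resname = "GLY", atom = "CA", element = "C",
                       x = seq_len(n) * step, y = 0, z = 0, occ = 1,
                       stringsAsFactors = FALSE), id = "line")
}

test_that("center selection is strictly above the threshold", {
  expo <- fake_exposure(1:3, c(80, 75, 74))
  expect_equal(select_centers(expo), "A|1|")
  expect_length(select_centers(fake_exposure(1:4, rep(50, 4))), 0L)
})

test_that("center merging is single-linkage with a strict radius", {
  st <- line_structure(1:3, step = 4.9)       # 1-2 and 2-3 at 4.9, 1-3 at 9.8
  grps <- merge_centers(residue_key("A", 1:3, ""), st)
  expect_length(grps, 1L)
  expect_setequal(grps[[1]], residue_key("A", 1:3, ""))
  st2 <- line_structure(1:2, step = 5.1)
  expect_length(merge_centers(residue_key("A", 1:2, ""), st2), 2L)
  st3 <- line_structure(1:2, step = 5.0)      # exactly 5.0 -> not merged
  expect_length(merge_centers(residue_key("A", 1:2, ""), st3), 2L)
})

test_that("expansion takes accessible residues within radius of any center", {
  # center at x=3.8; residue 2 at 9 A from it, residue 3 at 11 A
  st <- pdbstruct(data.frame(chain = "A", resno = 1:3, icode = "",
                             resname = "GLY", atom = "CA", element = "C",
                             x = c(3.8, 12.8, 14.8), y = 0, z = 0, occ = 1,
                             stringsAsFactors = FALSE), id = "exp")
  expo <- fake_exposure(1:3, c(80, 30, 30))
  mem <- expand_members(residue_key("A", 1, ""), expo, st)
  expect_setequal(mem, residue_key("A", 1:2, ""))
  # the same residue below the member threshold is excluded
  expo$rel_sasa[2] <- 20   # strict: 20 is NOT above 20
  mem2 <- expand_members(residue_key("A", 1, ""), expo, st)
  expect_equal(mem2, residue_key("A", 1, ""))
})

test_that("a lone center with nothing nearby stays a singleton", {
  st <- line_structure(1:2, step = 50)
  expo <- fake_exposure(1:2, c(90, 90))
  mem <- expand_members(residue_key("A", 1, ""), expo, st)
  expect_equal(mem, residue_key("A", 1, ""))
})

test_that("gap filling adds only single-residue gaps, once", {
  res <- structure_residues(line_structure(1:10))
  mem <- residue_key("A", c(5L, 7L), "")
  expect_setequal(fill_single_gaps(mem, res), residue_key("A", 5:7, ""))
  mem2 <- residue_key("A", c(5L, 8L), "")
  expect_setequal(fill_single_gaps(mem2, res), mem2)
  # no iteration: {4,6,8} fills 5 and 7 but not beyond
  mem3 <- residue_key("A", c(4L, 6L, 8L), "")
  expect_setequal(fill_single_gaps(mem3, res), residue_key("A", 4:8, ""))
})

test_that("gap filling equals an exhaustive scan on random member sets", {
  res <- structure_residues(line_structure(1:30))
  set.seed(42)
  for (rep in 1:25) {
    mem <- residue_key("A", sort(sample(1:30, sample(3:15, 1))), "")
    got <- fill_single_gaps(mem, res)
    memno <- as.integer(sub("^A\\|(\\d+)\\|$", "\\1", mem))
    want <- mem
    for (i in 1:30) {
      if (!(i %in% memno) && (i - 1L) %in% memno && (i + 1L) %in% memno) {
        want <- c(want, residue_key("A", i, ""))
      }
    }
    expect_setequal(got, want)
  }
})

test_that("a structure with no protruding residue yields an empty table", {
  tab <- predict_epitopes(make_globule(30, seed = 5)$structure)
  expect_equal(nrow(tab), 0L)
})

test_that("planted protruding residues become exactly the epitope centers", {
  g <- make_globule(80, protruding = c(10L, 40L, 70L), seed = 13)
  expo <- compute_exposure(g$structure)
  centers <- select_centers(expo)
  expect_setequal(centers, residue_key("A", c(10L, 40L, 70L), ""))
})

test_that("the full pipeline equals the composed brute-force oracle", {
  params <- epitope_params()
  set.seed(99)
  for (seed in c(1L, 2L, 3L)) {
    n <- 40L + 10L * seed
    plant <- sort(sample(seq_len(n), 3L))
    g <- make_globule(n, protruding = plant, seed = seed)
    expo <- compute_exposure(g$structure)
    tab <- predict_epitopes(g$structure, exposures = expo, params = params)
    want <- oracle_epitopes(g$structure, expo, params)
    expect_equal(nrow(tab), length(want))
    for (i in seq_len(nrow(tab))) {
      expect_setequal(epitope_members(tab, i), want[[i]])
    }
  }
})

test_that("epitope tables are deterministic and centers are disjoint", {
  g <- make_globule(70, protruding = c(5L, 6L, 50L), seed = 21)
  t1 <- predict_epitopes(g$structure)
  t2 <- predict_epitopes(g$structure)
  expect_identical(t1, t2)
  ctr <- strsplit(t1$centers, ";", fixed = TRUE)
  expect_equal(anyDuplicated(unlist(ctr)), 0L)
})

test_that("member sets grow monotonically with looser thresholds", {
  g <- make_globule(60, protruding = c(10L, 40L), seed = 3)
  expo <- compute_exposure(g$structure)
  base <- predict_epitopes(g$structure, exposures = expo)
  low_member <- predict_epitopes(g$structure, exposures = expo,
                                 params = epitope_params(member_threshold = 10))
  wide <- predict_epitopes(g$structure, exposures = expo,
                           params = epitope_params(expansion_radius = 14))
  for (i in seq_len(nrow(base))) {
    expect_true(all(epitope_members(base, i) %in%
                      epitope_members(low_member, i)))
    expect_true(all(epitope_members(base, i) %in%
                      epitope_members(wide, i)))
  }
})

test_that("the parameter sweep reports every table/basis combination", {
  g <- make_globule(40, protruding = 8L, seed = 6)
  sw <- epitope_parameter_sweep(g$structure)
  expect_equal(nrow(sw), 4L)
  expect_setequal(unique(sw$gxg_table), c("tien2013", "miller1987"))
  expect_setequal(unique(sw$basis), c("calpha", "min_heavy"))
  expect_true(all(sw$n_epitopes >= 0))
})
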