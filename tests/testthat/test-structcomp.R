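test_that("identical coordinate sets superpose at RMSD zero with identity rotation", {
  set.seed(5)
  A <- matrix(rnorm(30), 10)
  f <- kabsch_superpose(A, A)
  expect_equal(f$rmsd, 0, tolerance = 1e-9)
  expect_equal(f$rotation, diag(3), tolerance = 1e-9)
  expect_equal(det(f$rotation), 1, tolerance = 1e-9)
})

test_that("a planted rigid transform is recovered to 1e-9", {
  set.seed(6)
  A <- matrix(rnorm(60), 20)
  R <- rotation_matrix(c(1, -2, 0.5), 1.2)
  t <- c(4, -7, 2)
  B <- sweep(A %*% t(R), 2, -t)       # B = R A + t applied rowwise
  f <- kabsch_superpose(A, B)
  expect_equal(f$rmsd, 0, tolerance = 1e-9)
  # recovered transform must invert the planted one
  expect_equal(f$rotation %*% R, diag(3), tolerance = 1e-9)
})

test_that("noisy superposition matches an independent numeric minimiser", {
  set.seed(8)
  A <- matrix(rnorm(300, sd = 5), 100)
  B <- A + matrix(rnorm(300, sd = 0.5), 100)
  f <- kabsch_superpose(A, B)
  obj <- function(par) {
    R <- rotation_matrix(if (sum(par[1:3]^2) < 1e-12) c(1, 0, 0)
                         else par[1:3],
                         sqrt(sum(par[1:3]^2)))
    Bf <- B %*% t(R) + matrix(par[4:6], 100, 3, byrow = TRUE)
    sqrt(mean(rowSums((Bf - A)^2)))
  }
  fit <- optim(c(0.01, 0.01, 0.01, 0, 0, 0), obj, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 2000))
  expect_equal(f$rmsd, fit$value, tolerance = 1e-6)
  expect_lte(f$rmsd, fit$value + 1e-9)   # Kabsch is the global optimum
})

test_that("degenerate inputs are rejected", {
  A <- matrix(rnorm(6), 2)
  expect_error(kabsch_superpose(A, A), ">= 3")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("superposition is invariant to pre-rotating both sets", {
  set.seed(9)
  A <- matrix(rnorm(45), 15)
  B <- A + matrix(rnorm(45, sd = 0.3), 15)
  R0 <- rotation_matrix(c(0, 1, 1), 0.9)
  f1 <- kabsch_superpose(A, B)
  f2 <- kabsch_superpose(A %*% t(R0), B %*% t(R0))
  expect_equal(f1$rmsd, f2$rmsd, tolerance = 1e-9)
})

test_that("pairwise RMSD is symmetric, zero on self, exact for uniform shifts", {
  g <- make_globule(50, protruding = c(7L, 33L), seed = 11)
  s1 <- g$structure
  # identical copy
  s2 <- pdbstruct(s1$atoms, id = "copy")
  out <- pairwise_structure_rmsd(list(s1, s2))
  expect_equal(out$rmsd["copy", s1$id], 0, tolerance = 1e-6)
  expect_equal(out$rmsd, t(out$rmsd))
  expect_equal(diag(out$rmsd), setNames(c(0, 0), rownames(out$rmsd)))
  # planted per-residue displacement: every residue moved by d along a
  # direction that cannot be absorbed by a rigid transform
  a <- s1$atoms
  d <- 0.9
  radial <- as.matrix(a[, c("x", "y", "z")])
  radial <- radial / sqrt(rowSums(radial^2))
  a$x <- a$x + d * radial[, 1]
  a$y <- a$y + d * radial[, 2]
  a$z <- a$z + d * radial[, 3]
  s3 <- pdbstruct(a, id = "inflated")
  out2 <- pairwise_structure_rmsd(list(s1, s3))
  expect_equal(out2$rmsd[s1$id, "inflated"], d, tolerance = 0.02 * d)
})

test_that("alignment-derived mapping handles indels between chains", {
  g <- make_globule(40, seed = 15)
  a <- g$structure$atoms
  # give the chain a non-repetitive sequence so the alignment is unique
  one <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
           rev(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]))
  three <- names(epimap:::AA3to1)[match(one, epimap:::AA3to1)]
  a$resname <- three[a$resno]
  g$structure <- pdbstruct(a, id = g$structure$id)
  # delete residues 10-12 to force a gapped mapping
  s2 <- pdbstruct(a[!(a$resno %in% 10:12), , drop = FALSE], id = "del")
  out <- pairwise_structure_rmsd(list(g$structure, s2))
  expect_equal(out$n_pairs[1, 2], 37L)
  expect_equal(out$rmsd[1, 2], 0, tolerance = 1e-6)
})

test_that("cysteine pair distances match the planted geometry", {
  cys <- data.frame(i = c(5L, 30L), j = c(20L, 45L), dist = c(5.0, 6.5))
  g <- make_globule(50, cys_pairs = cys, seed = 1)
  tab <- cys_pair_distances(g$structure)
  expect_equal(nrow(tab), 6L)    # 4 cysteines -> 6 unordered pairs
  d1 <- tab$distance[tab$resno_a == 5 & tab$resno_b == 20]
  d2 <- tab$distance[tab$resno_a == 30 & tab$resno_b == 45]
  expect_equal(d1, 5.0, tolerance = 0.01)
  expect_equal(d2, 6.5, tolerance = 0.01)
  expect_true(tab$feasible[tab$resno_a == 5 & tab$resno_b == 20])
  # brute-force Euclidean check of all six distances
  ca <- calpha_coords(g$structure)
  for (k in seq_len(nrow(tab))) {
    want <- sqrt(sum((ca[paste0("A|", tab$resno_a[k], "|"), ] -
                        ca[paste0("A|", tab$resno_b[k], "|"), ])^2))
    expect_equal(tab$distance[k], want, tolerance = 1e-9)
  }
  # invariance under rigid motion
  a <- g$structure$atoms
  R <- rotation_matrix(c(2, 1, 0), 0.6)
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(R)
  a$x <- xyz[, 1] + 3; a$y <- xyz[, 2]; a$z <- xyz[, 3] - 5
  tab2 <- cys_pair_distances(pdbstruct(a, id = "moved"))
  expect_equal(tab2$distance, tab$distance, tolerance = 1e-6)
})

test_that("structures with fewer than two cysteines give an empty pair table", {
  g <- make_globule(30, seed = 2)
  expect_equal(nrow(cys_pair_distances(g$structure)), 0L)
})

test_that("sequence charge counts acidic and basic residues", {
  ch <- sequence_charge("DEK")
  expect_equal(ch$n_negative, 2L)
  expect_equal(ch$pct_negative, 200 / 3)
  expect_equal(ch$n_positive, 1L)
  expect_equal(ch$net_charge, -1)
  z <- sequence_charge("GGG")
  expect_equal(c(z$n_negative, z$n_positive, z$net_charge), c(0, 0, 0))
  h <- sequence_charge("HHH", include_his = TRUE)
  expect_equal(h$net_charge, 3)
  set.seed(12)
  s <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 131,
                    replace = TRUE), collapse = "")
  ch2 <- sequence_charge(s)
  aa <- strsplit(s, "")[[1]]
  expect_equal(ch2$n_negative, sum(aa == "D") + sum(aa == "E"))
  expect_equal(ch2$n_positive, sum(aa == "K") + sum(aa == "R"))
  expect_equal(ch2$pct_negative, 100 * ch2$n_negative / 131)
})
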