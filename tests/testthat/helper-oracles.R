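# Independent oracles and fixture builders. Everything here is written as
# plainly as possible (closed forms, exhaustive loops) and stays separate
# from the implementation paths it checks.

# exact area of an isolated solvent-expanded sphere
oracle_sphere_area <- function(r, probe = 1.4) 4 * pi * (r + probe)^2

# accessible area of sphere 1 (expanded radius rho1) partially covered by
# sphere 2 (rho2) at centre distance d: full area minus the spherical cap
# of sphere 1 lying inside sphere 2
oracle_two_sphere_area <- function(r1, r2, d, probe = 1.4) {
  rho1 <- r1 + probe; rho2 <- r2 + probe
  if (d >= rho1 + rho2) return(4 * pi * rho1^2)
  cos_theta <- (d^2 + rho1^2 - rho2^2) / (2 * d * rho1)
  cos_theta <- max(-1, min(1, cos_theta))
  h <- rho1 * (1 - cos_theta)
  4 * pi * rho1^2 - 2 * pi * rho1 * h
}

# direct-count Wu-Kabat: loops, no table()
oracle_wu_kabat <- function(column) {
  col <- column[!(column %in% c("-", ".")) & !is.na(column)]
  N <- length(col)
  distinct <- character(0)
  best <- 0L
  for (x in unique(col)) {
    distinct <- c(distinct, x)
    cnt <- 0L
    for (y in col) if (y == x) cnt <- cnt + 1L
    if (cnt > best) best <- cnt
  }
  N * length(distinct) / best
}

# brute-force composed three-rule epitope predictor over residue keys,
# written as literal double loops against a residue distance lookup
oracle_epitopes <- function(structure, exposures, params) {
  res <- structure_residues(structure)
  keys <- res$key
  d <- residue_distance_matrix(structure, keys, params$distance_basis)
  rel <- exposures$rel_sasa[match(keys, exposures$key)]
  centers <- keys[rel > params$center_threshold]
  if (length(centers) == 0L) return(list())
  # single linkage by repeated sweeps
  grp <- seq_along(centers)
  repeat {
    changed <- FALSE
    for (i in seq_along(centers)) for (j in seq_along(centers)) {
      if (i == j) next
      if (d[centers[i], centers[j]] < params$merge_radius &&
          grp[i] != grp[j]) {
        grp[grp == max(grp[i], grp[j])] <- min(grp[i], grp[j])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  groups <- split(centers, grp)
  minres <- sapply(groups, function(g) {
    min(res$resno[match(g, res$key)])
  })
  groups <- groups[order(minres)]
  lapply(groups, function(g) {
    members <- g
    for (k in keys) {
      if (k %in% g) next
      if (rel[match(k, keys)] <= params$member_threshold) next
      for (c0 in g) {
        if (d[k, c0] < params$expansion_radius) {
          members <- c(members, k)
          break
        }
      }
    }
    memno <- res$resno[match(members, res$key)]
    fills <- character(0)
    for (i in seq_len(nrow(res))) {
      if (res$key[i] %in% members) next
      if ((res$resno[i] - 1L) %in% memno && (res$resno[i] + 1L) %in% memno) {
        fills <- c(fills, res$key[i])
      }
    }
    sort(unique(c(members, fills)))
  })
}

# hand-written PDB fixture: one CA-style atom per row
write_toy_pdb <- function(path, resno, resname, xyz, chain = "A",
                          atom = "CA", element = "C", occ = 1,
                          altloc = "") {
  n <- length(resno)
  atomn <- rep_len(atom, n); eln <- rep_len(element, n)
  occn <- rep_len(occ, n); alt <- rep_len(altloc, n)
  chn <- rep_len(chain, n)
  lines <- vapply(seq_len(n), function(i) {
    sprintf("ATOM  %5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            i, paste0(" ", atomn[i]), alt[i], resname[i], chn[i], resno[i],
            xyz[i, 1], xyz[i, 2], xyz[i, 3], occn[i], 0, eln[i])
  }, character(1))
  writeLines(c(lines, "END"), path)
  path
}

write_toy_clustal <- function(path, ids, seqs) {
  pad <- formatC(ids, width = max(nchar(ids)) + 6L, flag = "-")
  lines <- c("CLUSTAL W (1.83) multiple sequence alignment", "", "",
             paste0(pad, seqs),
             paste0(strrep(" ", max(nchar(ids)) + 6L),
                    strrep("*", nchar(seqs[1]))))
  writeLines(lines, path)
  path
}

rotation_matrix <- function(axis, theta) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3,
              byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}
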