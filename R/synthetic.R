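# Seeded synthetic-data generators with machine-readable ground truth.
#
# The globule generator builds idealised single-chain C-alpha models whose
# exposure and distance properties are known by construction (and verified
# numerically before the structure is returned): shell residues occlude one
# another below the protruding threshold while planted residues, displaced
# radially outward, clear it. Realistic folds are deliberately not
# emulated - the algorithms under test depend only on distances and
# exposure.

#' Generate a synthetic globular structure with planted ground truth
#'
#' Residues sit on a sphere (golden-spiral packing, one C-alpha atom per
#' residue, glycine by default so the Gly-X-Gly-relative exposure of an
#' unoccluded atom exceeds 100%). Residues listed in `protruding` are
#' displaced radially outward until unoccluded (relative SASA > 75% under
#' the default [sasa_config()]); shell residues stay mutually occluding
#' (<= 75%). Cysteine pairs are repositioned to their exact target C-alpha
#' distances.
#'
#' @param n_res residue count (20..150).
#' @param protruding integer residue indices planted as protruding.
#' @param cys_pairs optional data.frame with columns `i`, `j`, `dist`:
#'   residue index pairs renamed to CYS and placed at `dist` Angstrom.
#' @param seed integer seed controlling the residue-to-shell-slot shuffle.
#' @param spacing target nearest-neighbour spacing on the shell (Angstrom).
#' @param protrusion radial displacement of planted residues (Angstrom).
#' @param verify numerically check the planted exposure classes with the
#'   default SASA engine before returning (recommended).
#' @return list with `structure` (a `pdbstruct`) and `truth`
#'   (`protruding` indices, `cys` table with exact distances, `seed`).
#' @export
make_globule <- function(n_res, protruding = integer(), cys_pairs = NULL,
                         seed = 1L, spacing = 3.8, protrusion = 8,
                         verify = TRUE) {
  if (n_res < 20L || n_res > 150L) {
    stop("n_res must be in 20..150 for a packable shell")
  }
  protruding <- as.integer(protruding)
  if (any(protruding < 1L | protruding > n_res)) {
    stop("planted protruding indices out of range")
  }
  if (!is.null(cys_pairs)) {
    ci <- c(cys_pairs$i, cys_pairs$j)
    if (any(ci < 1L | ci > n_res)) stop("cysteine indices out of range")
    if (anyDuplicated(ci)) stop("cysteine indices must be distinct")
    if (any(cys_pairs$dist <= 0)) stop("target distances must be > 0")
    if (any(ci %in% protruding)) {
      stop("cysteine and protruding indices must not overlap")
    }
  }
  R <- sqrt(n_res * spacing^2 / (4 * pi))
  shell <- golden_spiral_points(n_res) * R
  # seeded residue->slot assignment; local RNG, no global state leaks.
  # Planted residues take mutually distant slots (farthest-point sampling)
  # so removing them from the shell leaves only isolated holes and the
  # remaining shell residues keep enough occluding neighbours.
  k <- length(protruding)
  slot_of <- integer(n_res)
  if (k > 0L) {
    start <- local_sample(n_res, seed)[1L]
    psl <- farthest_point_slots(shell, k, start)
    slot_of[protruding] <- psl
    rest <- setdiff(seq_len(n_res), psl)
    slot_of[-protruding] <- rest[local_sample(length(rest), seed + 1L)]
  } else {
    slot_of <- local_sample(n_res, seed)
  }
  xyz <- shell[slot_of, , drop = FALSE]
  if (k > 0L) {
    scale <- (R + protrusion) / R
    xyz[protruding, ] <- xyz[protruding, , drop = FALSE] * scale
  }
  resname <- rep("GLY", n_res)
  truth_cys <- data.frame(i = integer(), j = integer(), dist = numeric())
  if (!is.null(cys_pairs)) {
    for (k in seq_len(nrow(cys_pairs))) {
      i <- cys_pairs$i[k]; j <- cys_pairs$j[k]; d <- cys_pairs$dist[k]
      resname[c(i, j)] <- "CYS"
      u <- xyz[j, ] - xyz[i, ]
      nu <- sqrt(sum(u^2))
      if (nu < 1e-8) u <- c(1, 0, 0) else u <- u / nu
      xyz[j, ] <- xyz[i, ] + u * d
    }
    truth_cys <- data.frame(i = cys_pairs$i, j = cys_pairs$j,
                            dist = cys_pairs$dist)
  }
  atoms <- data.frame(chain = "A", resno = seq_len(n_res), icode = "",
                      resname = resname, atom = "CA", element = "C",
                      x = round(xyz[, 1L], 3), y = round(xyz[, 2L], 3),
                      z = round(xyz[, 3L], 3), occ = 1,
                      stringsAsFactors = FALSE)
  st <- pdbstruct(atoms, id = sprintf("globule_n%d_s%d", n_res, seed))
  if (verify) {
    expo <- compute_exposure(st)
    prot <- which(expo$protruding)
    if (!setequal(prot, protruding)) {
      stop("globule construction failed: protruding set is {",
           paste(prot, collapse = ","), "} instead of {",
           paste(protruding, collapse = ","), "}")
    }
  }
  list(structure = st,
       truth = list(protruding = sort(protruding), cys = truth_cys,
                    seed = seed))
}

# greedy farthest-point sampling of k slots on the shell, deterministic
# given the start slot
farthest_point_slots <- function(shell, k, start) {
  chosen <- start
  if (k > 1L) {
    for (step in 2L:k) {
      dmin <- rep(Inf, nrow(shell))
      for (c0 in chosen) {
        d <- sqrt(rowSums(sweep(shell, 2L, shell[c0, ])^2))
        dmin <- pmin(dmin, d)
      }
      dmin[chosen] <- -Inf
      chosen <- c(chosen, which.max(dmin))
    }
  }
  chosen
}

# deterministic permutation from an explicit seed without touching the
# caller's RNG state
local_sample <- function(n, seed) {
  state <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(state)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", state, envir = globalenv())
    }
  })
  set.seed(seed)
  sample.int(n)
}

#' Generate a synthetic alignment with planted variant frequencies
#'
#' Builds `n` sequences from a template: inside each region a variant is
#' assigned by largest-remainder quota of its target frequency; outside the
#' regions all sequences carry the template. Region blocks are padded with
#' gaps to the longest variant, so indel variants stay column-consistent.
#' The first record always carries the template variant in every region and
#' serves as the alignment reference.
#'
#' @param template ungapped template amino-acid sequence.
#' @param regions data.frame with `id`, `start`, `end` (template
#'   coordinates, non-overlapping).
#' @param variants data.frame with `region`, `seq`, `freq` (percent; sums
#'   to 100 within each region; each region must include the template's own
#'   subsequence with freq > 0).
#' @param n number of sequences.
#' @param seed integer seed for the per-region assignment shuffle.
#' @return list with `msa` (an [msa()], ids `seq1..seqN`, reference
#'   `seq1`) and `truth` (per-region variant counts as planted).
#' @export
make_msa <- function(template, regions, variants, n, seed = 1L) {
  template <- toupper(template)
  tlen <- nchar(template)
  regions <- regions[order(regions$start), , drop = FALSE]
  if (any(regions$start < 1L | regions$end > tlen |
          regions$start > regions$end)) {
    stop("region span outside template")
  }
  if (nrow(regions) > 1L &&
      any(regions$start[-1L] <= regions$end[-nrow(regions)])) {
    stop("regions overlap")
  }
  truth <- list(); assign_tab <- list()
  for (r in seq_len(nrow(regions))) {
    rid <- regions$id[r]
    v <- variants[variants$region == rid, , drop = FALSE]
    if (nrow(v) == 0L) stop("no variants for region ", rid)
    if (abs(sum(v$freq) - 100) > 1e-6) {
      stop("variant frequencies for region ", rid, " sum to ",
           sum(v$freq), ", not 100")
    }
    tmpl_sub <- substr(template, regions$start[r], regions$end[r])
    ti <- match(tmpl_sub, v$seq)
    if (is.na(ti) || v$freq[ti] <= 0) {
      stop("region ", rid, " must include the template variant '",
           tmpl_sub, "' with freq > 0")
    }
    counts <- largest_remainder(v$freq, n)
    if (counts[ti] < 1L) stop("template variant quota is zero in region ",
                              rid)
    pool <- rep(seq_len(nrow(v)), counts)
    perm <- local_sample(n, seed + r)
    asg <- pool[perm]
    # record 1 is the reference: force it onto the template variant by
    # swapping with the first template carrier (quota counts unchanged)
    if (asg[1L] != ti) {
      sw <- which(asg == ti)[1L]
      asg[sw] <- asg[1L]; asg[1L] <- ti
    }
    truth[[rid]] <- data.frame(region = rid, variant = v$seq,
                               count = counts, stringsAsFactors = FALSE)
    assign_tab[[rid]] <- list(variants = v$seq, assignment = asg,
                              width = max(nchar(v$seq)))
  }
  # assemble aligned rows: template segments verbatim, region blocks padded
  rows <- character(n)
  for (s in seq_len(n)) {
    pos <- 1L; parts <- character(0)
    for (r in seq_len(nrow(regions))) {
      rid <- regions$id[r]
      if (regions$start[r] > pos) {
        parts <- c(parts, substr(template, pos, regions$start[r] - 1L))
      }
      at <- assign_tab[[rid]]
      vs <- at$variants[at$assignment[s]]
      parts <- c(parts, formatC(vs, width = -at$width, flag = "-"))
      pos <- regions$end[r] + 1L
    }
    if (pos <= tlen) parts <- c(parts, substr(template, pos, tlen))
    rows[s] <- paste(parts, collapse = "")
  }
  rows <- gsub(" ", "-", rows, fixed = TRUE)
  ids <- paste0("seq", seq_len(n))
  list(msa = msa(ids, rows, reference = "seq1"),
       truth = do.call(rbind, truth))
}

largest_remainder <- function(freq, n) {
  exact <- freq * n / 100
  base <- floor(exact)
  short <- n - sum(base)
  if (short > 0L) {
    extra <- order(exact - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1L
  }
  as.integer(base)
}

#' Write an alignment as FASTA
#'
#' Deterministic serialisation (60-column wrap) so identical alignments are
#' byte-identical on disk.
#'
#' @param msa an [msa()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_msa_fasta <- function(msa, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  for (i in seq_along(msa$ids)) {
    s <- msa$seqs[i]
    chunks <- substring(s, seq(1L, nchar(s), 60L),
                        pmin(seq(1L, nchar(s), 60L) + 59L, nchar(s)))
    writeLines(c(paste0(">", msa$ids[i]), chunks), con, sep = "\n")
  }
  invisible(path)
}
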