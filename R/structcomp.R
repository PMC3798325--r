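# Rigid-body superposition, cysteine disulfide feasibility and sequence
# formal-charge summaries.

#' Kabsch least-squares superposition
#'
#' Finds the proper rotation and translation minimising the RMSD between
#' mapped coordinate pairs (SVD solution with reflection correction), and
#' reports the RMSD after the transform is applied to `coords_b`.
#'
#' @param coords_a n x 3 reference coordinates.
#' @param coords_b n x 3 mobile coordinates.
#' @param mapping optional 2-column index matrix (rows of a, rows of b);
#'   default pairs rows 1:1.
#' @return list of class `superposition`: `rotation` (3 x 3, det +1),
#'   `translation` (length 3), `rmsd`, `n` (pair count). The transform maps
#'   b onto a as `b %*% t(rotation) + translation`.
#' @export
kabsch_superpose <- function(coords_a, coords_b, mapping = NULL) {
  A <- as.matrix(coords_a); B <- as.matrix(coords_b)
  if (!is.null(mapping)) {
    A <- A[mapping[, 1L], , drop = FALSE]
    B <- B[mapping[, 2L], , drop = FALSE]
  }
  if (nrow(A) != nrow(B)) stop("coordinate sets differ in pair count")
  n <- nrow(A)
  if (n < 3L) stop("superposition needs >= 3 mapped pairs, got ", n)
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2L, ca); B0 <- sweep(B, 2L, cb)
  sv <- svd(crossprod(B0, A0))   # H = B0^T A0
  if (sv$d[2L] < 1e-10 * max(sv$d[1L], 1)) {
    stop("degenerate geometry: mapped points are (near-)collinear")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  t <- ca - as.numeric(R %*% cb)
  Bfit <- B %*% t(R) + matrix(t, n, 3L, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((Bfit - A)^2)))
  structure(list(rotation = R, translation = t, rmsd = rmsd, n = n),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> %d pairs, RMSD %.4f A\n", x$n, x$rmsd))
  invisible(x)
}

# global sequence alignment (match +1, mismatch 0, gap -1) between two
# chain sequences, returning aligned index pairs at non-gap columns
align_chain_indices <- function(seq_a, seq_b) {
  aa <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")
  sm <- matrix(0, length(aa), length(aa), dimnames = list(aa, aa))
  diag(sm) <- 1
  al <- Biostrings::pairwiseAlignment(seq_a, seq_b, type = "global",
                                      substitutionMatrix = sm,
                                      gapOpening = 0, gapExtension = 1)
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  ia <- cumsum(pa != "-"); ib <- cumsum(sa != "-")
  keep <- pa != "-" & sa != "-"
  cbind(a = ia[keep], b = ib[keep])
}

#' Pairwise alignment-mapped C-alpha RMSD between structures
#'
#' For every structure pair, the two chain sequences are globally aligned
#' (match +1, mismatch 0, gap -1), C-alpha pairs are taken at aligned
#' non-gap columns and superposed with [kabsch_superpose()]. With
#' `trim_outliers`, pairs further than 2 standard deviations from the mean
#' deviation are iteratively removed and the superposition repeated until
#' stable (the refinement performed by interactive structure viewers).
#'
#' @param structures list of `pdbstruct` objects.
#' @param chains chain id per structure (recycled; default: first chain of
#'   each).
#' @param trim_outliers logical; iterative 2-sigma trimming.
#' @return list with `rmsd` (symmetric matrix, zero diagonal) and `n_pairs`
#'   (mapped pair counts). Unmappable pairs carry `NA`.
#' @export
pairwise_structure_rmsd <- function(structures, chains = NULL,
                                    trim_outliers = FALSE) {
  m <- length(structures)
  if (m < 2L) stop("need >= 2 structures")
  if (is.null(chains)) {
    chains <- vapply(structures, function(s) s$atoms$chain[1L], character(1))
  } else {
    chains <- rep_len(chains, m)
  }
  ids <- vapply(structures, function(s) s$id, character(1))
  seqs <- mapply(chain_sequence, structures, chains)
  cas <- mapply(calpha_coords, structures, chains, SIMPLIFY = FALSE)
  rmsd <- matrix(0, m, m, dimnames = list(ids, ids))
  npairs <- matrix(0L, m, m, dimnames = list(ids, ids))
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (j <= i) next
      res <- tryCatch({
        map <- align_chain_indices(seqs[i], seqs[j])
        A <- cas[[i]][map[, "a"], , drop = FALSE]
        B <- cas[[j]][map[, "b"], , drop = FALSE]
        fit <- kabsch_superpose(A, B)
        if (trim_outliers) fit <- trim_superpose(A, B)
        list(rmsd = fit$rmsd, n = fit$n)
      }, error = function(e) list(rmsd = NA_real_, n = NA_integer_))
      rmsd[i, j] <- rmsd[j, i] <- res$rmsd
      npairs[i, j] <- npairs[j, i] <- res$n
    }
  }
  list(rmsd = rmsd, n_pairs = npairs)
}

trim_superpose <- function(A, B, max_iter = 10L) {
  fit <- kabsch_superpose(A, B)
  for (k in seq_len(max_iter)) {
    Bfit <- B %*% t(fit$rotation) +
      matrix(fit$translation, nrow(B), 3L, byrow = TRUE)
    dev <- sqrt(rowSums((Bfit - A)^2))
    keep <- dev <= mean(dev) + 2 * stats::sd(dev)
    if (all(keep) || sum(keep) < 3L) break
    A <- A[keep, , drop = FALSE]; B <- B[keep, , drop = FALSE]
    fit <- kabsch_superpose(A, B)
  }
  fit
}

#' Cysteine C-alpha pair distances and disulfide feasibility
#'
#' Lists every unordered cysteine pair of a chain with its C-alpha
#' distance; a pair is flagged feasible when the distance falls inside the
#' window compatible with cystine stereochemistry (default 3.0-7.5 A).
#'
#' @param structure a `pdbstruct`.
#' @param window numeric `(min, max)` feasibility window in Angstrom.
#' @param chain chain id (default: first chain).
#' @return data.frame of class `cys_pair_table`: `cys_a`, `cys_b` (labels
#'   like `"C13"`), `resno_a`, `resno_b`, `distance`, `feasible`. Empty with
#'   fewer than two cysteines.
#' @export
cys_pair_distances <- function(structure, window = c(3.0, 7.5),
                               chain = NULL) {
  res <- structure_residues(structure, chain = chain %||%
                              structure$atoms$chain[1L])
  cys <- res[res$resname == "CYS", , drop = FALSE]
  empty <- data.frame(cys_a = character(), cys_b = character(),
                      resno_a = integer(), resno_b = integer(),
                      distance = numeric(), feasible = logical(),
                      stringsAsFactors = FALSE)
  class(empty) <- c("cys_pair_table", "data.frame")
  if (nrow(cys) < 2L) return(empty)
  ca <- calpha_coords(structure, chain %||% structure$atoms$chain[1L])
  miss <- setdiff(cys$key, rownames(ca))
  if (length(miss) > 0L) {
    stop("cysteine(s) lacking a C-alpha atom: ",
         paste(miss, collapse = ", "))
  }
  pairs <- utils::combn(seq_len(nrow(cys)), 2L)
  d <- vapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    sqrt(sum((ca[cys$key[i], ] - ca[cys$key[j], ])^2))
  }, numeric(1))
  out <- data.frame(cys_a = paste0("C", cys$resno[pairs[1L, ]]),
                    cys_b = paste0("C", cys$resno[pairs[2L, ]]),
                    resno_a = cys$resno[pairs[1L, ]],
                    resno_b = cys$resno[pairs[2L, ]],
                    distance = d,
                    feasible = d >= window[1] & d <= window[2],
                    stringsAsFactors = FALSE)
  class(out) <- c("cys_pair_table", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Formal-charge summary of a protein sequence
#'
#' Counts acidic (Asp, Glu) and basic (Lys, Arg; His optional) residues.
#' Net formal charge is basic minus acidic; termini and unknown residues
#' are ignored (unknowns still count toward the length used for the
#' percentages).
#'
#' @param sequence one-letter amino-acid string.
#' @param include_his count histidine as positive.
#' @return data.frame row of class `charge_summary`: `length`, `n_negative`,
#'   `pct_negative`, `n_positive`, `pct_positive`, `net_charge`.
#' @export
sequence_charge <- function(sequence, include_his = FALSE) {
  aa <- strsplit(toupper(sequence), "")[[1]]
  if (length(aa) == 0L) stop("empty sequence")
  pos_set <- if (include_his) c("K", "R", "H") else c("K", "R")
  neg <- sum(aa %in% c("D", "E"))
  pos <- sum(aa %in% pos_set)
  out <- data.frame(length = length(aa), n_negative = neg,
                    pct_negative = 100 * neg / length(aa),
                    n_positive = pos,
                    pct_positive = 100 * pos / length(aa),
                    net_charge = pos - neg)
  class(out) <- c("charge_summary", "data.frame")
  out
}
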