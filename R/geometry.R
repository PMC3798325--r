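# Residue-level coordinate extraction and distances.

#' C-alpha coordinates of a chain
#'
#' @param structure a `pdbstruct`.
#' @param chain chain id (default: first chain).
#' @return numeric matrix (n x 3) with residue keys as row names, in chain
#'   order. Residues without a CA atom are dropped.
#' @export
calpha_coords <- function(structure, chain = NULL) {
  a <- structure$atoms
  if (is.null(chain)) chain <- a$chain[1L]
  a <- a[a$chain == chain & a$atom == "CA", , drop = FALSE]
  key <- residue_key(a$chain, a$resno, a$icode)
  a <- a[!duplicated(key), , drop = FALSE]
  m <- as.matrix(a[, c("x", "y", "z")])
  rownames(m) <- residue_key(a$chain, a$resno, a$icode)
  m
}

# per-residue heavy-atom coordinate list keyed by residue key
heavy_coords <- function(structure, chain = NULL) {
  a <- structure$atoms
  if (is.null(chain)) chain <- a$chain[1L]
  a <- a[a$chain == chain & a$element != "H", , drop = FALSE]
  key <- residue_key(a$chain, a$resno, a$icode)
  split.data.frame(as.matrix(a[, c("x", "y", "z")]), key)
}

# residue-residue distance matrix over the given keys;
# basis "calpha" uses CA-CA distances, "min_heavy" the minimum over all
# heavy-atom pairs
residue_distance_matrix <- function(structure, keys,
                                    basis = c("calpha", "min_heavy"),
                                    chain = NULL) {
  basis <- match.arg(basis)
  if (basis == "calpha") {
    ca <- calpha_coords(structure, chain)
    miss <- setdiff(keys, rownames(ca))
    if (length(miss) > 0L) {
      stop("residue(s) missing a CA atom: ", paste(miss, collapse = ", "))
    }
    m <- as.matrix(stats::dist(ca[keys, , drop = FALSE]))
  } else {
    hv <- heavy_coords(structure, chain)
    miss <- setdiff(keys, names(hv))
    if (length(miss) > 0L) {
      stop("residue(s) without heavy atoms: ", paste(miss, collapse = ", "))
    }
    n <- length(keys)
    m <- matrix(0, n, n, dimnames = list(keys, keys))
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (j <= i) next
        A <- hv[[keys[i]]]; B <- hv[[keys[j]]]
        d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
        m[i, j] <- m[j, i] <- sqrt(max(0, min(d2)))
      }
    }
  }
  m
}
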