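# Mapping linear B-/T-cell epitopes onto structures and classifying their
# overlap with conformational epitopes.

#' Map a linear epitope onto a chain by sequence match
#'
#' Ungapped scan of all offsets; the best-scoring placement (fewest
#' mismatches, ties to the leftmost) wins, provided it does not exceed
#' `max_mismatches`. Linear epitopes are always localised by sequence
#' match, never by foreign coordinate numbering.
#'
#' @param structure a `pdbstruct`.
#' @param label epitope label (e.g. `"10A4"`).
#' @param sequence defining amino-acid sequence of the epitope.
#' @param kind `"bcell"` or `"tcell"`.
#' @param max_mismatches maximum tolerated substitutions (default 2).
#' @param chain chain id (default: first chain).
#' @return list of class `linear_epitope`: `label`, `kind`, `sequence`,
#'   `start` (1-based chain position), `mismatches`, `span` (residue keys),
#'   `resno` (author numbers).
#' @export
map_linear <- function(structure, label, sequence,
                       kind = c("bcell", "tcell"), max_mismatches = 2L,
                       chain = NULL) {
  kind <- match.arg(kind)
  res <- structure_residues(structure,
                            chain = chain %||% structure$atoms$chain[1L])
  chainseq <- aa_three_to_one(res$resname)
  pat <- strsplit(toupper(sequence), "")[[1]]
  L <- length(pat); n <- length(chainseq)
  if (L > n) stop("epitope '", label, "' longer than chain")
  mism <- vapply(seq_len(n - L + 1L), function(o) {
    sum(chainseq[o:(o + L - 1L)] != pat)
  }, integer(1))
  best <- which.min(mism)   # leftmost minimum
  if (mism[best] > max_mismatches) {
    stop("epitope '", label, "' not mappable within ", max_mismatches,
         " mismatches; best candidate at chain position ", best, " with ",
         mism[best], " mismatches")
  }
  idx <- best:(best + L - 1L)
  structure(list(label = label, kind = kind,
                 sequence = paste(pat, collapse = ""), start = best,
                 mismatches = mism[best], span = res$key[idx],
                 resno = res$resno[idx]),
            class = "linear_epitope")
}

#' Classify overlap between a conformational and a linear epitope
#'
#' `total` when every residue of the linear span belongs to the
#' conformational member set, `none` when they share no residue, `partial`
#' otherwise. Containment of the conformational epitope inside the linear
#' span reports as `partial` with full shared count.
#'
#' @param conf_members character vector of conformational-epitope residue
#'   keys.
#' @param linear a `linear_epitope` (or character vector of residue keys).
#' @return list with `class` (`"total"`, `"partial"`, `"none"`) and
#'   `shared` (residue count).
#' @export
classify_overlap <- function(conf_members, linear) {
  span <- if (inherits(linear, "linear_epitope")) linear$span else linear
  shared <- length(intersect(conf_members, span))
  cls <- if (shared == 0L) "none"
         else if (shared == length(span)) "total"
         else "partial"
  list(class = cls, shared = shared)
}

#' Overlap matrix and rollup between conformational and linear epitopes
#'
#' @param epitopes an `epitope_table` from [predict_epitopes()].
#' @param linears list of `linear_epitope` objects mapped on the same
#'   structure.
#' @return list of class `overlap_report`: `matrix` (long data.frame of
#'   epitope x linear classifications with shared counts) and `rollup` (per
#'   conformational epitope: overlaps B only / T only / both / neither).
#' @export
overlap_summary <- function(epitopes, linears) {
  labels <- vapply(linears, function(l) l$label, character(1))
  kinds <- vapply(linears, function(l) l$kind, character(1))
  rows <- list(); k <- 0L
  hitsB <- hitsT <- rep(FALSE, nrow(epitopes))
  for (i in seq_len(nrow(epitopes))) {
    mem <- epitope_members(epitopes, i)
    for (j in seq_along(linears)) {
      ov <- classify_overlap(mem, linears[[j]])
      k <- k + 1L
      rows[[k]] <- data.frame(epitope_id = epitopes$epitope_id[i],
                              linear = labels[j], kind = kinds[j],
                              class = ov$class, shared = ov$shared,
                              stringsAsFactors = FALSE)
      if (ov$class != "none") {
        if (kinds[j] == "bcell") hitsB[i] <- TRUE else hitsT[i] <- TRUE
      }
    }
  }
  mat <- if (k > 0L) do.call(rbind, rows) else
    data.frame(epitope_id = integer(), linear = character(),
               kind = character(), class = character(), shared = integer(),
               stringsAsFactors = FALSE)
  rollup <- data.frame(epitope_id = epitopes$epitope_id,
                       category = ifelse(hitsB & hitsT, "both",
                                  ifelse(hitsB, "B-only",
                                  ifelse(hitsT, "T-only", "neither"))),
                       stringsAsFactors = FALSE)
  structure(list(matrix = mat, rollup = rollup), class = "overlap_report")
}
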