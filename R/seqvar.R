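# Alignment-column variability, epitope-variant enumeration and T-cell
# anchor frequency analysis.

#' Wu-Kabat variability of an alignment column
#'
#' V = N * k / n over the non-gap residues of the column, where N is the
#' number of residues, k the number of distinct residues and n the count of
#' the most frequent one. V is 1 for a fully conserved column.
#'
#' @param column character vector of single residues (`-` and `.` are
#'   treated as gaps and excluded).
#' @return numeric V (>= 1).
#' @export
wu_kabat <- function(column) {
  col <- column[!(column %in% c("-", ".")) & !is.na(column)]
  if (length(col) == 0L) stop("undefined column: all gaps")
  tab <- table(col)
  length(col) * length(tab) / max(tab)
}

#' Per-position variability profile of an alignment
#'
#' Computes raw Wu-Kabat V for every ungapped reference position and a
#' normalised index viv = V / median(V) over all positions, classified as
#' `low` (viv < low threshold), `intermediate` (low <= viv <= high) or
#' `high` (viv > high threshold). Columns where the reference carries a gap
#' are skipped.
#'
#' @param msa an [msa()] object with at least 2 records.
#' @param thresholds numeric `(low, high)` viv cut-offs, default `c(1, 3)`.
#' @return data.frame with `ref_pos`, `column`, `V`, `viv`, `class`.
#' @export
variability_profile <- function(msa, thresholds = c(1, 3)) {
  if (length(msa$ids) < 2L) stop("variability requires >= 2 sequences")
  mat <- do.call(rbind, strsplit(msa$seqs, ""))
  cols <- msa$ref_map
  V <- vapply(cols, function(j) wu_kabat(mat[, j]), numeric(1))
  viv <- V / stats::median(V)
  cls <- ifelse(viv < thresholds[1], "low",
                ifelse(viv > thresholds[2], "high", "intermediate"))
  data.frame(ref_pos = seq_along(cols), column = cols, V = V, viv = viv,
             class = factor(cls, levels = c("low", "intermediate", "high")),
             stringsAsFactors = FALSE)
}

#' Enumerate sequence variants of a region across an alignment
#'
#' The region is a span in ungapped reference coordinates; each record's
#' ungapped subsequence over the corresponding alignment columns (including
#' insertion columns inside the span) is collected, so indels appear as
#' length-variant strings. Records whose region contains an unknown residue
#' (`X`) are excluded and reported in the `excluded` attribute. Variants are
#' suffix-labelled: suffix 0 is the designated template's variant, suffixes
#' 1..m follow descending frequency (ties by first occurrence in record
#' order).
#'
#' @param msa an [msa()] object.
#' @param region list or data.frame row with `id`, `start`, `end` (1-based
#'   inclusive reference positions).
#' @param template record identifier whose variant gets suffix 0.
#' @return data.frame of class `variant_table` with `region`, `suffix`,
#'   `label` (e.g. `"A2-1"`), `variant`, `count`, `freq` (%); attributes
#'   `excluded` (record ids) and `n_included`.
#' @export
extract_region_variants <- function(msa, region, template) {
  start <- as.integer(region$start); end <- as.integer(region$end)
  if (is.na(start) || is.na(end) || start < 1L || end < start ||
      end > length(msa$ref_map)) {
    stop("invalid region span [", start, ", ", end,
         "] for reference of length ", length(msa$ref_map))
  }
  if (!template %in% msa$ids) stop("template record '", template,
                                   "' not found")
  c1 <- msa$ref_map[start]
  # insertion columns immediately after the last reference position belong
  # to the region, so indel variants keep their inserted residues
  c2 <- if (end < length(msa$ref_map)) msa$ref_map[end + 1L] - 1L
        else nchar(msa$seqs[1L])
  sub <- substr(msa$seqs, c1, c2)
  sub <- gsub("-", "", sub, fixed = TRUE)
  bad <- grepl("X", sub, fixed = TRUE) | sub == ""
  ids <- msa$ids[!bad]
  variants <- sub[!bad]
  if (length(variants) == 0L) stop("no usable sequences in region ",
                                   region$id)
  if (bad[match(template, msa$ids)]) {
    stop("template record region contains unknown residues")
  }
  uniq <- unique(variants)   # first-occurrence order
  count <- vapply(uniq, function(v) sum(variants == v), integer(1))
  freq <- 100 * count / length(variants)
  tmpl_variant <- sub[match(template, msa$ids)]
  is_tmpl <- uniq == tmpl_variant
  rest <- order(-count[!is_tmpl])
  ordered <- c(uniq[is_tmpl], uniq[!is_tmpl][rest])
  i <- match(ordered, uniq)
  out <- data.frame(region = region$id,
                    suffix = seq_along(ordered) - 1L,
                    label = paste0(region$id, "-", seq_along(ordered) - 1L),
                    variant = ordered, count = unname(count[i]),
                    freq = unname(freq[i]), stringsAsFactors = FALSE)
  attr(out, "excluded") <- msa$ids[bad]
  attr(out, "n_included") <- length(variants)
  class(out) <- c("variant_table", "data.frame")
  out
}

#' T-cell anchor presence/frequency matrix across sequence groups
#'
#' For each anchor motif (identified by its initial residue label, e.g.
#' `"L70"`) and each group of sequences, the percentage of sequences in the
#' group carrying the anchor is classified as `absent` (0%), `low`
#' (< low threshold), `high` (> high threshold) or `intermediate`. An anchor
#' is `shared` when high in every group and `specific` when high in exactly
#' one.
#'
#' @param anchor_calls data.frame with columns `seq_id` and `anchor` (one
#'   row per anchor occurrence per sequence).
#' @param groups data.frame with columns `seq_id` and `group` covering every
#'   sequence exactly once.
#' @param thresholds numeric `(high, low)` percentage cut-offs, default
#'   `c(70, 30)`.
#' @return data.frame of class `anchor_matrix`: one row per anchor x group
#'   with `freq` and `class`, plus per-anchor `shared`/`specific` flags.
#' @export
anchor_analysis <- function(anchor_calls, groups, thresholds = c(70, 30)) {
  if (anyDuplicated(groups$seq_id)) {
    stop("each sequence must belong to exactly one group")
  }
  gsizes <- table(groups$group)
  if (any(gsizes == 0L)) stop("empty group")
  unknown <- setdiff(anchor_calls$seq_id, groups$seq_id)
  if (length(unknown) > 0L) {
    stop("anchor calls for ungrouped sequence(s): ",
         paste(unknown, collapse = ", "))
  }
  anchors <- unique(anchor_calls$anchor)
  gnames <- names(gsizes)
  rows <- list()
  for (a in anchors) {
    carriers <- unique(anchor_calls$seq_id[anchor_calls$anchor == a])
    freq <- vapply(gnames, function(g) {
      in_g <- groups$seq_id[groups$group == g]
      100 * sum(in_g %in% carriers) / length(in_g)
    }, numeric(1))
    cls <- ifelse(freq == 0, "absent",
                  ifelse(freq > thresholds[1], "high",
                         ifelse(freq < thresholds[2], "low",
                                "intermediate")))
    high <- cls == "high"
    rows[[a]] <- data.frame(anchor = a, group = gnames, freq = unname(freq),
                            class = unname(cls),
                            shared = all(high), specific = sum(high) == 1L,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("anchor_matrix", "data.frame")
  out
}
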