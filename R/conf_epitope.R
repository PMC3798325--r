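# Three-rule conformational B-cell epitope prediction.
#
# (i)   residues with relative SASA strictly above the center threshold are
#       epitope centers; centers closer than the merge radius are combined
#       (single-linkage, so chains of centers coalesce);
# (ii)  every partially accessible residue (relative SASA strictly above the
#       member threshold) within the expansion radius of ANY center of the
#       group joins the epitope;
# (iii) single residues flanked in author-number sequence by two members are
#       filled in, once, after expansion.
#
# All comparisons are strict, matching the published wording (">75%",
# ">20%", "closer than 0.5 nm", "within 1 nm").

#' Parameters of the conformational epitope predictor
#'
#' @param center_threshold relative SASA (%) above which a residue is a
#'   center (default 75).
#' @param member_threshold relative SASA (%) above which a residue may join
#'   an epitope (default 20).
#' @param merge_radius centers closer than this (Angstrom) merge into one
#'   epitope (default 5, i.e. 0.5 nm).
#' @param expansion_radius residues within this distance (Angstrom) of a
#'   center join the epitope (default 10, i.e. 1 nm, the typical span of an
#'   antigen-antibody contact surface).
#' @param distance_basis `"calpha"` (default) or `"min_heavy"`.
#' @return list of class `epitope_params`.
#' @export
epitope_params <- function(center_threshold = 75, member_threshold = 20,
                           merge_radius = 5, expansion_radius = 10,
                           distance_basis = c("calpha", "min_heavy")) {
  distance_basis <- match.arg(distance_basis)
  if (member_threshold >= center_threshold) {
    stop("member_threshold must be below center_threshold")
  }
  if (merge_radius <= 0 || expansion_radius <= 0) stop("radii must be > 0")
  structure(list(center_threshold = center_threshold,
                 member_threshold = member_threshold,
                 merge_radius = merge_radius,
                 expansion_radius = expansion_radius,
                 distance_basis = distance_basis),
            class = "epitope_params")
}

#' Select epitope center residues
#'
#' @param exposures output of [compute_exposure()] for one chain.
#' @param params an [epitope_params()].
#' @return character vector of residue keys with relative SASA strictly
#'   above the center threshold (possibly empty).
#' @export
select_centers <- function(exposures, params = epitope_params()) {
  exposures$key[exposures$rel_sasa > params$center_threshold]
}

#' Merge nearby centers into epitope seed groups
#'
#' Single-linkage connected components of the graph joining center pairs at
#' distance strictly below the merge radius.
#'
#' @param centers residue keys from [select_centers()].
#' @param structure the `pdbstruct`.
#' @param params an [epitope_params()].
#' @param chain chain id (default: first chain).
#' @return list of character vectors (groups), ordered by lowest residue
#'   number within each group.
#' @export
merge_centers <- function(centers, structure, params = epitope_params(),
                          chain = NULL) {
  if (length(centers) == 0L) return(list())
  d <- residue_distance_matrix(structure, centers, params$distance_basis,
                               chain)
  n <- length(centers)
  comp <- seq_len(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      if (d[i, j] < params$merge_radius) {
        old <- comp[j]; new <- comp[i]
        comp[comp == old] <- new
      }
    }
  }
  resno <- as.integer(sub("^[^|]*\\|([^|]*)\\|.*$", "\\1", centers))
  groups <- split(centers, comp)
  ord <- order(vapply(split(resno, comp), min, integer(1)))
  unname(groups[ord])
}

#' Expand a center group to its accessible neighbourhood
#'
#' @param group character vector of center residue keys.
#' @param exposures output of [compute_exposure()].
#' @param structure the `pdbstruct`.
#' @param params an [epitope_params()].
#' @param chain chain id (default: first chain).
#' @return character vector of member residue keys (group plus proximal
#'   accessible residues), in chain order.
#' @export
expand_members <- function(group, exposures, structure,
                           params = epitope_params(), chain = NULL) {
  if (length(group) == 0L) stop("empty center group")
  cand <- exposures$key[exposures$rel_sasa > params$member_threshold]
  cand <- setdiff(cand, group)
  members <- group
  if (length(cand) > 0L) {
    keys <- c(group, cand)
    d <- residue_distance_matrix(structure, keys, params$distance_basis,
                                 chain)
    dmin <- apply(d[cand, group, drop = FALSE], 1L, min)
    members <- c(group, cand[dmin < params$expansion_radius])
  }
  exposures$key[exposures$key %in% members]
}

#' Fill single-residue sequence gaps in a member set
#'
#' A residue whose immediate sequence neighbours (author number - 1 and + 1,
#' same chain) are both members is added. Applied once; two-residue gaps are
#' never filled.
#'
#' @param members character vector of member residue keys (one chain).
#' @param residues residue table for that chain ([structure_residues()]).
#' @return member keys including gap fills, in chain order.
#' @export
fill_single_gaps <- function(members, residues) {
  memno <- residues$resno[residues$key %in% members]
  gaps <- residues$key[!(residues$key %in% members) &
                         (residues$resno - 1L) %in% memno &
                         (residues$resno + 1L) %in% memno]
  residues$key[residues$key %in% c(members, gaps)]
}

#' Predict conformational epitopes on a chain
#'
#' Runs center selection, center merging, member expansion and single-gap
#' filling; epitopes are numbered in ascending order of their smallest
#' center residue number. Epitopes may share members through expansion, but
#' their center sets are disjoint.
#'
#' @param structure a `pdbstruct`.
#' @param exposures optional precomputed [compute_exposure()] table for the
#'   chain; computed with `config` when missing.
#' @param params an [epitope_params()].
#' @param chain chain id (default: first chain in the file).
#' @param config [sasa_config()] used when `exposures` is missing.
#' @return data.frame of class `epitope_table` with one row per epitope:
#'   `structure`, `epitope_id`, `centers`, `members` (semicolon-joined
#'   `chain:resno:resname`), `n_residues` and `provenance`
#'   (`center`/`proximity`/`gap_fill`, aligned with `members`).
#' @export
predict_epitopes <- function(structure, exposures = NULL,
                             params = epitope_params(), chain = NULL,
                             config = sasa_config()) {
  if (is.null(chain)) chain <- structure$atoms$chain[1L]
  if (is.null(exposures)) {
    exposures <- compute_exposure(structure, config, chain = chain)
  }
  residues <- structure_residues(structure, chain = chain)
  centers <- select_centers(exposures, params)
  groups <- merge_centers(centers, structure, params, chain)
  rows <- lapply(seq_along(groups), function(k) {
    grp <- groups[[k]]
    expanded <- expand_members(grp, exposures, structure, params, chain)
    members <- fill_single_gaps(expanded, residues)
    prov <- ifelse(members %in% grp, "center",
                   ifelse(members %in% expanded, "proximity", "gap_fill"))
    lab <- residue_label(residues, members)
    data.frame(structure = structure$id, epitope_id = k,
               centers = paste(residue_label(residues, grp), collapse = ";"),
               members = paste(lab, collapse = ";"),
               n_residues = length(members),
               provenance = paste(prov, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows) > 0L) {
    do.call(rbind, rows)
  } else {
    data.frame(structure = character(), epitope_id = integer(),
               centers = character(), members = character(),
               n_residues = integer(), provenance = character(),
               stringsAsFactors = FALSE)
  }
  class(out) <- c("epitope_table", "data.frame")
  out
}

residue_label <- function(residues, keys) {
  i <- match(keys, residues$key)
  paste(residues$chain[i], residues$resno[i], residues$resname[i], sep = ":")
}

#' Member residue keys of an epitope table row
#'
#' @param table an `epitope_table`.
#' @param i row index.
#' @return character vector of residue keys (`chain|resno|icode` with empty
#'   insertion codes).
#' @export
epitope_members <- function(table, i) {
  trip <- strsplit(table$members[i], ";", fixed = TRUE)[[1]]
  parts <- strsplit(trip, ":", fixed = TRUE)
  vapply(parts, function(p) residue_key(p[1], as.integer(p[2]), ""),
         character(1))
}

#' Sensitivity sweep of the epitope predictor
#'
#' Re-runs [predict_epitopes()] over combinations of Gly-X-Gly reference
#' table and distance basis, reporting how the epitope count and size range
#' respond to these choices.
#'
#' @param structure a `pdbstruct`.
#' @param chain chain id (default: first chain).
#' @param gxg_tables character vector of shipped reference table names.
#' @param bases distance bases to try.
#' @param params base [epitope_params()]; the distance basis is overridden
#'   per sweep cell.
#' @return data.frame with one row per combination: `gxg_table`, `basis`,
#'   `n_epitopes`, `min_size`, `max_size`.
#' @export
epitope_parameter_sweep <- function(structure, chain = NULL,
                                    gxg_tables = c("tien2013", "miller1987"),
                                    bases = c("calpha", "min_heavy"),
                                    params = epitope_params()) {
  grid <- expand.grid(gxg_table = gxg_tables, basis = bases,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- sasa_config(ref_table = grid$gxg_table[i])
    p <- params
    p$distance_basis <- grid$basis[i]
    tab <- predict_epitopes(structure, params = p, chain = chain,
                            config = cfg)
    data.frame(gxg_table = grid$gxg_table[i], basis = grid$basis[i],
               n_epitopes = nrow(tab),
               min_size = if (nrow(tab)) min(tab$n_residues) else NA_integer_,
               max_size = if (nrow(tab)) max(tab$n_residues) else NA_integer_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
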