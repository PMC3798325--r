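# Shrake-Rupley solvent accessible surface area.
#
# Per-atom areas come from a deterministic golden-spiral point set on each
# solvent-expanded sphere; a sample point is accessible when it lies outside
# every neighbouring expanded sphere. Relative (percentage) exposure
# normalises each residue's summed area by its value in an extended
# Gly-X-Gly tripeptide, the convention used for exposure classification.

# van der Waals radii (Angstrom), NACCESS-like element set
DEFAULT_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20,
                   P = 1.80, SE = 1.90)

# Published maximal accessible areas in Gly-X-Gly (Angstrom^2).
# tien2013: theoretical maxima of Tien et al. (2013).
# miller1987: Miller et al. (1987) standard-state values.
GXG_TABLES <- list(
  tien2013 = c(A = 129, R = 274, N = 195, D = 193, C = 167, Q = 225,
               E = 223, G = 104, H = 224, I = 197, L = 201, K = 236,
               M = 224, F = 240, P = 159, S = 155, T = 172, W = 285,
               Y = 263, V = 174),
  miller1987 = c(A = 113, R = 241, N = 158, D = 151, C = 140, Q = 189,
                 E = 183, G = 85, H = 194, I = 182, L = 180, K = 211,
                 M = 204, F = 218, P = 143, S = 122, T = 146, W = 259,
                 Y = 229, V = 160)
)

#' Gly-X-Gly reference accessibility table
#'
#' @param name `"tien2013"` (default) or `"miller1987"`.
#' @return named numeric vector of maximal accessible areas (A^2) per
#'   one-letter residue code, with an `X` fallback equal to the table mean.
#' @export
gxg_reference <- function(name = c("tien2013", "miller1987")) {
  name <- match.arg(name)
  tab <- GXG_TABLES[[name]]
  c(tab, X = mean(tab))
}

#' SASA computation configuration
#'
#' @param probe probe (solvent) radius in Angstrom.
#' @param n_points sphere sample points per atom (>= 24).
#' @param radii named vector of van der Waals radii per element.
#' @param ref_table Gly-X-Gly reference table (named vector, one-letter
#'   codes) or the name of a shipped table.
#' @param thresholds named vector with `buried`, `surface` and `protruding`
#'   percentage cut-offs.
#' @return list of class `sasa_config`.
#' @export
sasa_config <- function(probe = 1.4, n_points = 960L,
                        radii = DEFAULT_RADII, ref_table = "tien2013",
                        thresholds = c(buried = 20, surface = 25,
                                       protruding = 75)) {
  if (probe <= 0) stop("probe radius must be > 0")
  if (n_points < 24L) stop("n_points must be >= 24")
  if (is.character(ref_table)) ref_table <- gxg_reference(ref_table)
  if (!all(names(AA3to1) %in% names(ref_table) |
           unname(AA3to1) %in% names(ref_table))) {
    stop("reference table must cover all 20 standard residues")
  }
  structure(list(probe = probe, n_points = as.integer(n_points),
                 radii = radii, ref_table = ref_table,
                 thresholds = thresholds),
            class = "sasa_config")
}

# deterministic, seed-free quasi-uniform points on the unit sphere
golden_spiral_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Per-atom solvent accessible surface area
#'
#' @param structure a `pdbstruct`.
#' @param config a [sasa_config()].
#' @return numeric vector of per-atom areas (A^2), one per atom row.
#' @export
atom_sasa <- function(structure, config = sasa_config()) {
  a <- structure$atoms
  n <- nrow(a)
  radii <- config$radii[a$element]
  if (any(is.na(radii))) {
    bad <- which(is.na(radii))[1L]
    stop("no van der Waals radius for element '", a$element[bad],
         "' (atom ", a$atom[bad], " of residue ", a$resname[bad], " ",
         a$chain[bad], a$resno[bad], ")")
  }
  R <- unname(radii) + config$probe
  xyz <- as.matrix(a[, c("x", "y", "z")])
  pts <- golden_spiral_points(config$n_points)
  areas <- numeric(n)
  # neighbour pre-screen on pairwise distances (n is small at protein scale)
  d2 <- as.matrix(stats::dist(xyz))^2
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (R[i] + R)^2 & seq_len(n) != i)
    P <- pts * R[i]
    P[, 1L] <- P[, 1L] + xyz[i, 1L]
    P[, 2L] <- P[, 2L] + xyz[i, 2L]
    P[, 3L] <- P[, 3L] + xyz[i, 3L]
    acc <- rep(TRUE, config$n_points)
    for (j in nb) {
      if (!any(acc)) break
      dx <- P[, 1L] - xyz[j, 1L]
      dy <- P[, 2L] - xyz[j, 2L]
      dz <- P[, 3L] - xyz[j, 3L]
      acc <- acc & (dx * dx + dy * dy + dz * dz > R[j]^2)
    }
    areas[i] <- 4 * pi * R[i]^2 * sum(acc) / config$n_points
  }
  areas
}

#' Per-residue absolute SASA
#'
#' Sums per-atom areas over each residue; the residue total therefore
#' conserves the atom total exactly.
#'
#' @param atom_areas output of [atom_sasa()] on the same structure.
#' @param structure the `pdbstruct` the areas were computed on.
#' @return data.frame with `key`, `chain`, `resno`, `icode`, `resname`,
#'   `abs_sasa`.
#' @export
residue_sasa <- function(atom_areas, structure) {
  a <- structure$atoms
  if (length(atom_areas) != nrow(a)) {
    stop("atom area vector length differs from structure atom count")
  }
  key <- residue_key(a$chain, a$resno, a$icode)
  res <- structure_residues(structure)
  sums <- tapply(atom_areas, factor(key, levels = res$key), sum)
  res$abs_sasa <- as.numeric(sums)
  res
}

#' Relative (Gly-X-Gly) SASA and exposure classification
#'
#' Relative SASA is 100 x absolute / reference; values above 100% are kept
#' unclamped (chain termini legitimately exceed the tripeptide reference).
#' Cumulative exposure flags: `buried` (< buried threshold),
#' `partially_accessible` (>= buried), `surface` (>= surface) and
#' `protruding` (> protruding).
#'
#' @param res_sasa output of [residue_sasa()].
#' @param config a [sasa_config()].
#' @return `res_sasa` with added columns `ref_sasa`, `rel_sasa`, logical
#'   flag columns and an `exposure_class` factor.
#' @export
relative_sasa <- function(res_sasa, config = sasa_config()) {
  aa <- aa_three_to_one(res_sasa$resname)
  ref <- config$ref_table[aa]
  if (any(is.na(ref))) {
    stop("no Gly-X-Gly reference value for residue type(s): ",
         paste(unique(res_sasa$resname[is.na(ref)]), collapse = ", "))
  }
  th <- config$thresholds
  out <- res_sasa
  out$ref_sasa <- unname(ref)
  out$rel_sasa <- 100 * out$abs_sasa / out$ref_sasa
  out$buried <- out$rel_sasa < th[["buried"]]
  out$partially_accessible <- out$rel_sasa >= th[["buried"]]
  out$surface <- out$rel_sasa >= th[["surface"]]
  out$protruding <- out$rel_sasa > th[["protruding"]]
  out$exposure_class <- factor(
    ifelse(out$protruding, "protruding",
           ifelse(out$surface, "surface",
                  ifelse(out$partially_accessible, "partially_accessible",
                         "buried"))),
    levels = c("buried", "partially_accessible", "surface", "protruding"))
  out
}

#' Residue exposure in one call
#'
#' Convenience wrapper: [atom_sasa()] then [residue_sasa()] then
#' [relative_sasa()].
#'
#' @inheritParams atom_sasa
#' @param chain optional chain restriction applied before computing areas
#'   (the chain is analysed in isolation).
#' @return data.frame as returned by [relative_sasa()].
#' @export
compute_exposure <- function(structure, config = sasa_config(),
                             chain = NULL) {
  if (!is.null(chain)) {
    a <- structure$atoms[structure$atoms$chain %in% chain, , drop = FALSE]
    if (nrow(a) == 0L) stop("no atoms on chain ", chain)
    structure <- pdbstruct(a, id = structure$id)
  }
  relative_sasa(residue_sasa(atom_sasa(structure, config), structure),
                config)
}
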