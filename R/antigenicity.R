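# Sliding-window physicochemical profiles and high-antigenicity region
# calling.
#
# Three literature per-residue scales are embedded: Kyte-Doolittle
# hydropathy (antigenic direction = hydrophilic, i.e. negative values),
# Welling antigenicity (log ratio of residue frequency in known antigenic
# regions vs average proteins; positive = antigenic) and Parker HPLC
# hydrophilicity (positive = hydrophilic/antigenic).

AA_SCALES <- list(
  kd = c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
         E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
         M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
         Y = -1.3, V = 4.2),
  welling = c(A = 0.115, R = 0.058, N = -0.077, D = 0.065, C = -0.120,
              Q = -0.011, E = -0.071, G = -0.184, H = 0.312, I = -0.292,
              L = 0.075, K = 0.206, M = -0.385, F = -0.141, P = -0.053,
              S = -0.026, T = -0.045, W = -0.114, Y = 0.013, V = -0.013),
  parker = c(A = 2.1, R = 4.2, N = 7.0, D = 10.0, C = 1.4, Q = 6.0,
             E = 7.8, G = 5.7, H = 2.1, I = -8.0, L = -9.2, K = 5.7,
             M = -4.2, F = -9.2, P = 2.1, S = 6.5, T = 5.2, W = -10.0,
             Y = -1.9, V = -3.7)
)

# scales where smaller values mean more antigenic (hydropathy): the
# antigenic-direction signal is the negated windowed mean
INVERTED_SCALES <- "kd"

#' Available antigenicity scales
#'
#' @return character vector of scale names usable in [scale_profile()].
#' @export
antigenicity_scales <- function() names(AA_SCALES)

#' Sliding-window profile of a physicochemical scale
#'
#' Each position carries the mean scale value over a centred window of odd
#' size; within half a window of either terminus the mean is taken over the
#' truncated window and the position is flagged (`edge`). Unknown residues
#' (`X`) are excluded from window means and flag every window they touch
#' (`has_x`).
#'
#' @param sequence amino-acid string (one-letter, `X` allowed).
#' @param scale scale name, one of [antigenicity_scales()].
#' @param window odd window size, at most the sequence length.
#' @return data.frame of class `antigenicity_profile` with `pos`, `aa`,
#'   `value`, `edge`, `has_x`; the scale name and window are attributes.
#' @export
scale_profile <- function(sequence, scale = "kd", window = 7L) {
  if (!scale %in% names(AA_SCALES)) {
    stop("unknown scale '", scale, "'; available: ",
         paste(names(AA_SCALES), collapse = ", "))
  }
  aa <- strsplit(toupper(sequence), "")[[1]]
  n <- length(aa)
  if (window %% 2L != 1L) stop("window must be odd")
  if (window > n) stop("window larger than sequence")
  vals <- AA_SCALES[[scale]][aa]
  unknown <- setdiff(unique(aa[is.na(vals)]), "X")
  if (length(unknown) > 0L) {
    stop("sequence contains non-amino-acid letters: ",
         paste(unknown, collapse = ", "))
  }
  half <- window %/% 2L
  value <- numeric(n); edge <- logical(n); has_x <- logical(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    w <- vals[lo:hi]
    edge[i] <- (hi - lo + 1L) < window
    has_x[i] <- anyNA(w)
    value[i] <- mean(w, na.rm = TRUE)
  }
  out <- data.frame(pos = seq_len(n), aa = aa, value = value, edge = edge,
                    has_x = has_x, stringsAsFactors = FALSE)
  attr(out, "scale") <- scale
  attr(out, "window") <- as.integer(window)
  class(out) <- c("antigenicity_profile", "data.frame")
  out
}

#' Call high-antigenicity regions from profiles and accessibility
#'
#' A position is antigenicity-positive when at least `min_scales` profiles
#' point in the antigenic direction there (value > 0, with hydropathy
#' counted positive when below 0). Maximal runs of positive positions of at
#' least `min_run` residues become regions; when residue exposures are
#' supplied, a region is kept only if its mean relative SASA exceeds
#' `sasa_threshold`. Regions are labelled `A1`, `A2`, ... left to right.
#'
#' @param profiles list of [scale_profile()] outputs on one sequence.
#' @param exposures optional [compute_exposure()] table aligned with the
#'   sequence positions.
#' @param min_run minimal region length (default 5).
#' @param min_scales minimal number of supporting scales (default 2).
#' @param sasa_threshold relative SASA gate in percent (default 25).
#' @return data.frame of class `antigenic_regions`: `region`, `start`,
#'   `end`, `length`, `n_scales_min`, `mean_rel_sasa` (NA without
#'   exposures).
#' @export
call_regions <- function(profiles, exposures = NULL, min_run = 5L,
                         min_scales = 2L, sasa_threshold = 25) {
  if (!is.list(profiles) || length(profiles) == 0L) {
    stop("profiles must be a non-empty list")
  }
  lens <- vapply(profiles, nrow, integer(1))
  if (length(unique(lens)) > 1L) {
    stop("profiles have differing sequence lengths")
  }
  n <- lens[1L]
  if (!is.null(exposures) && nrow(exposures) != n) {
    stop("exposure table length (", nrow(exposures),
         ") does not match profile length (", n, ")")
  }
  signed <- vapply(profiles, function(p) {
    v <- p$value
    if (attr(p, "scale") %in% INVERTED_SCALES) -v else v
  }, numeric(n))
  if (is.null(dim(signed))) signed <- matrix(signed, nrow = n)
  support <- rowSums(signed > 0)
  positive <- support >= min_scales
  r <- rle(positive)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run
  out <- data.frame(start = starts[keep], end = ends[keep])
  if (nrow(out) > 0L && !is.null(exposures)) {
    sasa <- vapply(seq_len(nrow(out)), function(i) {
      mean(exposures$rel_sasa[out$start[i]:out$end[i]])
    }, numeric(1))
    out$mean_rel_sasa <- sasa
    out <- out[sasa > sasa_threshold, , drop = FALSE]
  } else {
    out$mean_rel_sasa <- rep(NA_real_, nrow(out))
  }
  if (nrow(out) > 0L) {
    out <- data.frame(region = paste0("A", seq_len(nrow(out))),
                      start = out$start, end = out$end,
                      length = out$end - out$start + 1L,
                      n_scales_min = vapply(seq_len(nrow(out)), function(i) {
                        min(support[out$start[i]:out$end[i]])
                      }, numeric(1)),
                      mean_rel_sasa = out$mean_rel_sasa,
                      stringsAsFactors = FALSE)
  } else {
    out <- data.frame(region = character(), start = integer(),
                      end = integer(), length = integer(),
                      n_scales_min = numeric(), mean_rel_sasa = numeric(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  class(out) <- c("antigenic_regions", "data.frame")
  out
}
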