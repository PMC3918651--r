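#' Construct a panel of ancestry-informative markers
#'
#' An AIM panel holds, for each marker, the frequency of a designated
#' "counted" allele in two ancestral reference populations: population 1
#' (African reference, `p_afr`) and population 2 (European reference,
#' `p_eur`).  Frequencies are clamped away from 0 and 1 so that the
#' admixture log-likelihood is finite for every genotype.
#'
#' @param marker_id character vector of unique marker identifiers.
#' @param p_afr counted-allele frequency in the African reference, in
#'   `[0, 1]`.
#' @param p_eur counted-allele frequency in the European reference.
#' @param counted_allele optional per-marker allele label (e.g. "A");
#'   defaults to `"A"` for every marker.
#' @param eps clamping bound: frequencies are moved into
#'   `[eps, 1 - eps]`.  Must satisfy `0 < eps < 0.5`.
#'
#' @return An object of class `aim_panel`: a list with elements
#'   `marker_id`, `counted_allele`, `p_afr`, `p_eur`, `delta`
#'   (the absolute frequency differential `|p_afr - p_eur|` after
#'   clamping), `eps` and `n_markers`.
#' @export
aim_panel <- function(marker_id, p_afr, p_eur, counted_allele = NULL,
                      eps = 0.001) {
  marker_id <- as.character(marker_id)
  if (length(marker_id) < 1L)
    stop("an AIM panel needs at least one marker")
  if (anyDuplicated(marker_id))
    stop("duplicate marker ids: ",
         paste(unique(marker_id[duplicated(marker_id)]), collapse = ", "))
  if (is.null(counted_allele)) counted_allele <- rep("A", length(marker_id))
  n <- length(marker_id)
  if (length(p_afr) != n || length(p_eur) != n || length(counted_allele) != n)
    stop("per-marker fields must all have length ", n)
  check_freq <- function(p, label) {
    bad <- !is.finite(p) | p < 0 | p > 1
    if (any(bad))
      stop("invalid ", label, " frequency for marker(s): ",
           paste(marker_id[bad], collapse = ", "))
  }
  check_freq(p_afr, "p_afr")
  check_freq(p_eur, "p_eur")
  panel <- structure(
    list(marker_id = marker_id,
         counted_allele = as.character(counted_allele),
         p_afr = as.numeric(p_afr), p_eur = as.numeric(p_eur),
         delta = NA_real_, eps = eps, n_markers = n),
    class = "aim_panel")
  clamp_frequencies(panel, eps)
}

#' Clamp panel allele frequencies away from the boundaries
#'
#' Moves every ancestral allele frequency into `[eps, 1 - eps]`.
#' Pseudo-ancestral panels often carry fixed differences (frequencies of
#' exactly 0 or 1); without clamping these give `-Inf` log-likelihood
#' whenever an individual carries the "impossible" allele.
#'
#' @param panel an [aim_panel].
#' @param eps new clamping bound in `(0, 0.5)`.
#' @return The panel with frequencies clamped and `delta` recomputed.
#' @export
clamp_frequencies <- function(panel, eps = panel$eps) {
  stopifnot(inherits(panel, "aim_panel"))
  if (!is.numeric(eps) || length(eps) != 1L || eps <= 0 || eps >= 0.5)
    stop("eps must be a single number in (0, 0.5)")
  panel$p_afr <- pmin(pmax(panel$p_afr, eps), 1 - eps)
  panel$p_eur <- pmin(pmax(panel$p_eur, eps), 1 - eps)
  panel$delta <- abs(panel$p_afr - panel$p_eur)
  panel$eps <- eps
  panel
}

#' Select ancestry-informative markers by frequency differential
#'
#' Retains the markers whose absolute counted-allele frequency
#' differential between the two ancestral populations,
#' `delta = |p_afr - p_eur|`, is at least `delta_min`.  The differential
#' is the classical informativeness screen for AIMs: loci with large
#' frequency differences between the parental populations carry the
#' ancestry signal.
#'
#' @param panel an [aim_panel].
#' @param delta_min minimum differential in `[0, 1]`.
#' @return The subset panel (class `aim_panel`), markers in their
#'   original order.
#' @export
select_aims <- function(panel, delta_min) {
  stopifnot(inherits(panel, "aim_panel"))
  if (!is.numeric(delta_min) || delta_min < 0 || delta_min > 1)
    stop("delta_min must lie in [0, 1]")
  keep <- panel$delta >= delta_min
  if (!any(keep))
    stop("no informative markers: no |p_afr - p_eur| >= ", delta_min)
  subset_panel(panel, keep)
}

subset_panel <- function(panel, idx) {
  panel$marker_id <- panel$marker_id[idx]
  panel$counted_allele <- panel$counted_allele[idx]
  panel$p_afr <- panel$p_afr[idx]
  panel$p_eur <- panel$p_eur[idx]
  panel$delta <- panel$delta[idx]
  panel$n_markers <- length(panel$marker_id)
  panel
}

#' @export
print.aim_panel <- function(x, ...) {
  cat("AIM panel:", x$n_markers, "markers\n")
  cat(sprintf("  |p_afr - p_eur|: mean %.3f, range [%.3f, %.3f]\n",
              mean(x$delta), min(x$delta), max(x$delta)))
  cat(sprintf("  frequencies clamped to [%g, %g]\n", x$eps, 1 - x$eps))
  invisible(x)
}

#' Read an ancestral allele-frequency table
#'
#' Expects a tab-separated file with header
#' `marker_id  counted_allele  p_afr  p_eur`, one marker per row.
#' Population 1 (`p_afr`) is the African reference, population 2
#' (`p_eur`) the European reference; the per-individual ancestry
#' proportion estimated downstream is the *European* fraction.
#'
#' @param path file path.
#' @param eps clamping bound applied on read.
#' @return An [aim_panel].
#' @export
read_frequency_table <- function(path, eps = 0.001) {
  if (!file.exists(path)) stop("frequency table not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", strip.white = TRUE)
  need <- c("marker_id", "counted_allele", "p_afr", "p_eur")
  if (!all(need %in% names(tab)))
    stop("frequency table must have columns: ", paste(need, collapse = ", "))
  for (col in c("p_afr", "p_eur")) {
    x <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- is.na(x) | x < 0 | x > 1
    if (any(bad))
      stop("invalid ", col, " at line(s) ",
           paste(which(bad) + 1L, collapse = ", "),
           " (marker ", paste(tab$marker_id[bad], collapse = ", "), ")")
    tab[[col]] <- x
  }
  aim_panel(tab$marker_id, tab$p_afr, tab$p_eur, tab$counted_allele, eps)
}

#' Write an allele-frequency table
#' @param panel an [aim_panel].
#' @param path output path (TSV).
#' @export
write_frequency_table <- function(panel, path) {
  stopifnot(inherits(panel, "aim_panel"))
  df <- data.frame(marker_id = panel$marker_id,
                   counted_allele = panel$counted_allele,
                   p_afr = panel$p_afr, p_eur = panel$p_eur)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
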