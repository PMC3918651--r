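#' Construct a genotype dosage matrix
#'
#' Dosages count copies (0/1/2) of the panel's counted allele per
#' individual and marker; missing genotypes are `NA` (the value `-1` is
#' also accepted on input and recoded).
#'
#' @param dosage numeric matrix, individuals in rows, markers in
#'   columns; entries in `{0, 1, 2, NA}`.
#' @param individual_id unique row identifiers (defaults to existing
#'   rownames).
#' @param marker_id column identifiers (defaults to existing colnames).
#' @return A `genotype_matrix`: the integer matrix with dimnames set.
#' @export
genotype_matrix <- function(dosage, individual_id = rownames(dosage),
                            marker_id = colnames(dosage)) {
  dosage <- as.matrix(dosage)
  if (is.null(individual_id) || is.null(marker_id))
    stop("individual and marker identifiers are required")
  if (anyDuplicated(individual_id)) stop("duplicate individual ids")
  if (anyDuplicated(marker_id)) stop("duplicate marker ids")
  storage.mode(dosage) <- "double"
  dosage[dosage %in% -1] <- NA_real_
  ok <- is.na(dosage) | dosage %in% c(0, 1, 2)
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1L, ]
    stop("dosage entries must be 0, 1, 2 or NA; found ",
         dosage[!ok][1L], " at individual ", individual_id[bad[1L]],
         ", marker ", marker_id[bad[2L]])
  }
  dimnames(dosage) <- list(as.character(individual_id),
                           as.character(marker_id))
  class(dosage) <- c("genotype_matrix", class(dosage))
  dosage
}

#' Read a genotype dosage matrix
#'
#' Tab-separated layout in the style of a PLINK additive export: first
#' column `individual_id`, remaining columns named by marker id, entries
#' 0/1/2/NA (or -1 for missing).  Columns not present in `panel` are
#' dropped with a warning; the result is aligned to the panel's marker
#' order restricted to the columns present.
#'
#' @param path file path.
#' @param panel an [aim_panel] the columns must belong to.
#' @return A [genotype_matrix] aligned to `panel`.
#' @export
read_genotypes <- function(path, panel) {
  if (!file.exists(path)) stop("genotype file not found: ", path)
  stopifnot(inherits(panel, "aim_panel"))
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE)
  if (names(tab)[1L] != "individual_id")
    stop("first column must be 'individual_id'")
  ids <- as.character(tab[[1L]])
  mat <- as.matrix(tab[, -1L, drop = FALSE])
  unknown <- setdiff(colnames(mat), panel$marker_id)
  if (length(unknown)) {
    warning(length(unknown), " column(s) not in the panel dropped: ",
            paste(utils::head(unknown, 5L), collapse = ", "))
    mat <- mat[, setdiff(colnames(mat), unknown), drop = FALSE]
  }
  if (ncol(mat) == 0L) stop("no genotype columns match the panel")
  keep <- panel$marker_id[panel$marker_id %in% colnames(mat)]
  genotype_matrix(mat[, keep, drop = FALSE], ids, keep)
}

#' Write a genotype dosage matrix
#' @param gm a [genotype_matrix].
#' @param path output path (TSV).
#' @export
write_genotypes <- function(gm, path) {
  df <- data.frame(individual_id = rownames(gm),
                   unclass(gm)[, , drop = FALSE], check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# align a genotype matrix to a panel: intersect markers (a pruned panel
# legitimately covers fewer loci than the genotyping), keep panel order
align_to_panel <- function(gm, panel) {
  keep <- panel$marker_id[panel$marker_id %in% colnames(gm)]
  if (!length(keep))
    stop("no genotype markers overlap the panel")
  list(gm = gm[, keep, drop = FALSE], panel = select_markers(panel, keep))
}

select_markers <- function(panel, ids) {
  subset_panel(panel, match(ids, panel$marker_id))
}
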