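#' Hellberg z-scale descriptor table
#'
#' Loads the three-component z-scale table of Hellberg et al. (1987): for
#' each of the 20 standard amino acids a triple (z1, z2, z3) describing
#' hydrophobicity, molecular size and polarity. The scales were derived by
#' principal component analysis of 29 physicochemical properties and are the
#' per-residue descriptors underlying the ACC transformation.
#'
#' The values are read from a versioned data file shipped with the package
#' (`inst/extdata/hellberg_z3.tsv`, header documents the transcription
#' source) and validated on load. The returned table is a plain numeric
#' matrix and is value-identical across calls.
#'
#' @return A 20 x 3 numeric matrix with row names `A`..`V` (one-letter
#'   codes) and column names `z1`, `z2`, `z3`.
#' @references Hellberg S, Sjostrom M, Skagerberg B, Wold S (1987).
#'   J Med Chem 30(7):1126-1135.
#' @examples
#' zt <- zscales()
#' zt["A", ]   # alanine: hydrophobicity, size, polarity
#' @export
zscales <- function() {
  path <- system.file("extdata", "hellberg_z3.tsv", package = "allerknn",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (!identical(sort(tab$aa), sort(AA_STANDARD)) ||
      nrow(tab) != 20L ||
      !all(is.finite(as.matrix(tab[, c("z1", "z2", "z3")])))) {
    stop("built-in z-scale table is corrupt or incomplete", call. = FALSE)
  }
  m <- as.matrix(tab[, c("z1", "z2", "z3")])
  rownames(m) <- tab$aa
  m
}

# the 20 standard one-letter codes, in the conventional property order
AA_STANDARD <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
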