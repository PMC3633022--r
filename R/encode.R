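#' Encode a protein sequence as z-descriptor rows
#'
#' Maps each residue of a protein sequence to its (z1, z2, z3) descriptor
#' triple, producing an n x 3 matrix (one row per residue, in sequence
#' order). Input is uppercased and stripped of whitespace/line breaks before
#' validation, so sequences pasted in plain format are accepted.
#'
#' In `strict` mode (the default) any character outside the 20 standard
#' one-letter codes is an error naming the offending position and character.
#' In `permissive` mode the common ambiguity codes are substituted with a
#' warning: `B` = mean of D and N, `Z` = mean of E and Q, `J` = mean of I
#' and L, and `X`/`U`/`O` = the column-wise mean of all 20 triples. Other
#' characters (gaps, `*`) are errors in both modes.
#'
#' @param seq A single character string of one-letter amino-acid codes.
#' @param table z-scale table from [zscales()].
#' @param mode `"strict"` or `"permissive"` handling of non-standard
#'   residues.
#' @return An object of class `encoded_seq`: a list with `residues`
#'   (character vector), `zmatrix` (n x 3 numeric matrix) and `n` (length).
#' @examples
#' enc <- encode_sequence("MKVLATT")
#' enc$zmatrix
#' @seealso [acc_transform()]
#' @export
encode_sequence <- function(seq, table = zscales(),
                            mode = c("strict", "permissive")) {
  mode <- match.arg(mode)
  if (!is.character(seq) || length(seq) != 1L || is.na(seq)) {
    stop("'seq' must be a single character string", call. = FALSE)
  }
  seq <- toupper(gsub("[[:space:]]", "", seq))
  if (!nzchar(seq)) stop("empty sequence", call. = FALSE)
  res <- strsplit(seq, "", fixed = TRUE)[[1]]

  known <- res %in% rownames(table)
  if (!all(known)) {
    bad <- which(!known)
    if (mode == "strict") {
      stop(sprintf(
        "non-standard residue(s) in strict mode: %s",
        paste(sprintf("'%s' at position %d", res[bad], bad),
              collapse = ", ")), call. = FALSE)
    }
    amb <- ambiguity_rows(table)
    unmapped <- bad[!(res[bad] %in% rownames(amb))]
    if (length(unmapped)) {
      stop(sprintf(
        "unmappable character(s): %s",
        paste(sprintf("'%s' at position %d", res[unmapped], unmapped),
              collapse = ", ")), call. = FALSE)
    }
    warning(sprintf("substituted %d non-standard residue(s): %s",
                    length(bad),
                    paste(unique(res[bad]), collapse = ", ")),
            call. = FALSE)
    table <- rbind(table, amb)
  }

  zmat <- table[res, , drop = FALSE]
  rownames(zmat) <- NULL
  structure(list(residues = res, zmatrix = zmat, n = length(res)),
            class = "encoded_seq")
}

# descriptor rows for ambiguity codes (permissive mode)
ambiguity_rows <- function(table) {
  rbind(
    B = colMeans(table[c("D", "N"), ]),
    Z = colMeans(table[c("E", "Q"), ]),
    J = colMeans(table[c("I", "L"), ]),
    X = colMeans(table),
    U = colMeans(table),
    O = colMeans(table)
  )
}

#' @export
print.encoded_seq <- function(x, ...) {
  cat(sprintf("Encoded protein sequence: %d residues x 3 z-descriptors\n",
              x$n))
  invisible(x)
}
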