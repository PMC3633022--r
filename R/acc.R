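#' Auto- and cross-covariance (ACC) transformation
#'
#' Converts a variable-length encoded sequence into a fixed-length feature
#' vector of lagged covariance terms, making proteins of any length
#' comparable without alignment. For descriptor indices j, k in 1..3 and
#' lag l in 1..L the terms are
#' \deqn{A_{jj}(l) = \sum_{i=1}^{n-l} Z_{j,i} Z_{j,i+l} / (n-l)}
#' \deqn{C_{jk}(l) = \sum_{i=1}^{n-l} Z_{j,i} Z_{k,i+l} / (n-l), j \ne k}
#' giving (3 auto pairs + 6 ordered cross pairs) x L terms: 45 at the
#' default L = 5. Both orders of each cross pair are kept because the
#' sequence is directional.
#'
#' The layout is frozen as descriptor-pair-major, lag-minor: for each pair
#' in the order A11, A22, A33, C12, C13, C21, C23, C31, C32, the lags
#' 1..L consecutively; element names encode the pair and lag
#' (`A11_l1` ... `C32_l5`).
#'
#' @param enc An `encoded_seq` from [encode_sequence()], or a string to be
#'   encoded with default settings.
#' @param L Maximum lag (positive integer, default 5). Requires sequence
#'   length n >= L + 1.
#' @return Named numeric vector of length 9 * L (45 for L = 5), class
#'   `acc_vector`.
#' @examples
#' v <- acc_transform(encode_sequence("MKVLATTGHWEE"))
#' length(v)  # 45
#' @export
acc_transform <- function(enc, L = 5L) {
  L <- stopifnot_count(L, "L", min = 1L)
  if (is.character(enc)) enc <- encode_sequence(enc)
  if (!inherits(enc, "encoded_seq")) {
    stop("'enc' must be an encoded_seq or a sequence string", call. = FALSE)
  }
  n <- enc$n
  if (n < L + 1L) {
    stop(sprintf("sequence too short: %d residues; minimum length is L+1 = %d",
                 n, L + 1L), call. = FALSE)
  }
  Z <- enc$zmatrix
  pairs <- acc_pairs()
  out <- numeric(nrow(pairs) * L)
  idx <- 1L
  for (p in seq_len(nrow(pairs))) {
    zj <- Z[, pairs[p, 1L]]
    zk <- Z[, pairs[p, 2L]]
    for (l in seq_len(L)) {
      out[idx] <- sum(zj[1:(n - l)] * zk[(1L + l):n]) / (n - l)
      idx <- idx + 1L
    }
  }
  names(out) <- acc_layout(L)
  class(out) <- "acc_vector"
  out
}

# ordered (j, k) descriptor pairs in the frozen layout order
acc_pairs <- function() {
  cbind(j = c(1L, 2L, 3L, 1L, 1L, 2L, 2L, 3L, 3L),
        k = c(1L, 2L, 3L, 2L, 3L, 1L, 3L, 1L, 2L))
}

#' ACC feature layout
#'
#' Names of the ACC vector components in their frozen order. Auto terms are
#' named `Ajj_l<lag>`, cross terms `Cjk_l<lag>`.
#'
#' @param L Maximum lag.
#' @return Character vector of length 9 * L.
#' @export
acc_layout <- function(L = 5L) {
  p <- acc_pairs()
  lab <- ifelse(p[, 1L] == p[, 2L], "A", "C")
  base <- sprintf("%s%d%d", lab, p[, 1L], p[, 2L])
  as.vector(t(outer(base, seq_len(L),
                    function(b, l) sprintf("%s_l%d", b, l))))
}

#' ACC feature matrix for a set of sequences
#'
#' Applies [encode_sequence()] and [acc_transform()] to each sequence and
#' stacks the results.
#'
#' @param seqs Character vector of sequences, or a `labeled_dataset`.
#' @param L Maximum lag.
#' @param table z-scale table.
#' @param mode Residue-validation mode, see [encode_sequence()].
#' @return Numeric matrix, one row per sequence, 9 * L named columns; row
#'   names are sequence ids when available.
#' @export
acc_features <- function(seqs, L = 5L, table = zscales(),
                         mode = c("strict", "permissive")) {
  mode <- match.arg(mode)
  ids <- NULL
  if (inherits(seqs, "labeled_dataset")) {
    ids <- seqs$id
    seqs <- seqs$sequence
  } else if (!is.null(names(seqs))) {
    ids <- names(seqs)
  }
  X <- t(vapply(
    seqs,
    function(s) as.numeric(acc_transform(encode_sequence(s, table, mode), L)),
    numeric(9L * L), USE.NAMES = FALSE))
  colnames(X) <- acc_layout(L)
  rownames(X) <- ids
  X
}

#' @export
print.acc_vector <- function(x, ...) {
  cat(sprintf("ACC feature vector: %d covariance terms (L = %d)\n",
              length(x), length(x) / 9L))
  print(unclass(x), ...)
  invisible(x)
}

#' Write ACC vectors as a tab-separated table
#'
#' Exports a feature matrix as TSV with an `id` column followed by the
#' named feature columns (`A11_l1` ... `C32_l5`).
#'
#' @param x Feature matrix from [acc_features()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_acc_tsv <- function(x, path) {
  df <- data.frame(id = rownames(x) %||% seq_len(nrow(x)), x,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
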