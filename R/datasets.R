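#' Labelled protein sequence dataset
#'
#' Constructs and validates a labelled dataset: protein sequences with an
#' allergen/non-allergen class label, optional route-of-exposure tags
#' (food, inhalant, toxin; allergens may carry several — e.g. a food
#' allergen that is also a toxin) and an optional species tag used for
#' mirror-set construction.
#'
#' Sequences failing the strict residue rules are flagged in the `valid`
#' column, never silently dropped; downstream featurisation operates on the
#' valid records.
#'
#' @param id Character vector of unique identifiers.
#' @param sequence Character vector of amino-acid sequences.
#' @param label `"allergen"` or `"non-allergen"` per record.
#' @param routes Per-record comma-separated route tags (`""` for
#'   non-allergens). Alternatively a list of character vectors.
#' @param species Optional per-record species tag.
#' @param provenance Free-text source note stored as an attribute.
#' @return A `labeled_dataset`: a data.frame with columns `id`, `sequence`,
#'   `label`, `routes`, `species`, `valid`.
#' @export
labeled_dataset <- function(id, sequence, label, routes = "",
                            species = NA_character_, provenance = "") {
  id <- as.character(id)
  sequence <- toupper(gsub("[[:space:]]", "", as.character(sequence)))
  label <- as.character(label)
  if (is.list(routes)) {
    routes <- vapply(routes, function(r) paste(r, collapse = ","), "")
  }
  routes <- as.character(routes)
  n <- length(id)
  routes <- rep_len(routes, n)
  species <- rep_len(as.character(species), n)
  if (length(sequence) != n || length(label) != n) {
    stop("id, sequence and label must have equal length", call. = FALSE)
  }
  if (anyDuplicated(id)) {
    stop(sprintf("duplicate ids: %s",
                 paste(unique(id[duplicated(id)]), collapse = ", ")),
         call. = FALSE)
  }
  if (!all(label %in% c("allergen", "non-allergen"))) {
    stop("labels must be 'allergen' or 'non-allergen'", call. = FALSE)
  }
  rl <- strsplit(routes, ",", fixed = TRUE)
  rl <- lapply(rl, function(r) r[nzchar(r)])
  bad_tag <- !vapply(rl, function(r) all(r %in% ROUTES), TRUE)
  if (any(bad_tag)) {
    stop(sprintf("unknown route tag(s) on: %s",
                 paste(id[bad_tag], collapse = ", ")), call. = FALSE)
  }
  has_route <- lengths(rl) > 0L
  if (any(has_route & label == "non-allergen")) {
    stop("route tags are only allowed on allergens", call. = FALSE)
  }
  routes <- vapply(rl, function(r) paste(sort(unique(r)), collapse = ","), "")
  valid <- vapply(sequence, function(s) {
    nzchar(s) && all(strsplit(s, "")[[1]] %in% AA_STANDARD)
  }, TRUE, USE.NAMES = FALSE)
  out <- data.frame(id = id, sequence = sequence, label = label,
                    routes = routes, species = species, valid = valid,
                    stringsAsFactors = FALSE)
  attr(out, "provenance") <- provenance
  class(out) <- c("labeled_dataset", "data.frame")
  out
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf(
    "Labelled dataset: %d records (%d allergen, %d non-allergen, %d flagged invalid)\n",
    nrow(x), sum(x$label == "allergen"), sum(x$label == "non-allergen"),
    sum(!x$valid)))
  r <- route_counts(x)
  if (sum(r) > 0) {
    cat("  route tags:", paste(sprintf("%s=%d", names(r), r), collapse = " "),
        "\n")
  }
  prov <- attr(x, "provenance")
  if (!is.null(prov) && nzchar(prov)) cat("  provenance:", prov, "\n")
  invisible(x)
}

# per-route tag counts over allergens (multi-route members count once per tag)
route_counts <- function(x) {
  tags <- unlist(strsplit(x$routes[x$label == "allergen"], ",", fixed = TRUE))
  tags <- tags[nzchar(tags)]
  vapply(ROUTES, function(r) sum(tags == r), 0L)
}

# subset preserving class and provenance
dataset_subset <- function(x, i) {
  out <- as.data.frame(x)[i, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "provenance") <- attr(x, "provenance")
  class(out) <- c("labeled_dataset", "data.frame")
  out
}

#' Read a FASTA file of protein sequences
#'
#' Multi-record FASTA with wrapped lines; record ids are the first
#' whitespace-delimited token of each header.
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  seqs <- as.character(aa)
  names(seqs) <- vapply(strsplit(names(aa), "[[:space:]]+"), `[`, "", 1L)
  seqs
}

#' Read a single protein sequence from plain text
#'
#' Accepts plain-format input: the whole file is one sequence, with line
#' breaks and whitespace ignored. A single leading FASTA header line is
#' tolerated and skipped.
#'
#' @param path Text file path.
#' @return A single sequence string.
#' @export
read_plain_sequence <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) && startsWith(lines[1L], ">")) lines <- lines[-1L]
  seq <- toupper(gsub("[[:space:]]", "", paste(lines, collapse = "")))
  if (!nzchar(seq)) stop("no sequence found in ", path, call. = FALSE)
  seq
}

#' Read a labelled dataset from FASTA plus a label table
#'
#' The label table is tab-separated with `#` comments and columns
#' `id`, `label`, and optionally `routes` (comma-separated tags) and
#' `species`. Every FASTA id must appear in the table and vice versa.
#'
#' @param fasta_path FASTA file of sequences.
#' @param labels_path Tab-separated label table.
#' @return A [labeled_dataset()].
#' @export
read_labeled_fasta <- function(fasta_path, labels_path) {
  seqs <- read_fasta(fasta_path)
  lab <- utils::read.delim(labels_path, comment.char = "#",
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!all(c("id", "label") %in% names(lab))) {
    stop("label table must have 'id' and 'label' columns", call. = FALSE)
  }
  if (anyDuplicated(lab$id)) {
    stop(sprintf("duplicate ids in label table: %s",
                 paste(unique(lab$id[duplicated(lab$id)]), collapse = ", ")),
         call. = FALSE)
  }
  miss_lab <- setdiff(names(seqs), lab$id)
  miss_seq <- setdiff(lab$id, names(seqs))
  if (length(miss_lab) || length(miss_seq)) {
    stop(sprintf(
      "id mismatch between FASTA and labels%s%s",
      if (length(miss_lab)) paste0("; missing from labels: ",
                                   paste(miss_lab, collapse = ", ")) else "",
      if (length(miss_seq)) paste0("; missing from FASTA: ",
                                   paste(miss_seq, collapse = ", ")) else ""),
      call. = FALSE)
  }
  lab <- lab[match(names(seqs), lab$id), ]
  labeled_dataset(
    id = lab$id, sequence = unname(seqs), label = lab$label,
    routes = lab$routes %||% "",
    species = lab$species %||% NA_character_,
    provenance = sprintf("read from %s + %s", fasta_path, labels_path))
}

#' Write a labelled dataset as FASTA plus label table
#'
#' @param dataset A [labeled_dataset()].
#' @param fasta_path,labels_path Output paths.
#' @return Invisibly, a list of the two paths.
#' @export
write_labeled_fasta <- function(dataset, fasta_path, labels_path) {
  aa <- Biostrings::AAStringSet(setNames(dataset$sequence, dataset$id))
  Biostrings::writeXStringSet(aa, fasta_path, width = 60L)
  lab <- dataset[, c("id", "label", "routes", "species")]
  utils::write.table(lab, labels_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(list(fasta = fasta_path, labels = labels_path))
}

#' Dataset manifest
#'
#' Summary counts (per class, per route tag, invalid records) for logging;
#' serialisable as JSON.
#'
#' @param dataset A [labeled_dataset()].
#' @return A list of counts.
#' @export
dataset_manifest <- function(dataset) {
  list(
    n = nrow(dataset),
    allergens = sum(dataset$label == "allergen"),
    non_allergens = sum(dataset$label == "non-allergen"),
    routes = as.list(route_counts(dataset)),
    invalid = sum(!dataset$valid),
    provenance = attr(dataset, "provenance") %||% ""
  )
}
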