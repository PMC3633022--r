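#' Build a mirror non-allergen set
#'
#' Constructs a negative set that mirrors an allergen set: for each
#' allergen, one candidate protein from the same species is selected whose
#' sequence shows no detectable similarity to *any* allergen under the
#' configured screen. When a species yields no usable candidate the search
#' relaxes to the genus (first token of the species tag) and finally to a
#' designated fallback pool sampled at random. Selection order and random
#' draws are reproducible from the seed.
#'
#' Two similarity screens are available. The default `"kmer"` screen
#' rejects any candidate sharing an exact k-mer of length >= `kmer_k`
#' (default 8, motivated by the FAO/WHO guideline flagging identity of 6-8
#' contiguous residues) with any allergen; it is self-contained and
#' deterministic. The `"blast"` screen shells out to `makeblastdb`/`blastp`
#' and rejects candidates with any hit at `evalue` (default 0.001); it
#' requires the BLAST+ executables on the PATH.
#'
#' @param allergens [labeled_dataset()] of allergens (species tags used).
#' @param candidates [labeled_dataset()] candidate pool with species tags.
#' @param screen `"kmer"` or `"blast"`.
#' @param kmer_k Minimum shared-word length for the k-mer screen.
#' @param evalue E-value cutoff for the BLAST screen.
#' @param fallback Optional [labeled_dataset()] used to fill shortfalls
#'   (stands in for a random background proteome).
#' @param seed Integer seed for the random draws.
#' @return A [labeled_dataset()] of non-allergens, one per allergen.
#' @export
build_mirror_set <- function(allergens, candidates,
                             screen = c("kmer", "blast"),
                             kmer_k = 8L, evalue = 0.001,
                             fallback = NULL, seed = 1L) {
  screen <- match.arg(screen)
  stopifnot(inherits(allergens, "labeled_dataset"),
            inherits(candidates, "labeled_dataset"))
  al <- allergens[allergens$label == "allergen" & allergens$valid, ]
  if (nrow(al) == 0L) stop("no valid allergens supplied", call. = FALSE)

  pools <- list(cand = candidates,
                fb = fallback %||% candidates[0L, ])
  similar <- lapply(pools, function(p) {
    if (nrow(p) == 0L) logical(0L)
    else if (screen == "kmer") kmer_similar(p$sequence, al$sequence, kmer_k)
    else blast_similar(p$sequence, al$sequence, evalue)
  })

  genus_of <- function(sp) vapply(strsplit(sp, "[[:space:]_]+"), `[`, "", 1L)
  cand_ok <- !similar$cand & pools$cand$valid
  fb_ok <- !similar$fb & (if (nrow(pools$fb)) pools$fb$valid else logical(0L))
  used_c <- rep(FALSE, nrow(pools$cand))
  used_f <- rep(FALSE, nrow(pools$fb))
  pick_c <- integer(0L)
  pick_f <- integer(0L)
  n_fallback <- 0L

  with_seed(seed, {
    for (i in seq_len(nrow(al))) {
      sp <- al$species[i]
      hit <- which(cand_ok & !used_c & pools$cand$species == sp)
      if (!length(hit) && !is.na(sp)) {
        hit <- which(cand_ok & !used_c &
                       genus_of(pools$cand$species) == genus_of(sp))
      }
      if (length(hit)) {
        j <- if (length(hit) == 1L) hit else sample(hit, 1L)
        used_c[j] <- TRUE
        pick_c <- c(pick_c, j)
      } else {
        fhit <- which(fb_ok & !used_f)
        if (!length(fhit)) {
          stop(sprintf(
            "mirror set shortfall: no screened candidate for allergen '%s' (%d of %d placed) and fallback pool exhausted",
            al$id[i], length(pick_c) + length(pick_f), nrow(al)),
            call. = FALSE)
        }
        j <- if (length(fhit) == 1L) fhit else sample(fhit, 1L)
        used_f[j] <- TRUE
        pick_f <- c(pick_f, j)
        n_fallback <- n_fallback + 1L
      }
    }
  })

  sel <- rbind(as.data.frame(pools$cand)[pick_c, , drop = FALSE],
               as.data.frame(pools$fb)[pick_f, , drop = FALSE])
  labeled_dataset(sel$id, sel$sequence, rep("non-allergen", nrow(sel)),
                  routes = "", species = sel$species,
                  provenance = sprintf(
                    "mirror set (%s screen, %d of %d from fallback, seed %d)",
                    screen, n_fallback, nrow(al), seed))
}

# TRUE for each query sequence sharing an exact k-mer with any target
kmer_similar <- function(queries, targets, k = 8L) {
  kmers <- function(s) {
    n <- nchar(s)
    if (n < k) return(character(0L))
    substring(s, 1:(n - k + 1L), k:n)
  }
  bank <- unique(unlist(lapply(targets, kmers), use.names = FALSE))
  vapply(queries, function(q) any(kmers(q) %in% bank), TRUE,
         USE.NAMES = FALSE)
}

# TRUE for each query with any blastp hit against the targets at `evalue`
blast_similar <- function(queries, targets, evalue = 0.001) {
  if (Sys.which("blastp") == "" || Sys.which("makeblastdb") == "") {
    stop("BLAST screen requested but blastp/makeblastdb not found on PATH; use screen = 'kmer'",
         call. = FALSE)
  }
  dir <- tempfile("blastscreen")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  dbfa <- file.path(dir, "targets.fa")
  qfa <- file.path(dir, "queries.fa")
  writeLines(paste0(">t", seq_along(targets), "\n", targets), dbfa)
  writeLines(paste0(">q", seq_along(queries), "\n", queries), qfa)
  system2("makeblastdb", c("-in", dbfa, "-dbtype", "prot"),
          stdout = FALSE, stderr = FALSE)
  out <- system2("blastp",
                 c("-query", qfa, "-db", dbfa, "-evalue", format(evalue),
                   "-outfmt", "'6 qseqid'"),
                 stdout = TRUE, stderr = FALSE)
  hits <- unique(sub("^q", "", out))
  seq_along(queries) %in% as.integer(hits)
}
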