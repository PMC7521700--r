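#' MinHash sketch of a genome
#'
#' Bottom-s MinHash over canonical k-mers (k = 31 by default): every
#' k-mer of the genome and its reverse complement are 2-bit packed, the
#' lexicographically smaller of the pair is hashed with a seeded 64-bit
#' avalanche mix, and the `sketch_size` smallest distinct hash values
#' are retained as the genome's fingerprint. Deterministic for a fixed
#' `hash_seed`; multi-record FASTA input is pooled into one sketch.
#' k-mers containing letters outside ACGT are skipped.
#'
#' @param x genome sequence(s): a path to a FASTA file, a
#'   [Biostrings::DNAStringSet], or a character vector of sequences.
#' @param genome_id identifier; defaults to the FASTA base name or
#'   `"genome"`.
#' @param k k-mer length, 1..31 (default 31).
#' @param sketch_size number of smallest hashes retained (default 1000);
#'   `Inf` keeps every distinct k-mer hash (a full sketch).
#' @param hash_seed seed of the hash function; sketches are only
#'   comparable at equal `k` and `hash_seed`.
#' @return object of class `minhash_sketch`: list with `genome_id`, `k`,
#'   `sketch_size`, `hash_seed`, `hashes` (sorted increasing).
#' @export
sketch_genome <- function(x, genome_id = NULL, k = 31L,
                          sketch_size = 1000, hash_seed = 42L) {
  if (is.character(x) && length(x) == 1 && nchar(x) < 1000 &&
      file.exists(x)) {
    if (is.null(genome_id)) genome_id <- sub("\\.[^.]*$", "", basename(x))
    x <- Biostrings::readDNAStringSet(x)
  }
  seqs <- as.character(x)
  if (is.null(genome_id)) genome_id <- "genome"
  if (any(nchar(seqs) < k)) {
    stop("sequence shorter than k", call. = FALSE)
  }
  hashes <- minhash_hashes_cpp(seqs, as.integer(k), sketch_size,
                               as.integer(hash_seed))
  if (length(hashes) == 0) {
    warning("no valid k-mers; empty sketch", call. = FALSE)
  }
  structure(list(genome_id = genome_id, k = as.integer(k),
                 sketch_size = sketch_size,
                 hash_seed = as.integer(hash_seed), hashes = hashes),
            class = "minhash_sketch")
}

#' @export
print.minhash_sketch <- function(x, ...) {
  cat(sprintf("minhash_sketch %s: k=%d, %d hashes (sketch_size %s)\n",
              x$genome_id, x$k, length(x$hashes),
              format(x$sketch_size)))
  invisible(x)
}

#' All-by-all Jaccard similarity of MinHash sketches
#'
#' Estimates the Jaccard Similarity Index (JSI) for every pair of
#' genomes from their sketches: the bottom-s sketch of the union is
#' formed by merging the two sketches and keeping the s smallest
#' hashes, and the JSI estimate is the fraction of those that occur in
#' both sketches (unbiased for bottom sketches). The diagonal is 1 and
#' the matrix is symmetric.
#'
#' @param sketches list of `minhash_sketch` objects sharing `k`,
#'   `sketch_size` and `hash_seed`.
#' @return symmetric numeric matrix of JSI values in \[0, 1\] with
#'   genome ids as dimnames.
#' @export
compare_sketches <- function(sketches) {
  stopifnot(length(sketches) >= 2,
            all(vapply(sketches, inherits, logical(1), "minhash_sketch")))
  ks <- vapply(sketches, `[[`, integer(1), "k")
  seeds <- vapply(sketches, `[[`, integer(1), "hash_seed")
  if (length(unique(ks)) != 1 || length(unique(seeds)) != 1) {
    stop("sketches must share k and hash_seed", call. = FALSE)
  }
  ids <- vapply(sketches, `[[`, character(1), "genome_id")
  n <- length(sketches)
  jsi <- diag(1, n)
  dimnames(jsi) <- list(ids, ids)
  ss <- vapply(sketches, function(x) as.numeric(x$sketch_size), numeric(1))
  if (length(unique(ss)) != 1) {
    stop("sketches must share sketch_size", call. = FALSE)
  }
  s <- ss[1]
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- sketches[[i]]$hashes
      b <- sketches[[j]]$hashes
      merged <- sort(unique(c(a, b)))
      bottom <- merged[seq_len(min(s, length(merged)))]
      jsi[i, j] <- jsi[j, i] <-
        sum(bottom %in% a & bottom %in% b) / length(bottom)
    }
  }
  jsi
}

#' Exact k-mer Jaccard similarity of two sequences
#'
#' Brute-force oracle: enumerates the canonical k-mer sets of both
#' sequences (canonical = lexicographic min of k-mer and reverse
#' complement; k-mers with letters outside ACGT are skipped) and
#' returns |A intersect B| / |A union B|. Independent of the sketching
#' code path.
#'
#' @param seq_a,seq_b sequences (character or
#'   [Biostrings::DNAString]/set; multi-record input is pooled).
#' @param k k-mer length.
#' @return exact Jaccard similarity in \[0, 1\].
#' @export
exact_jaccard <- function(seq_a, seq_b, k = 31L) {
  a <- canonical_kmers(seq_a, k)
  b <- canonical_kmers(seq_b, k)
  if (length(a) == 0 && length(b) == 0) return(NA_real_)
  length(intersect(a, b)) / length(union(a, b))
}

#' Canonical k-mer set of a sequence
#'
#' @inheritParams exact_jaccard
#' @param x sequence(s); multi-record input is pooled.
#' @return character vector of distinct canonical k-mers.
#' @export
canonical_kmers <- function(x, k = 31L) {
  seqs <- toupper(as.character(x))
  if (any(nchar(seqs) < k)) stop("sequence shorter than k", call. = FALSE)
  kmers <- unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    substring(s, 1:(n - k + 1), k:n)
  }))
  kmers <- kmers[!grepl("[^ACGT]", kmers)]
  if (!length(kmers)) return(character(0))
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(kmers)))
  unique(ifelse(kmers <= rc, kmers, rc))
}
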