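#' Simulate a base genome and mutated copies
#'
#' Generates one random genome sequence and `n - 1` copies carrying
#' independent point substitutions at the given per-base rate, for use as
#' sketching fixtures with a brute-force-computable exact k-mer Jaccard.
#'
#' @param n number of genomes (>= 1); the first is the unmutated base.
#' @param length genome length in bp (must exceed `k`).
#' @param mutation_rate per-base substitution probability for the copies.
#' @param seed RNG seed.
#' @param k k-mer length the sequences are destined for; only used to
#'   validate that `length >= k + 1`.
#' @return a [Biostrings::DNAStringSet] named `genome1..genomeN`.
#' @export
simulate_genomes <- function(n, length, mutation_rate = 0, seed = 1L,
                             k = 31L) {
  stopifnot(n >= 1, mutation_rate >= 0, mutation_rate <= 1)
  if (length < k + 1) {
    stop("`length` must be at least k + 1 bases", call. = FALSE)
  }
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  base_seq <- sample(bases, length, replace = TRUE)
  seqs <- vector("list", n)
  seqs[[1]] <- base_seq
  if (n > 1) {
    for (i in 2:n) {
      s <- base_seq
      mut <- which(runif(length) < mutation_rate)
      if (length(mut)) {
        # substitute to a uniformly chosen *different* base
        s[mut] <- vapply(s[mut], function(b) sample(setdiff(bases, b), 1L),
                         character(1))
      }
      seqs[[i]] <- s
    }
  }
  out <- Biostrings::DNAStringSet(vapply(seqs, paste, character(1),
                                         collapse = ""))
  names(out) <- sprintf("genome%d", seq_len(n))
  out
}
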