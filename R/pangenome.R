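#' Categorize pangenome genes by prevalence
#'
#' Assigns every gene of a presence/absence matrix to exactly one
#' prevalence class across genomes: core (>= 99% of genomes by
#' default), soft-core (95-99%), shell (15-95%) and cloud (0-15%).
#' Boundary placement follows the Roary convention: core is closed at
#' 99% and each lower interval is closed on the left, open on the
#' right. The thresholds are configurable.
#'
#' @param pam binary matrix or data.frame, genes (rows) x genomes
#'   (columns); entries 0/1 (or logical).
#' @param bounds named numeric vector of the three prevalence
#'   boundaries as fractions, `c(core = 0.99, soft_core = 0.95,
#'   shell = 0.15)`.
#' @return list of class `pangenome_categories`: `labels` (data.frame
#'   `gene`, `n_genomes`, `prevalence`, `category`) and `counts` (named
#'   integer vector over the four categories, summing to the number of
#'   genes).
#' @export
categorize_genes <- function(pam, bounds = c(core = 0.99,
                                             soft_core = 0.95,
                                             shell = 0.15)) {
  pam <- as.matrix(pam)
  if (nrow(pam) == 0 || ncol(pam) == 0) {
    stop("presence/absence matrix is empty", call. = FALSE)
  }
  if (is.logical(pam)) pam <- pam * 1L
  if (!all(pam %in% c(0, 1))) {
    stop("presence/absence entries must be 0/1", call. = FALSE)
  }
  stopifnot(all(c("core", "soft_core", "shell") %in% names(bounds)),
            bounds["core"] >= bounds["soft_core"],
            bounds["soft_core"] >= bounds["shell"])
  n_genomes <- rowSums(pam)
  prevalence <- n_genomes / ncol(pam)
  category <- ifelse(prevalence >= bounds["core"], "core",
              ifelse(prevalence >= bounds["soft_core"], "soft_core",
              ifelse(prevalence >= bounds["shell"], "shell", "cloud")))
  genes <- if (is.null(rownames(pam))) {
    sprintf("gene%05d", seq_len(nrow(pam)))
  } else {
    rownames(pam)
  }
  labels <- data.frame(gene = genes, n_genomes = as.integer(n_genomes),
                       prevalence = prevalence, category = category,
                       row.names = NULL, stringsAsFactors = FALSE)
  counts <- vapply(c("core", "soft_core", "shell", "cloud"),
                   function(cl) sum(category == cl), integer(1))
  structure(list(labels = labels, counts = counts),
            class = "pangenome_categories")
}

#' @export
print.pangenome_categories <- function(x, ...) {
  cat(sprintf("pangenome: %d genes -> core %d, soft-core %d, shell %d, cloud %d\n",
              nrow(x$labels), x$counts["core"], x$counts["soft_core"],
              x$counts["shell"], x$counts["cloud"]))
  invisible(x)
}

#' Simulate a random gene presence/absence matrix
#'
#' Genes are planted with prevalence drawn uniformly on \[0, 1\] and
#' presence sampled independently per genome, giving a matrix spanning
#' all four pangenome categories.
#'
#' @param n_genes,n_genomes matrix dimensions.
#' @param seed RNG seed.
#' @return binary integer matrix with gene/genome dimnames.
#' @export
simulate_presence_absence <- function(n_genes, n_genomes, seed = 1L) {
  set.seed(seed)
  prev <- runif(n_genes)
  pam <- matrix(
    rbinom(n_genes * n_genomes, 1L, rep(prev, n_genomes)),
    nrow = n_genes, ncol = n_genomes,
    dimnames = list(sprintf("gene%05d", seq_len(n_genes)),
                    sprintf("genome%03d", seq_len(n_genomes))))
  pam
}

#' Read a gene presence/absence matrix
#'
#' Supports a plain binary CSV (gene rows, genome columns, 0/1 entries)
#' or the Roary `gene_presence_absence.csv` layout, in which the first
#' 14 columns are gene metadata and a non-empty cell in a genome column
#' means presence.
#'
#' @param path CSV file.
#' @param format `"binary"` or `"roary"`.
#' @return binary integer matrix, genes x genomes.
#' @export
read_presence_absence <- function(path, format = c("binary", "roary")) {
  format <- match.arg(format)
  if (format == "binary") {
    df <- read.csv(path, row.names = 1, check.names = FALSE)
    pam <- as.matrix(df)
    storage.mode(pam) <- "integer"
  } else {
    df <- read.csv(path, check.names = FALSE, colClasses = "character")
    genome_cols <- seq(15L, ncol(df))
    pam <- (as.matrix(df[, genome_cols, drop = FALSE]) != "") * 1L
    rownames(pam) <- df[[1]]
  }
  pam
}
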