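#' Filter CAZyme / transporter hits (strict coverage rule)
#'
#' The carbohydrate-trait screen uses a stricter coverage rule than the
#' canonical nif screen: retain records with model coverage strictly
#' greater than 85% and e-value at most 1e-9. (The asymmetry — `>` here,
#' `>=` for the nif screen — is deliberate and preserved.)
#'
#' @param hits per-domain hits from [parse_domtblout()].
#' @param min_coverage strict coverage threshold, default 0.85.
#' @param max_evalue e-value ceiling (inclusive), default 1e-9.
#' @inheritParams filter_hits
#' @return protein-model records passing both rules.
#' @export
filter_cazy_hits <- function(hits, min_coverage = 0.85, max_evalue = 1e-9,
                             evalue = c("full", "domain"),
                             merge = c("union", "best")) {
  filter_hits(hits, min_coverage = min_coverage, max_evalue = max_evalue,
              coverage_strict = TRUE, evalue = match.arg(evalue),
              merge = match.arg(merge))
}

#' Per-genome carbohydrate-trait profile
#'
#' Counts, per genome and substrate group (Ara, Gal, GlcA, Fuc, Man,
#' Xyl, Ara/Xyl, promiscuous, ...), the number of distinct genes whose
#' retained hits match a model mapped to that group. Glycosyl hydrolase
#' and sugar-transporter hits use the same record structure; run the two
#' trait classes through separate maps.
#'
#' @param retained protein-model records from [filter_cazy_hits()].
#' @param map named character vector, model/family or TCDB accession ->
#'   substrate group (see [default_gene_map()]).
#' @param genomes optional genome ids to include as all-zero rows.
#' @return integer matrix, genomes x substrate groups.
#' @export
build_trait_profile <- function(retained, map, genomes = NULL) {
  if (length(map) == 0) stop("empty substrate map", call. = FALSE)
  build_profile(retained, map, genomes = genomes)
}
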