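#' Simulate HMMER3 domtblout files with planted hits
#'
#' Writes syntactically valid `hmmscan --domtblout` per-domain tables in
#' which each planted protein-model hit has a prescribed model coverage
#' and e-value, so that parsing and filtering can be verified against a
#' known truth. A planted hit with coverage c on a model of length L
#' occupies model positions 1..round(c*L), split into `n_domains`
#' contiguous domain lines whose interval union reproduces the planted
#' coverage exactly.
#'
#' @param planted named list: genome id -> named list: model name ->
#'   data.frame with columns `coverage` (in (0, 1\]), `evalue`, and
#'   optionally `n_domains` (default 1); one row per planted query
#'   protein.
#' @param model_length model length in positions used for every model
#'   (default 300, so that 75% and 85% coverage fall on integer position
#'   counts).
#' @param qlen query protein length written to the table.
#' @return list with `text` (named list of character vectors, one per
#'   genome, each a complete domtblout file) and `truth` (data.frame
#'   genome_id, model_name, count of planted proteins).
#' @export
simulate_domtblout <- function(planted, model_length = 300L, qlen = 350L) {
  stopifnot(is.list(planted))
  header <- c(
    paste0("# target name        accession   tlen query name           ",
           "accession   qlen   E-value  score  bias   #  of  c-Evalue  ",
           "i-Evalue  score  bias  from    to  from    to  from    to  ",
           "acc description of target"),
    paste0("#------------------- ---------- ----- -------------------- ",
           "---------- ----- --------- ------ ----- --- --- --------- ",
           "--------- ------ ----- ----- ----- ----- ----- ----- ----- ",
           "---- ---------------------"))
  texts <- vector("list", length(planted))
  names(texts) <- names(planted)
  truth <- list()
  for (g in names(planted)) {
    lines <- header
    prot <- 0L
    for (model in names(planted[[g]])) {
      hits <- planted[[g]][[model]]
      stopifnot(is.data.frame(hits),
                all(c("coverage", "evalue") %in% names(hits)))
      if (any(hits$coverage <= 0 | hits$coverage > 1)) {
        stop("planted coverage must lie in (0, 1]", call. = FALSE)
      }
      nd <- if ("n_domains" %in% names(hits)) hits$n_domains else
        rep(1L, nrow(hits))
      for (i in seq_len(nrow(hits))) {
        prot <- prot + 1L
        qname <- sprintf("%s_p%04d", g, prot)
        m <- max(1L, round(hits$coverage[i] * model_length))
        # split [1, m] into nd[i] contiguous chunks
        cuts <- unique(round(seq(0L, m, length.out = nd[i] + 1L)))
        for (d in seq_len(length(cuts) - 1L)) {
          from <- cuts[d] + 1L
          to <- cuts[d + 1L]
          lines <- c(lines, sprintf(
            paste0("%-20s %-10s %5d %-20s %-10s %5d %9.2g %6.1f %5.1f ",
                   "%3d %3d %9.2g %9.2g %6.1f %5.1f %5d %5d %5d %5d ",
                   "%5d %5d %4.2f planted synthetic hit"),
            model, "-", model_length, qname, "-", qlen,
            hits$evalue[i], 100.0, 0.1,
            d, length(cuts) - 1L, hits$evalue[i], hits$evalue[i],
            50.0, 0.1, from, to, from, to, from, to, 0.95))
        }
      }
      truth[[length(truth) + 1L]] <- data.frame(
        genome_id = g, model_name = model, count = nrow(hits),
        stringsAsFactors = FALSE)
    }
    texts[[g]] <- c(lines, "#")
  }
  truth_df <- if (length(truth)) do.call(rbind, truth) else
    data.frame(genome_id = character(0), model_name = character(0),
               count = integer(0), stringsAsFactors = FALSE)
  list(text = texts, truth = truth_df)
}
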