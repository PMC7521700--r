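#' Parse HMMER3 per-domain tabular output (domtblout)
#'
#' Reads the whitespace-delimited 23-column `hmmscan --domtblout` layout
#' (comment lines starting with `#` are skipped). In hmmscan output the
#' *target* is the profile HMM and the *query* is the predicted protein,
#' so the target name/tlen map to the model name/length here.
#'
#' @param x path to a domtblout file, or a character vector of its lines.
#' @param genome_id genome identifier attached to every hit (domtblout
#'   files are per-genome); defaults to the file base name, or `"genome"`
#'   for in-memory text.
#' @return data.frame of per-domain hits: `genome_id`,
#'   `query_protein_id`, `model_name`, `model_accession`, `model_length`,
#'   `full_seq_evalue`, `domain_ievalue`, `hmm_from`, `hmm_to`.
#' @export
parse_domtblout <- function(x, genome_id = NULL) {
  if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) {
    if (is.null(genome_id)) {
      genome_id <- sub("\\.[^.]*$", "", basename(x))
    }
    lines <- readLines(x)
  } else {
    if (is.null(genome_id)) genome_id <- "genome"
    lines <- unlist(strsplit(x, "\n", fixed = TRUE))
  }
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) {
    return(data.frame(genome_id = character(0),
                      query_protein_id = character(0),
                      model_name = character(0),
                      model_accession = character(0),
                      model_length = integer(0),
                      full_seq_evalue = numeric(0),
                      domain_ievalue = numeric(0),
                      hmm_from = integer(0), hmm_to = integer(0),
                      stringsAsFactors = FALSE))
  }
  parse_line <- function(line, lineno) {
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(tok) < 22) {
      stop(sprintf("malformed domtblout line %d: expected >= 22 fields, got %d",
                   lineno, length(tok)), call. = FALSE)
    }
    num <- suppressWarnings(as.numeric(tok[c(3, 6, 7, 13, 16, 17)]))
    if (anyNA(num)) {
      stop(sprintf("malformed domtblout line %d: non-numeric field", lineno),
           call. = FALSE)
    }
    list(model_name = tok[1], model_accession = tok[2],
         model_length = as.integer(num[1]),
         query_protein_id = tok[4],
         full_seq_evalue = num[3], domain_ievalue = num[4],
         hmm_from = as.integer(num[5]), hmm_to = as.integer(num[6]))
  }
  rows <- mapply(parse_line, lines[idx], idx, SIMPLIFY = FALSE)
  out <- data.frame(
    genome_id = genome_id,
    query_protein_id = vapply(rows, `[[`, character(1), "query_protein_id"),
    model_name = vapply(rows, `[[`, character(1), "model_name"),
    model_accession = vapply(rows, `[[`, character(1), "model_accession"),
    model_length = vapply(rows, `[[`, integer(1), "model_length"),
    full_seq_evalue = vapply(rows, `[[`, numeric(1), "full_seq_evalue"),
    domain_ievalue = vapply(rows, `[[`, numeric(1), "domain_ievalue"),
    hmm_from = vapply(rows, `[[`, integer(1), "hmm_from"),
    hmm_to = vapply(rows, `[[`, integer(1), "hmm_to"),
    row.names = NULL, stringsAsFactors = FALSE)
  bad <- out$hmm_from < 1 | out$hmm_to < out$hmm_from |
    out$hmm_to > out$model_length |
    out$full_seq_evalue < 0 | out$domain_ievalue < 0
  if (any(bad)) {
    stop(sprintf("malformed domtblout line %d: invalid coordinates or e-value",
                 idx[which(bad)[1]]), call. = FALSE)
  }
  out
}

#' Model coverage of protein-model matches
#'
#' Collapses per-domain hits to one record per (genome, protein, model)
#' and computes the fraction of model positions matched. With
#' `merge = "union"` (default) a protein's multiple domains on the same
#' model contribute the union of their model-coordinate intervals; with
#' `merge = "best"` only the single longest domain counts.
#'
#' @param hits data.frame from [parse_domtblout()].
#' @param merge `"union"` or `"best"`.
#' @return data.frame per protein-model pair: `genome_id`,
#'   `query_protein_id`, `model_name`, `model_length`, `coverage`,
#'   `full_seq_evalue` (minimum over domains), `domain_ievalue`
#'   (minimum over domains).
#' @export
model_coverage <- function(hits, merge = c("union", "best")) {
  merge <- match.arg(merge)
  if (nrow(hits) == 0) {
    return(cbind(hits[, c("genome_id", "query_protein_id", "model_name",
                          "model_length")],
                 coverage = numeric(0),
                 full_seq_evalue = numeric(0), domain_ievalue = numeric(0)))
  }
  key <- paste(hits$genome_id, hits$query_protein_id, hits$model_name,
               sep = "\r")
  split_idx <- split(seq_len(nrow(hits)), key)
  rows <- lapply(split_idx, function(i) {
    h <- hits[i, , drop = FALSE]
    covered <- if (merge == "union") {
      interval_union_length(h$hmm_from, h$hmm_to)
    } else {
      max(h$hmm_to - h$hmm_from + 1L)
    }
    data.frame(genome_id = h$genome_id[1],
               query_protein_id = h$query_protein_id[1],
               model_name = h$model_name[1],
               model_length = h$model_length[1],
               coverage = covered / h$model_length[1],
               full_seq_evalue = min(h$full_seq_evalue),
               domain_ievalue = min(h$domain_ievalue),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# total length of the union of closed integer intervals [from, to]
interval_union_length <- function(from, to) {
  o <- order(from, to)
  from <- from[o]; to <- to[o]
  total <- 0L
  cur_from <- from[1]; cur_to <- to[1]
  for (i in seq_along(from)[-1]) {
    if (from[i] <= cur_to + 1L) {
      cur_to <- max(cur_to, to[i])
    } else {
      total <- total + (cur_to - cur_from + 1L)
      cur_from <- from[i]; cur_to <- to[i]
    }
  }
  total + (cur_to - cur_from + 1L)
}

#' Filter protein-model matches on coverage and e-value
#'
#' Retains matches with coverage at least (`coverage_strict = FALSE`,
#' the canonical nif rule of >= 75% coverage and e-value <= 1e-9) or
#' strictly above (`coverage_strict = TRUE`, the CAZyme rule of > 85%)
#' the coverage threshold, and e-value no greater than `max_evalue`.
#' Relaxing either threshold never drops a retained match.
#'
#' @param hits per-domain hits from [parse_domtblout()].
#' @param min_coverage coverage threshold in (0, 1\].
#' @param max_evalue e-value ceiling.
#' @param coverage_strict if TRUE use strict `>` for coverage.
#' @param evalue which e-value the ceiling applies to: the full-sequence
#'   e-value (default) or the per-domain i-Evalue.
#' @param merge domain merging rule passed to [model_coverage()].
#' @return protein-model records (as [model_coverage()]) passing both
#'   rules.
#' @export
filter_hits <- function(hits, min_coverage = 0.75, max_evalue = 1e-9,
                        coverage_strict = FALSE,
                        evalue = c("full", "domain"),
                        merge = c("union", "best")) {
  evalue <- match.arg(evalue)
  stopifnot(min_coverage > 0, max_evalue > 0)
  pm <- model_coverage(hits, merge = match.arg(merge))
  ev <- if (evalue == "full") pm$full_seq_evalue else pm$domain_ievalue
  cov_ok <- if (coverage_strict) pm$coverage > min_coverage else
    pm$coverage >= min_coverage
  pm[cov_ok & ev <= max_evalue, , drop = FALSE]
}

#' Read an accession-to-gene-alias map from YAML
#'
#' @param path YAML file mapping model accessions/names to gene aliases
#'   (e.g. `TIGR01287: nifH`).
#' @return named character vector (names = accessions, values = aliases).
#' @export
read_gene_map <- function(path) {
  m <- unlist(yaml::read_yaml(path))
  if (!length(m)) stop("empty gene map: ", path, call. = FALSE)
  m
}

#' Default gene/substrate maps shipped with the package
#'
#' Curated accession-to-alias maps for canonical nif genes, alternative
#' nitrogenase genes, CAZy glycosyl-hydrolase substrate groups and sugar
#' transporters. The accession lists follow the published screens; the
#' accession-to-alias correspondence is curated (and for the trait maps
#' a replaceable stand-in), so all maps ship as editable YAML under
#' `inst/extdata`.
#'
#' @param which one of `"nif"`, `"alt_nif"`, `"cazy"`, `"transporter"`.
#' @return named character vector as from [read_gene_map()].
#' @export
default_gene_map <- function(which = c("nif", "alt_nif", "cazy",
                                       "transporter")) {
  which <- match.arg(which)
  file <- c(nif = "nif_gene_map.yaml",
            alt_nif = "alt_nif_gene_map.yaml",
            cazy = "cazy_substrate_map.yaml",
            transporter = "transporter_substrate_map.yaml")[[which]]
  read_gene_map(system.file("extdata", file, package = "diazokit",
                            mustWork = TRUE))
}

#' Per-genome gene profile from retained hits
#'
#' Counts, for each genome and gene alias, the number of *distinct*
#' query proteins with at least one retained match to a model mapped to
#' that alias. A protein with several domains (or several models mapped
#' to the same alias) is counted once.
#'
#' @param retained protein-model records from [filter_hits()].
#' @param gene_map named character vector, accession -> gene alias.
#' @param genomes optional character vector of genome ids to include as
#'   all-zero rows even without retained hits.
#' @return integer matrix, genomes x gene aliases (aliases in map
#'   order).
#' @export
build_profile <- function(retained, gene_map, genomes = NULL) {
  aliases <- unique(unname(gene_map))
  gn <- sort(unique(c(retained$genome_id, genomes)))
  prof <- matrix(0L, nrow = length(gn), ncol = length(aliases),
                 dimnames = list(gn, aliases))
  if (nrow(retained)) {
    unmapped <- setdiff(unique(retained$model_name), names(gene_map))
    if (length(unmapped)) {
      warning("hits on models absent from the gene map were excluded: ",
              paste(unmapped, collapse = ", "), call. = FALSE)
      retained <- retained[retained$model_name %in% names(gene_map), ,
                           drop = FALSE]
    }
    if (nrow(retained)) {
      alias <- unname(gene_map[retained$model_name])
      tab <- unique(data.frame(genome = retained$genome_id,
                               protein = retained$query_protein_id,
                               alias = alias, stringsAsFactors = FALSE))
      counts <- table(tab$genome, tab$alias)
      prof[rownames(counts), colnames(counts)] <-
        prof[rownames(counts), colnames(counts)] + as.integer(counts)
    }
  }
  prof
}

DOS_SANTOS_GENES <- c("nifH", "nifD", "nifK", "nifE", "nifN", "nifB")
ALT_NIF_GENES <- c("nifH", "nifD", "nifK",
                   "anfD", "anfK", "anfG", "vnfD", "vnfK", "vnfG")

#' Classify genomes against the Dos Santos minimal nif gene set
#'
#' The Dos Santos model holds that nifH, nifD, nifK, nifE, nifN and nifB
#' are jointly essential for diazotrophy. Genomes possessing homologs of
#' all six are DS-positive (DSP), genomes with none are DS-negative
#' (DSN), and genomes with a semi-complete set are Semi-DS (SDS). The
#' three groups partition any genome set.
#'
#' @param profile genomes x gene-alias count matrix from
#'   [build_profile()]; must contain all six Dos Santos aliases.
#' @return data.frame: `genome_id`, `group` in \{DSP, SDS, DSN\},
#'   `dos_santos_present` (comma-separated genes present).
#' @export
classify_nif_group <- function(profile) {
  missing <- setdiff(DOS_SANTOS_GENES, colnames(profile))
  if (length(missing)) {
    stop("profile lacks Dos Santos aliases: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  pres <- profile[, DOS_SANTOS_GENES, drop = FALSE] >= 1
  n_present <- rowSums(pres)
  group <- ifelse(n_present == length(DOS_SANTOS_GENES), "DSP",
                  ifelse(n_present == 0, "DSN", "SDS"))
  data.frame(
    genome_id = rownames(profile),
    group = unname(group),
    dos_santos_present = apply(pres, 1, function(r)
      paste(DOS_SANTOS_GENES[r], collapse = ",")),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Partition genomes by alternative nitrogenase gene content
#'
#' Considers the Mo-Fe nitrogenase operon genes (nifH, nifD, nifK)
#' together with the six alternative nitrogenase genes of the Fe-only
#' (anfD, anfK, anfG) and vanadium (vnfD, vnfK, vnfG) systems:
#' `all_nine` when every gene is present, `mo_fe_only` when nifHDK are
#' present without any alternative gene, `nifH_only` when only nifH is
#' present, and `none` as the explicit residual for any other
#' combination.
#'
#' @param profile genomes x gene-alias count matrix covering all nine
#'   aliases.
#' @return data.frame: `genome_id`, `category`.
#' @export
classify_alt_nif <- function(profile) {
  missing <- setdiff(ALT_NIF_GENES, colnames(profile))
  if (length(missing)) {
    stop("profile lacks alternative-nif aliases: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  pres <- profile[, ALT_NIF_GENES, drop = FALSE] >= 1
  alt <- c("anfD", "anfK", "anfG", "vnfD", "vnfK", "vnfG")
  category <- apply(pres, 1, function(r) {
    if (all(r)) {
      "all_nine"
    } else if (all(r[c("nifH", "nifD", "nifK")]) && !any(r[alt])) {
      "mo_fe_only"
    } else if (r[["nifH"]] && sum(r) == 1) {
      "nifH_only"
    } else {
      "none"
    }
  })
  data.frame(genome_id = rownames(profile), category = unname(category),
             row.names = NULL, stringsAsFactors = FALSE)
}
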