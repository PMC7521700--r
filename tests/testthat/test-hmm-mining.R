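domline <- function(model = "TIGR01287", tlen = 100, query = "p1",
                    evalue = 1e-12, ievalue = evalue, from = 1, to = 100,
                    dom = 1, ndom = 1) {
  sprintf("%s - %d %s - 350 %.2g 100.0 0.1 %d %d %.2g %.2g 50.0 0.1 %d %d %d %d %d %d 0.95 test",
          model, tlen, query, evalue, dom, ndom, ievalue, ievalue,
          from, to, from, to, from, to)
}

test_that("domtblout parsing maps the HMMER3 column layout", {
  txt <- c("# comment", domline(from = 26, to = 100), "#")
  hits <- parse_domtblout(txt, genome_id = "G1")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$model_name, "TIGR01287")
  expect_equal(hits$model_length, 100L)
  expect_equal(hits$query_protein_id, "p1")
  expect_equal(hits$hmm_from, 26L)
  expect_equal(hits$hmm_to, 100L)
  expect_equal(hits$full_seq_evalue, 1e-12)

  expect_equal(nrow(parse_domtblout(c("# only", "# comments"))), 0L)

  txt3 <- c(domline(query = "p1", dom = 1, ndom = 2, from = 1, to = 40),
            domline(query = "p1", dom = 2, ndom = 2, from = 60, to = 90),
            domline(query = "p2", from = 5, to = 95))
  hits3 <- parse_domtblout(txt3)
  expect_equal(nrow(hits3), 3L)
  expect_equal(length(unique(hits3$query_protein_id)), 2L)

  expect_error(parse_domtblout(c("# ok", "too few fields")), "line 2")
  expect_error(parse_domtblout(domline(from = 50, to = 20)), "line 1")
})

test_that("model coverage merges domains by interval union", {
  one <- parse_domtblout(domline(from = 1, to = 100))
  expect_equal(model_coverage(one)$coverage, 1.0)
  expect_equal(model_coverage(parse_domtblout(
    domline(from = 26, to = 100)))$coverage, 0.75)

  two <- parse_domtblout(c(domline(from = 1, to = 40, dom = 1, ndom = 2),
                           domline(from = 30, to = 80, dom = 2, ndom = 2)))
  expect_equal(model_coverage(two)$coverage, 0.80)
  expect_equal(model_coverage(two, merge = "best")$coverage, 0.51)
})

test_that("interval-union coverage equals brute-force position marking", {
  set.seed(13)
  for (rep in 1:30) {
    len <- sample(50:300, 1)
    nd <- sample(1:6, 1)
    from <- sample(seq_len(len - 5), nd, replace = TRUE)
    to <- pmin(len, from + sample(0:40, nd, replace = TRUE))
    lines <- vapply(seq_len(nd), function(i) {
      domline(tlen = len, from = from[i], to = to[i], dom = i, ndom = nd)
    }, character(1))
    cov <- model_coverage(parse_domtblout(lines))$coverage
    expect_equal(cov, brute_union_length(from, to, len) / len)
  }
})

test_that("filter boundaries follow the canonical and strict rules", {
  mk <- function(cov, e) parse_domtblout(
    domline(tlen = 100, from = 1, to = round(cov * 100), evalue = e))
  # canonical: >= 75% coverage, e-value <= 1e-9, both inclusive
  expect_equal(nrow(filter_hits(mk(0.75, 1e-9))), 1L)
  expect_equal(nrow(filter_hits(mk(0.74, 1e-12))), 0L)
  expect_equal(nrow(filter_hits(mk(0.90, 1e-8))), 0L)
  # alternative-nif thresholds: e <= 1e-6, coverage >= 85%
  expect_equal(nrow(filter_hits(mk(0.90, 1e-6), min_coverage = 0.85,
                                max_evalue = 1e-6)), 1L)
  # CAZy rule: coverage strictly > 85%
  expect_equal(nrow(filter_cazy_hits(mk(0.85, 1e-12))), 0L)
  expect_equal(nrow(filter_cazy_hits(mk(0.86, 1e-9))), 1L)
})

test_that("filtering is monotone under threshold relaxation", {
  set.seed(41)
  lines <- vapply(1:200, function(i) {
    cov <- sample(50:100, 1)
    domline(model = sample(c("M1", "M2"), 1), query = sprintf("p%03d", i),
            tlen = 100, from = 1, to = cov,
            evalue = 10^(-sample(3:15, 1)))
  }, character(1))
  hits <- parse_domtblout(lines)
  strict <- filter_hits(hits, min_coverage = 0.85, max_evalue = 1e-9)
  relaxed <- filter_hits(hits, min_coverage = 0.75, max_evalue = 1e-6)
  key <- function(d) paste(d$query_protein_id, d$model_name)
  expect_true(all(key(strict) %in% key(relaxed)))
})

test_that("profiles count unique coding sequences per gene", {
  gm <- c(TIGR01287 = "nifH", TIGR01282 = "nifD")
  # one protein, two domains on a nifH model -> count 1
  hits <- parse_domtblout(c(
    domline(from = 1, to = 60, dom = 1, ndom = 2),
    domline(from = 50, to = 100, dom = 2, ndom = 2)))
  prof <- build_profile(filter_hits(hits), gm)
  expect_equal(unname(prof[, "nifH"]), 1L)
  expect_equal(unname(prof[, "nifD"]), 0L)

  # two proteins -> count 2
  hits2 <- parse_domtblout(c(domline(query = "p1"), domline(query = "p2")))
  expect_equal(unname(build_profile(filter_hits(hits2), gm)[, "nifH"]), 2L)

  # no retained hits -> all-zero profile for requested genomes
  prof0 <- build_profile(filter_hits(hits2, max_evalue = 1e-20), gm,
                         genomes = "G9")
  expect_equal(sum(prof0), 0L)
  expect_equal(rownames(prof0), "G9")

  # unmapped model -> warning and exclusion
  hits3 <- parse_domtblout(domline(model = "TIGR99999"))
  expect_warning(p3 <- build_profile(filter_hits(hits3), gm), "excluded")
  expect_equal(sum(p3), 0L)
})

test_that("Dos Santos classification defines DSP, SDS and DSN exactly", {
  genes <- c("nifH", "nifD", "nifK", "nifE", "nifN", "nifB")
  prof <- rbind(all6 = rep(1L, 6), none = rep(0L, 6),
                onlyH = c(1L, rep(0L, 5)), five = c(rep(1L, 5), 0L),
                multi = c(2L, 1L, 1L, 1L, 1L, 3L))
  colnames(prof) <- genes
  calls <- classify_nif_group(prof)
  expect_equal(calls$group, c("DSP", "DSN", "SDS", "SDS", "DSP"))
  expect_equal(calls$dos_santos_present[3], "nifH")
  expect_error(classify_nif_group(prof[, 1:5]), "lacks")
})

test_that("alternative-nif categories partition crafted profiles", {
  genes <- c("nifH", "nifD", "nifK", "anfD", "anfK", "anfG",
             "vnfD", "vnfK", "vnfG")
  prof <- rbind(
    all9 = rep(1L, 9),
    hdk = c(1L, 1L, 1L, rep(0L, 6)),
    honly = c(1L, rep(0L, 8)),
    mixed = c(1L, 1L, 0L, 1L, rep(0L, 5)))
  colnames(prof) <- genes
  calls <- classify_alt_nif(prof)
  expect_equal(calls$category, c("all_nine", "mo_fe_only", "nifH_only",
                                 "none"))
  expect_error(classify_alt_nif(prof[, 1:8]), "lacks")
})

test_that("group calls partition random synthetic genome sets", {
  set.seed(19)
  genes <- c("nifH", "nifD", "nifK", "nifE", "nifN", "nifB")
  prof <- matrix(rbinom(50 * 6, 2, 0.4), nrow = 50,
                 dimnames = list(sprintf("G%02d", 1:50), genes))
  calls <- classify_nif_group(prof)
  expect_equal(nrow(calls), 50L)
  tab <- table(factor(calls$group, levels = c("DSP", "SDS", "DSN")))
  expect_equal(sum(tab), 50L)
})

test_that("planted profiles round-trip through text, parse and filter", {
  set.seed(23)
  gm <- default_gene_map("nif")
  genomes <- sprintf("G%02d", 1:6)
  planted <- lapply(genomes, function(g) {
    models <- sample(names(gm), sample(0:6, 1))
    hits <- lapply(models, function(m) {
      n <- sample(1:2, 1)
      data.frame(coverage = runif(n, 0.80, 1.0),
                 evalue = 10^(-runif(n, 10, 30)),
                 n_domains = sample(1:3, n, replace = TRUE))
    })
    names(hits) <- models
    hits
  })
  names(planted) <- genomes
  out <- simulate_domtblout(planted)
  hits <- do.call(rbind, lapply(genomes, function(g) {
    parse_domtblout(out$text[[g]], genome_id = g)
  }))
  prof <- build_profile(filter_hits(hits), gm, genomes = genomes)
  for (i in seq_len(nrow(out$truth))) {
    expect_equal(
      unname(prof[out$truth$genome_id[i],
                  unname(gm[out$truth$model_name[i]])]),
      out$truth$count[i])
  }
  expect_equal(sum(prof), sum(out$truth$count))
})
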