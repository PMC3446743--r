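norm_cat <- function(counts, accession) {
  normalize_catalogue(clean_catalogue(sage_catalogue(counts, accession)))
}

tiny_panel <- function(genes, tags) {
  structure(data.frame(gene_symbol = genes, tag = tags,
                       stringsAsFactors = FALSE),
            class = c("gene_tag_catalogue", "data.frame"))
}

test_that("build_matrix maps panel tags to per-library tpm", {
  p <- tiny_panel("G1", "ACGTACGTAC")
  m <- build_matrix(list(norm_cat(c(ACGTACGTAC = 7), "L1")), p)
  expect_equal(unname(m[1, 1]), 1e6)
  expect_equal(rownames(m), "L1")
  expect_equal(colnames(m), "G1")

  # a library lacking all panel tags gives an all-zero row
  m2 <- build_matrix(list(norm_cat(c(GGGGGGGGGG = 10), "L2")), p)
  expect_true(all(m2 == 0))
})

test_that("build_matrix equals brute-force lookup on random instances", {
  set.seed(21)
  for (rep in 1:20) {
    cats <- lapply(1:4, function(i) {
      normalize_catalogue(clean_catalogue(
        random_catalogue(n_tags = 80, accession = sprintf("L%d", i))))
    })
    # panel: a mix of present and absent tags
    present <- sample(names(cats[[1]]$tpm), 5)
    absent <- setdiff(replicate(5, random_dna(10)), present)
    tags <- c(present, absent)
    p <- tiny_panel(sprintf("G%02d", seq_along(tags)), tags)
    m <- build_matrix(cats, p)
    for (i in seq_along(cats)) {
      for (j in seq_along(tags)) {
        want <- cats[[i]]$tpm[tags[j]]
        expect_equal(unname(m[i, j]),
                     if (is.na(want)) 0 else unname(want))
      }
    }
  }
})

test_that("shared panel tags warn, credit both genes, and count once in sums", {
  p <- tiny_panel(c("GA", "GB", "GC"),
                  c("ACGTACGTAC", "ACGTACGTAC", "TTTTGGGGCC"))
  expect_warning(
    m <- build_matrix(list(norm_cat(c(ACGTACGTAC = 2, TTTTGGGGCC = 2), "L")),
                      p),
    "shared")
  expect_equal(unname(m[1, "GA"]), unname(m[1, "GB"]))
  s <- summarize_matrix(m, n_panel_genes = 3)
  # 2 distinct tags at 50% each: the shared tag is not double-counted
  expect_equal(s$sum_tpm, 1e6)
})

test_that("summarize_library computes sum/avg/max, percent and dominance", {
  vals <- c(A = 100, B = 300, C = 0)
  s <- summarize_library(vals, n_panel_genes = 4, accession = "L")
  expect_equal(s$sum_tpm, 400)
  expect_equal(s$avg_tpm, 100)
  expect_equal(s$max_tpm, 300)
  expect_equal(s$max_gene, "B")
  expect_equal(s$percent_of_transcriptome, 0.04)
  expect_equal(s$dominance, 0.75)

  zero <- summarize_library(c(A = 0, B = 0), n_panel_genes = 2)
  expect_equal(zero$sum_tpm, 0)
  expect_equal(zero$dominance, 0)

  # argmax ties break to the lexicographically smallest gene symbol
  tie <- summarize_library(c(ZZ = 5, AA = 5), n_panel_genes = 2)
  expect_equal(tie$max_gene, "AA")
})

test_that("summary invariants hold on random matrices", {
  set.seed(31)
  for (rep in 1:20) {
    cats <- lapply(1:6, function(i) {
      normalize_catalogue(clean_catalogue(
        random_catalogue(n_tags = 60, accession = sprintf("L%d", i))))
    })
    tags <- unique(unlist(lapply(cats, function(x) names(x$tpm))))[1:20]
    p <- tiny_panel(sprintf("G%02d", 1:20), tags)
    s <- summarize_matrix(build_matrix(cats, p))
    expect_true(all(s$max_tpm <= s$sum_tpm + 1e-9))
    expect_true(all(s$sum_tpm <= 1e6 + 1e-6))
    expect_equal(s$avg_tpm * 20, s$sum_tpm, tolerance = 1e-9)
  }
})

test_that("dominance_report is max/sum in percent and rejects zero sums", {
  s <- data.frame(max_tpm = c(40054.67, 100), sum_tpm = c(43563.92, 100))
  expect_equal(dominance_report(s), c(40054.67 / 43563.92 * 100, 100),
               tolerance = 1e-12)
  expect_error(dominance_report(data.frame(max_tpm = 0, sum_tpm = 0)),
               "undefined")
})

test_that("rank_deciles returns ceil(fraction * n) entries with tie rule", {
  mk <- function(acc, s) data.frame(accession = acc, sum_tpm = s,
                                    stringsAsFactors = FALSE)
  ten <- do.call(rbind, lapply(1:10, function(i) mk(sprintf("L%02d", i), i)))
  d <- rank_deciles(ten, 0.10)
  expect_equal(nrow(d$top), 1L)
  expect_equal(d$top$accession, "L10")
  expect_equal(d$bottom$accession, "L01")

  many <- do.call(rbind, lapply(1:492, function(i) {
    mk(sprintf("L%03d", i), i)
  }))
  d2 <- rank_deciles(many, 0.10)
  expect_equal(nrow(d2$top), 50L)  # ceiling(49.2)
  expect_length(intersect(d2$top$accession, d2$bottom$accession), 0)

  equal <- do.call(rbind, lapply(c("B", "A", "C"), function(a) mk(a, 7)))
  d3 <- rank_deciles(equal, 0.34)
  expect_equal(d3$top$accession, c("A", "B"))
  expect_equal(d3$bottom$accession, c("A", "B"))
})

test_that("detection profiles count libraries and flag minimum-level genes", {
  p <- tiny_panel(c("RARE", "NEVER", "COMMON"),
                  c("ACGTACGTAC", "CCCCCGGGGG", "TTTTGGGGCC"))
  counts <- list(
    c(ACGTACGTAC = 1, TTTTGGGGCC = 50, AAGGTTCCAA = 1000),
    c(TTTTGGGGCC = 1, AAGGTTCCAA = 2000),
    c(ACGTACGTAC = 1, TTTTGGGGCC = 9, AAGGTTCCAA = 500),
    c(ACGTACGTAC = 1, AAGGTTCCAA = 100)
  )
  cats <- lapply(seq_along(counts), function(i) {
    clean_catalogue(sage_catalogue(counts[[i]], sprintf("L%d", i)))
  })
  ncats <- lapply(cats, normalize_catalogue)
  m <- build_matrix(ncats, p)
  raw <- build_raw_matrix(cats, p)
  prof <- detection_profiles(m, raw)
  expect_equal(prof$n_libraries_detected[prof$gene_symbol == "RARE"], 3)
  expect_true(prof$min_level_only[prof$gene_symbol == "RARE"])
  expect_equal(prof$n_libraries_detected[prof$gene_symbol == "NEVER"], 0)
  expect_equal(prof$n_libraries_detected[prof$gene_symbol == "COMMON"], 3)
  expect_false(prof$min_level_only[prof$gene_symbol == "COMMON"])

  # brute-force tally on a random instance
  set.seed(55)
  rm <- matrix(rpois(60, 0.7), 10, 6,
               dimnames = list(sprintf("L%d", 1:10), sprintf("G%d", 1:6)))
  tm <- rm * 17.3
  prof2 <- detection_profiles(tm, rm)
  for (j in 1:6) {
    expect_equal(prof2$n_libraries_detected[j], sum(rm[, j] > 0))
    expect_equal(prof2$min_level_only[j], all(rm[rm[, j] > 0, j] == 1))
  }
})

test_that("cohort_statistics averages percent shares per cluster and overall", {
  s <- data.frame(cluster = c("C", "C", "N"),
                  percent_of_transcriptome = c(1.0, 3.0, 5.0))
  cs <- cohort_statistics(s)
  expect_equal(cs$per_cluster[["C"]], 2.0)
  expect_equal(cs$per_cluster[["N"]], 5.0)
  expect_equal(cs$overall, 3.0)
  expect_false("IV" %in% names(cs$per_cluster))

  one <- cohort_statistics(data.frame(cluster = "D",
                                      percent_of_transcriptome = 0.9))
  expect_equal(one$overall, 0.9)
})
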