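test_that("VCF genotypes are coded toward the minor allele", {
  path <- tiny_vcf()
  g <- read_genotypes(path, format = "vcf")
  # site 1: 0/0, 0/1, 1/1 -> dosages 0,1,2 toward ALT (already minor at 0.5)
  expect_equal(unname(g$counts[, "1:100:A:G"]), c(0, 1, 2))
  expect_equal(g$variants$maf[1], 0.5)
  # site 2: ALT frequency 5/6 > 0.5 -> flipped so coded frequency is 1/6
  expect_equal(unname(g$counts[, "1:200:C:T"]), c(0, 0, 1))
  expect_equal(g$variants$maf[2], 1 / 6)
})

test_that("multi-allelic VCF sites are dropped with a warning", {
  path <- tiny_vcf("1\t300\trs3\tA\tG,T\t.\tPASS\t.\tGT\t0/0\t0/1\t0/2")
  expect_warning(g <- read_genotypes(path, format = "vcf"), "multi-allelic")
  expect_equal(ncol(g$counts), 2L)
})

test_that("matrix format reads 0/1/2 and mean-imputes missing entries", {
  # 2 variants x 4 samples; vB has one '.' among observed (0, 2, 1):
  # observed MAF = 3/6 = 0.5, imputed dosage = 2 * 0.5 = 1
  path <- write_tmp(c(
    "variant_id\ts1\ts2\ts3\ts4",
    "vA\t0\t1\t0\t0",
    "vB\t0\t2\t.\t1"
  ))
  g <- read_genotypes(path, format = "matrix", missing = "mean")
  expect_equal(unname(g$counts[, "vB"]), c(0, 2, 1, 1))
  expect_equal(g$variants$maf[2], mean(c(0, 2, 1, 1)) / 2)
  # drop_variant policy removes vB entirely
  expect_warning(
    g2 <- read_genotypes(path, format = "matrix", missing = "drop_variant"),
    "dropping"
  )
  expect_equal(colnames(g2$counts), "vA")
  expect_error(read_genotypes(path, format = "matrix", missing = "fail"),
               "missing")
})

test_that("matrix write/read round-trip reproduces counts exactly", {
  g <- make_genotypes(10, 5, seed = 1)
  path <- tempfile(fileext = ".tsv")
  write_genotypes(g, path)
  g2 <- read_genotypes(path, format = "matrix")
  expect_identical(unname(g2$counts), unname(g$counts))
  expect_equal(g2$variants$maf, g$variants$maf)
})

test_that("rare filter keeps exactly the polymorphic sub-threshold variants", {
  counts <- cbind(
    v1 = c(1, rep(0, 99)),   # MAF 0.005
    v2 = c(2, 1, 1, rep(0, 97)), # MAF 0.02
    v3 = rep(0, 100)         # monomorphic
  )
  rownames(counts) <- paste0("s", 1:100)
  g <- genotype_matrix(counts)
  expect_warning(gr <- rare_filter(g, 0.01), "monomorphic")
  expect_equal(colnames(gr$counts), "v1")
  # idempotent
  expect_identical(rare_filter(gr, 0.01)$counts, gr$counts)
  # threshold 0.5 keeps all polymorphic variants
  expect_warning(g_all <- rare_filter(g, 0.5), "monomorphic")
  expect_equal(colnames(g_all$counts), c("v1", "v2"))
  # nothing survives -> empty-set condition
  g_common <- make_genotypes(20, 3, maf = c(0.3, 0.4, 0.2), seed = 2)
  expect_error(rare_filter(g_common, 0.01), class = "rvlrt_empty_set")
})

test_that("MAF agrees with brute-force allele counting", {
  for (s in 1:5) {
    g <- make_genotypes(10, 5, seed = s)
    brute <- apply(g$counts, 2, function(col) sum(col) / (2 * length(col)))
    expect_equal(g$variants$maf, unname(brute), tolerance = 1e-12)
  }
})

test_that("alignment intersects and reorders samples and set variants", {
  g <- make_genotypes(6, 4, seed = 3)
  ph <- make_data(7, seed = 4) # one extra sample s7
  al <- align_data(g, ph)
  expect_equal(al$genotypes$samples, al$phenotypes$sample_id)
  expect_equal(nrow(al$phenotypes), 6L)
  # identical sample lists pass through unchanged
  al2 <- align_data(g, ph[1:6, ])
  expect_identical(al2$genotypes$counts, g$counts)
  # set with absent ids: present ones kept, warning notes the absences
  set <- list(name = "S", variant_ids = c("v1", "v3", "nope1", "nope2", "v2"))
  expect_warning(al3 <- align_data(g, ph, set), "2 of 5")
  expect_equal(colnames(al3$genotypes$counts), c("v1", "v3", "v2"))
  expect_error(align_data(g, ph[0, ], NULL), "fewer than 2")
})

test_that("set files are parsed with de-duplication", {
  path <- write_tmp(c("geneA\tv1", "geneA\tv2", "geneA\tv1", "geneB\tv3"))
  expect_warning(sets <- read_variant_sets(path), "duplicate")
  expect_named(sets, c("geneA", "geneB"))
  expect_equal(sets$geneA$variant_ids, c("v1", "v2"))
})

test_that("result files render p-values and lambda columns as specified", {
  rec <- tibble::tibble(
    set = c("g1", "g2"), m_total = c(5L, 3L), m_rare = c(4L, 2L),
    p_SKAT = c(4.99e-5, 0.25), lambda_LRT.M = c(1.778, 4e-4),
    note = c("ok", "ok")
  )
  path <- tempfile(fileext = ".tsv")
  write_results(rec, path)
  tab <- read.delim(path, colClasses = "character")
  expect_equal(tab$p_SKAT, c("4.99e-05", "0.25"))
  # machine column keeps full precision
  expect_equal(as.numeric(tab$lambda_LRT.M), c(1.778, 4e-4))
  write_results(rec, path, human = TRUE)
  tab_h <- read.delim(path, colClasses = "character")
  expect_equal(tab_h$lambda_LRT.M, c("1.778", "<0.001"))
  # empty record list -> header-only file
  write_results(rec[0, ], path)
  expect_equal(nrow(read.delim(path)), 0L)
})
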