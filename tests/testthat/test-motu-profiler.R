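mg_fixture <- function(n_species = 30, n_samples = 40, noise_sd = 0.1,
                       seed = 7L) {
  set.seed(seed)
  load <- matrix(10^rnorm(n_species * n_samples), n_species, n_samples,
                 dimnames = list(sprintf("sp%02d", seq_len(n_species)),
                                 sprintf("s%02d", seq_len(n_samples))))
  simulate_marker_genes(load, n_families = 10, noise_sd = noise_sd,
                        seed = seed)
}

test_that("noise-free marker genes recover the true species partition", {
  mg <- mg_fixture(n_species = 12, noise_sd = 0)
  gr <- link_marker_genes(mg, seed = 1L)
  expect_length(gr, 12L)
  truth <- vapply(split(mg$genes$gene_id, mg$genes$species),
                  function(m) paste(sort(m), collapse = "|"), character(1))
  recovered <- vapply(gr, function(g) paste(sort(g$members), collapse = "|"),
                      character(1))
  expect_setequal(unname(recovered), unname(truth))
})

test_that("two genes with identical profiles form one group of size 2", {
  counts <- matrix(10^rnorm(10), 1, 10)
  counts <- rbind(counts, counts)
  # a third, unrelated gene stays a singleton and is discarded
  counts <- rbind(counts, matrix(10^rnorm(10), 1, 10))
  rownames(counts) <- c("gA", "gB", "gC")
  colnames(counts) <- sprintf("s%02d", 1:10)
  genes <- data.frame(gene_id = c("gA", "gB", "gC"),
                      family = c("COG01", "COG02", "COG03"),
                      length = c(1000L, 1000L, 800L))
  gr <- link_marker_genes(marker_gene_table(genes, counts), seed = 3L)
  expect_length(gr, 1L)
  expect_setequal(gr[[1]]$members, c("gA", "gB"))
})

test_that("independent white-noise genes rarely link at FDR 0.02", {
  n_with_groups <- 0L
  for (s in 1:20) {
    set.seed(s)
    counts <- matrix(1000 * 10^rnorm(20 * 32, 0, 0.5), 20, 32,
                     dimnames = list(sprintf("g%02d", 1:20),
                                     sprintf("s%02d", 1:32)))
    genes <- data.frame(gene_id = rownames(counts),
                        family = rep(sprintf("COG%02d", 1:10), 2),
                        length = 1000L)
    gr <- link_marker_genes(marker_gene_table(genes, counts),
                            n_permutations = 200L, seed = s)
    if (length(gr) > 0L) n_with_groups <- n_with_groups + 1L
  }
  expect_lte(n_with_groups, 1L)   # >= 95% of seeds group-free
})

test_that("linkage groups respect size and single-copy constraints", {
  mg <- mg_fixture(noise_sd = 0.2)
  gr <- link_marker_genes(mg, seed = 2L)
  for (g in gr) {
    expect_gte(length(g$members), 2L)
    expect_lte(length(g$members), 10L)
    expect_false(anyDuplicated(g$families) > 0)
  }
  la <- lg_abundance(mg, gr)
  expect_true(all(abs(colSums(la) - 1) < 1e-9))
})

test_that("group abundance is summed counts over summed lengths, closed", {
  genes <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                      family = c("COG01", "COG02", "COG01", "COG02"),
                      length = c(1000L, 500L, 400L, 600L))
  counts <- matrix(c(1000, 500, 300, 200,   # sample A
                     0, 0, 150, 100),       # sample B
                   4, 2, dimnames = list(genes$gene_id, c("A", "B")))
  mg <- marker_gene_table(genes, counts)
  groups <- list(LG1 = list(members = c("g1", "g2")),
                 LG2 = list(members = c("g3", "g4")))
  la <- lg_abundance(mg, groups)
  # raw coverages in A: (1000+500)/1500 = 1 and (300+200)/1000 = 0.5
  expect_equal(unname(la[, "A"]), c(1, 0.5) / 1.5)
  # LG1 absent in B -> abundance 0, LG2 takes all mass
  expect_equal(unname(la[, "B"]), c(0, 1))
  # two groups with raw coverages 3:1 close to 0.75/0.25
  counts2 <- matrix(c(4500, 0, 600, 400), 4, 1,
                    dimnames = list(genes$gene_id, "C"))
  la2 <- lg_abundance(marker_gene_table(genes, counts2), groups)
  expect_equal(unname(la2[, "C"]), c(0.75, 0.25))
  expect_error(lg_abundance(mg, list(list(members = character(0)))), "empty")
})

test_that("detection limits take the per-sample minimum and global maximum", {
  m <- cbind(a = c(0.9, 0.0999, 1e-4), b = c(0.5, 2e-5, 0.4999))
  rownames(m) <- c("x", "y", "z")
  dl <- detection_limits(m)
  expect_equal(unname(dl$per_sample), c(1e-4, 2e-5))
  expect_equal(dl$global, 1e-4)   # the least sensitive sample
  single <- detection_limits(m[, 1, drop = FALSE])
  expect_equal(single$global, unname(single$per_sample))
  expect_error(detection_limits(cbind(c(0, 0))), "no non-zero")
})

test_that("linkage-group annotation requires rank-wise unanimity", {
  mk_lin <- function(genus, species) {
    c(superkingdom = "Bacteria", phylum = "Firmicutes", class = "Bacilli",
      order = "Lactobacillales", family = "Streptococcaceae",
      genus = genus, species = species)
  }
  lins <- list(g1 = mk_lin("Gen1", "Sp1"), g2 = mk_lin("Gen1", "Sp1"))
  ids <- c(g1 = 98, g2 = 97)
  fams <- c(g1 = "COG01", g2 = "COG02")
  cuts <- c(COG01 = 96.5, COG02 = 95.0)
  full <- annotate_lg(lins, ids, fams, cuts)
  expect_equal(full[["species"]], "Sp1")
  # species split within one genus -> genus only
  lins2 <- lins
  lins2$g2["species"] <- "Sp2"
  part <- annotate_lg(lins2, ids, fams, cuts)
  expect_equal(part[["genus"]], "Gen1")
  expect_true(is.na(part[["species"]]))
  # unanimous species but one identity below its family cutoff -> genus only
  low <- annotate_lg(lins, c(g1 = 98, g2 = 94), fams, cuts)
  expect_equal(low[["genus"]], "Gen1")
  expect_true(is.na(low[["species"]]))
  expect_error(annotate_lg(list(), ids, fams, cuts), "annotated member")
})

test_that("marker-gene tables round-trip through TSV", {
  dir <- withr::local_tempdir()
  mg <- mg_fixture(n_species = 4, n_samples = 6)
  path <- file.path(dir, "mg.tsv")
  write_marker_genes_tsv(mg, path)
  back <- read_marker_genes_tsv(path)
  expect_equal(back$genes$gene_id, mg$genes$gene_id)
  expect_equal(back$counts, mg$counts, tolerance = 1e-7)
})
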