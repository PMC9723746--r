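test_that("reading transposes taxa-as-rows input and round-trips", {
  tsv <- tempfile(fileext = ".tsv")
  counts <- matrix(1:12, nrow = 4,
                   dimnames = list(paste0("asv", 1:4), paste0("s", 1:3)))
  write.table(data.frame(id = rownames(counts), counts, check.names = FALSE),
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  tab <- read_community_table(tsv, orientation = "taxa-as-rows")
  expect_identical(dim(tab), c(3L, 4L))
  expect_identical(tab$counts["s2", "asv3"], 7L)

  out <- tempfile(fileext = ".tsv")
  write_community_table(tab, out)
  back <- read_community_table(out, orientation = "samples-as-rows")
  expect_identical(back$counts, tab$counts)
})

test_that("QIIME2-style leading comments and lineage columns are handled", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("# Constructed from biom file",
               "#OTU ID\ts1\ts2\ttaxonomy",
               "asv1\t5\t0\tk__Bacteria; p__Proteobacteria; c__Gamma",
               "asv2\t1\t2\tk__Bacteria; p__Firmicutes"), tsv)
  tab <- read_community_table(tsv, orientation = "taxa-as-rows")
  expect_identical(dim(tab), c(2L, 2L))
  expect_identical(tab$taxonomy["asv1", "class"], "Gamma")
  expect_true(is.na(tab$taxonomy["asv2", "class"]))
})

test_that("malformed tables are rejected with located errors", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines("id\ts1\ts2", tsv)
  expect_error(read_community_table(tsv), "no samples")

  writeLines(c("id\ts1\ts2", "asv1\t3\t12.5"), tsv)
  expect_error(read_community_table(tsv), "asv1.*s2.*12\\.5")

  writeLines(c("id\ts1", "asv1\t3", "asv1\t4"), tsv)
  expect_error(read_community_table(tsv), "duplicate.*asv1")

  writeLines(c("id\ts1", "asv1\t-2"), tsv)
  expect_error(read_community_table(tsv), "asv1")

  m <- matrix(1, 1, 1, dimnames = list("s1", "t1"))
  expect_error(community_table(rbind(m, m)), "duplicate sample")
  expect_error(community_table(m - 2), "non-negative")
})

test_that("rarefaction preserves depth, identity, and determinism", {
  set.seed(1)
  counts <- matrix(rpois(5 * 20, 40), nrow = 5)
  tab <- make_table(counts)
  depth <- min(rowSums(counts))
  r1 <- rarefy_table(tab, depth, seed = 9)
  expect_true(all(rowSums(r1$counts) == depth))
  expect_identical(colnames(r1$counts), colnames(tab$counts))
  r2 <- rarefy_table(tab, depth, seed = 9)
  expect_identical(r1$counts, r2$counts)

  # a sample whose total equals depth is returned unchanged
  exact <- make_table(matrix(c(3L, 2L), 1, 2))
  expect_identical(rarefy_table(exact, 5, seed = 1)$counts, exact$counts)

  # single-taxon sample keeps all reads in that taxon
  single <- make_table(matrix(c(10L, 0L), 1, 2))
  expect_identical(as.vector(rarefy_table(single, 5, seed = 2)$counts),
                   c(5L, 0L))

  # samples below depth are dropped with a warning; all below is an error
  mixed <- make_table(matrix(c(10L, 2L, 10L, 1L), 2, 2))
  expect_warning(rr <- rarefy_table(mixed, 10, seed = 3), "dropped")
  expect_identical(rownames(rr$counts), "s01")
  expect_error(suppressWarnings(rarefy_table(mixed, 50)), "no samples")
})

test_that("rarefaction matches the hypergeometric expectation", {
  tab <- make_table(matrix(c(6L, 4L), 1, 2))
  a <- vapply(1:400, function(s)
    rarefy_table(tab, 5, seed = s)$counts[1, 1], integer(1))
  # E[A] = 5 * 6/10 = 3; var = 5*.6*.4*(5/9); 3 SE over 400 draws
  expect_lt(abs(mean(a) - 3), 3 * sqrt(5 * 0.6 * 0.4 * 5 / 9 / 400))
})

test_that("rarefaction is permutation-equivariant under canonical column order", {
  canon <- function(tab, depth, seed) {
    o <- order(colnames(tab$counts))
    r <- rarefy_table(community_table(tab$counts[, o, drop = FALSE]),
                      depth, seed = seed)
    r$counts[, colnames(tab$counts), drop = FALSE]
  }
  set.seed(4)
  tab <- make_table(matrix(rpois(3 * 8, 30), nrow = 3))
  perm <- sample(ncol(tab$counts))
  permuted <- community_table(tab$counts[, perm, drop = FALSE])
  expect_identical(canon(permuted, 50, seed = 5),
                   canon(tab, 50, seed = 5)[, colnames(permuted$counts)])
})

test_that("relative abundance normalizes rows and flags empty samples", {
  tab <- make_table(rbind(c(2, 2, 0), c(1, 2, 3)))
  ra <- relative_abundance(tab)
  expect_equal(ra[1, ], c(t01 = 0.5, t02 = 0.5, t03 = 0))
  expect_equal(unname(ra[2, ]), c(1 / 6, 1 / 3, 1 / 2))
  expect_equal(unname(relative_abundance(
    make_table(matrix(c(20000, 0), 1, 2)))[1, ]), c(1, 0))
  empty <- make_table(rbind(c(1, 1), c(0, 0)))
  expect_error(relative_abundance(empty), "s02")
})

test_that("taxonomy subsetting filters columns and composes across ranks", {
  tax <- data.frame(
    phylum = rep(c("P1", "P2"), each = 5),
    class = rep(c("C1", "C2", "C3", "C4", "C5"), each = 2),
    row.names = paste0("t", sprintf("%02d", 1:10)))
  tab <- make_table(matrix(1L, 2, 10), taxonomy = tax)
  sub <- subset_by_rank(tab, "class", "C2")
  expect_identical(colnames(sub$counts), c("t03", "t04"))
  expect_identical(nrow(sub$counts), 2L)

  # chaining a coarse subset before a fine one equals the fine one alone
  chained <- subset_by_rank(subset_by_rank(tab, "phylum", "P1"), "class", "C2")
  expect_identical(chained$counts, sub$counts)

  expect_warning(none <- subset_by_rank(tab, "class", "C99"), "no taxa")
  expect_identical(ncol(none$counts), 0L)
  expect_error(subset_by_rank(tab, "order", "X"), "absent")
  expect_error(subset_by_rank(make_table(matrix(1, 2, 2)), "class", "C1"),
               "no taxonomy")
})
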