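# Data-collection construction: merging, leaves, clustering,
# bipartitions, controls, CpG ratio.

two_tissue_input <- function() {
  list(A = data.frame(chrom = "chr1", start = c(0L, 5000L),
                      end = c(400L, 5200L)),
       B = data.frame(chrom = "chr1", start = c(200L, 9000L),
                      end = c(600L, 9400L)))
}

test_that("intervals sharing a bin merge; disjoint ones do not", {
  tab <- merge_across_tissues(two_tissue_input(), bin_size = 200,
                              element_width = 1000)
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$tissues[[1]], c("A", "B"))  # [0,400)+[200,600)
  expect_equal(tab$tissues[[2]], "A")
  expect_equal(tab$tissues[[3]], "B")
  # non-bin-aligned fallback: >= 1 bp overlap merges
  tab2 <- merge_across_tissues(
    list(A = data.frame(chrom = "chr1", start = 0L, end = 200L),
         B = data.frame(chrom = "chr1", start = 100L, end = 250L)))
  expect_equal(nrow(tab2), 1L)
  # touching but not overlapping stays separate
  tab3 <- merge_across_tissues(
    list(A = data.frame(chrom = "chr1", start = 0L, end = 200L),
         B = data.frame(chrom = "chr1", start = 200L, end = 400L)))
  expect_equal(nrow(tab3), 2L)
})

test_that("merged elements are resized to the element width around centers", {
  tab <- merge_across_tissues(two_tissue_input(), element_width = 1000)
  expect_true(all(tab$end - tab$start == 1000L))
  # merged span [0,600): center 300 -> [-200, 800)
  expect_equal(tab$start[1], -200L)
  expect_equal(tab$end[1], 800L)
  # resize preserves centers (rounding down)
  merged_centers <- c(300L, 5100L, 9200L)
  expect_equal((tab$start + tab$end) %/% 2L, merged_centers)
})

test_that("merging an already-merged table changes nothing", {
  tab <- merge_across_tissues(two_tissue_input(), element_width = 400)
  again <- merge_across_tissues(
    list(A = tab[vapply(tab$tissues, function(t) "A" %in% t, TRUE),
                 c("chrom", "start", "end")],
         B = tab[vapply(tab$tissues, function(t) "B" %in% t, TRUE),
                 c("chrom", "start", "end")]),
    element_width = 400)
  expect_equal(again$start, tab$start)
  expect_equal(again$end, tab$end)
  expect_equal(again$tissues, tab$tissues)
})

make_table <- function(acts, chrom = NULL) {
  n <- length(acts)
  if (is.null(chrom)) chrom <- rep("chr1", n)
  element_table(
    data.frame(chrom = chrom, start = 1000L * seq_len(n),
               end = 1000L * seq_len(n) + 1000L,
               id = sprintf("e%03d", seq_len(n)),
               stringsAsFactors = FALSE),
    tissues = acts)
}

test_that("leaves collection keeps exclusive positives and drops shared ones", {
  tab <- make_table(list("fb", c("fb", "liver"), "liver", "heart",
                         c("liver", "heart")))
  spec <- leaves_collection(tab, "fb")
  expect_equal(spec$id[spec$label == 1], "e001")
  expect_setequal(spec$id[spec$label == 0], c("e003", "e004", "e005"))
  expect_equal(attr(spec, "removed_ids"), "e002")
  expect_error(leaves_collection(tab, "lung"), "not present")
  # partition exhaustiveness
  expect_setequal(c(spec$id, attr(spec, "removed_ids")), tab$id)
})

test_that("tissue similarity counts shared elements symmetrically", {
  tab <- make_table(list(c("A", "B"), c("A", "B"), c("A", "B"), "A", "C"))
  s <- tissue_similarity(tab)
  expect_equal(s["A", "B"], 3L)
  expect_equal(s["B", "A"], 3L)
  expect_equal(s["A", "C"], 0L)
  expect_equal(diag(s), c(A = 4L, B = 3L, C = 1L))
  expect_true(isSymmetric(s))
})

test_that("clustering separates similarity blocks and ignores input order", {
  s <- matrix(c(10, 8, 1, 1,
                8, 10, 1, 1,
                1, 1, 10, 9,
                1, 1, 9, 10), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- cluster_tissues(s)
  cl <- cutree(tr, 2)
  expect_equal(cl[["A"]], cl[["B"]])
  expect_equal(cl[["C"]], cl[["D"]])
  expect_false(cl[["A"]] == cl[["C"]])
  perm <- c("D", "B", "A", "C")
  tr2 <- cluster_tissues(s[perm, perm])
  expect_identical(cophenetic(tr), cophenetic(tr2))
  expect_error(cluster_tissues(s[1, 1, drop = FALSE]), "at least two")
})

test_that("a 3-leaf tree yields the single inner-edge bipartition", {
  s <- matrix(c(10, 9, 1,
                9, 10, 1,
                1, 1, 10), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tab <- make_table(list("A", "B", "C", c("A", "C"), c("A", "B")))
  coll <- clustered_collection(cluster_tissues(s), tab)
  expect_length(coll, 1L)
  bp <- coll[[1]]$bipartition
  # the single inner edge splits {A,B} from {C}; the smaller side is
  # labeled positive
  expect_setequal(bp$positive, "C")
  expect_setequal(bp$negative, c("A", "B"))
  spec <- coll[[1]]$spec
  # {A,C} element straddles the bipartition and is removed
  expect_equal(attr(spec, "removed_ids"), "e004")
  expect_setequal(spec$id[spec$label == 0], c("e001", "e002", "e005"))
  expect_equal(spec$id[spec$label == 1], "e003")
})

test_that("an 8-tissue tree yields the expected bipartitions, smaller side positive", {
  tissues <- c("forebrain", "heart", "hindbrain", "kidney", "limb",
               "liver", "lung", "midbrain")
  # block similarity: brain trio; kidney+lung pair joined by heart;
  # liver most dissimilar
  s <- matrix(1L, 8, 8, dimnames = list(tissues, tissues))
  diag(s) <- 100L
  set_s <- function(a, b, v) {
    s[a, b] <<- v; s[b, a] <<- v
  }
  set_s("midbrain", "hindbrain", 80L)
  set_s("forebrain", "midbrain", 60L); set_s("forebrain", "hindbrain", 60L)
  set_s("kidney", "lung", 70L)
  set_s("heart", "kidney", 40L); set_s("heart", "lung", 40L)
  set_s("limb", "heart", 20L); set_s("limb", "kidney", 20L)
  set_s("limb", "lung", 20L)
  for (t in setdiff(tissues, "liver")) set_s("liver", t, 0L)
  tr <- cluster_tissues(s)
  tab <- make_table(as.list(tissues))
  coll <- clustered_collection(tr, tab)
  pos_sets <- lapply(coll, function(e) sort(e$bipartition$positive))
  expect_true(list(c("kidney", "lung")) %in% pos_sets ||
                any(vapply(pos_sets, identical, TRUE, c("kidney", "lung"))))
  expect_true(any(vapply(pos_sets, identical, TRUE,
                         c("hindbrain", "midbrain"))))
  expect_true(any(vapply(pos_sets, identical, TRUE,
                         c("forebrain", "hindbrain", "midbrain"))))
  expect_true(any(vapply(pos_sets, identical, TRUE, "liver")))
  # every bipartition puts the smaller set positive and is unique
  for (e in coll) {
    expect_lte(length(e$bipartition$positive),
               length(e$bipartition$negative))
    expect_length(intersect(e$bipartition$positive,
                            e$bipartition$negative), 0)
  }
  expect_equal(anyDuplicated(vapply(
    pos_sets, paste, "", collapse = ",")), 0L)
})

test_that("bipartition datasets partition the elements exhaustively", {
  set.seed(31)
  tissues <- c("A", "B", "C", "D")
  acts <- replicate(60, sample(tissues, sample(1:3, 1)), simplify = FALSE)
  tab <- make_table(acts)
  s <- tissue_similarity(tab)
  coll <- clustered_collection(cluster_tissues(s), tab)
  for (e in coll) {
    spec <- e$spec
    expect_length(intersect(spec$id[spec$label == 1],
                            spec$id[spec$label == 0]), 0)
    expect_setequal(c(spec$id, attr(spec, "removed_ids")), tab$id)
  }
})

test_that("a leaf's one-vs-rest dataset matches its clustered bipartition", {
  s <- matrix(c(10, 9, 1,
                9, 10, 1,
                1, 1, 10), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tab <- make_table(list("A", "B", "C", c("A", "C"), "C", c("B", "C")))
  coll <- clustered_collection(cluster_tissues(s), tab)
  # the single inner edge is {C} (positive) vs {A,B}; that bipartition
  # is exactly the one-vs-rest dataset of leaf C
  spec_cl <- coll[[1]]$spec
  spec_lv <- leaves_collection(tab, "C")
  expect_setequal(spec_lv$id[spec_lv$label == 1],
                  spec_cl$id[spec_cl$label == 1])
  expect_setequal(spec_lv$id[spec_lv$label == 0],
                  spec_cl$id[spec_cl$label == 0])
  expect_setequal(attr(spec_lv, "removed_ids"),
                  attr(spec_cl, "removed_ids"))
})

test_that("enhancer-vs-random uses equal-size width-matched negatives", {
  sim <- small_sim(seed = 21, n_per = 15, L = 200)
  spec <- enhancer_vs_random(sim$elements, sim$genome, seed = 4)
  expect_equal(sum(spec$label == 0), sum(spec$label == 1))
  expect_equal(sum(spec$label == 1), nrow(sim$elements))
  neg <- spec[spec$label == 0, ]
  expect_true(all(neg$end - neg$start == 200L))
  expect_equal(spec$id[spec$label == 1], sim$elements$id)
  spec2 <- enhancer_vs_random(sim$elements, sim$genome, seed = 5)
  expect_false(identical(spec2$start[spec2$label == 0], neg$start))
})

test_that("chromosome control labels by the positive chromosome list", {
  tab <- make_table(list("A", "B", "A", "B"),
                    chrom = c("chr3", "chr1", "chr19", "chrX"))
  spec <- chromosome_control(tab)
  expect_equal(spec$label[match(c("e001", "e003"), spec$id)], c(1, 1))
  expect_equal(spec$label[match(c("e002", "e004"), spec$id)], c(0, 0))
  expect_length(attr(spec, "removed_ids"), 0)
})

test_that("CpG observed-to-expected ratio matches hand counts", {
  expect_equal(cpg_ratio("cgcg"), 2)
  expect_equal(cpg_ratio("acgt"), 4)
  expect_true(is.na(cpg_ratio("aaaa")))
  expect_true(is.na(cpg_ratio("cccc")))  # no g
  expect_equal(cpg_ratio(c("cgcg", "acgt")), c(2, 4))
})

test_that("datasets built from specs carry features, labels and coordinates", {
  sim <- small_sim(seed = 22, n_per = 12, L = 120, mu = 0)
  sp <- codeword_space(4, 4)
  spec <- leaves_collection(sim$elements, "liver")
  ds <- build_dataset(spec, sim$genome, sp, mode = "occurrence")
  expect_s3_class(ds, "klr_dataset")
  expect_equal(nrow(ds$x), nrow(spec))
  expect_equal(ds$y, spec$label)
  expect_equal(ds$chrom, spec$chrom)
  seqs <- element_sequences(spec, sim$genome)
  expect_equal(unname(nchar(seqs)), rep(120L, nrow(spec)))
})
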