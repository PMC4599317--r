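# Region classification, state assignment, interaction counting and the
# enrichment statistics.

test_that("region classification follows the promoter/body/ambiguous rules", {
  genes <- toy_genes()  # geneA + strand TSS 10000, geneB - strand TSS 60000
  probes <- data.frame(
    probe_id = c("upstream", "edge_in", "edge_out", "body_only",
                 "amb", "far"),
    chrom = "chr1",
    pos = c(8600L,    # 1400 bp upstream of geneA TSS, outside the body
            8500L,    # exactly 1500 bp away: still promoter
            8499L,    # 1501 bp away: not promoter
            15000L,   # inside geneA body, 5000 bp from its TSS
            59000L,   # inside geneB body and 1000 bp from its TSS
            200000L))
  cls <- classify_region(probes, genes)
  got <- setNames(cls$class, cls$probe_id)
  expect_equal(unname(got[c("upstream", "edge_in", "edge_out")]),
               c("promoter", "promoter", "intergenic"))
  expect_equal(unname(got["body_only"]), "gene_body")
  expect_equal(unname(got["amb"]), "ambiguous")
  expect_equal(unname(got["far"]), "intergenic")

  g2 <- genes; g2$strand <- c("+", "*")
  expect_error(classify_region(probes, g2), "strand")
})

test_that("region classes partition simulated probes and match ground truth", {
  cfg <- sim_pairs_config(30, n_samples = 20, seed = 71)
  ann_fix <- gen_annotation(cfg, tissues = "pbmc")
  cls <- classify_region(cfg$probe_specs, ann_fix$genes)
  expect_equal(nrow(cls), nrow(cfg$probe_specs))
  expect_equal(sum(table(factor(cls$class,
                                c("promoter", "gene_body",
                                  "intergenic", "ambiguous")))),
               nrow(cfg$probe_specs))
  expect_equal(setNames(cls$class, cls$probe_id)[names(ann_fix$truth$region_class)],
               ann_fix$truth$region_class)
})

test_that("state assignment respects the half-open BED convention and input order", {
  seg_bed <- data.frame(chrom = "chr1", start0 = c(0L, 100L, 200L),
                        end0 = c(100L, 200L, 300L),
                        category = c("enhancer", "tss", "quiescent"))
  path <- withr::local_tempfile(fileext = ".bed")
  write.table(seg_bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  seg <- read_bed4(path)
  probes <- data.frame(probe_id = c("p100", "p101", "p201"), chrom = "chr1",
                       pos = c(100L, 101L, 201L))
  st <- assign_state(probes, list(t1 = seg))
  expect_equal(st$category, c("enhancer", "tss", "quiescent"))
  # interval order in the file is irrelevant
  st2 <- assign_state(probes, list(t1 = seg[c(3, 1, 2), ]))
  expect_equal(st2$category, st$category)
  # positions beyond the tiling are reported uncovered
  st3 <- assign_state(data.frame(probe_id = "far", chrom = "chr1",
                                 pos = 5000L), list(t1 = seg))
  expect_equal(st3$status, "uncovered")
  # state-labelled segmentations need a complete map
  seg_lab <- transform(seg, state = c("E7", "E1", "E18"), category = NULL)
  expect_error(assign_state(probes, list(t1 = seg_lab)), "map required")
  expect_error(assign_state(probes, list(t1 = seg_lab),
                            c(E7 = "enhancer", E1 = "tss")), "unmapped")
  st4 <- assign_state(probes, list(t1 = seg_lab),
                      c(E7 = "enhancer", E1 = "tss", E18 = "quiescent"))
  expect_equal(st4$category, st$category)
})

test_that("simulated state tilings are recovered exactly per tissue", {
  cfg <- sim_pairs_config(25, n_samples = 20, seed = 72)
  ann_fix <- gen_annotation(cfg, tissues = c("pbmc", "liver"))
  st <- assign_state(cfg$probe_specs, ann_fix$states)
  for (ti in c("pbmc", "liver")) {
    v <- st[st$tissue == ti, ]
    expect_equal(setNames(v$category, v$probe_id),
                 setNames(ann_fix$truth$state_category[, ti],
                          cfg$probe_specs$probe_id))
  }
})

test_that("interaction counting tallies anchor overlaps and promoter partners", {
  probes <- data.frame(probe_id = c("hit", "miss"), chrom = "chr1",
                       pos = c(1000L, 90000L))
  anchors <- data.frame(
    chrom1 = "chr1", start1 = c(900L, 950L, 800L, 5000L),
    end1 = c(1100L, 1050L, 1200L, 5100L),
    chrom2 = "chr1", start2 = c(30000L, 40000L, 9000L, 50000L),
    end2 = c(30400L, 40400L, 9400L, 50400L))
  ic <- count_interactions(probes, anchors)
  expect_equal(ic$n_interactions[ic$probe_id == "hit"], 3)
  expect_equal(ic$n_interactions[ic$probe_id == "miss"], 0)

  # partner anchor covering TSS +/- 1500 of geneA (TSS 10000) sets the flag
  ic2 <- count_interactions(probes, anchors, genes = toy_genes())
  expect_true(ic2$promoter_interaction[ic2$probe_id == "hit"])
  expect_false(ic2$promoter_interaction[ic2$probe_id == "miss"])

  bad <- anchors; bad$end1[2] <- bad$start1[2] - 1
  expect_error(count_interactions(probes, bad), "row 2")
})

test_that("planted interaction pairs round-trip through BEDPE and counting", {
  cfg <- sim_pairs_config(8, n_samples = 20, seed = 73)
  k <- c(cg000002 = 4L, cg000005 = 1L)
  ann_fix <- gen_annotation(cfg, tissues = "pbmc", interaction_counts = k)
  path <- withr::local_tempfile(fileext = ".bedpe")
  write_bedpe(ann_fix$interactions, path)
  anchors <- read_bedpe(path)
  ic <- count_interactions(cfg$probe_specs, anchors, ann_fix$genes)
  expect_equal(setNames(ic$n_interactions, ic$probe_id)[names(k)],
               setNames(as.integer(k), names(k)))
  # pairs planted with a promoter partner are flagged
  expect_true(all(ic$promoter_interaction[ic$probe_id %in% names(k)]))
})

test_that("Fisher enrichment equals hypergeometric enumeration", {
  # complete separation: p = 2 / C(10,5)
  memb <- setNames(rep(c(TRUE, FALSE), each = 5), paste0("p", 1:10))
  res <- fisher_enrichment(paste0("p", 1:5), paste0("p", 1:10), memb)
  expect_equal(res$p_value, 2 / choose(10, 5), tolerance = 1e-12)
  expect_equal(res$odds_ratio, Inf)

  # proportionally identical membership: OR 1, p 1
  memb2 <- setNames(rep(c(TRUE, FALSE), 10), paste0("p", 1:20))
  res2 <- fisher_enrichment(paste0("p", 1:4), paste0("p", 1:20), memb2)
  expect_equal(res2$p_value, 1)
  expect_equal(res2$odds_ratio, 1)

  # zero margin: degenerate table, p = 1
  memb3 <- setNames(rep(FALSE, 10), paste0("p", 1:10))
  expect_equal(fisher_enrichment(paste0("p", 1:3), paste0("p", 1:10),
                                 memb3)$p_value, 1)

  # random tables against the enumeration oracle
  set.seed(81)
  for (i in 1:50) {
    a <- sample(0:12, 1); b <- sample(0:12, 1)
    c_ <- sample(0:12, 1); d <- sample(0:12, 1)
    if (a + b == 0 || a + c_ == 0) next
    n_assoc <- a + b
    ids <- paste0("q", seq_len(a + b + c_ + d))
    memb_i <- setNames(c(rep(TRUE, a), rep(FALSE, b),
                         rep(TRUE, c_), rep(FALSE, d)), ids)
    r <- fisher_enrichment(ids[seq_len(n_assoc)], ids, memb_i)
    expect_equal(r$p_value, fisher_enum_p(a, b, c_, d), tolerance = 1e-9)
  }
  expect_error(fisher_enrichment(character(), paste0("p", 1:3), memb3),
               "empty")
})

test_that("enrichment is symmetric under complementing the category", {
  set.seed(82)
  ids <- paste0("p", 1:40)
  memb <- setNames(runif(40) < 0.4, ids)
  assoc <- sample(ids, 12)
  r1 <- fisher_enrichment(assoc, ids, memb)
  r2 <- fisher_enrichment(assoc, ids, !memb)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
  expect_equal(r1$odds_ratio, 1 / r2$odds_ratio, tolerance = 1e-12)
})

test_that("the overlapping-background variant uses all tested probes", {
  ids <- paste0("p", 1:20)
  memb <- setNames(rep(c(TRUE, FALSE), 10), ids)
  assoc <- ids[1:6]
  r <- fisher_enrichment(assoc, ids, memb, background = "all_tested")
  expect_equal(r$n_bg_in + r$n_bg_out, 20)
  rd <- fisher_enrichment(assoc, ids, memb)
  expect_equal(rd$n_bg_in + rd$n_bg_out, 14)
})

test_that("Mann-Whitney comparison matches exact enumeration for small samples", {
  # identical multisets: no evidence at all
  expect_equal(compare_interaction_counts(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  # complete separation with n1 = n2 = 3: 2 of 20 labelings as extreme
  r <- compare_interaction_counts(c(1, 2, 3), c(10, 11, 12))
  expect_equal(r$p_value, 0.1)
  expect_equal(r$method, "exact permutation")

  set.seed(83)
  for (i in 1:30) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- sample(0:4, n1, replace = TRUE)  # skewed, tied counts
    y <- sample(0:4, n2, replace = TRUE)
    got <- compare_interaction_counts(x, y)
    expect_equal(got$p_value, mw_enum_p(x, y), tolerance = 1e-12)
  }
  expect_error(compare_interaction_counts(numeric(), 1:3), "nonempty")
})

test_that("the large-sample Mann-Whitney approximation is calibrated under the null", {
  set.seed(84)
  ps <- replicate(400, {
    x <- rpois(25, 3); y <- rpois(30, 3)
    compare_interaction_counts(x, y)$p_value
  })
  frac <- mean(ps < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 400) + 0.01)
})

test_that("probe annotation combines all layers consistently", {
  cfg <- sim_pairs_config(10, n_samples = 20, seed = 74)
  fx <- gen_annotation(cfg, tissues = "pbmc",
                       interaction_counts = c(cg000003 = 2))
  ann <- annotate_probes(cfg$probe_specs, fx$genes, fx$states,
                         fx$interactions, fx$enhancers)
  expect_equal(nrow(ann), nrow(cfg$probe_specs))
  expect_true(all(c("class", "state_pbmc", "n_interactions",
                    "in_enhancer") %in% names(ann)))
  expect_equal(ann$n_interactions[ann$probe_id == "cg000003"], 2)
  # enhancer flag agrees with the tissue-1 state assignment
  expect_equal(ann$in_enhancer, ann$state_pbmc == "enhancer")
})
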