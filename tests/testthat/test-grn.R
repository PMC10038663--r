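test_that("chip_epoch maps network time points onto ChIP epochs", {
  expect_equal(chip_epoch(0), 5)
  expect_equal(chip_epoch(1), 5)
  expect_equal(chip_epoch(3), 5)
  expect_equal(chip_epoch(5), 5)
  expect_equal(chip_epoch(7), 9)
  expect_equal(chip_epoch(9), 9)
  expect_equal(chip_epoch(12), 12)
  expect_error(chip_epoch(4), "unknown")
})

test_that("edge_sign implements the rule table in both modes", {
  # activation sites: co-regulation positive, opposition negative
  expect_equal(edge_sign("up", "up", "activation"), "positive")
  expect_equal(edge_sign("down", "down", "activation"), "positive")
  expect_equal(edge_sign("up", "down", "activation"), "negative")
  expect_equal(edge_sign("down", "up", "activation"), "negative")
  # repression sites: reversed
  expect_equal(edge_sign("up", "up", "repression"), "negative")
  expect_equal(edge_sign("up", "down", "repression"), "positive")
  # unexpressed regulator or unchanged target: no interaction
  expect_true(is.na(edge_sign("none", "up", "activation")))
  expect_true(is.na(edge_sign("none", "up", "repression")))
  expect_true(is.na(edge_sign("up", "none", "activation")))
})

mk_profile <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(gene = r[[1]], time = as.numeric(r[[2]]), direction = r[[3]],
               stringsAsFactors = FALSE)))
}

test_that("infer_edges_at applies the temporal gate", {
  sh <- data.frame(target_gene = "T1", site_id = "s1",
                   site_class = "activation", tf_gene = "R1",
                   stringsAsFactors = FALSE)
  # regulator called at t
  p1 <- mk_profile(list("R1", 5, "up"), list("T1", 5, "up"))
  e1 <- infer_edges_at(5, p1, sh)
  expect_equal(e1$sign, "positive")
  # regulator called only at the preceding time point ("just before")
  p2 <- mk_profile(list("R1", 3, "up"), list("R1", 5, "none"),
                   list("T1", 5, "down"))
  e2 <- infer_edges_at(5, p2, sh)
  expect_equal(e2$sign, "negative")
  # regulator none at t and t-1 -> no edge
  p3 <- mk_profile(list("R1", 1, "up"), list("T1", 5, "up"))
  expect_equal(nrow(infer_edges_at(5, p3, sh)), 0)
  # target none -> no edge even with active regulator
  p4 <- mk_profile(list("R1", 5, "up"), list("T1", 5, "none"))
  expect_equal(nrow(infer_edges_at(5, p4, sh)), 0)
})

test_that("dedup_edges is unique on (regulator,target,sign,time) and unions sites", {
  e <- data.frame(regulator = c("R", "R", "R", "R"),
                  target = c("T", "T", "T", "T"),
                  sign = c("positive", "positive", "positive", "negative"),
                  time = c(5, 5, 9, 5),
                  site_id = c("s1", "s2", "s1", "s1"),
                  stringsAsFactors = FALSE)
  d <- dedup_edges(e)
  expect_equal(nrow(d), 3)  # (+,5h) collapsed; (+,9h) and (-,5h) kept
  expect_equal(d$sites[d$sign == "positive" & d$time == 5], "s1,s2")
  expect_equal(dedup_edges(d), d)  # idempotent
})

test_that("prune_isolated keeps self-loops, removes unconnected, idempotent", {
  edges <- data.frame(regulator = c("A", "B"), target = c("A", "C"),
                      sign = "positive", time = 5, sites = "s",
                      stringsAsFactors = FALSE)
  grn <- structure(list(edges = edges, genes = c("A", "B", "C", "D"),
                        profile = NULL, time_points = c(5),
                        pruned = character()), class = "timed_grn")
  p <- prune_isolated(grn)
  expect_equal(sort(p$genes), c("A", "B", "C"))  # self-loop keeps A
  expect_equal(p$pruned, "D")
  expect_equal(prune_isolated(p)$genes, p$genes)
})

test_that("build_subnetwork merges sites across epochs and gates inputs", {
  # two site instances 400 bp apart at 5h and 9h -> one merged node;
  # a distant site active at 9h and 12h only
  sites <- data.frame(chrom = "chr1",
                      start = c(1000L, 1640L, 5000L, 5000L),
                      end = c(1240L, 1880L, 5240L, 5240L),
                      chip_time = c(5, 9, 9, 12),
                      index = c(1L, 1L, 2L, 7L),
                      category = c("activation", "activation", "activation",
                                   "poised"),
                      site_id = c("a5", "b9", "c9", "c12"),
                      stringsAsFactors = FALSE)
  hits <- data.frame(site_id = c("a5", "b9", "c9", "c12"),
                     tf_gene = "R1", stringsAsFactors = FALSE)
  profile <- mk_profile(list("R1", 5, "up"), list("R1", 7, "up"),
                        list("R1", 9, "up"), list("R1", 12, "up"),
                        list("TGT", 5, "up"), list("TGT", 7, "up"),
                        list("TGT", 9, "up"), list("TGT", 12, "up"))
  sub <- build_subnetwork("TGT", sites, hits, profile)
  expect_equal(nrow(sub$nodes), 2)  # 1000-1880 merged (gap 400 <= 500)
  expect_equal(sub$nodes$node, c("TGT_site1", "TGT_site2"))
  # node 2 (5000-5240) has no inputs at 5h epochs (active only at 9, 12)
  n2 <- sub$edges[sub$edges$node == "TGT_site2", ]
  expect_false(any(n2$time %in% c(0, 1, 3, 5)))
  expect_true(all(c(7, 9, 12) %in% n2$time))
  # node 1 receives its 5h-epoch inputs
  n1 <- sub$edges[sub$edges$node == "TGT_site1", ]
  expect_true(5 %in% n1$time)
  expect_true(all(sub$edges$sign == "positive"))
  # activity table records the per-epoch states
  expect_equal(sub$activity$index[sub$activity$node == "TGT_site2"],
               c(2L, 7L))
})

test_that("repression-mode subnetwork reverses signs and gates on expression", {
  sites <- data.frame(chrom = "chr1", start = 1000L, end = 1240L,
                      chip_time = 5, index = 4L, category = "repression",
                      site_id = "r5", stringsAsFactors = FALSE)
  hits <- data.frame(site_id = "r5", tf_gene = "R1",
                     stringsAsFactors = FALSE)
  profile <- mk_profile(list("R1", 5, "up"), list("TGT", 5, "up"))
  sub <- build_subnetwork("TGT", sites, hits, profile)
  expect_equal(sub$edges$sign[sub$edges$time == 5], "negative")
  # regulator not expressed -> no interaction at a repressed site
  profile2 <- mk_profile(list("R1", 5, "none"), list("TGT", 5, "up"))
  sub2 <- build_subnetwork("TGT", sites, hits, profile2)
  expect_equal(nrow(sub2$edges), 0)
})

test_that("BioTapestry export round-trips, including the empty network", {
  res <- zero_noise_result()
  grn <- res$grn
  csv <- tempfile(fileext = ".csv"); xml <- tempfile(fileext = ".xml")
  export_biotapestry(grn, csv, xml)
  back <- parse_biotapestry_csv(csv)
  expect_equal(sort(back$nodes), sort(grn$genes))
  got <- back$edges[order(back$edges$time, back$edges$regulator,
                          back$edges$target, back$edges$sign), ]
  want <- grn$edges[order(grn$edges$time, grn$edges$regulator,
                          grn$edges$target, grn$edges$sign),
                    c("regulator", "target", "sign", "time")]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)
  xm <- parse_biotapestry_xml(xml)
  prof <- grn$profile[grn$profile$gene %in% grn$genes,
                      c("gene", "time", "direction")]
  xm <- xm[order(xm$gene, xm$time), ]; prof <- prof[order(prof$gene,
                                                          prof$time), ]
  rownames(xm) <- rownames(prof) <- NULL
  expect_equal(xm, prof)

  # empty network -> valid header-only files
  empty <- structure(list(edges = grn$edges[0, ], genes = character(),
                          profile = grn$profile[0, ],
                          time_points = grn$time_points,
                          pruned = character()), class = "timed_grn")
  export_biotapestry(empty, csv, xml)
  back2 <- parse_biotapestry_csv(csv)
  expect_equal(nrow(back2$edges), 0)
  expect_equal(nrow(parse_biotapestry_xml(xml)), 0)

  # single positive edge -> one enhance link row
  one <- empty
  one$genes <- c("A", "B")
  one$edges <- data.frame(regulator = "A", target = "B", sign = "positive",
                          time = 5, sites = "s", stringsAsFactors = FALSE)
  export_biotapestry(one, csv, xml)
  lines <- readLines(csv)
  expect_equal(sum(grepl("^link", lines)), 1)
  expect_match(lines[grepl("^link", lines)], "enhance")
})

test_that("BED export round-trips and orders deterministically", {
  iv <- data.frame(chrom = c("chr2", "chr1"), start = c(100L, 100L),
                   end = c(200L, 200L), name = c("b", "a"),
                   score = c(1, 2), strand = c("+", "-"))
  f <- tempfile(fileext = ".bed")
  export_bed(iv, f, "t")
  back <- read_bed(f)
  expect_equal(back$chrom, c("chr1", "chr2"))  # sorted
  expect_equal(back$start, c(100L, 100L))
  expect_equal(back$name, c("a", "b"))
  expect_equal(readLines(f)[1], 'track name="t"')
  export_bed(iv[0, ], f, "empty")
  expect_equal(length(readLines(f)), 1)  # header-only
  expect_equal(nrow(read_bed(f)), 0)
})
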