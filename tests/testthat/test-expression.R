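test_that("classify_fpkm applies the fold-change and abundance rules", {
  expect_equal(classify_fpkm(20, 10), "up")      # FC = 2
  expect_equal(classify_fpkm(9, 3), "none")      # abundance gate fails
  expect_equal(classify_fpkm(5, 20), "down")     # FC = 0.25, uninduced > 10
  expect_equal(classify_fpkm(15, 10), "none")    # FC = 1.5 not > 1.5
  expect_equal(classify_fpkm(20, 0), "up")       # zero denominator -> +Inf
  expect_equal(classify_fpkm(5, 0), "none")      # +Inf never takes down path
  expect_error(classify_fpkm(-1, 5), "non-negative")
})

test_that("abundance gate is monotone: joint scaling never flips up<->down", {
  set.seed(11)
  ind <- runif(300, 0, 40)
  unind <- runif(300, 0, 40)
  base <- classify_fpkm(ind, unind)
  for (c_mul in c(1.5, 3, 10)) {
    scaled <- classify_fpkm(c_mul * ind, c_mul * unind)
    flip <- (base == "up" & scaled == "down") |
      (base == "down" & scaled == "up")
    expect_false(any(flip))
  }
})

test_that("classify_time_zero requires all four clauses", {
  expect_equal(classify_time_zero(30, 10, 20), "up")
  expect_equal(classify_time_zero(30, 25, 20), "none")  # unind_5 < ind_5
  expect_equal(classify_time_zero(8, 2, 20), "none")    # abundance gate
  expect_equal(classify_time_zero(30, 0, 20), "up")     # ratio -> +Inf
  expect_equal(classify_time_zero(30, 10, 9), "none")   # unind_5 <= 10
})

test_that("select_candidates applies the probe-set thresholds", {
  expect_equal(select_candidates(1.5, 0.01, 100, 10), "up-candidate")
  expect_equal(select_candidates(-2, 0.01, 5, 300), "down-candidate")
  expect_equal(select_candidates(1.5, 0.2, 100, 10), "rejected")
  expect_equal(select_candidates(1.1, 0.01, 100, 10), "rejected")
  expect_equal(select_candidates(1.2, 0.01, 44, 10), "rejected")
  expect_equal(select_candidates(-1.2, 0.01, 5, 199), "rejected")
})

make_assay <- function(assay, pos, neg, hk, endo, fov = 600, bd = 1) {
  data.frame(assay = assay,
             probe = c(sprintf("P%d", seq_along(pos)),
                       sprintf("N%d", seq_along(neg)),
                       sprintf("H%d", seq_along(hk)),
                       sprintf("E%d", seq_along(endo))),
             class = rep(c("positive", "negative", "housekeeping",
                           "endogenous"),
                         c(length(pos), length(neg), length(hk),
                           length(endo))),
             count = c(pos, neg, hk, endo), fields_of_view = fov,
             binding_density = bd, stringsAsFactors = FALSE)
}

test_that("nanostring_normalize matches the hand-computed 3-lane oracle", {
  # positives with geomeans 100, 200, 400; flat negatives 10; HK 1000;
  # one endogenous probe at 500 in every lane
  tab <- rbind(make_assay("L1", rep(100, 6), rep(10, 8), rep(1000, 2), 500),
               make_assay("L2", rep(200, 6), rep(10, 8), rep(1000, 2), 500),
               make_assay("L3", rep(400, 6), rep(10, 8), rep(1000, 2), 500))
  r <- nanostring_normalize(tab)
  avg <- (100 + 200 + 400) / 3                      # arithmetic mean, 233.33
  expect_equal(unname(r$plnf), avg / c(100, 200, 400))
  # HK geomeans post-PLNF are 1000*plnf; LSNF = mean(plnf)/plnf
  expect_equal(unname(r$lsnf), mean(avg / c(100, 200, 400)) /
                 (avg / c(100, 200, 400)))
  # combined factor is identical across lanes: plnf*lsnf = mean(plnf)
  combined <- mean(avg / c(100, 200, 400))
  expect_equal(unname(r$background), rep(10 * combined, 3))  # sd = 0
  expect_equal(unname(r$endogenous["E1", ]),
               rep(500 * combined - 10 * combined, 3))
})

test_that("nanostring_normalize degenerate and QC paths", {
  tab <- rbind(make_assay("L1", rep(100, 6), rep(10, 8), rep(1000, 2),
                          c(500, 12, 5)),
               make_assay("L2", rep(100, 6), rep(10, 8), rep(1000, 2),
                          c(500, 12, 5)))
  r <- nanostring_normalize(tab)
  expect_equal(unname(r$plnf), c(1, 1))
  expect_equal(unname(r$lsnf), c(1, 1))
  # output = input - background (10), clipped at 0, zeros -> 1
  expect_equal(unname(r$endogenous[, "L1"]), c(490, 2, 1))

  # doubling one lane: its normalized counts equal the unscaled lane's
  tab2 <- tab
  tab2$count[tab2$assay == "L2"] <- tab2$count[tab2$assay == "L2"] * 2
  r2 <- nanostring_normalize(tab2)
  expect_equal(r2$endogenous[, "L2"], r2$endogenous[, "L1"])

  # QC: wrong fields_of_view excludes the assay
  tab3 <- rbind(tab, make_assay("L3", rep(100, 6), rep(10, 8),
                                rep(1000, 2), c(500, 12, 5), fov = 599))
  expect_message(r3 <- nanostring_normalize(tab3), "QC")
  expect_equal(r3$excluded$assay, "L3")
  expect_false("L3" %in% colnames(r3$endogenous))

  # zero positive count -> zero geomean -> error
  tab4 <- tab
  tab4$count[tab4$assay == "L1" & tab4$probe == "P1"] <- 0
  expect_error(nanostring_normalize(tab4), "geometric mean")
})

test_that("nanostring_de matches the pooled-variance t oracle", {
  # identical triplicates both sides
  r <- nanostring_de(c(100, 100, 100), c(100, 100, 100))
  expect_equal(r$fc, 1)
  expect_equal(r$direction, "none")
  # zero variance, unequal means: p -> 0 by convention, direction up
  r <- nanostring_de(c(100, 100, 100), c(50, 50, 50))
  expect_equal(r$fc, 2)
  expect_equal(r$p, 0)
  expect_equal(r$direction, "up")
  # hand-computed pooled t: means 120 vs 100, s1^2=100, s2^2=25
  r <- nanostring_de(c(120, 130, 110), c(100, 95, 105))
  sp2 <- (2 * 100 + 2 * 25) / 4
  t_stat <- 20 / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(r$p, 2 * pt(-t_stat, df = 4))
  expect_equal(r$fc, 1.2)
  expect_equal(r$direction, "up")
  # zero uninduced mean -> FC +Inf
  r <- nanostring_de(c(10, 12, 11), c(0, 0, 0))
  expect_equal(r$fc, Inf)
  expect_error(nanostring_de(100, c(1, 2)), "replicates")
})

test_that("integrate_platforms keeps non-contradictory genes and merges calls", {
  rna <- data.frame(gene = rep(c("A", "B", "C"), each = 4),
                    time = rep(c(0, 5, 9, 12), 3),
                    direction = c("none", "up", "up", "up",
                                  "none", "none", "up", "up",
                                  "none", "up", "up", "up"))
  nano <- data.frame(gene = rep(c("A", "B", "C"), each = 6),
                     time = rep(c(1, 3, 5, 7, 9, 12), 3),
                     direction = c("none", "up", "up", "up", "up", "up",
                                   "none", "none", "none", "up", "down", "up",
                                   "none", "none", "none", "none", "none",
                                   "none"))
  r <- integrate_platforms(rna, nano)
  # B contradicts at 9h (rnaseq up vs nanostring down) -> dropped
  expect_equal(r$dropped$gene, "B")
  expect_match(r$dropped$reason, "9h")
  # A retained; profile takes rnaseq at 0/5/9/12 and nanostring at 1/3/7
  a <- r$profile[r$profile$gene == "A", ]
  expect_equal(a$time, c(0, 1, 3, 5, 7, 9, 12))
  expect_equal(a$platform,
               c("rnaseq", "nanostring", "nanostring", "rnaseq",
                 "nanostring", "rnaseq", "rnaseq"))
  expect_equal(a$direction[a$time == 3], "up")
  # C: nonzero rnaseq against none nanostring is not a contradiction
  expect_true("C" %in% r$profile$gene)
  # never invents a direction absent from both platforms
  cc <- r$profile[r$profile$gene == "C", ]
  expect_true(all(cc$direction[cc$time %in% c(1, 3, 7)] == "none"))
})

test_that("profile_direction falls back to none for unknown entries", {
  prof <- data.frame(gene = "A", time = 5, direction = "up")
  expect_equal(profile_direction(prof, "A", 5), "up")
  expect_equal(profile_direction(prof, "A", 9), "none")
  expect_equal(profile_direction(prof, "Z", 5), "none")
})
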